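## HOMER-style peak annotation: each peak gets exactly one region label,
## decided by its midpoint with a configurable precedence order.

DEFAULT_PRECEDENCE <- c("3UTR", "5UTR", "exon", "TSS", "TTS", "intron",
                        "intergenic")

#' Annotate peaks with gene regions
#'
#' Assigns every peak exactly one region label from the vocabulary
#' 3'UTR / 5'UTR / exon / TSS / TTS / intron / intergenic. The label is
#' decided by the peak midpoint; where the midpoint lies in several regions
#' the first label in `precedence` wins.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param regions Labelled region tibble from [derive_regions()].
#' @param precedence Character vector ordering the labels (highest first).
#' @return `peaks` with an added `region` column.
#' @export
annotate_peaks_regions <- function(peaks, regions,
                                   precedence = DEFAULT_PRECEDENCE) {
  if (!nrow(peaks)) return(mutate(peaks, region = character(0)))
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2
  lab <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hit <- regions$region[regions$chrom == peaks$chrom[i] &
                          regions$start <= mid[i] & regions$end > mid[i]]
    hit <- c(hit, "intergenic")
    lab[i] <- precedence[min(match(hit, precedence), na.rm = TRUE)]
  }
  mutate(peaks, region = lab)
}

#' Region distribution of annotated peaks
#'
#' @param annotated Peaks with a `region` column (and optionally grouping
#'   columns such as `condition` or `subtype`).
#' @param by Character vector of grouping column names (default none).
#' @return Tibble of per-group region counts and proportions; proportions
#'   sum to 1 within each group. Empty groups are dropped with a warning.
#' @export
region_distribution <- function(annotated, by = character(0)) {
  if (!nrow(annotated)) {
    warning("region_distribution: empty peak set")
    return(tibble(region = character(), n = integer(),
                  proportion = double()))
  }
  annotated |>
    group_by(across(dplyr::all_of(c(by, "region")))) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Per-chromosome peak counts
#'
#' @param peaks Peak tibble with a `chrom` column.
#' @return Tibble `chrom`, `n`; counts sum to the number of peaks.
#' @export
chromosome_distribution <- function(peaks) {
  if (!nrow(peaks)) return(tibble(chrom = character(), n = integer()))
  peaks |> count(.data$chrom)
}

#' Metagene profile of peak midpoints
#'
#' Projects each peak midpoint into transcript-relative coordinates and bins
#' the 5'UTR, CDS/exon body and 3'UTR segments into `bins_per_region` bins
#' each (a Guitar-plot-style profile). Transcripts without annotated UTRs
#' contribute to the exon segment only. Peaks whose midpoint falls outside
#' any exonic region are dropped.
#'
#' @param peaks Peak tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param catalog A `pg_catalog`.
#' @param bins_per_region Number of bins per segment (default 30).
#' @return Tibble `segment`, `bin`, `density`; density sums to 1 over all
#'   bins (all-zero with a warning when no peak could be projected).
#' @export
metagene_profile <- function(peaks, catalog, bins_per_region = 30L) {
  segs <- c("5UTR", "exon", "3UTR")
  grid <- tidyr::expand_grid(segment = segs, bin = seq_len(bins_per_region))
  if (!nrow(peaks)) {
    warning("metagene_profile: empty peak set; all-zero profile")
    return(mutate(grid, density = 0))
  }
  regions <- derive_regions(catalog, flank = 0L) |>
    filter(.data$region %in% segs)
  reg_by_gene <- split(regions, regions$gene_id)
  hits <- list()
  for (gid in intersect(unique(peaks$gene_id), names(reg_by_gene))) {
    pk <- peaks[peaks$gene_id == gid, , drop = FALSE]
    mid <- pk$start + (pk$end - pk$start) %/% 2
    regs_g <- reg_by_gene[[gid]]
    for (seg in unique(regs_g$region)) {
      iv <- regs_g[regs_g$region == seg, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      seg_len <- sum(iv$end - iv$start)
      cum <- cumsum(c(0, head(iv$end - iv$start, -1)))
      ## transcript-relative offset of each midpoint inside this segment
      off <- rep(NA_real_, length(mid))
      for (j in seq_len(nrow(iv))) {
        inj <- mid >= iv$start[j] & mid < iv$end[j]
        off[inj] <- cum[j] + mid[inj] - iv$start[j]
      }
      keep <- !is.na(off)
      if (!any(keep)) next
      frac <- off[keep] / seg_len
      if (iv$strand[1] == "-") frac <- 1 - frac - 1 / seg_len
      bin <- pmin(bins_per_region,
                  floor(frac * bins_per_region) + 1L)
      hits[[length(hits) + 1L]] <- tibble(segment = seg,
                                          bin = as.integer(bin))
    }
  }
  if (!length(hits)) {
    warning("metagene_profile: no peak midpoint fell in an exonic region")
    return(mutate(grid, density = 0))
  }
  tal <- bind_rows(hits) |> count(.data$segment, .data$bin)
  grid |>
    left_join(tal, by = c("segment" = "segment", "bin" = "bin")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           density = .data$n / sum(.data$n)) |>
    select("segment", "bin", "density")
}
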