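## Windowed IP-vs-input m6A peak calling, tumour-vs-normal differential
## methylation, and per-gene relative m6A level with tertile assignment.
##
## Counts are pooled across the replicate samples of a condition and each
## window is tested with a one-sided 2x2 exact (hypergeometric) test of
## [ip_w, ip_rest; input_w, input_rest]; BH correction is applied over all
## windows and adjacent significant windows are merged into peaks.

#' Tile gene exons into windows
#'
#' Deterministic sliding-window tiling of each exon at (`window_size`,
#' `step`). The trailing partial window is kept only when it covers strictly
#' more than half a window. Windows never span exon junctions.
#'
#' @param catalog A `pg_catalog`.
#' @param window_size,step Window width and offset between window starts, nt.
#' @return Tibble: `gene_id`, `window_index` (1-based within gene), `chrom`,
#'   `start`, `end`, `strand`.
#' @export
window_tiling <- function(catalog, window_size = 50L, step = 25L) {
  stopifnot(inherits(catalog, "pg_catalog"), window_size > 0, step > 0)
  zero_len <- setdiff(catalog$genes$gene_id, catalog$exons$gene_id)
  if (length(zero_len)) {
    warning("window_tiling: skipping gene(s) with zero exonic length: ",
            paste(zero_len, collapse = ", "))
  }
  ex <- catalog$exons |> arrange(.data$gene_id, .data$start)
  len <- ex$end - ex$start
  n_off <- pmax(0L, (len - 1L) %/% step) + 1L
  row <- rep(seq_len(nrow(ex)), n_off)
  off <- (sequence(n_off) - 1L) * as.integer(step)
  we <- pmin(off + as.integer(window_size), len[row])
  keep <- we - off > window_size / 2
  out <- tibble(
    gene_id = ex$gene_id[row], chrom = ex$chrom[row],
    start = ex$start[row] + off, end = ex$start[row] + we,
    strand = ex$strand[row])[keep, ]
  out |>
    group_by(.data$gene_id) |>
    mutate(window_index = row_number()) |>
    ungroup() |>
    select("gene_id", "window_index", "chrom", "start", "end", "strand")
}

#' Window counts from per-base coverage
#'
#' Sums bedGraph-style per-base read coverage into exon-tiled windows.
#'
#' @param coverage Long tibble with columns `sample`, `assay` (`IP`/`input`),
#'   `condition`, `chrom`, `start`, `end`, `value` (per-base coverage over
#'   the 0-based half-open interval), e.g. from [read_bedgraph()].
#' @param catalog A `pg_catalog`.
#' @param window_size,step Tiling parameters; see [window_tiling()].
#' @return A `pg_windowcounts` (see [simulate_merip()] for the layout).
#' @export
count_windows <- function(coverage, catalog, window_size = 50L, step = 25L) {
  tiling <- window_tiling(catalog, window_size, step)
  samples <- distinct(coverage, .data$sample, .data$assay, .data$condition)
  if (!nrow(samples)) {
    empty <- tiling[0, ] |>
      mutate(sample = character(0), assay = character(0),
             condition = character(0), count = integer(0))
    return(structure(
      list(counts = empty,
           lib_sizes = tibble(sample = character(0), assay = character(0),
                              condition = character(0),
                              lib_size = integer(0))),
      class = "pg_windowcounts"))
  }
  counts <- list()
  for (i in seq_len(nrow(samples))) {
    cov_i <- coverage |> filter(.data$sample == samples$sample[i])
    cnt <- integer(nrow(tiling))
    for (ch in unique(tiling$chrom)) {
      wi <- which(tiling$chrom == ch)
      ci <- cov_i |> filter(.data$chrom == ch)
      if (!nrow(ci)) next
      ir_w <- IRanges::IRanges(tiling$start[wi] + 1L, tiling$end[wi])
      ir_c <- IRanges::IRanges(ci$start + 1L, ci$end)
      hits <- IRanges::findOverlaps(ir_w, ir_c)
      if (!length(hits)) next
      ov <- IRanges::pintersect(ir_w[S4Vectors::queryHits(hits)],
                                ir_c[S4Vectors::subjectHits(hits)])
      contrib <- IRanges::width(ov) * ci$value[S4Vectors::subjectHits(hits)]
      agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
      cnt[wi[as.integer(names(agg))]] <- as.integer(round(agg))
    }
    counts[[i]] <- tiling |>
      mutate(sample = samples$sample[i], assay = samples$assay[i],
             condition = samples$condition[i], count = cnt)
  }
  counts <- bind_rows(counts)
  libs <- counts |>
    group_by(.data$sample, .data$assay, .data$condition) |>
    summarise(lib_size = sum(.data$count), .groups = "drop")
  structure(list(counts = counts, lib_sizes = libs),
            class = "pg_windowcounts")
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param sample,assay,condition Labels attached to every row.
#' @return Long coverage tibble as consumed by [count_windows()].
#' @export
read_bedgraph <- function(path, sample, assay, condition) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", comment = "#") |>
    mutate(sample = sample, assay = assay, condition = condition)
}

pool_condition <- function(wc, condition) {
  cond <- condition
  pooled <- wc$counts |>
    filter(.data$condition == cond) |>
    group_by(.data$gene_id, .data$window_index, .data$chrom, .data$start,
             .data$end, .data$strand, .data$assay) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "count",
                       values_fill = 0L)
  for (a in c("IP", "input")) if (!a %in% names(pooled)) pooled[[a]] <- 0L
  pooled
}

## greedy non-overlapping subset of (sorted) member windows, so pooled peak
## counts never double-count reads shared by overlapping sliding windows
nonoverlapping_members <- function(w) {
  keep <- logical(nrow(w))
  last_end <- -Inf
  for (i in order(w$start)) {
    if (w$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- w$end[i]
    }
  }
  w[keep, , drop = FALSE]
}

#' Call m6A-enriched peaks from IP/input window counts
#'
#' Counts are pooled across the condition's replicates; each window gets a
#' one-sided exact (hypergeometric) test of the 2x2 table
#' `[ip_w, ip_rest; input_w, input_rest]`, where the rest is the remainder
#' of the same gene's counts -- the input sample provides the gene's
#' background transcriptome level, and conditioning on the gene totals
#' cancels gene-level abundance fluctuations that the 2x2 null does not
#' model. BH correction is applied over all windows, and significant windows
#' of a gene lying within one step of each other are merged into peaks. The peak p-value is the minimum member-window p; the
#' enrichment score is `log2((IP CPM + 1) / (input CPM + 1))` over a
#' non-overlapping cover of the merged span.
#'
#' @param wc A `pg_windowcounts`.
#' @param condition Condition label to call peaks in.
#' @param alpha BH FDR threshold for window significance (default 0.05).
#' @param step Step used for the tiling (merge gap allowance).
#' @return Tibble of peaks: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_windows`, `log2_enrichment`, `p_value`, `q_value`, `condition`.
#' @export
call_peaks <- function(wc, condition, alpha = 0.05, step = 25L) {
  stopifnot(inherits(wc, "pg_windowcounts"))
  pooled <- pool_condition(wc, condition)
  if (!nrow(pooled)) return(empty_peaks())
  ip_total <- sum(pooled$IP)
  input_total <- sum(pooled$input)
  if (input_total == 0) stop("call_peaks: all-zero input library")

  pooled <- pooled |>
    group_by(.data$gene_id) |>
    mutate(ip_gene = sum(.data$IP), input_gene = sum(.data$input)) |>
    ungroup() |>
    mutate(
      p_value = hyper_p_greater(.data$IP, .data$ip_gene - .data$IP,
                                .data$input,
                                .data$input_gene - .data$input),
      q_value = p.adjust(.data$p_value, "BH"),
      sig = .data$q_value < alpha)

  sig <- pooled |> filter(.data$sig) |> arrange(.data$gene_id, .data$start)
  if (!nrow(sig)) return(empty_peaks())

  peaks <- sig |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(function(w, key) {
      w <- w[order(w$start), , drop = FALSE]
      grp <- cumsum(c(TRUE, w$start[-1] - head(w$end, -1) > step))
      purrr::map_dfr(split(w, grp), function(g) {
        nm <- nonoverlapping_members(g)
        tibble(start = min(g$start), end = max(g$end),
               n_windows = nrow(g), p_value = min(g$p_value),
               q_value = min(g$q_value),
               ip_peak = sum(nm$IP), input_peak = sum(nm$input))
      })
    }) |>
    ungroup() |>
    mutate(
      log2_enrichment = log2((.data$ip_peak / ip_total * 1e6 + 1) /
                             (.data$input_peak / input_total * 1e6 + 1)),
      condition = condition) |>
    select("gene_id", "chrom", "start", "end", "strand", "n_windows",
           "log2_enrichment", "p_value", "q_value", "condition")
  peaks
}

empty_peaks <- function() {
  tibble(gene_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), n_windows = integer(),
         log2_enrichment = double(), p_value = double(), q_value = double(),
         condition = character())
}

## union of (possibly overlapping) peak spans per gene across conditions
union_peaks <- function(peaks) {
  peaks |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(function(w, key) {
      w <- arrange(w, .data$start)
      grp <- cumsum(c(TRUE, w$start[-1] > cummax(head(w$end, -1))))
      w |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  .groups = "drop") |>
        select(-".grp")
    }) |>
    ungroup()
}

peak_span_counts <- function(wc, peaks_u, condition) {
  pooled <- pool_condition(wc, condition)
  res <- tibble(gene_id = peaks_u$gene_id, start = peaks_u$start,
                end = peaks_u$end, IP = 0, input = 0)
  for (i in seq_len(nrow(peaks_u))) {
    ## member windows fully inside the span (peaks are unions of windows,
    ## so the defining windows are always contained)
    memb <- pooled |>
      filter(.data$gene_id == peaks_u$gene_id[i],
             .data$start >= peaks_u$start[i], .data$end <= peaks_u$end[i])
    if (!nrow(memb)) next
    nm <- nonoverlapping_members(memb)
    res$IP[i] <- sum(nm$IP)
    res$input[i] <- sum(nm$input)
  }
  res
}

#' Tumour-vs-normal differential methylation of peaks
#'
#' For every peak in the union peak set over both conditions, tests the 2x2
#' table `[IP_t, input_t; IP_n, input_n]` of counts pooled over the peak
#' span, after scaling each of the four libraries to the common mean library
#' size (then rounding). The direction is `hyper` when the odds ratio of
#' methylation favours the tumour, `hypo` otherwise. Matching the published
#' rule, a raw p-value < 0.05 flags significance; the BH q-value is reported
#' alongside.
#'
#' @param wc_tumour,wc_normal `pg_windowcounts` for the two conditions (may
#'   be the same object holding both conditions).
#' @param peaks Peak tibble(s) from [call_peaks()] on each condition;
#'   concatenated with [dplyr::bind_rows()] if you have two.
#' @param alpha Raw significance threshold (default 0.05).
#' @return Tibble: peak span, pooled scaled counts, `diff_log2fc` (log2 odds
#'   ratio), `direction`, `p_value`, `q_value`, `significant`.
#' @export
diff_methylation <- function(wc_tumour, wc_normal, peaks, alpha = 0.05) {
  if (!nrow(peaks)) return(empty_diffpeaks())
  peaks_u <- union_peaks(peaks)
  ct <- peak_span_counts(wc_tumour, peaks_u, "tumour")
  cn <- peak_span_counts(wc_normal, peaks_u, "normal")

  libs <- function(wc, cond) {
    wc$lib_sizes |> filter(.data$condition == cond) |>
      group_by(.data$assay) |> summarise(lib = sum(.data$lib_size)) |>
      tidyr::pivot_wider(names_from = "assay", values_from = "lib")
  }
  lt <- libs(wc_tumour, "tumour"); ln <- libs(wc_normal, "normal")
  target <- mean(c(lt$IP, lt$input, ln$IP, ln$input))

  tab <- peaks_u |>
    mutate(
      ip_t = round(ct$IP / lt$IP * target),
      in_t = round(ct$input / lt$input * target),
      ip_n = round(cn$IP / ln$IP * target),
      in_n = round(cn$input / ln$input * target))

  drop <- with(tab, ip_t + in_t + ip_n + in_n == 0)
  n_drop <- sum(drop)
  if (n_drop) {
    message("diff_methylation: excluded ", n_drop,
            " peak(s) with zero total counts")
  }
  tab <- tab[!drop, , drop = FALSE]
  if (!nrow(tab)) return(empty_diffpeaks())

  stats_tbl <- purrr::pmap_dfr(
    tab[, c("ip_t", "in_t", "ip_n", "in_n")],
    function(ip_t, in_t, ip_n, in_n) {
      m <- matrix(c(ip_t, in_t, ip_n, in_n), 2, byrow = FALSE)
      p <- fisher.test(m)$p.value
      if (min(m) == 0) m <- m + 0.5
      or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
      tibble(p_value = p, diff_log2fc = log2(or))
    })

  tab |>
    bind_cols(stats_tbl) |>
    mutate(
      direction = if_else(.data$diff_log2fc > 0, "hyper", "hypo"),
      q_value = p.adjust(.data$p_value, "BH"),
      significant = .data$p_value < alpha) |>
    select("gene_id", "chrom", "start", "end", "strand",
           "ip_t", "in_t", "ip_n", "in_n", "diff_log2fc", "direction",
           "p_value", "q_value", "significant")
}

empty_diffpeaks <- function() {
  tibble(gene_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), ip_t = double(),
         in_t = double(), ip_n = double(), in_n = double(),
         diff_log2fc = double(), direction = character(), p_value = double(),
         q_value = double(), significant = logical())
}

#' Per-gene relative m6A level and tertile assignment
#'
#' The relative m6A level of a gene is `log2((IP CPM + alpha) /
#' (input CPM + alpha))` over its significant peak spans (whole gene when it
#' has no peak), computed from counts pooled across the condition's
#' replicates. Genes are ranked by level and cut into tertiles
#' (low / median / high) whose sizes differ by at most one; `m6a_positive`
#' flags genes carrying at least one significant peak.
#'
#' @param wc A `pg_windowcounts`.
#' @param peaks Peaks from [call_peaks()] (the condition's significant set).
#' @param condition Condition whose counts to use.
#' @param alpha Pseudocount on the CPM scale (default 1).
#' @return Tibble: `gene_id`, `ip_cpm`, `input_cpm`, `level`, `tertile`,
#'   `m6a_positive`.
#' @export
gene_m6a_level <- function(wc, peaks, condition, alpha = 1) {
  stopifnot(inherits(wc, "pg_windowcounts"))
  pooled <- pool_condition(wc, condition)
  ip_total <- sum(pooled$IP); input_total <- sum(pooled$input)

  with_peaks <- unique(peaks$gene_id)
  gene_tot <- pooled |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(w, key) {
      gid <- key$gene_id
      if (gid %in% with_peaks) {
        sp <- peaks |> filter(.data$gene_id == gid)
        keep <- rep(FALSE, nrow(w))
        for (i in seq_len(nrow(sp))) {
          keep <- keep | (w$start >= sp$start[i] & w$end <= sp$end[i])
        }
        if (any(keep)) w <- w[keep, , drop = FALSE]
      }
      nm <- nonoverlapping_members(w)
      tibble(IP = sum(nm$IP), input = sum(nm$input))
    }) |>
    ungroup()

  res <- gene_tot |>
    mutate(
      ip_cpm = .data$IP / ip_total * 1e6,
      input_cpm = .data$input / input_total * 1e6,
      level = log2((.data$ip_cpm + alpha) / (.data$input_cpm + alpha)),
      m6a_positive = .data$gene_id %in% with_peaks) |>
    arrange(.data$level) |>
    mutate(tertile = tertile_of_rank(row_number(), n())) |>
    arrange(.data$gene_id) |>
    select("gene_id", "ip_cpm", "input_cpm", "level", "tertile",
           "m6a_positive")
  res
}

#' Write peaks as BED6+
#'
#' Score is `round(100 * log2_enrichment)`; extra columns carry p, q and
#' (for differential peaks) the direction.
#'
#' @param peaks Peak or differential-peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  score_col <- if ("log2_enrichment" %in% names(peaks)) {
    peaks$log2_enrichment
  } else {
    peaks$diff_log2fc
  }
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = paste0(peaks$gene_id, "_peak", seq_len(nrow(peaks))),
    score = round(100 * score_col), strand = peaks$strand,
    p = peaks$p_value, q = peaks$q_value)
  if ("direction" %in% names(peaks)) out$direction <- peaks$direction
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
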