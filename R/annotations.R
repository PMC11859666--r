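## Genomic data model.
##
## A catalog holds one transcript model per gene, with pseudogenes labelled by
## subtype (processed / unprocessed / unitary / polymorphic) and optionally
## paired with their cognate parent gene. All internal coordinates are
## 0-based half-open; GTF I/O converts at the boundary.

PSEUDOGENE_SUBTYPES <- c("processed", "unprocessed", "unitary", "polymorphic")

## GTF/GENCODE-style biotypes mapped onto the four subtype classes; anything
## else is recorded as a non-pseudogene gene.
.biotype_to_subtype <- c(
  processed_pseudogene   = "processed",
  unprocessed_pseudogene = "unprocessed",
  unitary_pseudogene     = "unitary",
  polymorphic_pseudogene = "polymorphic"
)

new_catalog <- function(genes, exons, cds = NULL, pairs = NULL) {
  if (is.null(cds)) {
    cds <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character())
  }
  if (is.null(pairs)) {
    pairs <- tibble(pseudogene_id = character(), parent_gene_id = character())
  }
  structure(
    list(genes = as_tibble(genes), exons = as_tibble(exons),
         cds = as_tibble(cds), pairs = as_tibble(pairs),
         pair_summary = NULL),
    class = "pg_catalog"
  )
}

empty_catalog <- function() {
  new_catalog(
    genes = tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   biotype = character(), is_pseudogene = logical(),
                   subtype = character(), parent_gene_id = character(),
                   unpaired = logical()),
    exons = tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character())
  )
}

#' @export
print.pg_catalog <- function(x, ...) {
  np <- sum(x$genes$is_pseudogene)
  cat("<pg_catalog> ", nrow(x$genes), " genes (", np, " pseudogenes, ",
      nrow(x$pairs), " parent pairs), ", nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Read a GTF file into a gene catalog
#'
#' Parses gene/transcript/exon (and CDS) features into a catalog with one
#' transcript model per gene. GTF coordinates (1-based inclusive) are
#' converted to the package's internal 0-based half-open convention.
#' Pseudogene biotypes (`processed_pseudogene` etc.) are mapped onto the four
#' subtype classes; any other biotype is kept as an ordinary gene.
#'
#' @param path Path to a GTF file.
#' @return A `pg_catalog`: a list of tibbles `genes`, `exons`, `cds`, `pairs`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("read_gtf: malformed GTF line ", i, " in ", path)
    }
  }
  if (!length(body)) return(empty_catalog())

  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  ## tolerate either gene_biotype or gene_type attribute naming
  if (is.null(md$gene_biotype) && !is.null(md$gene_type)) {
    md$gene_biotype <- md$gene_type
  }
  if (is.null(md$gene_biotype)) md$gene_biotype <- NA_character_
  md$start0 <- md$start - 1L   # to 0-based half-open
  md$end0 <- md$end

  exons <- md[md$type == "exon", , drop = FALSE]
  cds <- md[md$type == "CDS", , drop = FALSE]
  gene_rows <- md[md$type == "gene", , drop = FALSE]
  if (!nrow(gene_rows)) {
    gene_rows <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      g <- e[1, , drop = FALSE]
      g$start0 <- min(e$start0); g$end0 <- max(e$end0)
      g
    }))
  }

  genes <- tibble(
    gene_id = as.character(gene_rows$gene_id),
    chrom = as.character(gene_rows$seqnames),
    start = as.integer(gene_rows$start0),
    end = as.integer(gene_rows$end0),
    strand = as.character(gene_rows$strand),
    biotype = as.character(gene_rows$gene_biotype)
  ) |>
    mutate(
      subtype = unname(.biotype_to_subtype[.data$biotype]),
      is_pseudogene = !is.na(.data$subtype),
      parent_gene_id = NA_character_,
      unpaired = .data$is_pseudogene
    ) |>
    arrange(.data$chrom, .data$start, .data$gene_id)

  exon_tbl <- tibble(
    gene_id = as.character(exons$gene_id),
    chrom = as.character(exons$seqnames),
    start = as.integer(exons$start0),
    end = as.integer(exons$end0),
    strand = as.character(exons$strand)
  ) |> arrange(.data$gene_id, .data$start)

  cds_tbl <- tibble(
    gene_id = as.character(cds$gene_id),
    chrom = as.character(cds$seqnames),
    start = as.integer(cds$start0),
    end = as.integer(cds$end0),
    strand = as.character(cds$strand)
  ) |> arrange(.data$gene_id, .data$start)

  ## validation: every exon inside its gene span
  chk <- exon_tbl |> inner_join(genes, by = "gene_id", suffix = c("", ".g"))
  bad <- chk$start < chk$start.g | chk$end > chk$end.g
  if (any(bad)) {
    stop("read_gtf: exon outside gene span for gene(s): ",
         paste(unique(chk$gene_id[bad]), collapse = ", "))
  }

  new_catalog(genes, exon_tbl, cds_tbl)
}

#' Write a gene catalog back to GTF
#'
#' Emits gene, transcript and exon (and CDS) rows, converting internal
#' 0-based half-open coordinates back to GTF's 1-based inclusive convention.
#' `read_gtf(write_gtf(x))` preserves all ids and coordinates exactly.
#'
#' @param catalog A `pg_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path) {
  stopifnot(inherits(catalog, "pg_catalog"))
  g <- catalog$genes
  fmt_attr <- function(gene_id, biotype, with_tx = TRUE) {
    a <- sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, biotype)
    if (with_tx) a <- paste0(a, sprintf(' transcript_id "%s.t1";', gene_id))
    a
  }
  row_of <- function(chrom, src, type, start0, end0, strand, attr) {
    paste(chrom, src, type, start0 + 1L, end0, ".", strand, ".", attr,
          sep = "\t")
  }
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    out <- c(out,
             row_of(gi$chrom, "pseudom6a", "gene", gi$start, gi$end,
                    gi$strand, fmt_attr(gi$gene_id, gi$biotype, FALSE)),
             row_of(gi$chrom, "pseudom6a", "transcript", gi$start, gi$end,
                    gi$strand, fmt_attr(gi$gene_id, gi$biotype)))
    ex <- catalog$exons[catalog$exons$gene_id == gi$gene_id, ]
    for (j in seq_len(nrow(ex))) {
      out <- c(out, row_of(ex$chrom[j], "pseudom6a", "exon", ex$start[j],
                           ex$end[j], ex$strand[j],
                           fmt_attr(gi$gene_id, gi$biotype)))
    }
    cd <- catalog$cds[catalog$cds$gene_id == gi$gene_id, ]
    for (j in seq_len(nrow(cd))) {
      out <- c(out, row_of(cd$chrom[j], "pseudom6a", "CDS", cd$start[j],
                           cd$end[j], cd$strand[j],
                           fmt_attr(gi$gene_id, gi$biotype)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Attach pseudogene-parent pairings to a catalog
#'
#' Takes a mapping table of pseudogene to cognate parent gene (the functional
#' paralog a pseudogene derives from), validates that both ids resolve in the
#' catalog, and records the pair list plus a summary of how many pseudogenes
#' were paired.
#'
#' @param catalog A `pg_catalog`.
#' @param mapping A data frame with columns `pseudogene_id`, `parent_gene_id`.
#' @return The catalog with `pairs` populated, per-pseudogene
#'   `parent_gene_id`/`unpaired` fields updated, and a `pair_summary` tibble
#'   (`n_pseudogenes`, `n_paired`, `n_unique_parents`, `n_skipped`).
#' @export
pair_parents <- function(catalog, mapping) {
  stopifnot(inherits(catalog, "pg_catalog"))
  mapping <- as_tibble(mapping)
  assert_cols(mapping, c("pseudogene_id", "parent_gene_id"), "pair_parents")
  mapping <- distinct(mapping, .data$pseudogene_id, .data$parent_gene_id)

  pg_ids <- catalog$genes$gene_id[catalog$genes$is_pseudogene]
  ok_pg <- mapping$pseudogene_id %in% pg_ids
  ok_parent <- mapping$parent_gene_id %in% catalog$genes$gene_id
  skipped <- sum(!ok_pg | !ok_parent)
  if (skipped > 0) {
    warning("pair_parents: skipped ", skipped,
            " pair(s) whose id(s) do not resolve in the catalog")
  }
  pairs <- mapping[ok_pg & ok_parent, ]

  catalog$pairs <- pairs
  catalog$genes <- catalog$genes |>
    mutate(
      parent_gene_id = if_else(
        .data$is_pseudogene,
        pairs$parent_gene_id[match(.data$gene_id, pairs$pseudogene_id)],
        NA_character_),
      unpaired = .data$is_pseudogene & is.na(.data$parent_gene_id)
    )
  catalog$pair_summary <- tibble(
    n_pseudogenes = length(pg_ids),
    n_paired = nrow(pairs),
    n_unique_parents = dplyr::n_distinct(pairs$parent_gene_id),
    n_skipped = skipped
  )
  catalog
}

#' Derive labelled gene regions for annotation
#'
#' Expands each gene's transcript model into the region vocabulary used for
#' peak annotation: exon (CDS portions keep the exon label), 5'UTR, 3'UTR,
#' intron, and strand-aware TSS/TTS windows spanning `flank` nt upstream
#' through `flank` nt downstream of the transcription start/termination site.
#'
#' @param catalog A `pg_catalog`.
#' @param flank TSS/TTS window half-width in nt (default 1000).
#' @return Tibble with columns `gene_id`, `region`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
derive_regions <- function(catalog, flank = 1000L) {
  stopifnot(inherits(catalog, "pg_catalog"), flank >= 0)
  flank <- as.integer(flank)
  out <- vector("list", nrow(catalog$genes))
  for (i in seq_len(nrow(catalog$genes))) {
    g <- catalog$genes[i, ]
    ex <- catalog$exons |> filter(.data$gene_id == g$gene_id) |>
      arrange(.data$start)
    cd <- catalog$cds |> filter(.data$gene_id == g$gene_id) |>
      arrange(.data$start)
    regs <- list()
    add <- function(region, start, end) {
      if (end > start) {
        regs[[length(regs) + 1L]] <<- tibble(
          gene_id = g$gene_id, region = region, chrom = g$chrom,
          start = as.integer(start), end = as.integer(end),
          strand = g$strand)
      }
    }
    if (nrow(cd)) {
      cds_lo <- min(cd$start); cds_hi <- max(cd$end)
      for (j in seq_len(nrow(ex))) {
        s <- ex$start[j]; e <- ex$end[j]
        ## exonic portion left of CDS
        if (s < cds_lo) {
          add(if (g$strand == "+") "5UTR" else "3UTR", s, min(e, cds_lo))
        }
        ## CDS-overlapping portion keeps the exon label
        add("exon", max(s, cds_lo), min(e, cds_hi))
        if (e > cds_hi) {
          add(if (g$strand == "+") "3UTR" else "5UTR", max(s, cds_hi), e)
        }
      }
    } else {
      for (j in seq_len(nrow(ex))) add("exon", ex$start[j], ex$end[j])
    }
    ## introns: gaps between consecutive exons
    if (nrow(ex) > 1) {
      for (j in seq_len(nrow(ex) - 1)) add("intron", ex$end[j], ex$start[j + 1])
    }
    tss <- if (g$strand == "+") g$start else g$end
    tts <- if (g$strand == "+") g$end else g$start
    add("TSS", max(0L, tss - flank), tss + flank)
    add("TTS", max(0L, tts - flank), tts + flank)
    out[[i]] <- bind_rows(regs)
  }
  bind_rows(out)
}

#' Write intervals as BED6
#'
#' @param df Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (internal coordinates are already 0-based
#'   half-open, i.e. BED-native).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  assert_cols(df, c("chrom", "start", "end"), "write_bed")
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  readr::write_tsv(
    tibble(chrom = df$chrom, start = df$start, end = df$end,
           name = name, score = score, strand = strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a pseudogene-parent pair table
#'
#' @param path TSV with columns `pseudogene_id`, `parent_gene_id`.
#' @return A tibble.
#' @export
read_pair_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
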