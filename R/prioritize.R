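## The Diff-m6A candidate filter cascade and ranked report -- the pipeline's
## headline output -- plus end-to-end orchestration over simulated or
## user-supplied inputs.

#' Multi-omics candidate filter cascade
#'
#' Applies the ordered filters that funnel differentially methylated
#' pseudogenes down to prioritized candidates:
#' \enumerate{
#'   \item differential m6A at raw p < `p_diff`;
#'   \item expressed ("stabilized RNA"): mean CPM >= `min_cpm` in at least
#'     half the samples of one condition;
#'   \item concurrent differential expression with sign opposite to the
#'     m6A change (hypo -> up, hyper -> down); set
#'     `directional = FALSE` to accept either direction;
#'   \item prognostic at p < `p_cox` with direction consistent with the
#'     expression change (up + risk or down + protective);
#'   \item genetic confound excluded: mutation frequency < `max_mut_freq`
#'     and CNV frequency < `max_cnv_freq`;
#'   \item optional ceRNA evidence: at least one shared miRNA and a
#'     positively correlated parent. Off by default
#'     (`apply_cerna = FALSE`): the ceRNA layer corroborates candidates and
#'     is annotated in the report, but is not part of the published
#'     candidate funnel. Set `apply_cerna = TRUE` to make it a hard filter.
#' }
#' A missing input layer skips its filter (flagged in the attrition table).
#'
#' @param diff_peaks Differential peaks from [diff_methylation()].
#' @param de A `pg_de` from [differential_expression()].
#' @param expr A `pg_expr` (for the expressed filter).
#' @param cox A `pg_cox_screen` from [cox_screen()], or `NULL`.
#' @param genetics Output of [genetic_summary()], or `NULL`.
#' @param correlations Output of [spearman_pairs()], or `NULL`.
#' @param sponges Tibble (`pseudogene_id`, `shared_mirna_count`), or `NULL`.
#' @param pseudogenes Tibble (`gene_id`, `subtype`) restricting the gene
#'   universe to pseudogenes.
#' @param p_diff,p_cox Raw p thresholds (default 0.05; BH q is carried in
#'   the report for users).
#' @param min_cpm Detectability threshold (default 1).
#' @param max_mut_freq,max_cnv_freq Genetic confound thresholds (defaults
#'   0.01 and 0.05).
#' @param directional Require opposite-sign m6A/expression concurrence
#'   (default TRUE).
#' @param apply_cerna Make the ceRNA evidence a hard filter (default FALSE:
#'   annotate only).
#' @return List of class `pg_candidates`: `report` (per-candidate tibble
#'   with `rank_score`, ordered), `attrition` (survivor count after each
#'   filter, with skipped flags), `survivors` (ids per stage).
#' @export
filter_cascade <- function(diff_peaks, de, expr, cox = NULL, genetics = NULL,
                           correlations = NULL, sponges = NULL,
                           pseudogenes, p_diff = 0.05, p_cox = 0.05,
                           min_cpm = 1, max_mut_freq = 0.01,
                           max_cnv_freq = 0.05, directional = TRUE,
                           apply_cerna = FALSE) {
  universe <- pseudogenes$gene_id
  if (!length(universe)) {
    return(structure(list(report = empty_candidates(),
                          attrition = tibble(), survivors = list()),
                     class = "pg_candidates"))
  }
  attrition <- list()
  note <- function(stage, ids, skipped = FALSE) {
    attrition[[length(attrition) + 1L]] <<-
      tibble(stage = stage, n_survivors = length(ids), skipped = skipped)
    ids
  }

  ## (1) significant differential m6A
  dm <- empty_diffpeaks()
  if (is.null(diff_peaks) || !nrow(diff_peaks)) {
    s1 <- note("diff_m6a", character(0))
  } else {
    dm <- diff_peaks |>
      filter(.data$gene_id %in% universe, .data$p_value < p_diff) |>
      group_by(.data$gene_id) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      ungroup()
    s1 <- note("diff_m6a", dm$gene_id)
  }

  ## (2) expressed ("stabilized RNA")
  if (is.null(expr)) {
    s2 <- note("expressed", s1, skipped = TRUE)
  } else {
    cpm <- normalize_cpm(expr$counts)
    cond <- expr$samples$condition
    detect <- vapply(rownames(cpm), function(g) {
      any(vapply(unique(cond), function(cc) {
        mean(cpm[g, cond == cc] >= min_cpm) >= 0.5
      }, logical(1)))
    }, logical(1))
    s2 <- note("expressed", intersect(s1, names(detect)[detect]))
  }

  ## (3) concurrent DE opposite in sign to the m6A change
  if (is.null(de)) {
    s3 <- note("concurrent_de", s2, skipped = TRUE)
  } else {
    de_dir <- setNames(de$direction, de$gene_id)
    m6a_dir <- setNames(dm$direction, dm$gene_id)
    ok <- vapply(s2, function(g) {
      dd <- unname(de_dir[g]) %||% "ns"
      if (dd == "ns") return(FALSE)
      if (!directional) return(TRUE)
      (m6a_dir[[g]] == "hypo" && dd == "up") ||
        (m6a_dir[[g]] == "hyper" && dd == "down")
    }, logical(1))
    s3 <- note("concurrent_de", s2[ok])
  }

  ## (4) prognostic, consistent with the expression direction
  if (is.null(cox)) {
    s4 <- note("prognostic", s3, skipped = TRUE)
  } else {
    cls <- setNames(cox$classification, cox$gene_id)
    pcx <- setNames(cox$p_value, cox$gene_id)
    de_dir <- setNames(de$direction, de$gene_id)
    ok <- vapply(s3, function(g) {
      if (!g %in% names(cls) || is.na(pcx[[g]]) || pcx[[g]] >= p_cox) {
        return(FALSE)
      }
      (de_dir[[g]] == "up" && cls[[g]] == "risk") ||
        (de_dir[[g]] == "down" && cls[[g]] == "protective")
    }, logical(1))
    s4 <- note("prognostic", s3[ok])
  }

  ## (5) genetic confound excluded
  if (is.null(genetics)) {
    s5 <- note("genetics", s4, skipped = TRUE)
  } else {
    mf <- setNames(genetics$mutation_frequency, genetics$gene_id)
    cf <- setNames(genetics$cnv_frequency, genetics$gene_id)
    ok <- vapply(s4, function(g) {
      (unname(mf[g]) %||% 0) < max_mut_freq &&
        (unname(cf[g]) %||% 0) < max_cnv_freq
    }, logical(1))
    s5 <- note("genetics", s4[ok])
  }

  ## (6) optional ceRNA evidence
  if (!apply_cerna || is.null(sponges) || is.null(correlations)) {
    s6 <- note("cerna", s5, skipped = TRUE)
  } else {
    sp <- setNames(sponges$shared_mirna_count, sponges$pseudogene_id)
    pos <- correlations$pseudogene_id[correlations$sign_class == "Positive"]
    ok <- vapply(s5, function(g) {
      (unname(sp[g]) %||% 0L) >= 1L && g %in% pos
    }, logical(1))
    s6 <- note("cerna", s5[ok])
  }

  report <- tibble(pseudogene_id = s6) |>
    left_join(pseudogenes |> rename(pseudogene_id = "gene_id"),
              by = "pseudogene_id") |>
    left_join(dm |> select(pseudogene_id = "gene_id",
                           diff_m6a = "direction",
                           diff_log2fc = "diff_log2fc",
                           diff_p = "p_value", diff_q = "q_value"),
              by = "pseudogene_id") |>
    left_join(de |> select(pseudogene_id = "gene_id",
                           de_direction = "direction",
                           expr_log2fc = "log2fc"),
              by = "pseudogene_id")
  if (!is.null(cox)) {
    report <- report |>
      left_join(cox |> select(pseudogene_id = "gene_id",
                              cox_beta = "beta", cox_hr = "hr",
                              prognostic = "classification"),
                by = "pseudogene_id")
  } else {
    report <- report |> mutate(cox_beta = NA_real_, cox_hr = NA_real_,
                               prognostic = NA_character_)
  }
  if (!is.null(correlations)) {
    report <- report |>
      left_join(correlations |> select("pseudogene_id",
                                       parent_correlation = "sign_class"),
                by = "pseudogene_id")
  } else {
    report$parent_correlation <- NA_character_
  }
  if (!is.null(sponges)) {
    report <- report |>
      left_join(sponges, by = "pseudogene_id") |>
      mutate(shared_mirna_count =
               tidyr::replace_na(.data$shared_mirna_count, 0L))
  } else {
    report$shared_mirna_count <- NA_integer_
  }

  report <- rank_candidates(report)
  structure(
    list(report = report, attrition = bind_rows(attrition),
         survivors = list(diff_m6a = s1, expressed = s2, concurrent_de = s3,
                          prognostic = s4, genetics = s5, cerna = s6)),
    class = "pg_candidates")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

empty_candidates <- function() {
  tibble(pseudogene_id = character(), subtype = character(),
         diff_m6a = character(), diff_log2fc = double(), diff_p = double(),
         diff_q = double(), de_direction = character(),
         expr_log2fc = double(), cox_beta = double(), cox_hr = double(),
         prognostic = character(), parent_correlation = character(),
         shared_mirna_count = integer(), rank_score = double(),
         rank = integer())
}

#' Rank surviving candidates
#'
#' `rank_score = |z(diff m6A log2FC)| + |z(expression log2FC)| +
#' |z(Cox beta)|`, z-scored over the survivors (a z of 0 is used when the
#' spread is zero or the value is missing). Descending score; ties broken by
#' smaller differential-m6A p, then lexicographic id.
#'
#' @param report Candidate tibble from [filter_cascade()].
#' @return The tibble ordered with `rank_score` and `rank` columns.
#' @export
rank_candidates <- function(report) {
  if (!nrow(report)) return(mutate(report, rank_score = double(0),
                                   rank = integer(0)))
  zs <- function(x) {
    x[!is.finite(x)] <- NA
    s <- sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else
      (x - mean(x, na.rm = TRUE)) / s
    z[is.na(z)] <- 0
    z
  }
  report |>
    mutate(rank_score = abs(zs(.data$diff_log2fc)) +
             abs(zs(.data$expr_log2fc)) + abs(zs(.data$cox_beta))) |>
    arrange(desc(.data$rank_score), .data$diff_p, .data$pseudogene_id) |>
    mutate(rank = row_number())
}

#' @export
print.pg_candidates <- function(x, ...) {
  cat("<pg_candidates> ", nrow(x$report), " candidate(s)\n", sep = "")
  print(x$attrition)
  if (nrow(x$report)) print(head(x$report, 5))
  invisible(x)
}

#' Run the full pipeline on a simulated cohort
#'
#' Chains every stage -- simulation, peak calling in both conditions,
#' differential methylation, region annotation, motif discovery on peak
#' sequences, differential expression, pseudogene-parent correlation,
#' per-gene Cox screening, shared-miRNA detection for paired pseudogenes,
#' and the candidate filter cascade -- and returns every intermediate plus
#' the ranked candidate report. Identical `config` (including its seed)
#' gives identical output.
#'
#' @param config A [sim_config()].
#' @param find_motifs_stage Run the motif stage (default TRUE; it is the
#'   slowest stage).
#' @param out_dir Optional directory; when given, the main outputs are
#'   written there as TSV/BED/GTF/FASTA plus a `run_log.tsv` recording
#'   stages, the seed and the package version.
#' @return List of class `pg_pipeline` with elements `cohort`, `peaks`
#'   (both conditions), `diff`, `annotated`, `motifs`, `de`, `m6a_levels`,
#'   `correlations`, `cox`, `sponges`, `candidates`, and `log` (stage
#'   summary tibble).
#' @export
run_pipeline <- function(config, find_motifs_stage = TRUE, out_dir = NULL) {
  log <- list()
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log[[length(log) + 1L]] <<- tibble(stage = name, ok = TRUE)
    res
  }

  cohort <- stage("simulate", simulate_cohort(config))
  peaks_t <- stage("callpeaks_tumour",
                   call_peaks(cohort$merip, "tumour", step = config$step))
  peaks_n <- stage("callpeaks_normal",
                   call_peaks(cohort$merip, "normal", step = config$step))
  peaks <- bind_rows(peaks_t, peaks_n)
  diff <- stage("diffm6a",
                diff_methylation(cohort$merip, cohort$merip, peaks))
  regions <- stage("regions", derive_regions(cohort$catalog))
  annotated <- stage("annotate", annotate_peaks_regions(peaks, regions))
  motifs <- if (find_motifs_stage && nrow(peaks_t)) {
    stage("motifs", {
      seqs <- peak_sequences(peaks_t, cohort$genome)
      ctrl <- shuffle_controls(seqs, seed = substream_seed(config$seed,
                                                          "motif_ctrl"))
      find_motifs(seqs, ctrl)
    })
  } else {
    empty_motifs()
  }
  de <- stage("integrate_de", differential_expression(cohort$expression))
  m6a_levels <- stage("m6a_levels",
                      gene_m6a_level(cohort$merip, peaks_t, "tumour"))
  correlations <- stage("correlations", {
    tum <- cohort$expression$samples$sample_id[
      cohort$expression$samples$condition == "tumour"]
    spearman_pairs(cohort$expression, cohort$catalog$pairs, samples = tum)
  })
  cox <- stage("survive",
               cox_screen(cohort$expression, cohort$survival,
                          genes = cohort$truth$gene_id))
  genetics <- stage("genetics_summary",
                    genetic_summary(cohort$genetics$mutation,
                                    cohort$genetics$cnv))
  sponges <- stage("cerna", {
    paired <- cohort$catalog$pairs
    purrr::pmap_dfr(paired, function(pseudogene_id, parent_gene_id, ...) {
      pg_seq <- gene_exonic_sequence(cohort$catalog, cohort$genome,
                                     pseudogene_id)
      pa_seq <- gene_exonic_sequence(cohort$catalog, cohort$genome,
                                     parent_gene_id)
      sm <- shared_mirnas(pg_seq, pa_seq, cohort$mirnas)
      tibble(pseudogene_id = pseudogene_id,
             shared_mirna_count = nrow(sm$shared))
    })
  })
  pg_tbl <- cohort$catalog$genes |>
    filter(.data$is_pseudogene) |>
    select("gene_id", "subtype")
  candidates <- stage("prioritize",
                      filter_cascade(diff, de, cohort$expression, cox,
                                     genetics, correlations, sponges,
                                     pseudogenes = pg_tbl))
  result <- structure(
    list(cohort = cohort, peaks = peaks, diff = diff, annotated = annotated,
         motifs = motifs, de = de, m6a_levels = m6a_levels,
         correlations = correlations, cox = cox, genetics = genetics,
         sponges = sponges, candidates = candidates,
         log = bind_rows(log)),
    class = "pg_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_gtf(result$cohort$catalog, p("annotation.gtf"))
  writeLines(unlist(lapply(names(result$cohort$genome), function(ch) {
    c(paste0(">", ch), result$cohort$genome[[ch]])
  })), p("genome.fa"))
  readr::write_tsv(result$cohort$truth, p("truth.tsv"))
  readr::write_tsv(result$cohort$merip$counts, p("window_counts.tsv"))
  if (nrow(result$peaks)) write_peaks_bed(result$peaks, p("peaks.bed"))
  readr::write_tsv(result$diff, p("diff_peaks.tsv"))
  readr::write_tsv(result$annotated, p("annotated_peaks.tsv"))
  readr::write_tsv(result$motifs, p("motifs.tsv"))
  readr::write_tsv(result$de, p("de.tsv"))
  readr::write_tsv(result$m6a_levels, p("m6a_levels.tsv"))
  readr::write_tsv(result$correlations, p("correlations.tsv"))
  readr::write_tsv(result$cox, p("cox.tsv"))
  readr::write_tsv(result$genetics, p("genetic_summary.tsv"))
  readr::write_tsv(result$sponges, p("sponges.tsv"))
  readr::write_tsv(result$candidates$report, p("candidates.tsv"))
  readr::write_tsv(result$candidates$attrition, p("attrition.tsv"))
  readr::write_tsv(
    tibble(stage = result$log$stage, ok = result$log$ok,
           seed = config$seed,
           package_version = as.character(
             utils::packageVersion("pseudom6a"))),
    p("run_log.tsv"))
  invisible(out_dir)
}

#' Spliced (exon-concatenated) gene sequence
#'
#' Concatenates a gene's exon sequences in transcription order,
#' reverse-complementing on the minus strand.
#'
#' @param catalog A `pg_catalog`.
#' @param genome Named character vector of chromosome sequences.
#' @param gene_id Gene id.
#' @return A character scalar (DNA).
#' @export
gene_exonic_sequence <- function(catalog, genome, gene_id) {
  gid <- gene_id
  ex <- catalog$exons |> filter(.data$gene_id == gid) |> arrange(.data$start)
  if (!nrow(ex)) return("")
  s <- paste(vapply(seq_len(nrow(ex)), function(j) {
    substr(genome[[ex$chrom[j]]], ex$start[j] + 1L, ex$end[j])
  }, character(1)), collapse = "")
  if (ex$strand[1] == "-") s <- revcomp_dna(s)
  s
}

#' @export
print.pg_pipeline <- function(x, ...) {
  cat("<pg_pipeline> stages:", paste(x$log$stage, collapse = ", "), "\n")
  print(x$candidates)
  invisible(x)
}
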