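## Expression analysis and cross-omic integration: NB Wald differential
## expression, pseudogene-parent Spearman correlation with sign classes,
## tristile m6A-vs-expression analysis, correspondence (Sankey) tables and
## genetic-alteration summaries.

#' Negative-binomial Wald differential expression
#'
#' Tumour-vs-normal test per gene on the log2 fold change of CPM means with
#' pseudocount 1. Gene-wise NB dispersions are estimated by the method of
#' moments and shrunk toward the across-gene trend mean; the Wald statistic
#' uses a delta-method standard error of the log-ratio of group means and a
#' moderated t reference with `n_t + n_n - 2 + prior_df` degrees of
#' freedom. BH correction is
#' applied over all genes; `direction` is up/down at `q < 0.05`, else `ns`.
#'
#' @param expr A `pg_expr` (list with `counts` matrix and `samples` tibble),
#'   or a counts matrix together with `condition`.
#' @param condition Optional character vector of sample conditions
#'   (`tumour` / `normal`) when `expr` is a bare matrix.
#' @param shrink_weight Weight on the gene-wise dispersion estimate
#'   (remainder goes to the trend mean); default 0.25.
#' @param prior_df Extra degrees of freedom credited to the dispersion
#'   trend in the t reference (moderated-statistic logic: shrinking toward
#'   a trend estimated from all genes makes the variance estimate much less
#'   noisy than its per-gene degrees of freedom suggest); default 40.
#' @return Tibble of class `pg_de`: `gene_id`, `base_cpm`, `log2fc`, `se`,
#'   `p_value`, `q_value`, `direction`.
#' @export
differential_expression <- function(expr, condition = NULL,
                                    shrink_weight = 0.25, prior_df = 40) {
  if (inherits(expr, "pg_expr")) {
    counts <- expr$counts
    condition <- expr$samples$condition
  } else {
    counts <- as.matrix(expr)
  }
  stopifnot(!is.null(condition), ncol(counts) == length(condition))
  grp_t <- condition == "tumour"; grp_n <- condition == "normal"
  if (sum(grp_t) < 2 || sum(grp_n) < 2) {
    stop("differential_expression: need >= 2 samples per condition")
  }
  cpm <- normalize_cpm(counts)

  moments <- function(g) {
    m <- rowMeans(cpm[, g, drop = FALSE])
    v <- apply(cpm[, g, drop = FALSE], 1, var)
    list(m = m, v = v)
  }
  mt <- moments(grp_t); mn <- moments(grp_n)

  ## method-of-moments dispersion on the CPM scale, pooled over groups
  phi_of <- function(m, v) ifelse(m > 0, pmax((v - m) / m^2, 0), 0)
  phi_raw <- (phi_of(mt$m, mt$v) + phi_of(mn$m, mn$v)) / 2
  phi_trend <- mean(phi_raw[mt$m + mn$m > 0])
  phi <- shrink_weight * phi_raw + (1 - shrink_weight) * phi_trend

  nt <- sum(grp_t); nn <- sum(grp_n)
  ## delta method: Var(log(mean + 1)) = Var(mean) / (mean + 1)^2,
  ## Var(mean) = (mu + phi mu^2) / n on the CPM scale
  var_t <- (mt$m + phi * mt$m^2) / nt / (mt$m + 1)^2
  var_n <- (mn$m + phi * mn$m^2) / nn / (mn$m + 1)^2
  log2fc <- log2((mt$m + 1) / (mn$m + 1))
  se <- sqrt(var_t + var_n) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = nt + nn - 2 + prior_df)
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  log2fc[all_zero] <- 0
  q <- p.adjust(p, "BH")

  structure(
    tibble(
      gene_id = rownames(counts),
      base_cpm = unname((mt$m + mn$m) / 2),
      log2fc = unname(log2fc), se = unname(se), p_value = unname(p),
      q_value = unname(q),
      direction = dplyr::case_when(
        q < 0.05 & log2fc > 0 ~ "up",
        q < 0.05 & log2fc < 0 ~ "down",
        TRUE ~ "ns")),
    class = c("pg_de", "tbl_df", "tbl", "data.frame"))
}

#' Pseudogene-parent Spearman correlations with sign classes
#'
#' Rank correlation (average ranks for ties) of each pseudogene's expression
#' with its parent's across samples, classified `Positive` (rho > 0,
#' p < .05), `Negative` (rho < 0, p < .05), else `No`. A constant vector
#' makes rho undefined; such pairs are reported with `rho = NA` and class
#' `No`.
#'
#' @param expr A `pg_expr` or matrix of counts (log-scale is applied
#'   internally: `log2(CPM + 1)`).
#' @param pairs Tibble `pseudogene_id`, `parent_gene_id`.
#' @param samples Optional sample ids to restrict to (e.g. tumour only).
#' @return Tibble: pair ids, `rho`, `p_value`, `sign_class`.
#' @export
spearman_pairs <- function(expr, pairs, samples = NULL) {
  counts <- if (inherits(expr, "pg_expr")) expr$counts else as.matrix(expr)
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  if (ncol(counts) < 5) stop("spearman_pairs: need >= 5 samples")
  lg <- log2(normalize_cpm(counts) + 1)
  purrr::pmap_dfr(pairs, function(pseudogene_id, parent_gene_id, ...) {
    x <- lg[pseudogene_id, ]; y <- lg[parent_gene_id, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(pseudogene_id = pseudogene_id,
                    parent_gene_id = parent_gene_id,
                    rho = NA_real_, p_value = NA_real_, sign_class = "No"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
    tibble(pseudogene_id = pseudogene_id, parent_gene_id = parent_gene_id,
           rho = rho, p_value = p,
           sign_class = dplyr::case_when(
             rho > 0 & p < 0.05 ~ "Positive",
             rho < 0 & p < 0.05 ~ "Negative",
             TRUE ~ "No"))
  })
}

#' Tristile integration of m6A level and expression
#'
#' Groups genes by their m6A tertile, summarises each gene's expression as
#' the mean `log2(CPM + 1)` over tumour samples, runs pairwise two-sided
#' Wilcoxon rank-sum tests between tertiles, and returns the per-tertile
#' empirical CDF table used for CDF plots.
#'
#' @param m6a_levels Tibble from [gene_m6a_level()].
#' @param expr A `pg_expr`.
#' @param subtype_filter Optional tibble (`gene_id`, `subtype`) plus
#'   `subtypes` to keep.
#' @param subtypes Character vector of subtypes to keep (requires
#'   `subtype_filter`).
#' @return List: `gene_values` (gene, tertile, expression), `tests`
#'   (pairwise Wilcoxon results; tertiles with < 3 genes are skipped and
#'   flagged), `cdf` (tertile, expression grid, empirical CDF).
#' @export
tristile_integration <- function(m6a_levels, expr, subtype_filter = NULL,
                                 subtypes = NULL) {
  counts <- expr$counts
  tum <- expr$samples$sample_id[expr$samples$condition == "tumour"]
  lg <- log2(normalize_cpm(counts)[, tum, drop = FALSE] + 1)
  gv <- m6a_levels |>
    filter(.data$gene_id %in% rownames(lg)) |>
    mutate(expression = rowMeans(lg[.data$gene_id, , drop = FALSE]))
  if (!is.null(subtype_filter) && !is.null(subtypes)) {
    keep <- subtype_filter$gene_id[subtype_filter$subtype %in% subtypes]
    gv <- gv |> filter(.data$gene_id %in% keep)
  }

  lv <- c("low", "median", "high")
  combs <- utils::combn(lv, 2, simplify = FALSE)
  tests <- purrr::map_dfr(combs, function(pr) {
    a <- gv$expression[gv$tertile == pr[1]]
    b <- gv$expression[gv$tertile == pr[2]]
    if (length(a) < 3 || length(b) < 3) {
      return(tibble(group1 = pr[1], group2 = pr[2], n1 = length(a),
                    n2 = length(b), p_value = NA_real_, skipped = TRUE))
    }
    w <- wilcox.test(a, b)
    tibble(group1 = pr[1], group2 = pr[2], n1 = length(a), n2 = length(b),
           p_value = w$p.value, skipped = FALSE)
  })

  grid <- sort(unique(gv$expression))
  cdf <- purrr::map_dfr(lv, function(tv) {
    x <- gv$expression[gv$tertile == tv]
    if (!length(x)) return(tibble(tertile = tv, expression = double(),
                                  cdf = double()))
    tibble(tertile = tv, expression = grid,
           cdf = stats::ecdf(x)(grid))
  })
  list(gene_values = gv, tests = tests, cdf = cdf)
}

#' Pseudogene-parent correlation stratified by m6A level
#'
#' Attaches each pair's pseudogene m6A tertile (and optionally subtype) and
#' compares the distribution of Spearman rho between tertiles with pairwise
#' Wilcoxon tests. Strata with fewer than 3 pairs are skipped and flagged.
#'
#' @param correlations Tibble from [spearman_pairs()].
#' @param m6a_levels Tibble from [gene_m6a_level()].
#' @param subtype_table Optional tibble (`gene_id`, `subtype`).
#' @return List: `pair_strata` (pair, tertile, subtype, rho), `summary`
#'   (per tertile x subtype mean/median rho), `tests` (pairwise Wilcoxon
#'   between tertiles within subtype).
#' @export
correlation_by_m6a_strata <- function(correlations, m6a_levels,
                                      subtype_table = NULL) {
  ps <- correlations |>
    inner_join(m6a_levels |> select("gene_id", "tertile"),
               by = c("pseudogene_id" = "gene_id"))
  if (!is.null(subtype_table)) {
    ps <- ps |> left_join(subtype_table |> select("gene_id", "subtype"),
                          by = c("pseudogene_id" = "gene_id"))
  } else {
    ps$subtype <- "all"
  }
  ps <- ps |> filter(!is.na(.data$rho))

  summary_tbl <- ps |>
    group_by(.data$subtype, .data$tertile) |>
    summarise(n = n(), mean_rho = mean(.data$rho),
              median_rho = median(.data$rho), .groups = "drop")

  lv <- c("low", "median", "high")
  combs <- utils::combn(lv, 2, simplify = FALSE)
  tests <- purrr::map_dfr(unique(ps$subtype), function(st) {
    purrr::map_dfr(combs, function(pr) {
      a <- ps$rho[ps$subtype == st & ps$tertile == pr[1]]
      b <- ps$rho[ps$subtype == st & ps$tertile == pr[2]]
      if (length(a) < 3 || length(b) < 3) {
        return(tibble(subtype = st, group1 = pr[1], group2 = pr[2],
                      n1 = length(a), n2 = length(b), p_value = NA_real_,
                      skipped = TRUE))
      }
      tibble(subtype = st, group1 = pr[1], group2 = pr[2],
             n1 = length(a), n2 = length(b),
             p_value = wilcox.test(a, b)$p.value, skipped = FALSE)
    })
  })
  list(pair_strata = ps, summary = summary_tbl, tests = tests)
}

#' Correspondence (Sankey) table between two categorical flags
#'
#' Cross-tabulates two categorical vectors over the same gene set, reports
#' row proportions, and tests independence with a chi-square test (Fisher's
#' exact test when any expected cell is below 5).
#'
#' @param flags_a,flags_b Vectors (or factors) of equal length.
#' @param labels Optional `c(name_a, name_b)` for the output columns.
#' @return List: `table` (contingency matrix), `row_proportions`, `test`
#'   (`method`, `p_value`).
#' @export
correspondence_tables <- function(flags_a, flags_b,
                                  labels = c("A", "B")) {
  stopifnot(length(flags_a) == length(flags_b))
  fa <- factor(flags_a); fb <- factor(flags_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("correspondence_tables: fewer than 2 levels in a vector")
  }
  tab <- table(fa, fb, dnn = labels)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("correspondence_tables: zero margin in contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    test <- tibble(method = "fisher", p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    test <- tibble(method = "chisq", p_value = ct$p.value)
  }
  list(table = tab, row_proportions = prop.table(tab, 1), test = test)
}

#' Per-gene genetic alteration summary
#'
#' Mutation and CNV frequencies as altered-sample fractions, plus the
#' Spearman correlation of CNV state with `log2(CPM + 1)` expression over
#' the shared samples.
#'
#' @param mutation,cnv Genes x samples matrices (0/1 mutations; integer CNV
#'   states in -2..2).
#' @param expr Optional `pg_expr` or counts matrix for the CNV-expression
#'   correlation (sample names must overlap the CNV matrix).
#' @return Tibble: `gene_id`, `mutation_frequency`, `cnv_frequency`,
#'   `cnv_expression_rho`, `cnv_expression_p`.
#' @export
genetic_summary <- function(mutation, cnv, expr = NULL) {
  stopifnot(identical(rownames(mutation), rownames(cnv)))
  res <- tibble(
    gene_id = rownames(mutation),
    mutation_frequency = unname(rowMeans(mutation != 0)),
    cnv_frequency = unname(rowMeans(cnv != 0)),
    cnv_expression_rho = NA_real_,
    cnv_expression_p = NA_real_)
  if (!is.null(expr)) {
    counts <- if (inherits(expr, "pg_expr")) expr$counts else as.matrix(expr)
    shared <- intersect(colnames(cnv), colnames(counts))
    if (!length(shared)) stop("genetic_summary: disjoint sample sets")
    lg <- log2(normalize_cpm(counts)[, shared, drop = FALSE] + 1)
    for (i in seq_len(nrow(res))) {
      g <- res$gene_id[i]
      if (!g %in% rownames(lg)) next
      cv <- cnv[g, shared]
      if (sd(cv) == 0 || sd(lg[g, ]) == 0) next
      ct <- suppressWarnings(cor.test(cv, lg[g, ], method = "spearman"))
      res$cnv_expression_rho[i] <- unname(ct$estimate)
      res$cnv_expression_p[i] <- ct$p.value
    }
  }
  res
}
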