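## Univariate Cox proportional-hazards screening with risk/protective
## classification, Kaplan-Meier curves and the two-group log-rank test.
## Fits use Efron tie handling; the covariate is z-scored before fitting so
## the hazard ratio is per SD of expression.

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ value` by partial-likelihood maximization with
#' Efron tie handling. The covariate is standardized (z-scored) first so
#' `beta` is the log hazard ratio per SD. Monotone likelihood (perfect
#' separation) is detected, flagged and the estimate capped at +/- 10.
#'
#' @param records Tibble with columns `time` (> 0), `event` (0/1) and
#'   `value` (the covariate).
#' @param gene_id Optional label carried into the result.
#' @return Object of class `pg_cox`: list with `gene_id`, `beta`, `hr`,
#'   `se`, `z`, `p_value`, `n`, `n_events`, `separation` flag.
#' @export
cox_univariate <- function(records, gene_id = NA_character_) {
  assert_cols(records, c("time", "event", "value"), "cox_univariate")
  stopifnot(all(records$time > 0), all(records$event %in% c(0, 1)))
  if (sum(records$event) < 2) stop("cox_univariate: need >= 2 events")
  if (sd(records$value) == 0) {
    stop("cox_univariate: constant covariate is non-identifiable")
  }
  z <- as.numeric(scale(records$value))
  fit <- survival::coxph(survival::Surv(records$time, records$event) ~ z,
                         ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  separation <- !is.finite(beta) || abs(beta) > 10 || !is.finite(se)
  if (separation) {
    warning("cox_univariate: monotone likelihood; beta capped at +/-10")
    beta <- sign(beta) * min(abs(beta), 10)
  }
  wald <- beta / se
  structure(
    list(gene_id = gene_id, beta = beta, hr = exp(beta), se = se, z = wald,
         p_value = 2 * pnorm(-abs(wald)), n = nrow(records),
         n_events = sum(records$event), separation = separation),
    class = "pg_cox")
}

#' @export
print.pg_cox <- function(x, ...) {
  cat(sprintf("<pg_cox> %s: HR = %.3f (beta = %.3f, se = %.3f), p = %.3g\n",
              x$gene_id, x$hr, x$beta, x$se, x$p_value))
  invisible(x)
}

#' Classify a Cox result as risk / protective / not significant
#'
#' Risk when HR > 1 and p < `alpha`; protective when HR < 1 and p < `alpha`;
#' otherwise not significant.
#'
#' @param cox A `pg_cox` (or any list with `hr` and `p_value`).
#' @param alpha Significance level (default 0.05).
#' @return One of `"risk"`, `"protective"`, `"not significant"`.
#' @export
classify_prognostic <- function(cox, alpha = 0.05) {
  if (cox$p_value < alpha && cox$hr > 1) return("risk")
  if (cox$p_value < alpha && cox$hr < 1) return("protective")
  "not significant"
}

#' Per-gene univariate Cox screen
#'
#' Runs [cox_univariate()] for each gene's expression (`log2(CPM + 1)` over
#' the survival samples) against the survival table and classifies each
#' result.
#'
#' @param expr A `pg_expr` or counts matrix.
#' @param survival_tbl Tibble `sample_id`, `time`, `event`.
#' @param genes Optional subset of gene ids (default all).
#' @param alpha Significance level for classification.
#' @return Tibble of class `pg_cox_screen`: per-gene `beta`, `hr`, `se`,
#'   `p_value`, `q_value`, `classification`.
#' @export
cox_screen <- function(expr, survival_tbl, genes = NULL, alpha = 0.05) {
  counts <- if (inherits(expr, "pg_expr")) expr$counts else as.matrix(expr)
  shared <- intersect(colnames(counts), survival_tbl$sample_id)
  if (!length(shared)) stop("cox_screen: no shared samples")
  lg <- log2(normalize_cpm(counts)[, shared, drop = FALSE] + 1)
  sv <- survival_tbl[match(shared, survival_tbl$sample_id), ]
  if (is.null(genes)) genes <- rownames(lg)
  res <- purrr::map_dfr(genes, function(g) {
    val <- lg[g, ]
    if (sd(val) == 0) {
      return(tibble(gene_id = g, beta = NA_real_, hr = NA_real_,
                    se = NA_real_, p_value = NA_real_,
                    classification = "not significant"))
    }
    cx <- cox_univariate(tibble(time = sv$time, event = sv$event,
                                value = val), gene_id = g)
    tibble(gene_id = g, beta = cx$beta, hr = cx$hr, se = cx$se,
           p_value = cx$p_value,
           classification = classify_prognostic(cx, alpha))
  })
  res$q_value <- p.adjust(res$p_value, "BH")
  structure(res, class = c("pg_cox_screen", class(tibble())))
}

#' Kaplan-Meier curves and log-rank test for a covariate split
#'
#' Splits samples into high/low groups at the covariate median (or a custom
#' threshold), computes product-limit survival estimates per group and the
#' two-group log-rank chi-square.
#'
#' @param records Tibble `time`, `event`, `value`.
#' @param split `"median"` or a numeric threshold; samples with
#'   `value > threshold` form the high group.
#' @return List of class `pg_km`: `curves` (tibble `group`, `time`,
#'   `surv`, `n_risk`, `n_event`), `chisq`, `p_value`, `groups` (sizes).
#' @export
km_logrank <- function(records, split = "median") {
  assert_cols(records, c("time", "event", "value"), "km_logrank")
  thr <- if (identical(split, "median")) median(records$value) else split
  grp <- factor(if_else(records$value > thr, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) {
    stop("km_logrank: a group has zero samples at this split")
  }
  sf <- survival::survfit(
    survival::Surv(records$time, records$event) ~ grp)
  curves <- tibble(
    group = rep(sub("^grp=", "", names(sf$strata)),
                times = sf$strata),
    time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
    n_event = sf$n.event)
  sd_ <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd_$chisq), p_value = p,
                 groups = table(grp)),
            class = "pg_km")
}

#' @export
print.pg_km <- function(x, ...) {
  cat(sprintf("<pg_km> log-rank chisq = %.3f, p = %.3g (low n=%d, high n=%d)\n",
              x$chisq, x$p_value, x$groups[["low"]], x$groups[["high"]]))
  invisible(x)
}
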