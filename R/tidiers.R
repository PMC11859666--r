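## broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a univariate Cox fit
#'
#' @param x A `pg_cox`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate` (log HR per SD), `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.pg_cox <- function(x, ...) {
  tibble(term = "value", estimate = x$beta, std.error = x$se,
         statistic = x$z, p.value = x$p_value)
}

#' @rdname tidy.pg_cox
#' @return For `glance()`: one-row tibble with `n`, `n_events`, `hr`,
#'   `separation`.
#' @export
glance.pg_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, hr = x$hr,
         separation = x$separation)
}

#' Tidy a differential-expression result
#'
#' @param x A `pg_de`.
#' @param ... Unused.
#' @return Tibble with broom-style column names (`term` = gene id,
#'   `estimate` = log2 fold change, `p.value`, `q.value`).
#' @export
tidy.pg_de <- function(x, ...) {
  tibble(term = x$gene_id, estimate = x$log2fc, std.error = x$se,
         p.value = x$p_value, q.value = x$q_value,
         direction = x$direction)
}

#' @rdname tidy.pg_de
#' @export
glance.pg_de <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"))
}

#' Tidy a candidate report
#'
#' @param x A `pg_candidates`.
#' @param ... Unused.
#' @return The ranked report tibble.
#' @export
tidy.pg_candidates <- function(x, ...) x$report

#' @rdname tidy.pg_candidates
#' @export
glance.pg_candidates <- function(x, ...) {
  tibble(n_candidates = nrow(x$report),
         n_stages = nrow(x$attrition),
         top_candidate = if (nrow(x$report)) x$report$pseudogene_id[1] else
           NA_character_)
}
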