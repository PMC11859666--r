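## ggplot2 helpers for the main result types. These return ggplot objects;
## nothing is drawn as a side effect.

#' Metagene profile plot
#'
#' @param profile Tibble from [metagene_profile()].
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  segs <- c("5UTR", "exon", "3UTR")
  df <- profile |>
    mutate(segment = factor(.data$segment, levels = segs),
           x = as.integer(.data$segment) - 1 +
             (.data$bin - 0.5) / max(.data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_x_continuous(breaks = c(0.5, 1.5, 2.5), labels = segs) +
    ggplot2::labs(x = NULL, y = "peak density",
                  title = "Metagene distribution of m6A peaks") +
    ggplot2::theme_minimal()
}

#' Tristile expression CDF plot
#'
#' Cumulative distribution of gene expression per m6A tertile, the display
#' behind the m6A-vs-expression coupling claim.
#'
#' @param tristile Output of [tristile_integration()].
#' @return A ggplot.
#' @export
plot_tristile_cdf <- function(tristile) {
  ggplot2::ggplot(tristile$cdf,
                  ggplot2::aes(x = .data$expression, y = .data$cdf,
                               colour = .data$tertile)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "mean log2(CPM + 1)", y = "cumulative fraction",
                  colour = "m6A tertile") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression
#'
#' @param de A `pg_de`.
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumour vs normal)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot
#'
#' @param object A `pg_km` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of the two survival curves.
#' @export
autoplot.pg_km <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
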