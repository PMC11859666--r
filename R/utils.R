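#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic component of the pipeline draws from its own named
#' substream, so adding a new generator never perturbs the draws of an
#' existing one. The sub-seed is a deterministic 31-bit hash of the master
#' seed and the stream name.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name, e.g. `"merip"`.
#' @return A single integer in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "merip")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

#' Counts-per-million normalization
#'
#' Scales each sample (column) so that its counts sum to one million.
#'
#' @param mat Numeric matrix of non-negative counts, genes in rows, samples
#'   in columns.
#' @return A numeric matrix of the same dimensions; every column sums to 1e6.
#' @export
#' @examples
#' m <- matrix(c(10, 90, 50, 150), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' colSums(normalize_cpm(m))
normalize_cpm <- function(mat) {
  mat <- as.matrix(mat)
  depth <- colSums(mat)
  if (any(depth <= 0)) {
    stop("normalize_cpm: zero-depth sample(s): ",
         paste(colnames(mat)[depth <= 0], collapse = ", "))
  }
  sweep(mat, 2, depth / 1e6, "/")
}

## one-sided (enrichment) p for 2x2 table [a b; c d], P(X >= a) hypergeometric
hyper_p_greater <- function(a, b, c, d) {
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

## cut ranks 1..n into k contiguous groups whose sizes differ by <= 1
tertile_of_rank <- function(r, n, labels = c("low", "median", "high")) {
  stopifnot(length(labels) == 3L)
  labels[ceiling(r * 3 / n)]
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
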