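## Wet-lab quantification formulas as small, exactly-testable utilities.

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))`.
#' Vectorized over its arguments.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control condition.
#' @return Relative expression (1 when ddCt = 0).
#' @export
#' @examples
#' ddct(21, 20, 20, 20)  # ddCt = 1 -> 0.5
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}

#' One-phase exponential decay fit and RNA half-life
#'
#' Least-squares fit of `y = y0 * exp(-k * t)` (plateau fixed at
#' `plateau`, default 0, since abundances are expressed relative to t = 0).
#' Half-life is `ln(2) / k`; when the fitted `k <= 0` the half-life is
#' undefined and flagged.
#'
#' @param times Time points (>= 3).
#' @param abundances Abundances normalized to ~1 at t = 0.
#' @param plateau Fixed decay plateau (default 0).
#' @return List: `k`, `y0`, `half_life` (NA when undefined),
#'   `half_life_defined`.
#' @export
one_phase_decay_fit <- function(times, abundances, plateau = 0) {
  if (length(times) < 3 || length(abundances) != length(times)) {
    stop("one_phase_decay_fit: need >= 3 matching timepoints")
  }
  y <- abundances - plateau
  ## log-linear start values (guard against non-positive y)
  pos <- y > 0
  k0 <- if (sum(pos) >= 2) {
    max(1e-6, -unname(coef(stats::lm(log(y[pos]) ~ times[pos]))[2]))
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 * exp(-k * t),
      data = list(y = y, t = times),
      start = list(y0 = max(y[1], 1e-6), k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- 0; y0 <- mean(y)
  } else {
    k <- unname(coef(fit)[["k"]])
    y0 <- unname(coef(fit)[["y0"]])
  }
  ## rates at numerical noise level mean no measurable decay
  defined <- k > 1e-6
  list(k = k, y0 = y0,
       half_life = if (defined) log(2) / k else NA_real_,
       half_life_defined = defined)
}

#' Xenograft tumour volume
#'
#' `V = 0.5 * A * B^2` with A the longitudinal and B the latitudinal
#' diameter.
#'
#' @param A,B Diameters (A >= B >= 0).
#' @return Volume.
#' @export
#' @examples
#' tumor_volume(10, 6)  # 180
tumor_volume <- function(A, B) {
  if (any(A < 0) || any(B < 0)) stop("tumor_volume: negative input")
  0.5 * A * B^2
}

#' Wound-closure (migration) percentage
#'
#' `(width_0h - width_12h) / width_0h * 100`; negative values indicate the
#' wound widened.
#'
#' @param width_0h Wound width at 0 h (> 0).
#' @param width_12h Wound width at 12 h.
#' @return Percent closure.
#' @export
#' @examples
#' wound_closure(400, 300)  # 25
wound_closure <- function(width_0h, width_12h) {
  if (any(width_0h <= 0)) stop("wound_closure: width_0h must be > 0")
  (width_0h - width_12h) / width_0h * 100
}
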