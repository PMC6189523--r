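#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' Computes the magnitude signal of a spoiled multi-echo FLASH acquisition,
#' either from the exact Ernst steady state or from its small-flip-angle
#' rational approximation (the form inverted by the variable-flip-angle map
#' estimators).
#'
#' With `TRs = TR/1000` and `TEs = TE/1000` (seconds), `E1 = exp(-TRs * R1)`
#' and flip angle `alpha` in radians:
#'
#' * `ernst`: `S = A sin(a) (1 - E1) / (1 - cos(a) (1 - delta) E1) *
#'   (1 - delta) * exp(-TEs * R2star)`. The MT pre-pulse enters as a
#'   fractional saturation `delta` of the longitudinal magnetization once per
#'   TR.
#' * `small_angle`: `S = A a (TRs R1) / (a^2/2 + TRs R1 + delta) *
#'   exp(-TEs * R2star)`. This places `delta` additively next to the
#'   apparent-relaxation term, which is exactly the form the MT-saturation
#'   estimator solves for.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param A signal amplitude (proportional to proton density), > 0.
#' @param R1 longitudinal relaxation rate, 1/s, > 0.
#' @param R2star effective transverse relaxation rate, 1/s.
#' @param delta MT saturation as a dimensionless fraction (0 for non-MT
#'   weightings); must lie in `[0, 0.1)`.
#' @param alpha true flip angle in radians, in (0, pi/2).
#' @param TR repetition time in ms.
#' @param TE echo time in ms (0 gives the echo-train intercept).
#' @param model `"ernst"` or `"small_angle"`.
#' @return signal amplitude(s), same units as `A`.
#' @export
#' @examples
#' flash_signal(1000, 1.0, 20, 0, 5 * pi / 180, 25, 0, model = "small_angle")
flash_signal <- function(A, R1, R2star, delta = 0, alpha, TR, TE,
                         model = c("ernst", "small_angle")) {
  model <- match.arg(model)
  if (any(A <= 0)) stop("amplitude A must be positive")
  if (any(R1 <= 0)) stop("R1 must be positive")
  if (any(delta < 0 | delta >= 0.1))
    stop("delta must lie in [0, 0.1)")
  if (any(alpha < 0 | alpha >= pi / 2)) stop("alpha must lie in [0, pi/2)")
  TRs <- TR / 1000
  TEs <- TE / 1000
  decay <- exp(-TEs * R2star)
  if (model == "ernst") {
    E1 <- exp(-TRs * R1)
    A * sin(alpha) * (1 - E1) / (1 - cos(alpha) * (1 - delta) * E1) *
      (1 - delta) * decay
  } else {
    A * alpha * (TRs * R1) / (alpha^2 / 2 + TRs * R1 + delta) * decay
  }
}

#' Ernst angle of a spoiled gradient echo
#'
#' Flip angle maximizing the steady-state FLASH signal at given `TR` and
#' `R1` (no MT saturation): `acos(exp(-TR * R1 / 1000))`.
#'
#' @param R1 longitudinal relaxation rate, 1/s.
#' @param TR repetition time, ms.
#' @return angle in radians.
#' @export
ernst_angle <- function(R1, TR) acos(exp(-TR / 1000 * R1))
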