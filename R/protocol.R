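#' FLASH acquisition protocol
#'
#' Describes a three-weighting (PDw / T1w / MTw) multi-echo FLASH protocol:
#' nominal excitation flip angle, repetition time and echo train per
#' weighting, plus the MT pre-pulse flag. Two presets reproduce the two
#' acquisition protocols the simulator emulates:
#'
#' * `"cohort1"`: PDw and T1w at TR 25.25 ms with flip angles 5 and 29
#'   degrees; MTw at TR 29.25 ms, 9 degrees; eight echoes per weighting with
#'   TE from 2.39 ms to 18.91 ms in steps of 2.36 ms.
#' * `"cohort2"`: PDw and MTw at 6 degrees, T1w at 21 degrees, all at TR
#'   25 ms; eight echoes (TE 2.34 ms to 18.44 ms, step 2.30 ms) for PDw/T1w
#'   and only the first six echoes for MTw.
#'
#' @param preset `"cohort1"` or `"cohort2"`.
#' @return An object of class `mpm_protocol`: a list with `cohort_id` and a
#'   `weightings` list; each weighting holds `flip_deg`, `flip_rad`, `TR`
#'   (ms), `TE` (ms, strictly increasing), and `mt_pulse`.
#' @export
#' @examples
#' p <- mpm_protocol("cohort1")
#' p$weightings$PDw$TE
mpm_protocol <- function(preset = c("cohort1", "cohort2")) {
  preset <- match.arg(preset)
  if (preset == "cohort1") {
    te <- 2.39 + 2.36 * (0:7)
    w <- list(
      PDw = list(flip_deg = 5, TR = 25.25, TE = te, mt_pulse = FALSE),
      T1w = list(flip_deg = 29, TR = 25.25, TE = te, mt_pulse = FALSE),
      MTw = list(flip_deg = 9, TR = 29.25, TE = te, mt_pulse = TRUE)
    )
    cohort_id <- 1L
  } else {
    te <- 2.34 + 2.30 * (0:7)
    w <- list(
      PDw = list(flip_deg = 6, TR = 25, TE = te, mt_pulse = FALSE),
      T1w = list(flip_deg = 21, TR = 25, TE = te, mt_pulse = FALSE),
      MTw = list(flip_deg = 6, TR = 25, TE = te[1:6], mt_pulse = TRUE)
    )
    cohort_id <- 2L
  }
  new_mpm_protocol(w, cohort_id)
}

#' Construct and validate a protocol from explicit settings
#'
#' @param weightings named list (`PDw`, `T1w`, `MTw`) of lists with
#'   `flip_deg`, `TR` (ms), `TE` (ms vector), `mt_pulse`.
#' @param cohort_id integer cohort tag (1 or 2).
#' @return validated `mpm_protocol` object.
#' @export
new_mpm_protocol <- function(weightings, cohort_id = 1L) {
  stopifnot(is.list(weightings),
            all(c("PDw", "T1w", "MTw") %in% names(weightings)))
  for (nm in names(weightings)) {
    ww <- weightings[[nm]]
    if (!is.numeric(ww$flip_deg) || ww$flip_deg <= 0 || ww$flip_deg >= 90)
      stop("flip angle for ", nm, " must lie in (0, 90) degrees")
    if (any(diff(ww$TE) <= 0))
      stop("echo times for ", nm, " must be strictly increasing")
    if (ww$TR <= max(ww$TE))
      stop("TR for ", nm, " must exceed the last echo time")
    weightings[[nm]]$flip_rad <- ww$flip_deg * pi / 180
    weightings[[nm]]$mt_pulse <- isTRUE(ww$mt_pulse)
  }
  if (weightings$MTw$mt_pulse != TRUE)
    stop("MTw weighting must carry the MT pre-pulse")
  if (weightings$PDw$mt_pulse || weightings$T1w$mt_pulse)
    stop("only the MTw weighting may carry the MT pre-pulse")
  n_pd <- length(weightings$PDw$TE)
  if (length(weightings$T1w$TE) != n_pd)
    stop("PDw and T1w must have the same number of echoes")
  if (length(weightings$MTw$TE) > n_pd)
    stop("MTw may not have more echoes than PDw")
  structure(list(weightings = weightings, cohort_id = as.integer(cohort_id)),
            class = "mpm_protocol")
}

#' @export
print.mpm_protocol <- function(x, ...) {
  cat("<mpm_protocol> cohort", x$cohort_id, "\n")
  for (nm in names(x$weightings)) {
    ww <- x$weightings[[nm]]
    cat(sprintf("  %s: flip %g deg, TR %g ms, %d echoes (TE %g..%g ms)%s\n",
                nm, ww$flip_deg, ww$TR, length(ww$TE), min(ww$TE), max(ww$TE),
                if (ww$mt_pulse) ", MT pulse" else ""))
  }
  invisible(x)
}

#' Echoes entering the averaged volume for each weighting
#'
#' The second protocol restricts averaging to the first six echoes for all
#' weightings (so that the MTw train, which only has six, is matched); the
#' first protocol averages all eight.
#'
#' @param protocol an `mpm_protocol`.
#' @return named integer vector (PDw, T1w, MTw).
#' @export
default_echoes_used <- function(protocol) {
  n <- if (protocol$cohort_id == 2L) 6L else 8L
  c(PDw = min(n, length(protocol$weightings$PDw$TE)),
    T1w = min(n, length(protocol$weightings$T1w$TE)),
    MTw = min(n, length(protocol$weightings$MTw$TE)))
}
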