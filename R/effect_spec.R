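#' Ground-truth effect specification for the synthetic cohort
#'
#' Encodes everything the phantom generator needs about the tissue
#' parameters: population depth profiles in grey matter, fixed white-matter /
#' CSF values, inter-regional offsets (with designated heavily-myelinated
#' "primary" regions), curvature coupling, linear age effects restricted to
#' designated regions with attenuation toward the pial surface,
#' between-subject variance components, and acquisition noise.
#'
#' Parameters are indexed `R1` (1/s), `R2star` (1/s), `MTdelta`
#' (dimensionless MT saturation fraction; multiply by 100 for percent
#' units), and `A` (amplitude, proportional to proton density; white matter
#' is pinned at 69 so that calibrated PD* is directly comparable).
#'
#' Grey-matter depth profiles are cubic polynomials in the depth fraction
#' `d` (0 = white surface, 1 = pial): R1, MTdelta and R2star decline toward
#' the pial surface (R2star with quadratic truth, R1/MTdelta with cubic
#' truth), A rises. The subject-level generative model for a GM voxel of
#' region `r` at depth `d` for a subject of age `a` is
#'
#' `value = profile(d) + region_offset[r] + curv_coef * curvature
#'   + b_subject + b_subject_region[r] + b_slope_subject_region[r] * (d - 0.5)
#'   + age_slope * (a - age_reference) * (1 - attenuation * d) * [r affected]`
#'
#' @param noise_sd Gaussian noise SD of the simulated raw signals (signal
#'   units; amplitudes are on the PD percent scale). The default is
#'   calibrated so the fitted white-matter R1 map has SNR of about 50.
#' @param age_slopes named list of per-year slopes applied in
#'   `age_affected_regions` (defaults: R1 0.003 1/s/yr and MTdelta
#'   7.5e-5/yr, i.e. 0.0075 pu/yr; R2star and A 0).
#' @param age_affected_regions integer region ids carrying the age effect.
#' @param age_depth_attenuation fraction by which the age slope shrinks from
#'   the white (d = 0) to the pial (d = 1) surface.
#' @param age_reference age (years) at which the age term vanishes.
#' @param subject_sd,subject_region_sd,subject_slope_sd named lists of
#'   between-subject variance components (SDs) for the random intercept,
#'   region-within-subject intercept, and region-within-subject linear depth
#'   slope.
#' @param region_offset_sd named list of population-level inter-regional
#'   offset SDs.
#' @param primary_regions region ids given an extra myelination offset
#'   (primary > association contrast).
#' @param primary_boost named list of offsets added in `primary_regions`.
#' @param profiles,wm,csf,curv_coef advanced overrides of the population
#'   depth-profile polynomial coefficients (constant term first), tissue
#'   constants and curvature couplings.
#' @param thickness_confound per-unit effect of the subject's relative
#'   thickness deviation on R1 (confounder removed by residualization).
#' @return object of class `effect_spec` (a validated list).
#' @export
effect_spec <- function(noise_sd = 0.12,
                        age_slopes = list(R1 = 0.003, R2star = 0,
                                          MTdelta = 7.5e-5, A = 0),
                        age_affected_regions = c(3L, 5L, 9L),
                        age_depth_attenuation = 0.5,
                        age_reference = 28.5,
                        subject_sd = list(R1 = 0.01, R2star = 0.7,
                                          MTdelta = 3e-4, A = 2),
                        subject_region_sd = list(R1 = 0.008, R2star = 0.3,
                                                 MTdelta = 2.5e-4, A = 1),
                        subject_slope_sd = list(R1 = 0.01, R2star = 0.4,
                                                MTdelta = 4e-4, A = 1),
                        region_offset_sd = list(R1 = 0.015, R2star = 0.5,
                                                MTdelta = 5e-4, A = 1.5),
                        primary_regions = c(1L, 8L, 12L),
                        primary_boost = list(R1 = 0.05, R2star = 1.5,
                                             MTdelta = 1.5e-3, A = -3),
                        profiles = NULL, wm = NULL, csf = NULL,
                        curv_coef = NULL,
                        thickness_confound = 0.05) {
  default_profiles <- list(
    R1 = c(0.72, -0.18, 0.10, -0.06),      # cubic decline, 0.72 -> 0.58
    R2star = c(16.5, -2.0, -1.5, 0),       # quadratic decline, 16.5 -> 13
    MTdelta = c(0.014, -0.005, 0, -0.002), # cubic decline, 1.4 -> 0.7 pu
    A = c(78, 6, 0, 2)                     # cubic rise, 78 -> 86
  )
  default_wm <- list(R1 = 1.05, R2star = 21, MTdelta = 0.019, A = 69)
  default_csf <- list(R1 = 0.25, R2star = 2, MTdelta = 0, A = 100)
  default_curv <- list(R1 = -0.05, R2star = -1.0, MTdelta = -5e-4, A = 2)
  spec <- list(
    profiles = profiles %||% default_profiles,
    wm = wm %||% default_wm,
    csf = csf %||% default_csf,
    curv_coef = curv_coef %||% default_curv,
    region_offset_sd = region_offset_sd,
    primary_regions = as.integer(primary_regions),
    primary_boost = primary_boost,
    age_slopes = age_slopes,
    age_affected_regions = as.integer(age_affected_regions),
    age_depth_attenuation = age_depth_attenuation,
    age_reference = age_reference,
    subject_sd = subject_sd,
    subject_region_sd = subject_region_sd,
    subject_slope_sd = subject_slope_sd,
    noise_sd = noise_sd,
    thickness_confound = thickness_confound
  )
  class(spec) <- "effect_spec"
  validate_effect_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mpm_params <- c("R1", "R2star", "MTdelta", "A")

#' @rdname effect_spec
#' @param spec an `effect_spec` to validate.
#' @export
validate_effect_spec <- function(spec) {
  for (p in .mpm_params) {
    for (comp in c("subject_sd", "subject_region_sd", "subject_slope_sd",
                   "region_offset_sd")) {
      v <- spec[[comp]][[p]]
      if (is.null(v) || v < 0)
        stop("variance component ", comp, "$", p, " must be >= 0")
    }
    if (is.null(spec$profiles[[p]])) stop("missing profile for ", p)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  # profiles must keep parameters physiological over the depth range, even
  # at +/- 4 SD of the combined random effects and extreme ages (18-39 with
  # the default reference)
  d <- seq(0, 1, by = 0.05)
  for (p in .mpm_params) {
    base <- .poly_eval(spec$profiles[[p]], d)
    spread <- 4 * sqrt(spec$subject_sd[[p]]^2 + spec$subject_region_sd[[p]]^2 +
                         (0.5 * spec$subject_slope_sd[[p]])^2 +
                         spec$region_offset_sd[[p]]^2) +
      abs(spec$primary_boost[[p]]) +
      abs(spec$age_slopes[[p]]) * 12
    lo <- min(base) - spread
    hi <- max(base) + spread
    if (p %in% c("R1", "R2star", "A") && lo <= 0)
      stop("effect spec can drive ", p, " non-positive; reduce variance ",
           "components or offsets")
    if (p == "MTdelta" && (lo < 0 || hi >= 0.1))
      stop("effect spec can drive MT saturation outside [0, 0.1)")
  }
  invisible(spec)
}

.poly_eval <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

#' Evaluate a population grey-matter depth profile
#'
#' @param spec an `effect_spec`.
#' @param param one of `"R1"`, `"R2star"`, `"MTdelta"`, `"A"`.
#' @param d depth fraction(s) in `[0, 1]`.
#' @return profile value(s), without regional or subject terms.
#' @export
gm_profile <- function(spec, param, d) {
  param <- match.arg(param, .mpm_params)
  .poly_eval(spec$profiles[[param]], d)
}
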