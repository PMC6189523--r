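#' Generate a synthetic subject cohort with ground-truth tissue parameters
#'
#' Draws the subject table (age in whole years, gender, acquisition cohort),
#' the population inter-regional offsets, and all between-subject random
#' effects declared in the [effect_spec()]. Ground-truth voxel volumes for a
#' given subject are materialized on demand with [subject_ground_truth()],
#' so the cohort object stays small. The full generative recipe (spec,
#' seed, drawn effects) is stored, making every subject's truth exactly
#' recoverable.
#'
#' Ages are drawn uniformly over `age_range` (whole years). The first
#' `round(n 34/93)` subjects belong to acquisition cohort 1 and the rest to
#' cohort 2, mirroring the emulated study's split. Each subject also gets
#' multiplicative "measurement" factors for thickness and curvature
#' (per-subject surface-reconstruction variability) used as residualization
#' covariates; the thickness factor feeds back into R1 through
#' `spec$thickness_confound`.
#'
#' @param n_subjects number of subjects (>= 2); default 93.
#' @param age_range inclusive age range in years.
#' @param spec an [effect_spec()].
#' @param n_regions number of regions (must match the cortical model).
#' @param seed integer seed; the cohort is byte-identical on regeneration.
#' @param covariate_jitter_sd SDs of the per-subject thickness and curvature
#'   measurement factors.
#' @return object of class `mpm_cohort`: `$subjects` (data.frame: `id`,
#'   `age`, `gender`, `cohort_id`, `thick_mult`, `curv_mult`),
#'   `$region_offsets` (region x parameter matrix), `$b_subject`,
#'   `$b_subject_region`, `$b_slope` (random-effect draws), `$spec`,
#'   `$seed`.
#' @export
make_cohort <- function(n_subjects = 93, age_range = c(18, 39),
                        spec = effect_spec(), n_regions = 17,
                        seed = 1,
                        covariate_jitter_sd = c(thickness = 0.03,
                                                curvature = 0.05)) {
  stopifnot(n_subjects >= 2, n_regions >= 2)
  validate_effect_spec(spec)
  .run_seeded(seed, {
    n_c1 <- round(n_subjects * 34 / 93)
    subjects <- data.frame(
      id = sprintf("sub-%03d", seq_len(n_subjects)),
      age = sample(seq(age_range[1], age_range[2]), n_subjects,
                   replace = TRUE),
      gender = sample(c("F", "M"), n_subjects, replace = TRUE,
                      prob = c(0.61, 0.39)),
      cohort_id = rep(c(1L, 2L), c(n_c1, n_subjects - n_c1)),
      thick_mult = 1 + stats::rnorm(n_subjects, 0,
                                    covariate_jitter_sd[["thickness"]]),
      curv_mult = 1 + stats::rnorm(n_subjects, 0,
                                   covariate_jitter_sd[["curvature"]]),
      stringsAsFactors = FALSE
    )
    region_offsets <- sapply(.mpm_params, function(p) {
      off <- stats::rnorm(n_regions, 0, spec$region_offset_sd[[p]])
      keep <- spec$primary_regions[spec$primary_regions <= n_regions]
      off[keep] <- off[keep] + spec$primary_boost[[p]]
      off
    })
    # Random intercepts are orthogonalized against age within the sample:
    # in the stated world the planted slopes are the ONLY age structure, so
    # the finite-sample chance correlation of these (vertex-shared) draws
    # with age - which would act as a global confounder of the vertex-wise
    # correlation maps - is removed at generation time.
    orth_age <- function(b)
      unname(stats::resid(stats::lm(b ~ subjects$age)))
    b_subject <- sapply(.mpm_params, function(p)
      orth_age(stats::rnorm(n_subjects, 0, spec$subject_sd[[p]])))
    b_subject_region <- sapply(.mpm_params, function(p)
      apply(matrix(stats::rnorm(n_subjects * n_regions, 0,
                                spec$subject_region_sd[[p]]),
                   n_subjects, n_regions), 2, orth_age),
      simplify = "array")
    b_slope <- sapply(.mpm_params, function(p)
      matrix(stats::rnorm(n_subjects * n_regions, 0,
                          spec$subject_slope_sd[[p]]),
             n_subjects, n_regions), simplify = "array")
    structure(list(subjects = subjects, region_offsets = region_offsets,
                   b_subject = b_subject, b_subject_region = b_subject_region,
                   b_slope = b_slope, spec = spec, n_regions = n_regions,
                   seed = seed),
              class = "mpm_cohort")
  })
}

#' @export
print.mpm_cohort <- function(x, ...) {
  cat("<mpm_cohort>", nrow(x$subjects), "subjects, ages",
      min(x$subjects$age), "-", max(x$subjects$age), ",",
      x$n_regions, "regions (seed", x$seed, ")\n")
  invisible(x)
}

#' Materialize a subject's ground-truth parameter volumes
#'
#' Evaluates the generative model of [make_cohort()] on the voxel grid of a
#' cortical model: white matter and CSF take their fixed tissue values,
#' grey-matter voxels get the population depth profile plus regional offset,
#' curvature coupling, subject random effects, the subject's random linear
#' depth slope, and (in designated regions) the attenuated linear age
#' effect. Background voxels have zero amplitude.
#'
#' @param cohort an `mpm_cohort`.
#' @param i subject index (row of `cohort$subjects`).
#' @param model the `cortical_model` whose grid to fill (its region count
#'   must match the cohort's).
#' @return object of class `tissue_ground_truth`: list of 3D arrays `R1`,
#'   `R2star`, `MTdelta`, `A` plus `subject` (the subject row) and
#'   `grid_meta`.
#' @export
subject_ground_truth <- function(cohort, i, model) {
  stopifnot(inherits(cohort, "mpm_cohort"), inherits(model, "cortical_model"))
  if (cohort$n_regions != model$params$n_regions)
    stop("cohort and model disagree on the number of regions")
  g <- model$grid
  spec <- cohort$spec
  subj <- cohort$subjects[i, ]
  gm <- which(g$tissue == 2L)
  wm <- g$tissue == 1L
  csf <- g$tissue == 3L
  d <- g$depth[gm]
  r <- g$region[gm]
  hv <- g$hemi[gm]
  vv <- g$vidx[gm]
  curv <- numeric(length(gm))
  for (hi in seq_along(model$hemis)) {
    sel <- hv == hi
    curv[sel] <- model$hemis[[hi]]$curvature[vv[sel]]
  }
  age_dev <- subj$age - spec$age_reference
  affected <- r %in% spec$age_affected_regions
  out <- list()
  for (p in .mpm_params) {
    arr <- array(0, g$dim)
    arr[wm] <- spec$wm[[p]]
    arr[csf] <- spec$csf[[p]]
    val <- .poly_eval(spec$profiles[[p]], d) +
      cohort$region_offsets[r, p] +
      spec$curv_coef[[p]] * curv +
      cohort$b_subject[i, p] +
      cohort$b_subject_region[i, r, p] +
      cohort$b_slope[i, r, p] * (d - 0.5) +
      ifelse(affected, spec$age_slopes[[p]] * age_dev *
               (1 - spec$age_depth_attenuation * d), 0)
    if (p == "R1")
      val <- val + spec$thickness_confound * (subj$thick_mult - 1)
    arr[gm] <- val
    out[[p]] <- arr
  }
  if (any(out$R1[g$tissue > 0] <= 0) || any(out$A[g$tissue > 0] <= 0) ||
      any(out$MTdelta[g$tissue > 0] < 0) ||
      any(out$MTdelta[g$tissue > 0] >= 0.1))
    stop("effect spec produced non-physical ground-truth parameters")
  out$subject <- subj
  out$tissue <- g$tissue
  out$grid_meta <- list(dim = g$dim, origin = g$origin,
                        voxel_size = g$voxel_size)
  class(out) <- "tissue_ground_truth"
  out
}
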