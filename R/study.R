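# High-level in-memory study drivers: simulate-fit-sample every subject of
# a cohort, and run the vertex-wise age-effect analysis on the sampled
# values. These power both the pipeline stages and the acceptance checks.

.subject_seed <- function(seed, i, salt = 0L) {
  (as.integer(seed) * 10007L + i * 7919L + salt) %% 2147483629L
}

#' Simulate, fit and depth-sample an entire cohort
#'
#' For each subject: materialize the ground truth on the model grid, draw
#' participant-specific transmit/receive fields, forward-simulate the
#' protocol of the subject's acquisition cohort, estimate the four
#' parameter maps, and sample them at the requested depth fractions. All
#' per-subject randomness derives from `seed`.
#'
#' @param model a `cortical_model`.
#' @param cohort an `mpm_cohort` (its `spec$noise_sd` sets the raw-signal
#'   noise).
#' @param fractions depth fractions to sample.
#' @param seed integer master seed.
#' @param params parameters to sample.
#' @param forward_model forward signal model for simulation.
#' @param keep_maps keep each subject's fitted `parameter_maps` (memory!).
#' @param progress print one line per subject.
#' @return list of class `mpm_study`: `values` (array `[vertex, depth,
#'   parameter, subject]`), `fractions`, `vertices` (vertex table),
#'   `subjects`, `model`, `cohort`, `maps` (if kept), `wm_snr` (per-subject
#'   white-matter R1 map SNR).
#' @export
run_study <- function(model, cohort, fractions = seq(0.1, 0.9, by = 0.1),
                      seed = 1, params = c("R1", "R2star", "MTsat", "PDstar"),
                      forward_model = "ernst", keep_maps = FALSE,
                      progress = FALSE) {
  n <- nrow(cohort$subjects)
  vt <- model_vertex_table(model)
  values <- array(NA_real_, c(nrow(vt), length(fractions), length(params), n),
                  dimnames = list(NULL, NULL, params, cohort$subjects$id))
  maps_list <- if (keep_maps) vector("list", n) else NULL
  wm_snr <- numeric(n)
  protocols <- list(`1` = mpm_protocol("cohort1"),
                    `2` = mpm_protocol("cohort2"))
  for (i in seq_len(n)) {
    gt <- subject_ground_truth(cohort, i, model)
    fields <- make_field_maps(model, seed = .subject_seed(seed, i, 1L))
    proto <- protocols[[as.character(cohort$subjects$cohort_id[i])]]
    vols <- simulate_weighted_volumes(gt, fields, proto,
                                      noise_sd = cohort$spec$noise_sd,
                                      seed = .subject_seed(seed, i, 2L),
                                      forward_model = forward_model)
    maps <- fit_all_maps(vols)
    wm <- vols$tissue == 1L & maps$valid
    wm_snr[i] <- mean(maps$R1[wm]) / stats::sd(maps$R1[wm])
    sampled <- sample_parameter_maps(maps, model, fractions, params)
    values[, , , i] <- sampled
    if (keep_maps) maps_list[[i]] <- maps
    if (progress)
      message(sprintf("subject %d/%d done (WM R1 SNR %.1f)", i, n, wm_snr[i]))
  }
  structure(list(values = values, fractions = fractions, vertices = vt,
                 subjects = cohort$subjects, model = model, cohort = cohort,
                 maps = maps_list, wm_snr = wm_snr, seed = seed),
            class = "mpm_study")
}

#' ROI x depth profile table for a study
#'
#' @param study an `mpm_study`.
#' @return tidy data.frame (subject, region, depth, parameter, value,
#'   n_vertices), hemisphere-averaged.
#' @export
study_roi_profiles <- function(study) {
  out <- lapply(seq_len(dim(study$values)[4]), function(i) {
    sampled <- study$values[, , , i, drop = FALSE]
    dim(sampled) <- dim(study$values)[1:3]
    dimnames(sampled) <- dimnames(study$values)[1:3]
    attr(sampled, "fractions") <- study$fractions
    roi_depth_means(sampled, study$model, subject = study$subjects$id[i])
  })
  do.call(rbind, out)
}

#' Vertex-wise jackknifed age-effect mapping for a study
#'
#' Implements the full age path: extract values at the analysis depth
#' (default mid-cortex, 0.5), residualize on curvature, thickness and
#' acquisition cohort (per-subject covariate measurements), Pearson-correlate
#' with age with the Fisher-z leave-one-out jackknife, threshold per
#' hemisphere at FDR `q`, intersect the R1 and MT masks into connected
#' overlap ROIs, and fit each ROI's age slope. Statistics are always
#' computed unsmoothed; `smooth_steps` only affects exported display maps.
#'
#' @param study an `mpm_study` whose sampled fractions include `depth`.
#' @param depth analysis depth fraction.
#' @param q_level FDR level per hemisphere.
#' @param params parameters to map (first two define the overlap ROIs).
#' @param residualize_covariates use curvature/thickness/cohort
#'   residualization before correlating.
#' @param smooth_steps smoothing steps for the exported display maps.
#' @return list of class `age_effect_results`: `stats` (per-parameter
#'   `jackknife_map` with `q` and `significant` columns), `masks`
#'   (per-parameter logical vectors), `rois` (overlap ROIs across
#'   hemispheres), `slopes` (per ROI x parameter age-slope fits),
#'   `display` (smoothed jackknife r maps), `depth`, `q_level`.
#' @export
age_effect_mapping <- function(study, depth = 0.5, q_level = 0.05,
                               params = c("R1", "MTsat"),
                               residualize_covariates = TRUE,
                               smooth_steps = 10) {
  k <- match(depth, study$fractions)
  if (is.na(k)) stop("depth ", depth, " was not sampled in this study")
  vt <- study$vertices
  ages <- study$subjects$age
  n <- length(ages)
  covars <- list(
    curvature = outer(vt$curvature, study$subjects$curv_mult),
    thickness = outer(vt$thickness, study$subjects$thick_mult),
    cohort = as.numeric(study$subjects$cohort_id == 2L))
  adjacency <- lapply(study$model$hemis, function(h) h$adjacency)
  stats_out <- list()
  masks <- list()
  display <- list()
  for (p in params) {
    vals <- study$values[, k, p, ]
    res <- if (residualize_covariates) {
      if (length(unique(study$subjects$cohort_id)) == 1)
        covars$cohort <- NULL
      suppressWarnings(residualize(vals, covars))
    } else vals
    jk <- jackknife_correlation(res, ages, hemi = vt$hemi)
    fdr <- fdr_threshold(jk$p, q_level, grouping = vt$hemi)
    jk$q <- fdr$q
    jk$significant <- fdr$mask
    stats_out[[p]] <- jk
    masks[[p]] <- fdr$mask
    disp <- jk$r_jack
    for (nm in names(adjacency)) {
      sel <- vt$hemi == nm
      disp[sel] <- surface_smooth(disp[sel], adjacency[[nm]], smooth_steps)
    }
    display[[p]] <- disp
  }
  rois <- list()
  slopes <- list()
  if (length(params) >= 2) {
    for (nm in names(adjacency)) {
      sel <- vt$hemi == nm
      rr <- overlap_rois(masks[[params[1]]][sel], masks[[params[2]]][sel],
                         adjacency[[nm]], hemi = nm)
      for (roi in rr) {
        rois[[length(rois) + 1]] <- roi
        gidx <- which(sel)[roi$vertices]
        slopes[[length(slopes) + 1]] <- lapply(params, function(p)
          roi_age_slope(list(vertices = gidx), study$values[, k, p, ], ages))
        names(slopes[[length(slopes)]]) <- params
      }
    }
  }
  structure(list(stats = stats_out, masks = masks, rois = rois,
                 slopes = slopes, display = display, depth = depth,
                 q_level = q_level, params = params),
            class = "age_effect_results")
}

#' @export
print.age_effect_results <- function(x, ...) {
  cat("<age_effect_results> depth", x$depth, ", q <", x$q_level,
      "per hemisphere\n")
  for (p in names(x$masks))
    cat(sprintf("  %-7s %d significant vertices\n", p, sum(x$masks[[p]])))
  cat(" ", length(x$rois), "overlap ROI(s)\n")
  invisible(x)
}
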