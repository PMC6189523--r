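# Hierarchical models of ROI-mean parameter value versus cortical depth:
# polynomial fixed effects for depth, random intercepts for subject and
# ROI-within-subject, a random linear depth slope within ROI, ML fitting so
# that likelihood-ratio tests on fixed effects are valid, and forward LRT
# selection of the depth polynomial order.

#' Fit a multilevel depth-profile model
#'
#' Fits, by maximum likelihood (not REML, so that likelihood-ratio tests of
#' nested fixed-effect structures are valid),
#'
#' `value ~ cohort + gender + roi + d_c + d_c^2 + ... + d_c^order
#'   [+ age (+ age:d_c) (+ age:roi) (+ age:d_c:roi)]
#'   + (1 | subject) + (1 + d_c | subject:roi)`
#'
#' where `d_c` is the depth fraction centered at its mean before polynomial
#' expansion (raw centered powers by default; an orthogonal basis is
#' available for conditioning). This realizes a three-level hierarchy -
#' depths nested in ROIs nested in subjects - with a random linear depth
#' slope within each subject-by-ROI cell. Constant covariates (single
#' cohort or gender) are dropped automatically. If the full random
#' structure fails, a simpler two-level fallback
#' `(1 | subject) + (1 | subject:roi)` is fitted and recorded.
#'
#' @param profile_data tidy data.frame with columns `subject`, `region`,
#'   `depth`, `value` (one parameter at a time; see [roi_depth_means()]).
#' @param subjects subject table with columns `id`, `age`, `gender`,
#'   `cohort_id`.
#' @param depth_order 1, 2 or 3.
#' @param include_age,age_depth,age_roi,age_depth_roi age fixed-effect
#'   terms: main effect, age x depth, age x ROI, age x depth x ROI.
#' @param orthogonal use an orthogonal polynomial depth basis.
#' @return object of class `multilevel_fit`: `model` (the lmerMod), `logLik`,
#'   `n_par`, `n_obs`, `fixed` (coefficient table), `varcomp`, `converged`,
#'   `random_structure` (`"full"` or `"fallback"`), `depth_order`,
#'   `formula`.
#' @export
fit_multilevel_depth <- function(profile_data, subjects, depth_order = 1,
                                 include_age = FALSE, age_depth = FALSE,
                                 age_roi = FALSE, age_depth_roi = FALSE,
                                 orthogonal = FALSE) {
  stopifnot(depth_order %in% 1:3,
            all(c("subject", "region", "depth", "value") %in%
                  names(profile_data)))
  if (length(unique(profile_data$subject)) < 2) stop("need >= 2 subjects")
  if (length(unique(profile_data$region)) < 2) stop("need >= 2 ROIs")
  if (length(unique(profile_data$depth)) < depth_order + 2)
    stop("need at least depth_order + 2 distinct depth points")
  dat <- merge(profile_data,
               subjects[, c("id", "age", "gender", "cohort_id")],
               by.x = "subject", by.y = "id", sort = FALSE)
  dat$roi <- factor(dat$region)
  dat$subj <- factor(dat$subject)
  dat$d_c <- dat$depth - mean(unique(profile_data$depth))
  if (orthogonal) {
    P <- stats::poly(dat$d_c, degree = depth_order)
    for (k in seq_len(depth_order)) dat[[paste0("dp", k)]] <- P[, k]
  } else {
    for (k in seq_len(depth_order)) dat[[paste0("dp", k)]] <- dat$d_c^k
  }
  terms <- c()
  if (length(unique(dat$cohort_id)) > 1) terms <- c(terms, "factor(cohort_id)")
  if (length(unique(dat$gender)) > 1) terms <- c(terms, "gender")
  terms <- c(terms, "roi", paste0("dp", seq_len(depth_order)))
  if (include_age) terms <- c(terms, "age")
  if (age_depth) terms <- c(terms, "age:dp1")
  if (age_roi) terms <- c(terms, "age:roi")
  if (age_depth_roi) terms <- c(terms, "age:dp1:roi")
  rhs_full <- paste(c(terms, "(1 | subj)", "(1 + d_c | subj:roi)"),
                    collapse = " + ")
  fml <- stats::as.formula(paste("value ~", rhs_full))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- NULL
  random_structure <- "full"
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(fml, data = dat, REML = FALSE, control = ctrl),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    random_structure <- "fallback"
    fml <- stats::as.formula(paste("value ~",
                                   paste(c(terms, "(1 | subj)",
                                           "(1 | subj:roi)"),
                                         collapse = " + ")))
    converged <- TRUE
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = dat, REML = FALSE, control = ctrl),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
  }
  ll <- stats::logLik(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  fe <- summary(fit)$coefficients
  structure(list(model = fit, logLik = as.numeric(ll),
                 n_par = attr(ll, "df"), n_obs = nrow(dat),
                 fixed = fe, varcomp = vc, converged = converged,
                 random_structure = random_structure,
                 depth_order = depth_order, formula = fml),
            class = "multilevel_fit")
}

#' @export
print.multilevel_fit <- function(x, ...) {
  cat("<multilevel_fit> depth order", x$depth_order, "|",
      x$n_obs, "obs |", x$n_par, "parameters | logLik",
      format(x$logLik, digits = 8),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested multilevel fits
#'
#' `statistic = 2 (logLik_large - logLik_small)`, referred to a chi-square
#' with degrees of freedom equal to the parameter-count difference. The
#' fits must be on identical data (same `n_obs`) and ML-estimated; a
#' negative statistic within optimizer tolerance is treated as 0.
#'
#' @param fit_small,fit_large `multilevel_fit` objects, small nested in
#'   large.
#' @return object of class `lrt_result`: `statistic`, `df`, `p_value`,
#'   `preferred` (`"large"` if p < 0.05 else `"small"`).
#' @export
lrt_compare <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "multilevel_fit"),
            inherits(fit_large, "multilevel_fit"))
  if (fit_small$n_obs != fit_large$n_obs)
    stop("models were not fitted to identical data")
  df <- fit_large$n_par - fit_small$n_par
  if (df < 0) stop("models are not nested (no extra parameters in large)")
  stat <- 2 * (fit_large$logLik - fit_small$logLik)
  if (df == 0) { # identical parameterizations
    return(structure(list(statistic = max(stat, 0), df = 0L, p_value = 1,
                          preferred = "small"), class = "lrt_result"))
  }
  if (stat < -1e-6 * abs(fit_large$logLik) - 1e-4)
    warning("large model has lower likelihood than the nested small model; ",
            "possible non-convergence")
  p <- stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 preferred = if (p < 0.05) "large" else "small"),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> chi2(%d) = %.3f, p = %.3g -> prefer %s model\n",
              x$df, x$statistic, x$p_value, x$preferred))
  invisible(x)
}

#' Select the depth polynomial order by forward likelihood-ratio tests
#'
#' Fits orders 1, 2, ... and accepts each higher order iff the LRT against
#' the previous order has `p < alpha` (linear vs quadratic, then quadratic
#' vs cubic); stops at the first non-significant step.
#'
#' @param profile_data,subjects as in [fit_multilevel_depth()].
#' @param max_order highest order to consider (<= 3).
#' @param alpha acceptance level for each LRT.
#' @param ... passed to [fit_multilevel_depth()].
#' @return list `order` (chosen order), `tests` (list of `lrt_result`),
#'   `fits` (list of `multilevel_fit`, by order).
#' @export
select_depth_order <- function(profile_data, subjects, max_order = 3,
                               alpha = 0.05, ...) {
  stopifnot(max_order >= 1, max_order <= 3)
  n_depths <- length(unique(profile_data$depth))
  max_order <- min(max_order, n_depths - 2L)
  if (max_order < 1) stop("need at least 3 distinct depth points")
  fits <- list()
  tests <- list()
  fits[[1]] <- fit_multilevel_depth(profile_data, subjects, depth_order = 1,
                                    ...)
  chosen <- 1L
  for (k in seq_len(max_order)[-1]) {
    fits[[k]] <- fit_multilevel_depth(profile_data, subjects,
                                      depth_order = k, ...)
    tests[[k - 1]] <- lrt_compare(fits[[chosen]], fits[[k]])
    if (tests[[k - 1]]$p_value < alpha) chosen <- k else break
  }
  list(order = chosen, tests = tests, fits = fits)
}

#' Simulate ROI-mean depth profiles from the hierarchical model
#'
#' Draws tidy ROI x depth profile tables directly from the generative model
#' that [fit_multilevel_depth()] assumes: fixed polynomial depth profile
#' (centered basis) plus ROI offsets, cohort and gender effects, subject
#' and subject-by-ROI random intercepts, a subject-by-ROI random linear
#' depth slope, and i.i.d. residual noise. Defaults mirror an R1-like
#' profile at the emulated study's scale (93 subjects x 17 ROIs x 9
#' depths); the residual SD reflects ROI means over a few hundred vertices,
#' not single vertices.
#'
#' @param n_subjects,n_rois,fractions design size.
#' @param fixed coefficients of the centered-depth polynomial (constant
#'   first); length determines the true order.
#' @param roi_sd SD of ROI fixed offsets (drawn once per simulation).
#' @param subject_sd,subject_roi_sd,slope_sd,resid_sd variance components.
#' @param cohort_effect,gender_effect fixed offsets for cohort 2 and gender
#'   M.
#' @param age_slope,age_depth_slope optional age effect per year and its
#'   interaction with centered depth (0 = no age terms in truth).
#' @param seed integer seed.
#' @return list `profiles` (tidy data.frame: subject, region, depth,
#'   parameter, value), `subjects` (id, age, gender, cohort_id), `truth`
#'   (the generating values).
#' @export
simulate_roi_profiles <- function(n_subjects = 93, n_rois = 17,
                                  fractions = seq(0.1, 0.9, by = 0.1),
                                  fixed = c(0.65, -0.15, 0.10, -0.06),
                                  roi_sd = 0.02,
                                  subject_sd = 0.02, subject_roi_sd = 0.008,
                                  slope_sd = 0.01, resid_sd = 0.006,
                                  cohort_effect = 0.01,
                                  gender_effect = 0.002,
                                  age_slope = 0, age_depth_slope = 0,
                                  seed = 1) {
  .run_seeded(seed, {
    n_c1 <- round(n_subjects * 34 / 93)
    subjects <- data.frame(
      id = sprintf("sub-%03d", seq_len(n_subjects)),
      age = sample(18:39, n_subjects, replace = TRUE),
      gender = sample(c("F", "M"), n_subjects, replace = TRUE,
                      prob = c(0.61, 0.39)),
      cohort_id = rep(c(1L, 2L), c(n_c1, n_subjects - n_c1)),
      stringsAsFactors = FALSE)
    roi_off <- stats::rnorm(n_rois, 0, roi_sd)
    b_s <- stats::rnorm(n_subjects, 0, subject_sd)
    b_sr <- matrix(stats::rnorm(n_subjects * n_rois, 0, subject_roi_sd),
                   n_subjects, n_rois)
    b_slope <- matrix(stats::rnorm(n_subjects * n_rois, 0, slope_sd),
                      n_subjects, n_rois)
    d_c <- fractions - mean(fractions)
    grid <- expand.grid(depth_idx = seq_along(fractions),
                        region = seq_len(n_rois),
                        subject_idx = seq_len(n_subjects))
    dc <- d_c[grid$depth_idx]
    mu <- .poly_eval(fixed, dc) + roi_off[grid$region] +
      b_s[grid$subject_idx] + b_sr[cbind(grid$subject_idx, grid$region)] +
      b_slope[cbind(grid$subject_idx, grid$region)] * dc +
      cohort_effect * (subjects$cohort_id[grid$subject_idx] == 2L) +
      gender_effect * (subjects$gender[grid$subject_idx] == "M") +
      (age_slope + age_depth_slope * dc) *
        (subjects$age[grid$subject_idx] - 28.5)
    value <- mu + stats::rnorm(nrow(grid), 0, resid_sd)
    profiles <- data.frame(subject = subjects$id[grid$subject_idx],
                           region = grid$region,
                           depth = fractions[grid$depth_idx],
                           parameter = "sim", value = value,
                           stringsAsFactors = FALSE)
    list(profiles = profiles, subjects = subjects,
         truth = list(fixed = fixed, roi_off = roi_off,
                      cohort_effect = cohort_effect,
                      gender_effect = gender_effect,
                      age_slope = age_slope,
                      age_depth_slope = age_depth_slope))
  })
}
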