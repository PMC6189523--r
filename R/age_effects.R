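# Vertex-wise age-effect mapping: covariate residualization, Pearson
# correlation with age, Fisher-z leave-one-out jackknife, per-hemisphere
# Benjamini-Hochberg FDR control, overlap ROI extraction, and ROI-level
# age-slope fits.

#' Residualize vertex values on nuisance covariates
#'
#' Per vertex, ordinary least squares of the value across subjects on an
#' intercept plus the supplied covariates (typically local curvature,
#' cortical thickness, and an acquisition-cohort indicator); the residuals
#' are returned. Covariates may vary per vertex (a vertices x subjects
#' matrix) or only per subject (a length-N vector, recycled across
#' vertices). Covariate columns that are constant (zero variance) at a
#' vertex are dropped there; a single warning summarizes the drops.
#'
#' @param values matrix `[n_vertices, n_subjects]`.
#' @param covariates named list of covariates (each a conforming matrix or
#'   a length-`n_subjects` vector). Factors/characters are converted to
#'   indicator codes.
#' @param keep_mean add each vertex's mean back onto the residuals.
#' @return residual matrix of the same shape, attribute `dropped` naming
#'   covariates dropped anywhere.
#' @export
residualize <- function(values, covariates, keep_mean = FALSE) {
  stopifnot(is.matrix(values), length(covariates) >= 1)
  nv <- nrow(values)
  ns <- ncol(values)
  covs <- lapply(covariates, function(cc) {
    if (is.character(cc) || is.factor(cc))
      cc <- as.numeric(factor(cc))
    if (is.matrix(cc)) {
      stopifnot(identical(dim(cc), dim(values)))
      cc
    } else {
      stopifnot(length(cc) == ns)
      matrix(cc, nv, ns, byrow = TRUE)
    }
  })
  if (ns < length(covs) + 2)
    stop("need at least p + 2 subjects for ", length(covs), " covariates")
  out <- values
  dropped <- character(0)
  for (v in seq_len(nv)) {
    y <- values[v, ]
    X <- vapply(covs, function(cc) cc[v, ], numeric(ns))
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    if (!all(keep))
      dropped <- union(dropped, names(covariates)[!keep])
    X <- cbind(1, X[, keep, drop = FALSE])
    ok <- !is.na(y)
    if (sum(ok) < ncol(X) + 1) {
      out[v, ] <- NA_real_
      next
    }
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    out[v, ok] <- fit$residuals
    out[v, !ok] <- NA_real_
    if (keep_mean) out[v, ] <- out[v, ] + mean(y[ok])
  }
  if (length(dropped))
    warning("constant covariate(s) dropped at some vertices: ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Jackknifed vertex-wise age correlation
#'
#' Per vertex: the Pearson correlation `r` of value with age over all `N`
#' subjects is Fisher-transformed to `T = atanh(r)`; each leave-one-out
#' subsample yields a partial estimate, whose z-transformed mean is `Tm`;
#' the jackknife estimate is `z_J = N T - (N - 1) Tm`, back-transformed to
#' `r_J = tanh(z_J)`. Two-sided p-values use, by default, the t-transform
#' `t = r_J sqrt((N - 2) / (1 - r_J^2))` on `N - 2` df; alternatively
#' (`p_method = "z"`) a normal approximation on `z_J` with the jackknife
#' standard error `sqrt((N - 1) mean((T_i - Tm)^2))`.
#'
#' Vertices with missing values use their complete subjects only; a vertex
#' is invalidated if any leave-one-out subsample has zero age variance or
#' fewer than 4 subjects remain.
#'
#' @param values matrix `[n_vertices, n_subjects]`.
#' @param ages numeric vector of subject ages (years).
#' @param hemi optional per-vertex hemisphere labels (for downstream FDR
#'   grouping; stored in the result).
#' @param p_method `"t"` or `"z"`.
#' @return data.frame of class `jackknife_map`, one row per vertex: `r`,
#'   `T`, `Tm`, `z_jack`, `r_jack`, `p`, `n`, `hemi`.
#' @export
jackknife_correlation <- function(values, ages, hemi = NULL,
                                  p_method = c("t", "z")) {
  p_method <- match.arg(p_method)
  stopifnot(is.matrix(values), ncol(values) == length(ages))
  N <- length(ages)
  if (N < 4) stop("need at least 4 subjects")
  if (stats::sd(ages) == 0) stop("ages are constant")
  nv <- nrow(values)
  M <- !is.na(values)
  V0 <- ifelse(M, values, 0)
  n_v <- rowSums(M)
  sx <- V0 %*% rep(1, N)
  sxx <- (V0^2) %*% rep(1, N)
  sy <- M %*% ages
  syy <- M %*% ages^2
  sxy <- V0 %*% ages
  corr_from_sums <- function(n, sx, sy, sxx, syy, sxy) {
    num <- n * sxy - sx * sy
    den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
    ifelse(den > 0, num / den, NA_real_)
  }
  r_full <- corr_from_sums(n_v, sx, sy, sxx, syy, sxy)
  r_full <- pmin(pmax(r_full, -1 + 1e-15), 1 - 1e-15)
  Tz <- atanh(r_full)
  z_sum <- numeric(nv)
  z_sq_sum <- numeric(nv)
  bad <- rep(FALSE, nv)
  for (i in seq_len(N)) {
    has <- M[, i]
    n_i <- n_v - has
    r_i <- corr_from_sums(n_i,
                          sx - has * V0[, i],
                          sy - has * ages[i],
                          sxx - has * V0[, i]^2,
                          syy - has * ages[i]^2,
                          sxy - has * V0[, i] * ages[i])
    bad <- bad | (has & (is.na(r_i) | n_i < 3))
    r_i <- pmin(pmax(r_i, -1 + 1e-15), 1 - 1e-15)
    z_i <- atanh(r_i)
    # only omissions of subjects actually present at the vertex contribute
    add <- has & !is.na(z_i)
    z_sum <- z_sum + ifelse(add, z_i, 0)
    z_sq_sum <- z_sq_sum + ifelse(add, z_i^2, 0)
  }
  Tm <- z_sum / n_v
  z_jack <- n_v * Tz - (n_v - 1) * Tm
  r_jack <- tanh(z_jack)
  if (p_method == "t") {
    tt <- r_jack * sqrt(pmax(n_v - 2, 0) / pmax(1 - r_jack^2, 1e-300))
    p <- 2 * stats::pt(abs(tt), df = pmax(n_v - 2, 1), lower.tail = FALSE)
  } else {
    se <- sqrt(pmax((n_v - 1) * (z_sq_sum / n_v - Tm^2), 1e-300))
    p <- 2 * stats::pnorm(abs(z_jack) / se, lower.tail = FALSE)
  }
  invalid <- bad | n_v < 4 | is.na(r_full)
  out <- data.frame(r = as.numeric(r_full), T = as.numeric(Tz),
                    Tm = as.numeric(Tm), z_jack = as.numeric(z_jack),
                    r_jack = as.numeric(r_jack), p = as.numeric(p),
                    n = as.integer(n_v),
                    hemi = if (is.null(hemi)) NA_character_ else hemi,
                    stringsAsFactors = FALSE)
  out[invalid, c("r", "T", "Tm", "z_jack", "r_jack", "p")] <- NA_real_
  class(out) <- c("jackknife_map", class(out))
  out
}

#' Benjamini-Hochberg FDR thresholding, grouped per hemisphere
#'
#' The step-up procedure applied separately within each group: with sorted
#' p-values `p_(1) <= ... <= p_(m)`, reject all `p_(i)` with
#' `i <= k = max { i : p_(i) <= i q / m }`. Adjusted q-values are the usual
#' step-up `cummin` of `m p_(i) / i` from the largest p downward. Missing
#' p-values are neither counted in `m` nor flagged.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param q_level FDR level (default 0.05).
#' @param grouping optional factor (e.g. hemisphere labels); `NULL` = one
#'   group.
#' @return list `mask` (logical, TRUE = significant), `q` (adjusted
#'   q-values), `q_level`.
#' @export
fdr_threshold <- function(p_values, q_level = 0.05, grouping = NULL) {
  if (!length(p_values))
    return(list(mask = logical(0), q = numeric(0), q_level = q_level))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(grouping)) grouping <- rep(1L, length(p_values))
  mask <- rep(FALSE, length(p_values))
  q <- rep(NA_real_, length(p_values))
  for (g in unique(grouping)) {
    idx <- which(grouping == g & ok)
    m <- length(idx)
    if (!m) next
    o <- order(p_values[idx])
    ps <- p_values[idx][o]
    adj <- rev(cummin(rev(m * ps / seq_len(m))))
    adj <- pmin(adj, 1)
    k <- which(ps <= seq_len(m) * q_level / m)
    if (length(k)) mask[idx[o[seq_len(max(k))]]] <- TRUE
    q[idx[o]] <- adj
  }
  list(mask = mask, q = q, q_level = q_level)
}

# breadth-first connected components of a vertex subset under mesh adjacency
.connected_components <- function(members, adjacency) {
  inset <- logical(length(adjacency))
  inset[members] <- TRUE
  comp <- integer(length(adjacency))
  cur <- 0L
  for (s in members) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adjacency[[v]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(members, comp[members])
}

#' Overlap ROIs from two significance masks
#'
#' Intersects the (unsmoothed) FDR-significant masks of two parameters on
#' one hemisphere mesh and splits the intersection into connected
#' components under mesh adjacency; each component becomes an ROI.
#' Components below `min_size` are dropped (default 1 = keep all).
#'
#' @param mask_r1,mask_mt logical per-vertex masks on the same mesh.
#' @param adjacency mesh adjacency list.
#' @param hemi hemisphere tag attached to each ROI.
#' @param min_size minimum component size.
#' @return list of ROIs; each a list `vertices` (integer), `hemi`, `size`.
#'   Empty intersection gives an empty list.
#' @export
overlap_rois <- function(mask_r1, mask_mt, adjacency, hemi = NA_character_,
                         min_size = 1) {
  stopifnot(length(mask_r1) == length(mask_mt),
            length(mask_r1) == length(adjacency))
  both <- which(mask_r1 & mask_mt)
  if (!length(both)) return(list())
  comps <- .connected_components(both, adjacency)
  out <- lapply(comps, function(v)
    list(vertices = sort(unname(v)), hemi = hemi, size = length(v)))
  out <- out[vapply(out, function(x) x$size >= min_size, TRUE)]
  unname(out)
}

#' ROI-level age slope of a parameter
#'
#' Averages the parameter over the ROI's vertices per subject (the values
#' supplied should be sampled at mid-cortical depth 0.5) and fits ordinary
#' least squares of the ROI mean on age. The slope is reported both in
#' native units per year and as percent of the cohort-mean value per year.
#'
#' @param roi an ROI from [overlap_rois()] (or any list with integer
#'   `vertices`).
#' @param values matrix `[n_vertices, n_subjects]` of the parameter at the
#'   ROI's mesh resolution.
#' @param ages subject ages (years).
#' @return list `intercept`, `slope` (units/year), `slope_pct`
#'   (percent/year relative to the cohort mean), `ci` (95% CI of the
#'   slope), `r`, `n_subjects`, `roi_means`.
#' @export
roi_age_slope <- function(roi, values, ages) {
  stopifnot(length(ages) == ncol(values))
  if (length(ages) < 3) stop("need at least 3 subjects")
  if (stats::sd(ages) == 0) stop("ages are constant")
  mu <- colMeans(values[roi$vertices, , drop = FALSE], na.rm = TRUE)
  fit <- stats::lm(mu ~ ages)
  sm <- summary(fit)
  ci <- stats::confint(fit)["ages", ]
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       slope_pct = unname(stats::coef(fit)[2]) / mean(mu) * 100,
       ci = unname(ci), r = unname(sign(stats::coef(fit)[2]) *
                                     sqrt(sm$r.squared)),
       n_subjects = length(ages), roi_means = mu)
}
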