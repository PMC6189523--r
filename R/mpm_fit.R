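# Quantitative map estimation from a weighted multi-echo FLASH volume set:
# ESTATICS joint R2* fitting, echo averaging, rational-approximation
# variable-flip-angle R1, semi-quantitative MT saturation, and
# white-matter-calibrated effective proton density (PD*).

#' Joint log-linear (ESTATICS) R2* fit
#'
#' Fits, per voxel, ordinary least squares on
#' `ln S_w(TE_i) = ln A_w - TE_i R2*` jointly over all weightings, with one
#' shared decay slope and one intercept per weighting. The solution is the
#' closed-form normal-equations solve; because all voxels share the echo
#' design, a single factorization covers the whole volume. Voxels with any
#' non-positive echo signal (or outside tissue) are masked invalid rather
#' than clamped; the degenerate rule invalidates voxels with fewer than 3
#' usable echo samples in total (which cannot occur here once a voxel
#' passes the positivity gate, since every protocol has >= 2 echoes in >= 2
#' weightings).
#'
#' @param volumes a `weighted_volumes` object.
#' @return object of class `estatics_fit`: `R2star` (3D array, 1/s),
#'   `lnA` (named list of 3D intercept arrays, one per weighting), `rss`
#'   (residual sum of squares in log space), `df` (residual degrees of
#'   freedom), `valid` (logical array).
#' @export
fit_r2star_estatics <- function(volumes) {
  stopifnot(inherits(volumes, "weighted_volumes"))
  wts <- names(volumes$signals)
  dm <- volumes$grid_meta$dim
  nvox <- prod(dm)
  te_all <- unlist(lapply(wts, function(w) volumes$protocol$weightings[[w]]$TE))
  n_rows <- length(te_all)
  if (n_rows < 3) stop("need at least 3 echo samples in total")
  wt_id <- rep(seq_along(wts),
               vapply(wts, function(w) dim(volumes$signals[[w]])[4], 0L))
  X <- matrix(0, n_rows, length(wts) + 1)
  for (k in seq_along(wts)) X[wt_id == k, k] <- 1
  X[, length(wts) + 1] <- -te_all
  Y <- matrix(NA_real_, n_rows, nvox)
  row <- 1
  for (w in wts) {
    sig <- volumes$signals[[w]]
    nte <- dim(sig)[4]
    for (i in seq_len(nte)) {
      Y[row, ] <- sig[(i - 1) * nvox + seq_len(nvox)]
      row <- row + 1
    }
  }
  valid <- as.vector(volumes$tissue > 0L) & colSums(Y <= 0) == 0
  fitidx <- which(valid)
  beta <- matrix(NA_real_, length(wts) + 1, nvox)
  rss <- rep(NA_real_, nvox)
  if (length(fitidx)) {
    logY <- log(Y[, fitidx, drop = FALSE])
    qrX <- qr(X)
    beta[, fitidx] <- qr.coef(qrX, logY)
    res <- logY - X %*% beta[, fitidx, drop = FALSE]
    rss[fitidx] <- colSums(res^2)
  }
  lnA <- lapply(seq_along(wts), function(k) array(beta[k, ], dm))
  names(lnA) <- wts
  structure(list(
    R2star = array(beta[length(wts) + 1, ] * 1000, dm), # 1/ms -> 1/s
    lnA = lnA, rss = array(rss, dm),
    df = n_rows - (length(wts) + 1),
    valid = array(valid, dm)
  ), class = "estatics_fit")
}

#' Average the echo train of each weighting
#'
#' Arithmetic mean over the first `n_echoes_used` echoes of each weighting,
#' raising signal-to-noise before the variable-flip-angle estimators. The
#' averaged volumes are deliberately not corrected for R2* decay (PD* is
#' "effective" for exactly this reason). Defaults follow the protocol
#' preset: all 8 echoes for cohort 1, the first 6 for cohort 2 (matching
#' the shorter MTw train).
#'
#' @param volumes a `weighted_volumes`.
#' @param n_echoes_used named integer vector (PDw/T1w/MTw) or a single
#'   count; `NULL` uses [default_echoes_used()].
#' @return named list of 3D averaged arrays, with the per-weighting echo
#'   count used stored in `attr(, "n_echoes_used")`.
#' @export
average_echoes <- function(volumes, n_echoes_used = NULL) {
  stopifnot(inherits(volumes, "weighted_volumes"))
  if (is.null(n_echoes_used)) n_echoes_used <- default_echoes_used(volumes$protocol)
  wts <- names(volumes$signals)
  if (length(n_echoes_used) == 1 && is.null(names(n_echoes_used)))
    n_echoes_used <- stats::setNames(rep(n_echoes_used, length(wts)), wts)
  out <- lapply(wts, function(w) {
    n <- as.integer(n_echoes_used[[w]])
    nte <- dim(volumes$signals[[w]])[4]
    if (n < 1) stop("n_echoes_used must be >= 1 for ", w)
    if (n > nte) stop("requested ", n, " echoes for ", w, " but only ",
                      nte, " available")
    dm <- dim(volumes$signals[[w]])[1:3]
    nvox <- prod(dm)
    acc <- numeric(nvox)
    for (i in seq_len(n))
      acc <- acc + volumes$signals[[w]][(i - 1) * nvox + seq_len(nvox)]
    array(acc / n, dm)
  })
  names(out) <- wts
  attr(out, "n_echoes_used") <- vapply(wts, function(w)
    as.integer(n_echoes_used[[w]]), 0L)
  out
}

#' Variable-flip-angle R1 and amplitude from the rational approximation
#'
#' Inverts the small-angle rational approximation of the Ernst equation
#' using the PDw and T1w averaged volumes. With local true flip angles
#' `a_w = f_T * alpha_w` (radians) and TR in ms:
#'
#' `R1 = (S_t1 a_t1 / TR_t1 - S_pd a_pd / TR_pd) /
#'       (2 (S_pd / a_pd - S_t1 / a_t1))`
#'
#' `A = S_pd S_t1 (TR_pd a_t1 / a_pd - TR_t1 a_pd / a_t1) /
#'      (S_t1 TR_pd a_t1 - S_pd TR_t1 a_pd)`
#'
#' R1 is returned in 1/s. Voxels whose denominators fall below a relative
#' tolerance (non-physical signal combinations) are masked.
#'
#' @param S_pd,S_t1 averaged PDw and T1w volumes (3D arrays).
#' @param protocol an `mpm_protocol`.
#' @param f_T transmit-efficiency map (3D array or scalar 1).
#' @param mask logical array of voxels to fit (default: both signals
#'   positive).
#' @return list `R1` (3D array, 1/s), `A` (3D array), `valid` (logical
#'   array).
#' @export
fit_r1_vfa <- function(S_pd, S_t1, protocol, f_T = 1, mask = NULL) {
  stopifnot(identical(dim(S_pd), dim(S_t1)))
  wpd <- protocol$weightings$PDw
  wt1 <- protocol$weightings$T1w
  a_pd <- f_T * wpd$flip_rad
  a_t1 <- f_T * wt1$flip_rad
  if (isTRUE(all(a_pd == a_t1)))
    stop("equal effective flip angles: R1 is unidentifiable")
  if (is.null(mask)) mask <- S_pd > 0 & S_t1 > 0
  den_r1 <- S_pd / a_pd - S_t1 / a_t1
  num_r1 <- S_t1 * a_t1 / wt1$TR - S_pd * a_pd / wpd$TR
  den_a <- S_t1 * wpd$TR * a_t1 - S_pd * wt1$TR * a_pd
  scale_r1 <- pmax(abs(S_pd / a_pd), abs(S_t1 / a_t1))
  scale_a <- pmax(abs(S_t1 * wpd$TR * a_t1), abs(S_pd * wt1$TR * a_pd))
  valid <- mask & abs(den_r1) > 1e-9 * scale_r1 & abs(den_a) > 1e-9 * scale_a
  R1 <- num_r1 / (2 * den_r1) * 1000 # 1/ms -> 1/s
  A <- S_pd * S_t1 * (wpd$TR * a_t1 / a_pd - wt1$TR * a_pd / a_t1) / den_a
  R1[!valid] <- NA_real_
  A[!valid] <- NA_real_
  valid <- valid & is.finite(R1) & is.finite(A) & R1 > 0
  R1[!valid] <- NA_real_
  A[!valid] <- NA_real_
  list(R1 = R1, A = A, valid = valid)
}

#' Semi-quantitative MT saturation map
#'
#' The percentage loss of longitudinal magnetization per TR caused by the
#' MT pre-pulse, accounting for local T1 and flip angle:
#' `delta = (A a_mt / S_mt - 1) R1 TR_mt - a_mt^2 / 2` with
#' `a_mt = f_T alpha_mt` (radians), TR in ms and R1 converted to 1/ms.
#' Reported as `MTsat = 100 delta` in percent units (pu). This exactly
#' inverts the small-angle forward model's additive saturation term.
#'
#' An optional multiplicative transmit-bias correction
#' `delta_corr = delta (1 - C) / (1 - C f_T)` is available but off by
#' default (`b1_correction_C = 0`).
#'
#' @param S_mt averaged MTw volume (3D array).
#' @param A,R1 amplitude and R1 (1/s) maps from [fit_r1_vfa()].
#' @param protocol an `mpm_protocol`.
#' @param f_T transmit-efficiency map (3D array or scalar 1).
#' @param b1_correction_C empirical correction constant C (0 disables).
#' @return list `MTsat` (3D array, pu), `valid` (logical array).
#' @export
compute_mtsat <- function(S_mt, A, R1, protocol, f_T = 1,
                          b1_correction_C = 0) {
  wmt <- protocol$weightings$MTw
  if (!wmt$mt_pulse) stop("MTw weighting carries no MT pulse")
  a_mt <- f_T * wmt$flip_rad
  valid <- S_mt > 0 & is.finite(A) & is.finite(R1)
  delta <- (A * a_mt / S_mt - 1) * (R1 / 1000) * wmt$TR - a_mt^2 / 2
  if (b1_correction_C != 0)
    delta <- delta * (1 - b1_correction_C) / (1 - b1_correction_C * f_T)
  delta[!valid] <- NA_real_
  list(MTsat = 100 * delta, valid = valid)
}

#' Calibrate the amplitude map to effective proton density (PD*)
#'
#' Divides the amplitude map by the receive sensitivity field (the known
#' synthetic receive field stands in for a UNICORT-style estimate) and
#' scales it so the white-matter mean equals the published value of 69
#' percent units. The post-condition holds by construction (to machine
#' precision), and the operation is idempotent and invariant to rescaling
#' of `g_R`.
#'
#' @param A amplitude map (3D array).
#' @param g_R receive sensitivity map (3D array or scalar 1).
#' @param wm_mask logical array selecting white-matter voxels.
#' @param target white-matter mean, percent units.
#' @return PD* map (3D array, pu).
#' @export
calibrate_pdstar <- function(A, g_R = 1, wm_mask, target = 69) {
  if (!any(wm_mask)) stop("white-matter mask is empty")
  pd <- A / g_R
  m <- mean(pd[wm_mask], na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("white-matter mean amplitude is zero")
  pd * (target / m)
}

#' Imperfect-spoiling correction hook
#'
#' Placeholder for a scanner-protocol-specific polynomial correction of R1
#' for incomplete RF spoiling. The identity transform is the default and
#' only shipped implementation; supply `coef` for a protocol-calibrated
#' quadratic in `f_T`.
#'
#' @param R1 R1 map (1/s).
#' @param f_T transmit field map.
#' @param coef length-3 numeric (P0, P1, P2): R1 is divided by
#'   `P0 + P1 f_T + P2 f_T^2`; `NULL` = identity.
#' @return corrected R1 map.
#' @export
spoiling_correction <- function(R1, f_T = 1, coef = NULL) {
  if (is.null(coef)) return(R1)
  stopifnot(length(coef) == 3)
  R1 / (coef[1] + coef[2] * f_T + coef[3] * f_T^2)
}

#' Estimate all four quantitative maps
#'
#' Pipeline order: ESTATICS shared-slope R2*, echo averaging, VFA R1 and
#' amplitude, MT saturation, and WM-calibrated PD*. Validity is tracked per
#' voxel; background voxels never produce numeric output.
#'
#' @param volumes a `weighted_volumes`.
#' @param wm_mask logical array; default: the volume's white-matter label.
#' @param n_echoes_used see [average_echoes()].
#' @param b1_correction_C see [compute_mtsat()].
#' @param spoiling_coef see [spoiling_correction()].
#' @return object of class `parameter_maps`: 3D arrays `R1` (1/s),
#'   `R2star` (1/s), `MTsat` (pu), `PDstar` (pu), `A`, logical `valid`,
#'   plus `grid_meta`.
#' @export
fit_all_maps <- function(volumes, wm_mask = NULL, n_echoes_used = NULL,
                         b1_correction_C = 0, spoiling_coef = NULL) {
  stopifnot(inherits(volumes, "weighted_volumes"))
  if (is.null(wm_mask)) wm_mask <- volumes$tissue == 1L
  est <- fit_r2star_estatics(volumes)
  avg <- average_echoes(volumes, n_echoes_used)
  f_T <- volumes$fields$f_T
  g_R <- volumes$fields$g_R
  vfa <- fit_r1_vfa(avg$PDw, avg$T1w, volumes$protocol, f_T,
                    mask = est$valid)
  R1 <- spoiling_correction(vfa$R1, f_T, spoiling_coef)
  mt <- compute_mtsat(avg$MTw, vfa$A, R1, volumes$protocol, f_T,
                      b1_correction_C)
  valid <- est$valid & vfa$valid & mt$valid
  pdstar <- calibrate_pdstar(vfa$A, g_R, wm_mask & valid)
  R2star <- est$R2star
  R1[!valid] <- NA_real_
  R2star[!valid] <- NA_real_
  pdstar[!valid] <- NA_real_
  MTsat <- mt$MTsat
  MTsat[!valid] <- NA_real_
  A <- vfa$A
  A[!valid] <- NA_real_
  structure(list(R1 = R1, R2star = R2star, MTsat = MTsat, PDstar = pdstar,
                 A = A, valid = valid, grid_meta = volumes$grid_meta),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat("<parameter_maps>", paste(x$grid_meta$dim, collapse = " x "),
      "voxels,", sum(x$valid), "valid\n")
  for (p in c("R1", "R2star", "MTsat", "PDstar")) {
    v <- x[[p]][x$valid]
    cat(sprintf("  %-7s median %.4g (IQR %.4g-%.4g)\n", p,
                stats::median(v), stats::quantile(v, .25),
                stats::quantile(v, .75)))
  }
  invisible(x)
}
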