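# mpm_fit module: ESTATICS, echo averaging, VFA R1, MT saturation, PD*.

test_that("ESTATICS recovers a noiseless decay exactly", {
  sig <- voxel_signals(R2star = 20)
  p <- mpm_protocol("cohort1")
  v <- as_weighted_volumes(lapply(sig, as.matrix), p, n_voxels = 1)
  fit <- fit_r2star_estatics(v)
  expect_equal(fit$R2star[1], 20, tolerance = 1e-10)
  expect_equal(exp(fit$lnA$PDw[1]), 500, tolerance = 1e-9)
  expect_equal(exp(fit$lnA$MTw[1]), 450, tolerance = 1e-9)
  expect_equal(fit$rss[1], 0, tolerance = 1e-18)
})

test_that("two echoes in one weighting give the two-point slope", {
  te <- c(3, 10)
  s <- c(400, 250)
  w <- list(PDw = list(flip_deg = 5, TR = 25, TE = te, mt_pulse = FALSE),
            T1w = list(flip_deg = 29, TR = 25, TE = te, mt_pulse = FALSE),
            MTw = list(flip_deg = 9, TR = 25, TE = te, mt_pulse = TRUE))
  p <- new_mpm_protocol(w)
  sig <- list(PDw = as.matrix(s), T1w = as.matrix(s), MTw = as.matrix(s))
  v <- as_weighted_volumes(sig, p, n_voxels = 1)
  fit <- fit_r2star_estatics(v)
  expect_equal(fit$R2star[1], (log(400) - log(250)) / (10 - 3) * 1000,
               tolerance = 1e-10)
})

test_that("ESTATICS equals the per-voxel normal-equations oracle", {
  p <- mpm_protocol("cohort1")
  set.seed(31)
  nvox <- 120
  sig <- lapply(c(PDw = 1, T1w = 2, MTw = 3), function(k) {
    te <- p$weightings[[k]]$TE
    A <- runif(nvox, 300, 900)
    r2 <- runif(nvox, 10, 30)
    sapply(seq_len(nvox), function(j)
      A[j] * exp(-te / 1000 * r2[j]) + rnorm(length(te), 0, 2))
  })
  names(sig) <- c("PDw", "T1w", "MTw")
  ok <- Reduce(`&`, lapply(sig, function(sm) colSums(sm <= 0) == 0))
  v <- as_weighted_volumes(sig, p, n_voxels = nvox)
  fit <- fit_r2star_estatics(v)
  # independent oracle: explicit lm per voxel with weighting intercepts
  te_all <- unlist(lapply(names(sig), function(w) p$weightings[[w]]$TE))
  wt <- factor(rep(names(sig), times = vapply(sig, nrow, 0L)),
               levels = names(sig))
  for (j in c(1, 17, 55, 120)) {
    if (!ok[j]) next
    y <- log(unlist(lapply(sig, function(sm) sm[, j])))
    o <- lm(y ~ 0 + wt + te_all)
    expect_equal(fit$R2star[j], unname(-coef(o)["te_all"]) * 1000,
                 tolerance = 1e-8)
    expect_equal(fit$lnA$T1w[j], unname(coef(o)["wtT1w"]), tolerance = 1e-8)
  }
})

test_that("noisy ESTATICS matches a nonlinear least-squares oracle within
          its standard error", {
  p <- mpm_protocol("cohort1")
  sig <- voxel_signals(R2star = 22, noise_sd = 3, seed = 77)
  v <- as_weighted_volumes(lapply(sig, as.matrix), p, n_voxels = 1)
  fit <- fit_r2star_estatics(v)
  te <- p$weightings$PDw$TE
  df <- data.frame(y = unlist(sig),
                   te = rep(te, 3),
                   w = rep(c("PDw", "T1w", "MTw"), each = length(te)))
  nls_fit <- nls(y ~ c(PDw = a1, T1w = a2, MTw = a3)[w] *
                   exp(-te / 1000 * r2),
                 data = df, start = list(a1 = 500, a2 = 700, a3 = 450,
                                         r2 = 15))
  r2_hat <- coef(nls_fit)[["r2"]]
  se <- summary(nls_fit)$coefficients["r2", "Std. Error"]
  expect_lt(abs(fit$R2star[1] - r2_hat), 2 * se)
})

test_that("voxels with non-positive signals are masked, not clamped", {
  sig <- voxel_signals()
  sig$PDw[3] <- -1
  p <- mpm_protocol("cohort1")
  v <- as_weighted_volumes(lapply(sig, as.matrix), p, n_voxels = 1)
  fit <- fit_r2star_estatics(v)
  expect_false(fit$valid[1])
  expect_true(is.na(fit$R2star[1]))
})

test_that("echo averaging: identity, bounds, cohort-2 echo subset", {
  m <- tiny_model()
  gt <- tiny_ground_truth()
  f <- make_field_maps(m, seed = 2)
  v <- simulate_weighted_volumes(gt, f, mpm_protocol("cohort2"),
                                 noise_sd = 0, seed = 1)
  avg <- average_echoes(v)
  expect_equal(attr(avg, "n_echoes_used"), c(PDw = 6L, T1w = 6L, MTw = 6L))
  i <- which(v$tissue == 2L)[3]
  nvox <- prod(v$grid_meta$dim)
  echoes <- v$signals$PDw[(0:7) * nvox + i]
  expect_equal(avg$PDw[i], mean(echoes[1:6]), tolerance = 1e-12)
  # mean of a decaying train lies strictly between last and first echo
  expect_true(avg$PDw[i] < echoes[1] && avg$PDw[i] > echoes[6])
  expect_error(average_echoes(v, 0), ">= 1")
  expect_error(average_echoes(v, c(PDw = 8, T1w = 8, MTw = 8)),
               "only 6 available")
  # identical echoes average to any echo
  const <- v
  for (w in names(const$signals))
    for (e in seq_len(dim(const$signals[[w]])[4]))
      const$signals[[w]][, , , e] <- const$signals[[w]][, , , 1]
  avg2 <- average_echoes(const)
  expect_equal(avg2$MTw, const$signals$MTw[, , , 1], tolerance = 1e-12)
})

test_that("VFA R1/A inversion is exact for the small-angle forward model", {
  p <- mpm_protocol("cohort1")
  A <- 800; R1 <- 0.9
  for (fT in c(1, 1.1)) {
    S_pd <- array(flash_signal(A, R1, 0, 0, fT * p$weightings$PDw$flip_rad,
                               p$weightings$PDw$TR, 0, "small_angle"),
                  c(1, 1, 1))
    S_t1 <- array(flash_signal(A, R1, 0, 0, fT * p$weightings$T1w$flip_rad,
                               p$weightings$T1w$TR, 0, "small_angle"),
                  c(1, 1, 1))
    out <- fit_r1_vfa(S_pd, S_t1, p, f_T = fT)
    expect_equal(out$R1[1], R1, tolerance = 1e-12)
    expect_equal(out$A[1], A, tolerance = 1e-12)
  }
  p_eq <- p
  p_eq$weightings$T1w$flip_rad <- p_eq$weightings$PDw$flip_rad
  expect_error(fit_r1_vfa(array(1, c(1, 1, 1)), array(1, c(1, 1, 1)), p_eq),
               "unidentifiable")
})

test_that("MT saturation inversion is exact for the small-angle forward", {
  p <- mpm_protocol("cohort1")
  A <- 800; R1 <- 0.9
  for (delta in c(0, 0.01)) {
    S_mt <- array(flash_signal(A, R1, 0, delta, p$weightings$MTw$flip_rad,
                               p$weightings$MTw$TR, 0, "small_angle"),
                  c(1, 1, 1))
    mt <- compute_mtsat(S_mt, array(A, c(1, 1, 1)), array(R1, c(1, 1, 1)),
                        p, f_T = 1)
    expect_equal(mt$MTsat[1], 100 * delta, tolerance = 1e-10)
  }
  expect_false(compute_mtsat(array(-5, c(1, 1, 1)), array(800, c(1, 1, 1)),
                             array(0.9, c(1, 1, 1)), p)$valid[1])
})

test_that("optional MT B1 bias correction has the documented form", {
  d <- array(0.01, c(1, 1, 1))
  p <- mpm_protocol("cohort1")
  A <- 800; R1 <- 0.9
  S_mt <- array(flash_signal(A, R1, 0, 0.01, p$weightings$MTw$flip_rad,
                             p$weightings$MTw$TR, 0, "small_angle"),
                c(1, 1, 1))
  mt0 <- compute_mtsat(S_mt, array(A, dim(d)), array(R1, dim(d)), p)
  mt1 <- compute_mtsat(S_mt, array(A, dim(d)), array(R1, dim(d)), p,
                       f_T = 1.2, b1_correction_C = 0.4)
  raw <- compute_mtsat(S_mt, array(A, dim(d)), array(R1, dim(d)), p,
                       f_T = 1.2)
  expect_equal(mt1$MTsat[1], raw$MTsat[1] * (1 - 0.4) / (1 - 0.4 * 1.2),
               tolerance = 1e-12)
  expect_equal(mt0$MTsat[1], 1, tolerance = 1e-10)
})

test_that("PD* calibration: WM mean 69, uniformity, scale invariance,
          idempotence", {
  set.seed(5)
  A <- array(runif(60, 50, 90), c(5, 4, 3))
  g <- array(runif(60, 0.8, 1.2), c(5, 4, 3))
  wm <- array(FALSE, c(5, 4, 3)); wm[1:10] <- TRUE
  pd <- calibrate_pdstar(A, g, wm)
  expect_equal(mean(pd[wm]), 69, tolerance = 1e-12)
  expect_equal(calibrate_pdstar(pd, 1, wm), pd, tolerance = 1e-12)
  expect_equal(calibrate_pdstar(A, 2 * g, wm), pd, tolerance = 1e-12)
  u <- calibrate_pdstar(array(5, c(2, 2, 2)), array(3, c(2, 2, 2)),
                        array(TRUE, c(2, 2, 2)))
  expect_equal(as.vector(u), rep(69, 8))
  expect_error(calibrate_pdstar(A, g, array(FALSE, c(5, 4, 3))), "empty")
})

test_that("full map fit recovers the small-angle-consistent phantom", {
  v <- tiny_volumes_small_angle()
  gt <- tiny_ground_truth()
  maps <- fit_all_maps(v)
  msk <- maps$valid
  expect_gt(sum(msk), 1000)
  expect_lt(max(abs(maps$R1[msk] - gt$R1[msk]) / gt$R1[msk]), 1e-9)
  expect_lt(max(abs(maps$R2star[msk] - gt$R2star[msk]) / gt$R2star[msk]),
            1e-9)
  expect_lt(max(abs(maps$MTsat[msk] - 100 * gt$MTdelta[msk])), 1e-9)
  # PD* equals ground-truth A up to the WM-69 calibration scale
  wm <- v$tissue == 1L & msk
  expect_equal(mean(maps$PDstar[wm]), 69, tolerance = 1e-12)
  # PD* is effective: the averaged volumes keep their R2* decay, so PD*
  # tracks A times the mean echo decay, normalized to WM = 69
  te <- mpm_protocol("cohort1")$weightings$PDw$TE
  decay <- function(r2) colMeans(exp(-outer(te / 1000, r2)))
  gm <- v$tissue == 2L & msk
  a_eff <- gt$A * array(decay(as.vector(gt$R2star)), dim(gt$A))
  expected_gm <- a_eff[gm] * 69 / mean(a_eff[wm])
  expect_equal(maps$PDstar[gm], expected_gm, tolerance = 1e-9)
  # background voxels carry no numeric output
  expect_true(all(is.na(maps$R1[v$tissue == 0L])))
  expect_false(any(maps$valid[v$tissue == 0L]))
})

test_that("shared-slope pooling beats single-weighting slopes under noise", {
  p <- mpm_protocol("cohort1")
  te <- p$weightings$PDw$TE
  set.seed(99)
  n_rep <- 150
  shared <- single <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sig <- voxel_signals(R2star = 20, noise_sd = 4, seed = 1000 + r)
    v <- as_weighted_volumes(lapply(sig, as.matrix), p, n_voxels = 1)
    shared[r] <- fit_r2star_estatics(v)$R2star[1]
    single[r] <- -coef(lm(log(pmax(sig$PDw, 1e-9)) ~ te))[2] * 1000
  }
  expect_lt(sd(shared), sd(single))
})

test_that("recovered maps show the laminar gradient near white vs pial", {
  v <- tiny_volumes_small_angle()
  m <- tiny_model()
  maps <- fit_all_maps(v)
  g <- m$grid
  near_white <- g$tissue == 2L & g$depth < 0.3 & maps$valid
  near_pial <- g$tissue == 2L & g$depth > 0.7 & maps$valid
  expect_gt(mean(maps$R1[near_white]), mean(maps$R1[near_pial]))
  expect_gt(mean(maps$MTsat[near_white]), mean(maps$MTsat[near_pial]))
  expect_gt(mean(maps$R2star[near_white]), mean(maps$R2star[near_pial]))
  expect_lt(mean(maps$PDstar[near_white]), mean(maps$PDstar[near_pial]))
})

test_that("spoiling correction hook defaults to identity", {
  R1 <- array(1, c(2, 2, 1))
  expect_identical(spoiling_correction(R1), R1)
  expect_equal(spoiling_correction(R1, 1.1, c(1, 0.1, 0))[1],
               1 / (1 + 0.1 * 1.1), tolerance = 1e-12)
})
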