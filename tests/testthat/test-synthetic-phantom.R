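# synthetic_phantom module: protocols, FLASH forward model, cortical
# geometry, cohort generation, volume simulation.

test_that("protocol presets carry the published sequence settings", {
  p1 <- mpm_protocol("cohort1")
  expect_equal(p1$weightings$PDw$TR, 25.25)
  expect_equal(p1$weightings$PDw$flip_deg, 5)
  expect_equal(p1$weightings$T1w$flip_deg, 29)
  expect_equal(p1$weightings$MTw$TR, 29.25)
  expect_equal(p1$weightings$MTw$flip_deg, 9)
  expect_equal(p1$weightings$PDw$TE, 2.39 + 2.36 * 0:7)
  expect_equal(max(p1$weightings$PDw$TE), 18.91)
  expect_true(p1$weightings$MTw$mt_pulse)

  p2 <- mpm_protocol("cohort2")
  expect_equal(p2$weightings$PDw$flip_deg, 6)
  expect_equal(p2$weightings$T1w$flip_deg, 21)
  expect_equal(length(p2$weightings$MTw$TE), 6)
  expect_equal(length(p2$weightings$PDw$TE), 8)
  expect_equal(p2$weightings$PDw$TE[1], 2.34)
  expect_equal(diff(p2$weightings$PDw$TE)[1], 2.30)
  expect_equal(default_echoes_used(p2), c(PDw = 6L, T1w = 6L, MTw = 6L))
  expect_equal(default_echoes_used(p1), c(PDw = 8L, T1w = 8L, MTw = 8L))
})

test_that("protocol invariants are enforced", {
  w <- mpm_protocol("cohort1")$weightings
  w$T1w$TE <- w$T1w$TE[1:4]
  expect_error(new_mpm_protocol(w), "same number of echoes")
  w <- mpm_protocol("cohort1")$weightings
  w$MTw$TE <- rev(w$MTw$TE)
  expect_error(new_mpm_protocol(w), "strictly increasing")
  w <- mpm_protocol("cohort1")$weightings
  w$PDw$TR <- 10
  expect_error(new_mpm_protocol(w), "TR")
  w <- mpm_protocol("cohort1")$weightings
  w$PDw$flip_deg <- 95
  expect_error(new_mpm_protocol(w), "flip angle")
})

test_that("flash_signal matches the arbitrary-precision oracle", {
  # frozen values computed with sympy at 30 digits before the build
  expect_equal(flash_signal(1000, 1, 20, 0, 5 * pi / 180, 25, 0,
                            model = "small_angle"),
               75.7318432556089542, tolerance = 1e-14)
  expect_equal(flash_signal(1000, 1, 20, 0, 5 * pi / 180, 25.25, 2.39,
                            model = "ernst"),
               72.3249896842988585, tolerance = 1e-14)
  expect_equal(flash_signal(1000, 1, 20, 0.015, 9 * pi / 180, 29.25, 0,
                            model = "ernst"),
               80.5090470766811422, tolerance = 1e-14)
})

test_that("flash_signal limits and argument checks", {
  for (mdl in c("ernst", "small_angle")) {
    expect_equal(flash_signal(100, 1, 20, 0, 1e-12, 25, 5, model = mdl), 0,
                 tolerance = 1e-10)
    expect_error(flash_signal(-1, 1, 20, 0, 0.1, 25, 5, model = mdl),
                 "positive")
    expect_error(flash_signal(100, 0, 20, 0, 0.1, 25, 5, model = mdl),
                 "positive")
  }
  expect_error(flash_signal(100, 1, 20, 0.2, 0.1, 25, 5), "delta")
})

test_that("ernst-model signal is maximized at the Ernst angle", {
  # golden-section / optimize() oracle over alpha
  for (R1 in c(0.6, 1.0, 1.4)) {
    TR <- 25
    opt <- stats::optimize(function(a)
      flash_signal(100, R1, 0, 0, a, TR, 0, model = "ernst"),
      c(1e-4, pi / 2 - 1e-4), maximum = TRUE, tol = 1e-10)
    expect_equal(opt$maximum, ernst_angle(R1, TR), tolerance = 1e-6)
  }
})

test_that("small-angle and ernst agree to <0.5% in the joint limit", {
  grid <- expand.grid(alpha = sqrt(2 * c(0.001, 0.005, 0.01)),
                      trr1 = c(0.01, 0.03, 0.05))
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]
    r1 <- grid$trr1[i] / 0.025 # TR 25 ms
    s1 <- flash_signal(100, r1, 15, 0, a, 25, 5, model = "ernst")
    s2 <- flash_signal(100, r1, 15, 0, a, 25, 5, model = "small_angle")
    expect_lt(abs(s1 - s2) / s1, 0.005)
  }
})

test_that("flat slab limit: zero curvature, constant thickness", {
  m <- make_cortical_model(150, folding_amplitude = 0, n_regions = 3,
                           seed = 1)
  for (h in m$hemis) {
    expect_equal(h$curvature, rep(0, length(h$curvature)))
    expect_equal(h$thickness, rep(h$thickness[1], length(h$thickness)))
    expect_equal(unname(h$normals[, 3]), rep(1, nrow(h$normals)))
  }
})

test_that("pial-white distance equals stored thickness everywhere", {
  m <- tiny_model()
  for (h in m$hemis) {
    d <- sqrt(rowSums((h$pial - h$white)^2))
    expect_equal(d, h$thickness, tolerance = 1e-12)
  }
})

test_that("17 regions label every vertex exactly once and contiguously", {
  m <- make_cortical_model(600, folding_amplitude = 2, n_regions = 17,
                           seed = 5)
  for (h in m$hemis) {
    expect_equal(sort(unique(h$region)), 1:17)
    expect_false(anyNA(h$region))
    # contiguity: every region's vertex set is one connected component
    for (r in unique(h$region)) {
      members <- which(h$region == r)
      comp <- mpmcortex:::.connected_components(members, h$adjacency)
      expect_length(comp, 1)
    }
  }
})

test_that("cortical model rejects self-intersecting geometry", {
  expect_error(make_cortical_model(400, folding_amplitude = 12, seed = 1),
               "self-intersect")
})

test_that("cortical geometry invariants: adjacency symmetric, thickness in
          range, sulci thinner than crowns", {
  m <- tiny_model()
  h <- m$hemis$lh
  for (v in seq(1, length(h$adjacency), by = 17))
    for (w in h$adjacency[[v]])
      expect_true(v %in% h$adjacency[[w]])
  expect_true(all(h$thickness >= 1.5 & h$thickness <= 4))
  crown <- which.min(h$curvature) # most convex
  fundus <- which.max(h$curvature) # most concave
  expect_gt(h$thickness[crown], h$thickness[fundus])
})

test_that("model determinism and voxel grid consistency", {
  m1 <- make_cortical_model(150, folding_amplitude = 1.5, n_regions = 3,
                            seed = 7)
  m2 <- make_cortical_model(150, folding_amplitude = 1.5, n_regions = 3,
                            seed = 7)
  expect_identical(m1, m2)
  g <- m1$grid
  expect_true(all(g$depth[g$tissue == 2L] >= 0 &
                    g$depth[g$tissue == 2L] <= 1))
  expect_true(all(is.na(g$depth[g$tissue != 2L])))
  expect_true(all(!is.na(g$region[g$tissue == 2L])))
})

test_that("cohort generation is deterministic and honors the age range", {
  c1 <- make_cohort(10, spec = effect_spec(), n_regions = 4, seed = 11)
  c2 <- make_cohort(10, spec = effect_spec(), n_regions = 4, seed = 11)
  expect_identical(c1, c2)
  expect_true(all(c1$subjects$age >= 18 & c1$subjects$age <= 39))
  expect_true(all(c1$subjects$age == round(c1$subjects$age)))
})

test_that("zero variance and zero slopes give identical subjects", {
  zero <- list(R1 = 0, R2star = 0, MTdelta = 0, A = 0)
  spec <- effect_spec(subject_sd = zero, subject_region_sd = zero,
                      subject_slope_sd = zero, age_slopes = zero,
                      thickness_confound = 0)
  co <- make_cohort(3, spec = spec, n_regions = 4, seed = 3)
  m <- tiny_model()
  g1 <- subject_ground_truth(co, 1, m)
  g2 <- subject_ground_truth(co, 3, m)
  for (p in c("R1", "R2star", "MTdelta", "A"))
    expect_identical(g1[[p]], g2[[p]])
})

test_that("planted R1 age slope produces the linear construction difference", {
  zero <- list(R1 = 0, R2star = 0, MTdelta = 0, A = 0)
  spec <- effect_spec(subject_sd = zero, subject_region_sd = zero,
                      subject_slope_sd = zero,
                      age_slopes = list(R1 = 0.003, R2star = 0,
                                        MTdelta = 0, A = 0),
                      age_affected_regions = 2L,
                      age_depth_attenuation = 0, thickness_confound = 0)
  co <- make_cohort(2, age_range = c(18, 39), spec = spec, n_regions = 4,
                    seed = 5)
  co$subjects$age <- c(18L, 39L)
  m <- tiny_model()
  g1 <- subject_ground_truth(co, 1, m)
  g2 <- subject_ground_truth(co, 2, m)
  gm2 <- m$grid$tissue == 2L & m$grid$region == 2L
  gm_other <- m$grid$tissue == 2L & m$grid$region != 2L
  expect_equal(unique(round(g2$R1[gm2] - g1$R1[gm2], 12)), 0.003 * 21)
  expect_equal(max(abs(g2$R1[gm_other] - g1$R1[gm_other])), 0)
})

test_that("default ground-truth depth profiles are monotone", {
  spec <- effect_spec()
  d <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(gm_profile(spec, "R1", d)) < 0))
  expect_true(all(diff(gm_profile(spec, "MTdelta", d)) < 0))
  expect_true(all(diff(gm_profile(spec, "R2star", d)) < 0))
  expect_true(all(diff(gm_profile(spec, "A", d)) > 0))
})

test_that("effect spec validation rejects non-physical settings", {
  expect_error(effect_spec(subject_sd = list(R1 = -1, R2star = 0.1,
                                             MTdelta = 1e-4, A = 1)),
               ">= 0")
  expect_error(effect_spec(profiles = list(R1 = c(0.05, -0.2, 0, 0),
                                           R2star = c(16, -2, -1, 0),
                                           MTdelta = c(0.014, -0.005, 0, 0),
                                           A = c(78, 6, 0, 2))),
               "non-positive")
})

test_that("field maps are positive and spatially smooth", {
  m <- tiny_model()
  f <- make_field_maps(m, seed = 9)
  for (nm in c("f_T", "g_R")) {
    x <- f[[nm]]
    expect_true(all(x > 0))
    # bounded per-voxel gradient: half-period modulation across the FOV
    gx <- abs(diff(x[, 1, 1]))
    bound <- 0.1 * pi / (dim(x)[1] * m$grid$voxel_size) * 1.01
    expect_true(all(gx <= bound * m$grid$voxel_size))
  }
})

test_that("noiseless simulation reproduces the forward model exactly", {
  m <- tiny_model()
  gt <- tiny_ground_truth()
  fields <- list(f_T = array(1, m$grid$dim), g_R = array(1, m$grid$dim))
  p <- mpm_protocol("cohort1")
  v <- simulate_weighted_volumes(gt, fields, p, noise_sd = 0, seed = 1)
  i <- which(m$grid$tissue == 2L)[5]
  for (w in names(p$weightings)) {
    ww <- p$weightings[[w]]
    for (e in c(1, 4, 8)) {
      expected <- flash_signal(gt$A[i], gt$R1[i], gt$R2star[i],
                               if (ww$mt_pulse) gt$MTdelta[i] else 0,
                               ww$flip_rad, ww$TR, ww$TE[e], model = "ernst")
      nvox <- prod(m$grid$dim)
      expect_equal(v$signals[[w]][(e - 1) * nvox + i], expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("simulated echo structure follows the preset and is seeded", {
  m <- tiny_model()
  gt <- tiny_ground_truth()
  f <- make_field_maps(m, seed = 2)
  v1 <- simulate_weighted_volumes(gt, f, mpm_protocol("cohort1"),
                                  noise_sd = 0.1, seed = 42)
  v1b <- simulate_weighted_volumes(gt, f, mpm_protocol("cohort1"),
                                   noise_sd = 0.1, seed = 42)
  expect_identical(v1$signals, v1b$signals)
  expect_equal(vapply(v1$signals, function(s) dim(s)[4], 0L),
               c(PDw = 8L, T1w = 8L, MTw = 8L))
  v2 <- simulate_weighted_volumes(gt, f, mpm_protocol("cohort2"),
                                  noise_sd = 0, seed = 1)
  expect_equal(vapply(v2$signals, function(s) dim(s)[4], 0L),
               c(PDw = 8L, T1w = 8L, MTw = 6L))
  vr <- simulate_weighted_volumes(gt, f, mpm_protocol("cohort1"),
                                  noise_sd = 0.1, seed = 42,
                                  noise_model = "rician")
  expect_true(all(vr$signals$PDw >= 0))
})

test_that("congruence errors are raised", {
  m <- tiny_model()
  gt <- tiny_ground_truth()
  bad_fields <- list(f_T = array(1, c(2, 2, 2)), g_R = array(1, c(2, 2, 2)))
  expect_error(simulate_weighted_volumes(gt, bad_fields,
                                         mpm_protocol("cohort1")),
               "congruent")
})
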