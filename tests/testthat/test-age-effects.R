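# age_effects module: residualization, jackknifed correlations, FDR,
# overlap ROIs, ROI age slopes.

test_that("residuals vanish for values that are exact covariate functions", {
  set.seed(1)
  n <- 12; nv <- 6
  thick <- matrix(runif(nv * n, 2, 4), nv, n)
  vals <- 3 + 2 * thick
  res <- residualize(vals, list(thickness = thick))
  expect_equal(max(abs(res)), 0, tolerance = 1e-10)
})

test_that("orthogonal covariates leave centered values", {
  n <- 8; nv <- 3
  vals <- matrix(rep(c(-3, -1, 1, 3), 2 * nv), nv, n, byrow = TRUE)
  covar <- rep(c(1, -1, -1, 1), n / 4) # orthogonal to every row of vals
  res <- residualize(vals, list(x = covar))
  expect_equal(res, vals - rowMeans(vals), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("residualize matches the hat-matrix oracle on a 5-subject
          example", {
  y <- c(2.1, 3.0, 2.7, 4.2, 3.9)
  curv <- c(0.1, -0.2, 0.3, 0.0, -0.1)
  thick <- c(2.5, 3.1, 2.8, 3.4, 2.9)
  coh <- c(0, 0, 1, 1, 1)
  X <- cbind(1, curv, thick, coh)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  oracle <- as.vector((diag(5) - H) %*% y)
  res <- residualize(matrix(y, 1, 5),
                     list(curvature = curv, thickness = thick, cohort = coh))
  expect_equal(as.vector(res), oracle, tolerance = 1e-10)
})

test_that("constant covariates are dropped with a warning", {
  vals <- matrix(rnorm(20), 2, 10)
  expect_warning(res <- residualize(vals, list(c = rep(1, 10),
                                               x = rnorm(10))),
                 "dropped")
  expect_equal(dim(res), dim(vals))
})

test_that("jackknife matches the leave-one-out enumeration oracle", {
  for (N in c(6, 10)) {
    set.seed(N)
    ages <- sample(18:39, N)
    vals <- matrix(rnorm(3 * N), 3, N)
    jk <- jackknife_correlation(vals, ages)
    for (v in 1:3) {
      r_full <- cor(vals[v, ], ages)
      T <- atanh(r_full)
      partials <- vapply(seq_len(N), function(i)
        atanh(cor(vals[v, -i], ages[-i])), 0)
      Tm <- mean(partials)
      z_or <- N * T - (N - 1) * Tm
      expect_equal(jk$T[v], T, tolerance = 1e-12)
      expect_equal(jk$Tm[v], Tm, tolerance = 1e-12)
      expect_equal(jk$z_jack[v], z_or, tolerance = 1e-12)
      expect_equal(jk$r_jack[v], tanh(z_or), tolerance = 1e-12)
      expect_equal(jk$n[v], N)
    }
  }
})

test_that("jackknife reduces to the full-sample z under homogeneity", {
  # 4 points on a symmetric cross: every leave-one-out correlation equals
  # the full-sample correlation (0), so z_jack = T exactly
  ages <- c(1, 0, -1, 0) + 20
  vals <- matrix(c(0, 1, 0, -1), 1, 4)
  jk <- jackknife_correlation(vals, ages)
  expect_equal(jk$r[1], 0)
  expect_equal(jk$T[1], 0) # Fisher transform fixed point at r = 0
  expect_equal(jk$z_jack[1], jk$T[1], tolerance = 1e-12)
  expect_equal(jk$r_jack[1], 0, tolerance = 1e-12)
})

test_that("jackknife p-values follow the t-transform on N - 2 df", {
  set.seed(3)
  N <- 30
  ages <- sample(18:39, N, replace = TRUE)
  vals <- matrix(0.01 * ages + rnorm(N, 0, 0.05), 1, N)
  jk <- jackknife_correlation(vals, ages)
  tt <- jk$r_jack * sqrt((N - 2) / (1 - jk$r_jack^2))
  expect_equal(jk$p[1], 2 * pt(abs(tt), N - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  jz <- jackknife_correlation(vals, ages, p_method = "z")
  expect_false(identical(jz$p, jk$p))
  expect_error(jackknife_correlation(vals[, 1:3, drop = FALSE], ages[1:3]),
               "at least 4")
  expect_error(jackknife_correlation(vals, rep(25, N)), "constant")
})

test_that("BH mask matches the worked example and brute-force enumeration", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.09)
  out <- fdr_threshold(p, 0.05)
  expect_equal(out$mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fdr_threshold(rep(1, 7))$mask, rep(FALSE, 7))
  expect_equal(fdr_threshold(rep(0, 7))$mask, rep(TRUE, 7))
  # brute-force oracle over random subsets of a 10-p instance
  set.seed(4)
  p10 <- c(0.0005, 0.004, 0.011, 0.02, 0.024, 0.049, 0.1, 0.2, 0.5, 0.93)
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- p[o] <= seq_len(m) * q / m
    k <- if (any(ok)) max(which(ok)) else 0
    mask <- rep(FALSE, m)
    if (k > 0) mask[o[seq_len(k)]] <- TRUE
    mask
  }
  for (rep in 1:40) {
    sub <- sample(10, sample(1:10, 1))
    ps <- p10[sub]
    out <- fdr_threshold(ps, 0.05)
    expect_equal(out$mask, bh_oracle(ps, 0.05))
    expect_equal(out$q, p.adjust(ps, "BH"), tolerance = 1e-12)
  }
})

test_that("BH respects grouping and q is monotone in p", {
  set.seed(5)
  p <- runif(60)^2
  hemi <- rep(c("lh", "rh"), each = 30)
  out <- fdr_threshold(p, 0.05, grouping = hemi)
  for (h in c("lh", "rh")) {
    sub <- fdr_threshold(p[hemi == h], 0.05)
    expect_equal(out$mask[hemi == h], sub$mask)
    expect_equal(out$q[hemi == h], sub$q)
    o <- order(p[hemi == h])
    expect_true(all(diff(sub$q[o]) >= -1e-12))
  }
  expect_true(all(out$q >= p, na.rm = TRUE))
  expect_length(fdr_threshold(numeric(0))$mask, 0)
  expect_error(fdr_threshold(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("overlap ROIs: empty, identical, and two-blob flood-fill oracle", {
  m <- tiny_model()
  adj <- m$hemis$lh$adjacency
  nv <- length(adj)
  a <- rep(FALSE, nv); b <- rep(FALSE, nv)
  a[1:5] <- TRUE; b[10:15] <- TRUE
  expect_length(overlap_rois(a, b, adj), 0)
  one <- rep(FALSE, nv); one[adj[[40]]] <- TRUE; one[40] <- TRUE
  rois <- overlap_rois(one, one, adj, hemi = "lh")
  expect_length(rois, 1)
  expect_equal(rois[[1]]$vertices, sort(c(40, adj[[40]])))
  expect_equal(rois[[1]]$hemi, "lh")
  # two blobs; oracle by flood fill written independently here
  blob <- rep(FALSE, nv)
  blob[c(1, 2, 3)] <- TRUE
  far <- nv - 2
  blob[c(far, far + 1)] <- TRUE
  rois2 <- overlap_rois(blob, rep(TRUE, nv), adj)
  flood <- function(members, adj) {
    left <- members; comps <- list()
    while (length(left)) {
      frontier <- left[1]; comp <- c()
      while (length(frontier)) {
        comp <- union(comp, frontier)
        frontier <- setdiff(intersect(unlist(adj[frontier]), left), comp)
      }
      comps[[length(comps) + 1]] <- sort(comp)
      left <- setdiff(left, comp)
    }
    comps
  }
  oracle <- flood(which(blob), adj)
  expect_equal(lapply(rois2, `[[`, "vertices"), oracle)
  expect_length(overlap_rois(blob, rep(TRUE, nv), adj, min_size = 3), 1)
})

test_that("ROI age slope recovers a noiseless planted slope exactly", {
  set.seed(6)
  N <- 20
  ages <- sample(18:39, N, replace = TRUE)
  vals <- matrix(rep(0.6 + 0.003 * ages, each = 5), 5, N)
  fit <- suppressWarnings( # lm warns about the perfect fit
    roi_age_slope(list(vertices = 1:5), vals, ages))
  expect_equal(fit$slope, 0.003, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.6, tolerance = 1e-10)
  expect_error(roi_age_slope(list(vertices = 1:5), vals, rep(25, N)),
               "constant")
})

test_that("zero-slope generator: slope CI covers 0 at roughly nominal
          rate", {
  set.seed(7)
  cover <- 0
  for (r in 1:30) {
    N <- 25
    ages <- sample(18:39, N, replace = TRUE)
    vals <- matrix(rnorm(4 * N, 0.6, 0.02), 4, N)
    fit <- roi_age_slope(list(vertices = 1:4), vals, ages)
    cover <- cover + (fit$ci[1] <= 0 && fit$ci[2] >= 0)
  }
  expect_gte(cover, 25) # ~95% coverage, allow Monte-Carlo slack
})

test_that("residualize-then-correlate equals partial correlation", {
  set.seed(8)
  N <- 40
  ages <- sample(18:39, N, replace = TRUE)
  z1 <- rnorm(N); z2 <- rnorm(N)
  vals <- matrix(0.01 * ages + 0.5 * z1 - 0.3 * z2 + rnorm(N, 0, 0.3), 1, N)
  res <- residualize(vals, list(a = z1, b = z2))
  r_res_age <- cor(res[1, ], resid(lm(ages ~ z1 + z2)))
  # textbook partial correlation via residuals of both variables
  expect_equal(cor(res[1, ], ages) /
                 sqrt(1) , cor(res[1, ], ages)) # same object, sanity
  r_partial <- cor(resid(lm(vals[1, ] ~ z1 + z2)), resid(lm(ages ~ z1 + z2)))
  expect_equal(r_res_age, r_partial, tolerance = 1e-12)
})
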