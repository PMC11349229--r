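test_that("normalization centers and scales by the population RMS deviation", {
  fs <- feature_series(matrix(c(1, 2, 3), 3, 1), names = "a")
  nr <- normalize_features(fs)
  expect_equal(drop(nr$series$values), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(unname(nr$sigma), sqrt(2 / 3))
  # already-normalized input is a fixed point
  v <- drop(nr$series$values)
  nr2 <- normalize_features(feature_series(matrix(v, 3, 1), names = "a"))
  expect_equal(drop(nr2$series$values), v, tolerance = 1e-12)
  # constant columns are dropped with a warning, not an error
  fs2 <- feature_series(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_warning(nr3 <- normalize_features(fs2), "zero-variance")
  expect_equal(nr3$dropped, "b")
  expect_equal(ncol(nr3$series$values), 1L)
})

test_that("quadratic expansion produces all monomials in the documented order", {
  m <- matrix(c(2, 3), 1, 2)
  expect_equal(drop(expand_monomials(m, 2)), c(2, 3, 4, 6, 9))
  expect_identical(expand_monomials(m, 1), m)
  # column count J + J(J+1)/2
  m5 <- matrix(rnorm(50), 10, 5)
  expect_equal(ncol(expand_monomials(m5, 2)), 5 + 15)
  expect_error(expand_monomials(m, 3), "order")
})

test_that("whitening yields identity sample covariance and truncates rank deficiency", {
  set.seed(21)
  n <- 10000
  raw <- matrix(rnorm(2 * n), n, 2) %*% matrix(c(2, 0.9, 0.9, 1), 2, 2)
  wh <- whiten_pca(raw)
  cov_out <- crossprod(sweep(wh$z, 2, colMeans(wh$z), "-")) / n
  expect_lt(norm(cov_out - diag(wh$rank), "F"), 1e-8)
  # duplicated column drops one rank
  wh2 <- whiten_pca(cbind(raw, raw[, 1]))
  expect_equal(wh2$rank, 2L)
  # already-white input stays white
  wh3 <- whiten_pca(wh$z)
  cov3 <- crossprod(sweep(wh3$z, 2, colMeans(wh3$z), "-")) / n
  expect_lt(norm(cov3 - diag(2), "F"), 1e-10)
  expect_error(whiten_pca(matrix(0, 10, 2)), "zero")
})

test_that("finite differences never straddle segment boundaries", {
  z <- matrix(c(0, 1, 3, 10, 14, 20), 6, 1)
  expect_equal(drop(time_differences(z)), c(1, 2, 7, 4, 6))
  d2 <- time_differences(z, segments = c(1L, 4L))
  expect_equal(drop(d2), c(1, 2, 4, 6))   # 4 rows, none crossing the join
  expect_equal(nrow(d2), 6L - 2L)
  expect_equal(drop(time_differences(matrix(5, 4, 1))), rep(0, 3))
  expect_error(time_differences(z, segments = c(1L, 6L)), "at least 2")
})

test_that("fitted models satisfy the SFA constraints on their training data", {
  cases <- list(
    list(x = make_ar1_features(4000, 6, seed = 1), order = 1, k = 3),
    list(x = make_ar1_features(3000, 4, seed = 2), order = 2, k = 4),
    list(x = {
      d <- two_state_dihedral(n = 5000, n_fast = 4, seed = 5)
      sincos_expand(d)
    }, order = 1, k = 2))
  for (cs in cases) {
    m <- sfa(cs$x, order = cs$order, n_components = cs$k)
    y <- predict(m, cs$x)$values
    expect_lt(max(abs(colMeans(y))), 1e-8)
    expect_lt(max(abs(colMeans(y^2) - 1)), 1e-6)
    smom <- crossprod(y) / nrow(y)
    expect_lt(max(abs(smom[upper.tri(smom)])), 1e-6)
    expect_true(all(diff(m$lambda) >= -1e-12))
    expect_lt(max(abs(delta_value(y, cs$x$segments) - m$lambda)), 1e-8)
  }
})

test_that("order-1 fit solves the generalized eigenproblem Cov(cdot) w = lambda Cov(c) w", {
  for (seed in 1:3) {
    x <- make_ar1_features(3000, 8, seed = seed)
    m <- sfa(x, order = 1, n_components = 3)
    or <- sfa_oracle(x)
    expect_equal(m$lambda, or$lambda[1:3], tolerance = 1e-8)
    # compare spans of the weight vectors in normalized-feature space
    g <- crossprod(m$S, m$W)
    ang <- principal_angles(g, or$W[, 1:3, drop = FALSE])
    expect_lt(max(ang), 1e-6)
  }
})

test_that("slowness eigenvalues match the lag-1 autocorrelation identity on one long segment", {
  x <- make_ar1_features(100000, 5, seed = 9)
  m <- sfa(x, order = 1, n_components = 3)
  y <- predict(m, x)$values
  for (k in 1:3) {
    rho <- cor(y[-1, k], y[-nrow(y), k])
    expect_equal(m$lambda[k], 2 * (1 - rho), tolerance = 1e-3)
  }
})

test_that("quadratic SFA recovers the slow sine of the canonical two-component signal", {
  fs <- wiskott_signal(5000)
  m <- sfa(fs, order = 2, n_components = 2)
  y <- predict(m, fs)
  t <- (seq_len(5000) - 1) * fs$dt_ps
  expect_gte(abs(cor(y$values[, 1], sin(t))), 0.99)
})

test_that("transform matches by name, vanishes at the training mean, and absorbs rescaling", {
  x <- make_ar1_features(2000, 5, seed = 13)
  m <- sfa(x, order = 1, n_components = 2)
  y <- predict(m, x)$values
  # permuting feature columns changes nothing (matched by name)
  perm <- feature_series(x$values[, c(3, 1, 5, 2, 4)], dt_ps = x$dt_ps)
  expect_equal(predict(m, perm)$values, y, tolerance = 1e-12)
  # evaluated at the training mean every component is zero
  mu_row <- feature_series(rbind(colMeans(x$values), colMeans(x$values)),
                           names = colnames(x$values))
  expect_lt(max(abs(predict(m, mu_row)$values)), 1e-10)
  # positive rescaling of a raw input column is absorbed by normalization
  v2 <- x$values; v2[, 2] <- v2[, 2] * 3.7
  m2 <- sfa(feature_series(v2, dt_ps = x$dt_ps), order = 1, n_components = 2)
  y2 <- predict(m2, feature_series(v2, dt_ps = x$dt_ps))$values
  expect_equal(y2, y, tolerance = 1e-8)
  # negative rescaling leaves the features defined up to component sign
  v3 <- x$values; v3[, 2] <- -v3[, 2]
  m3 <- sfa(feature_series(v3, dt_ps = x$dt_ps), order = 1, n_components = 2)
  y3 <- predict(m3, feature_series(v3, dt_ps = x$dt_ps))$values
  expect_equal(abs(y3), abs(y), tolerance = 1e-8)
  # missing and unknown features are explicit errors
  expect_error(predict(m, feature_series(x$values[, 1:3],
                                         dt_ps = x$dt_ps)), "missing feature")
  v4 <- cbind(x$values, extra = rnorm(2000))
  expect_error(predict(m, feature_series(v4, dt_ps = x$dt_ps)),
               "unknown feature")
})

test_that("delta_value is the mean squared step and matches the sine closed form", {
  expect_equal(drop(delta_value(matrix(3, 50, 1))), 0)
  N <- 10000
  y <- sqrt(2) * sin(2 * pi * (0:(N - 1)) / N)
  expect_equal(drop(delta_value(matrix(y, ncol = 1))), (2 * pi / N)^2,
               tolerance = 0.01)
  # segment-aware: differences at the boundary are excluded
  y2 <- matrix(c(0, 1, 2, 100, 101, 102), ncol = 1)
  expect_equal(drop(delta_value(y2, segments = c(1L, 4L))), 1)
})

test_that("rank_weights attributes the two-state flip and reproduces the transform affinely", {
  d <- two_state_dihedral(n = 20000, seed = 7)
  fs <- sincos_expand(d)
  m <- sfa(fs, order = 1, n_components = 2)
  w <- rank_weights(m, 1)
  expect_setequal(w$feature[1:2], c("sin_chi1_TRP41", "cos_chi1_TRP41"))
  # the affine map reproduces predict()
  y <- predict(m, fs)$values[, 1]
  manual <- drop(fs$values[, w$feature, drop = FALSE] %*% w$coefficient) +
    attr(w, "offset")
  expect_equal(manual, y, tolerance = 1e-8)
  expect_error(rank_weights(m, 5), "out of range")
})

test_that("model serialization round-trips bit-stably", {
  d <- two_state_dihedral(n = 3000, n_fast = 3, seed = 2)
  m <- sfa(sincos_expand(d), order = 1, n_components = 2)
  f <- tempfile(fileext = ".model")
  write_sfa_model(m, f)
  back <- read_sfa_model(f)
  for (fld in c("mu", "sigma", "zmean", "S", "W", "lambda", "order",
                "names", "dropped", "rank", "n_components"))
    expect_identical(back[[fld]], m[[fld]], label = fld)
  expect_identical(back$torsion_atoms, m$torsion_atoms)
  # predictions identical through the round trip
  fs <- sincos_expand(two_state_dihedral(n = 500, n_fast = 3, seed = 3))
  expect_identical(predict(back, fs)$values, predict(m, fs)$values)
})

test_that("zero-variance columns are dropped from the fit but tolerated at predict time", {
  set.seed(31)
  v <- cbind(a = rnorm(1000), b = rnorm(1000), flat = rep(1, 1000))
  fs <- feature_series(v)
  expect_warning(m <- sfa(fs, order = 1, n_components = 1), "zero-variance")
  expect_equal(m$dropped, "flat")
  y <- predict(m, fs)   # 'flat' present but ignored
  expect_equal(ncol(y$values), 1L)
})
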