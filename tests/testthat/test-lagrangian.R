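test_that("field interpolation is exact at nodes, for constants and bilinears", {
  gx <- c(10L, 20L, 30L); gy <- c(5L, 15L)
  f <- make_field(gx, gy, u = function(x, y) 0.1 * x - 0.2 * y,
                  v = function(x, y) 1 + 0.05 * y)
  at <- interpolate_field_at(f, cbind(20, 15))
  expect_equal(at$u, 0.1 * 20 - 0.2 * 15)
  expect_equal(at$v, 1 + 0.05 * 15)
  expect_false(at$flagged)
  # constant field reproduces the constants anywhere
  fc <- make_field(gx, gy, u = 2.5, v = -1.25)
  set.seed(5)
  q <- cbind(runif(20, 10, 30), runif(20, 5, 15))
  atc <- interpolate_field_at(fc, q)
  expect_equal(atc$u, rep(2.5, 20))
  expect_equal(atc$v, rep(-1.25, 20))
  # a bilinear u = a + b x + c y + d x y is reproduced exactly
  fb <- make_field(gx, gy,
                   u = function(x, y) 0.3 + 0.02 * x - 0.01 * y +
                     0.003 * x * y,
                   v = function(x, y) -0.1 + 0.01 * x * y)
  atb <- interpolate_field_at(fb, q)
  expect_equal(atb$u,
               0.3 + 0.02 * q[, 1] - 0.01 * q[, 2] +
                 0.003 * q[, 1] * q[, 2], tolerance = 1e-9)
  expect_equal(atb$v, -0.1 + 0.01 * q[, 1] * q[, 2], tolerance = 1e-9)
})

test_that("invalid nodes are excluded with renormalized weights", {
  gx <- c(10L, 20L); gy <- c(10L, 20L)
  valid <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)  # node (20,20) invalid
  u <- matrix(c(1, 1, 1, 100), 2, 2)
  f <- make_field(gx, gy, u = u, v = u, valid = valid)
  at <- interpolate_field_at(f, cbind(15, 15))
  expect_equal(at$u, 1)  # the poisoned corner is ignored
  # all four invalid: fallback 0, flagged
  f0 <- make_field(gx, gy, u = u, v = u,
                   valid = matrix(FALSE, 2, 2))
  at0 <- interpolate_field_at(f0, cbind(15, 15))
  expect_equal(at0$u, 0)
  expect_true(at0$flagged)
  # out-of-hull query snaps to the nearest node and is flagged
  ato <- interpolate_field_at(f, cbind(5, 5))
  expect_true(ato$flagged)
  expect_equal(ato$u, 1)
})

test_that("accumulation follows moved positions and prefix-sums increments", {
  gx <- seq(0L, 60L, by = 10L); gy <- seq(0L, 60L, by = 10L)
  zero <- make_field(gx, gy, u = 0, v = 0)
  p0 <- cbind(c(15, 30), c(20, 25))
  tr <- accumulate_trajectories(list(zero, zero), p0)
  expect_equal(tr$x, matrix(rep(p0[, 1], each = 3), 3))
  expect_equal(max(abs(tr$cumulative_u)), 0)
  # constant +1 then +2 in x: cumulative 0, 1, 3
  f1 <- make_field(gx, gy, u = 1, v = 0)
  f2 <- make_field(gx, gy, u = 2, v = 0)
  tr2 <- accumulate_trajectories(list(f1, f2), p0)
  expect_equal(tr2$cumulative_u[, 1], c(0, 1, 3))
  expect_equal(tr2$x[, 1], p0[1, 1] + c(0, 1, 3))
  # positions always equal points0 + cumulative displacement, exactly
  expect_equal(tr2$x, matrix(rep(p0[, 1], each = 3), 3) + tr2$cumulative_u)
  expect_equal(tr2$y, matrix(rep(p0[, 2], each = 3), 3) + tr2$cumulative_v)
})

test_that("accumulation matches a step-by-step brute-force oracle", {
  set.seed(6)
  gx <- seq(0L, 80L, by = 8L); gy <- seq(0L, 80L, by = 8L)
  for (rep in 1:5) {
    nf <- sample(2:5, 1)
    fields <- lapply(seq_len(nf), function(k) {
      a <- runif(4, -0.5, 0.5)
      b <- runif(4, -0.5, 0.5)
      make_field(gx, gy,
                 u = function(x, y) a[1] + a[2] * x / 80 + a[3] * y / 80 +
                   a[4] * x * y / 6400,
                 v = function(x, y) b[1] + b[2] * x / 80 + b[3] * y / 80 +
                   b[4] * x * y / 6400)
    })
    p0 <- cbind(runif(4, 20, 60), runif(4, 20, 60))
    tr <- accumulate_trajectories(fields, p0)
    # oracle: independent per-point loop re-interpolating at moved positions
    for (p in 1:4) {
      pos <- p0[p, ]; cum <- c(0, 0)
      for (k in seq_len(nf)) {
        it <- interpolate_field_at(fields[[k]], rbind(pos))
        pos <- pos + c(it$u, it$v)
        cum <- cum + c(it$u, it$v)
        expect_equal(tr$cumulative_u[k + 1, p], cum[1], tolerance = 1e-9)
        expect_equal(tr$cumulative_v[k + 1, p], cum[2], tolerance = 1e-9)
      }
    }
  }
})

test_that("points leaving the image are frozen and flagged", {
  gx <- seq(0L, 30L, by = 10L); gy <- seq(0L, 30L, by = 10L)
  push <- make_field(gx, gy, u = 25, v = 0, dim = c(40, 40))
  tr <- accumulate_trajectories(list(push, push), cbind(25, 15))
  expect_true(tr$frozen[2, 1])
  expect_equal(tr$x[3, 1], 25)  # never moved past the boundary
  expect_equal(tr$cumulative_u[3, 1], 0)
})

test_that("drift correction cancels a pure linear ramp and leaves closed curves alone", {
  fr <- 30; T <- 3
  t <- seq(0, 4, by = 1 / fr)
  ramp <- 2 * t / T
  corr <- drift_correct(ramp, T, fr)
  expect_lt(max(abs(corr[t <= T])), 1e-12)
  # beyond T the second branch subtracts the constant S(T)
  expect_equal(corr[t >= T], ramp[t >= T] - 2, tolerance = 1e-12)
  closed <- sin(2 * pi * t / T)  # S(T) interpolates to ~0 on this grid
  expect_equal(drift_correct(closed, T, fr)[t <= T], closed[t <= T],
               tolerance = 1e-9)
})

test_that("drift correction closes the curve at t = T even off the frame grid", {
  fr <- 30
  t <- seq(0, 4, by = 1 / fr)
  s <- sin(2 * pi * t / 2.5) + 0.31 * t
  for (T in c(2.5, 2.517)) {  # on- and off-grid periods
    corr <- drift_correct(s, T, fr)
    at_T <- stats::approx(t, corr, xout = T)$y
    expect_lt(abs(at_T), 1e-9)
    # continuity: both branches agree at the bracketing frames
    k <- max(which(t <= T))
    left <- s[k] - stats::approx(t, s, xout = T)$y / T * t[k]
    expect_equal(corr[k], left, tolerance = 1e-12)
  }
  # sinusoid plus mild drift: corrected curve tracks the sinusoid closely
  T <- 3
  s2 <- sin(2 * pi * t / T) + 0.1 * t
  corr2 <- drift_correct(s2, T, fr)
  expect_lt(max(abs(corr2[t <= T] - sin(2 * pi * t[t <= T] / T))), 0.01)
})

test_that("drift correction validates its period", {
  expect_error(drift_correct(1:10, 0, 30), "period")
  expect_error(drift_correct(1:10, 10, 30), "period")
})

test_that("the breathing period is recovered by autocorrelation", {
  fr <- 30
  t <- seq(0, 6, by = 1 / fr)
  pure <- sin(2 * pi * t / 3)
  expect_lt(abs(estimate_period(pure, fr) - 3), 1 / fr)
  drifted <- pure + 0.2 * t
  expect_lt(abs(estimate_period(drifted, fr) - 3), 1 / fr)
  expect_error(estimate_period(rep(1, 200), fr), "period")
})
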