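test_that("self-correlation peaks at exactly 1 at the centred lag", {
  set.seed(1)
  region <- matrix(rnorm(20 * 20), 20, 20)
  tmpl <- region[7:14, 7:14]
  s <- ncc_surface(tmpl, region)
  expect_equal(max(s), 1, tolerance = 1e-12)
  pk <- which(s == max(s), arr.ind = TRUE)
  expect_equal(as.integer(pk), c(7L, 7L))
  # contrast inversion gives -1 at the matching lag
  s_neg <- ncc_surface(-tmpl, region)
  expect_equal(s_neg[7, 7], -1, tolerance = 1e-12)
})

test_that("optimized NCC matches the textbook double-loop definition", {
  set.seed(2)
  for (i in 1:10) {
    tmpl <- matrix(rnorm(64), 8, 8)
    region <- matrix(rnorm(256), 16, 16)
    expect_lt(max(abs(ncc_surface(tmpl, region) - ncc_brute(tmpl, region))),
              1e-10)
  }
})

test_that("every NCC value lies in [-1, 1]", {
  set.seed(3)
  for (i in 1:20) {
    tmpl <- matrix(runif(49, 0, 255), 7, 7)
    region <- matrix(runif(625, 0, 255), 25, 25)
    s <- ncc_surface(tmpl, region)
    expect_lte(max(s), 1 + 1e-9)
    expect_gte(min(s), -1 - 1e-9)
  }
})

test_that("flat templates are flagged, not raised", {
  s <- ncc_surface(matrix(5, 4, 4), matrix(rnorm(100), 10, 10))
  expect_true(attr(s, "flat"))
  expect_true(all(s == 0))
  expect_error(ncc_surface(matrix(1, 8, 8), matrix(1, 8, 8)),
               "strictly larger")
})

test_that("lateral interpolation preserves samples and reproduces linears", {
  set.seed(4)
  img <- matrix(runif(30 * 11, 0, 255), 30, 11)
  expect_identical(interp_lateral(img, 1L), img)
  up <- interp_lateral(img, 5L)
  expect_equal(ncol(up), (11 - 1) * 5 + 1)
  expect_equal(up[, (0:10) * 5 + 1], img)
  # a column-linear ramp stays on the ramp at interpolated columns
  ramp <- outer(seq_len(6), seq_len(9), function(i, j) 2 * j + 0.5)
  up3 <- interp_lateral(ramp, 3L)
  truth <- outer(seq_len(6), seq(1, 9, by = 1 / 3),
                 function(i, x) 2 * x + 0.5)
  expect_equal(up3, truth, tolerance = 1e-9)
  expect_error(interp_lateral(img, 0), "factor")
})

test_that("subsample refinement recovers analytic peaks", {
  # symmetric discrete peak: refinement must return the integer lag exactly
  i <- -5:5
  sym <- outer(exp(-i^2 / 4), exp(-i^2 / 9))
  pk <- subsample_peak(sym, 5L)
  expect_equal(pk$row, 6)
  expect_equal(pk$col, 6)
  # known quadratic with maximum at fractional lags
  r0 <- 6 + 0.30; c0 <- 6 - 0.70
  quad <- outer(seq_len(11), seq_len(11), function(r, c)
    1 - 0.05 * (r - r0)^2 - 0.04 * (c - c0)^2)
  pk <- subsample_peak(quad, 5L)
  expect_lt(abs(pk$row - r0), 0.05)
  expect_lt(abs(pk$col - c0), 0.05)
  # degenerate factor with refinement disabled returns the integer argmax
  pk0 <- subsample_peak(quad, 1L, refine = FALSE)
  expect_equal(pk0$row, 6)
  expect_equal(pk0$col, 5)
  # border maximum is returned unrefined and flagged
  ramp <- outer(1:7, 1:7, function(r, c) r + c)
  pkb <- subsample_peak(ramp, 5L)
  expect_true(pkb$clipped)
  expect_equal(c(pkb$row, pkb$col), c(7, 7))
})

test_that("identity motion yields a zero field with perfect correlation", {
  rp <- rigid_pair()
  fld <- estimate_interframe_field(rp$f0, rp$f0, seq(40, 120, by = 16),
                                   seq(40, 120, by = 16))
  expect_true(all(fld$valid))
  expect_lt(max(abs(fld$u)), 1e-6)
  expect_lt(max(abs(fld$v)), 1e-6)
  expect_true(all(fld$peak_corr > 1 - 1e-9))
})

test_that("integer shifts are recovered to centipixel accuracy", {
  rp <- rigid_pair()
  gx <- seq(40, 120, by = 16); gy <- seq(40, 120, by = 16)
  fld <- estimate_interframe_field(rp$f0, rp$f1, gx, gy)
  expect_true(all(fld$valid))
  expect_lt(abs(mean(fld$u) - 3), 0.01)
  expect_lt(abs(mean(fld$v) - 1), 0.01)
})

test_that("swapping the frame order negates the field", {
  rp <- rigid_pair()
  gx <- seq(48, 112, by = 16); gy <- seq(48, 112, by = 16)
  fwd <- estimate_interframe_field(rp$f0, rp$f1, gx, gy)
  bwd <- estimate_interframe_field(rp$f1, rp$f0, gx, gy)
  ok <- fwd$valid & bwd$valid
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(fwd$u[ok] + bwd$u[ok])), 0.05)
  expect_lt(max(abs(fwd$v[ok] + bwd$v[ok])), 0.05)
})

test_that("estimation error grows monotonically with additive noise", {
  rp <- rigid_pair()
  gx <- seq(48, 112, by = 16); gy <- seq(48, 112, by = 16)
  err <- vapply(c(0, 10, 30), function(sd_noise) {
    set.seed(1234)
    n0 <- rp$f0 + matrix(rnorm(length(rp$f0), sd = sd_noise), nrow(rp$f0))
    n1 <- rp$f1 + matrix(rnorm(length(rp$f1), sd = sd_noise), nrow(rp$f1))
    fld <- estimate_interframe_field(n0, n1, gx, gy)
    mean(abs(fld$u[fld$valid] - 3) + abs(fld$v[fld$valid] - 1))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("tracking configuration is validated", {
  expect_error(tracking_config(kernel_size_px = c(16, 17)), "odd")
  expect_error(tracking_config(min_correlation = 1.5), "min_correlation")
  expect_error(tracking_config(lateral_interp_factor = 0), "lateral")
  expect_error(estimate_interframe_field(matrix(0, 5, 5), matrix(0, 6, 6),
                                         1, 1),
               "identical dimensions")
  expect_error(estimate_interframe_field(matrix(0, 50, 50),
                                         matrix(0, 50, 50),
                                         integer(0), 10),
               "at least one node")
})
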