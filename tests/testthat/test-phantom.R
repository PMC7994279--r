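test_that("scatterer generation is deterministic, seed-sensitive and density-linear", {
  spec <- phantom_spec(64, 64, n_frames = 2, rng_seed = 42)
  a <- generate_scatterers(spec)
  b <- generate_scatterers(spec)
  expect_identical(a, b)
  spec2 <- phantom_spec(64, 64, n_frames = 2, rng_seed = 43)
  expect_false(identical(generate_scatterers(spec2)$x, a$x))
  d2 <- phantom_spec(64, 64, n_frames = 2, scatterer_density = 20,
                     rng_seed = 42)
  expect_lte(abs(generate_scatterers(d2)$n - 2L * a$n), 1L)
})

test_that("invalid phantom specs are rejected naming the offending field", {
  expect_error(phantom_spec(64, 64, scatterer_density = 0),
               "scatterer_density")
  expect_error(phantom_spec(64, 64, n_frames = 1), "n_frames")
  expect_error(phantom_spec(64, 64, psf_axial_sigma_px = -1),
               "psf_axial_sigma_px")
  expect_error(phantom_spec(64, 64, motion_model = "breathing_sinusoid",
                            motion_params = list(amp_u_px = 1)),
               "motion_params")
})

test_that("rendering frame 0 does not depend on the motion amplitudes", {
  base <- list(image_height_px = 80L, image_width_px = 80L, n_frames = 5L)
  sA <- phantom_spec(80, 80, n_frames = 5,
                     motion_model = "breathing_sinusoid",
                     motion_params = list(amp_u_px = 4, amp_v_px = 2,
                                          period_s = 3), rng_seed = 9)
  sB <- phantom_spec(80, 80, n_frames = 5,
                     motion_model = "breathing_sinusoid",
                     motion_params = list(amp_u_px = 2, amp_v_px = 4,
                                          period_s = 2), rng_seed = 9)
  sc <- generate_scatterers(sA)
  expect_identical(render_frame(sc, sA, 0), render_frame(sc, sB, 0))
  expect_error(render_frame(sc, sA, 5), "out of range")
  expect_error(render_frame(sc, sA, -1), "out of range")
})

test_that("integer rigid translation circularly shifts the image interior", {
  spec <- phantom_spec(96, 96, n_frames = 2,
                       motion_model = "rigid_translation",
                       motion_params = list(du_per_frame = 2,
                                            dv_per_frame = 1),
                       rng_seed = 7)
  sc <- generate_scatterers(spec)
  ref <- mean(render_frame(sc, spec, 0, compress = FALSE))
  f0 <- render_frame(sc, spec, 0, ref = ref)
  f1 <- render_frame(sc, spec, 1, ref = ref)
  # content at (y, x) in frame 1 came from (y - 1, x - 2) in frame 0
  interior_r <- 10:85; interior_c <- 10:85
  expect_equal(f1[interior_r, interior_c],
               f0[interior_r - 1, interior_c - 2])
})

test_that("volume-preserving motion keeps the mean intensity within 2%", {
  spec <- phantom_spec(128, 128, n_frames = 16, frame_rate_hz = 30,
                       motion_model = "breathing_sinusoid",
                       motion_params = list(amp_u_px = 5, amp_v_px = 2.5,
                                            period_s = 2), rng_seed = 3)
  sc <- generate_scatterers(spec)
  ref <- mean(render_frame(sc, spec, 0, compress = FALSE))
  m0 <- mean(render_frame(sc, spec, 0, ref = ref))
  m_peak <- mean(render_frame(sc, spec, 15, ref = ref))
  expect_lt(abs(m_peak - m0) / m0, 0.02)
})

test_that("pre-log envelope has fully-developed-speckle statistics", {
  spec <- phantom_spec(128, 128, n_frames = 2, rng_seed = 17)
  sc <- generate_scatterers(spec)
  env <- render_frame(sc, spec, 0, compress = FALSE)
  snr <- mean(env) / stats::sd(env)
  rayleigh_snr <- sqrt(pi / (4 - pi))  # ~1.91
  expect_lt(abs(snr - rayleigh_snr) / rayleigh_snr, 0.20)
})

test_that("ground truth closes: zero at frame 0 and at a full breathing period", {
  spec <- phantom_spec(64, 64, n_frames = 61, frame_rate_hz = 30,
                       motion_model = "breathing_sinusoid",
                       motion_params = list(amp_u_px = 6, amp_v_px = 3,
                                            period_s = 2), rng_seed = 1)
  seq_ <- generate_sequence(spec)
  pts <- cbind(c(10, 30, 50), c(20, 32, 44))
  expect_equal(seq_$ground_truth$displacement_fn(0, pts),
               cbind(u = c(0, 0, 0), v = c(0, 0, 0)))
  # frame 60 is t = 2 s = one full period
  d <- seq_$ground_truth$displacement_fn(60, pts)
  expect_lt(max(abs(d)), 1e-9)
  expect_lt(max(abs(seq_$ground_truth$gs_curve)), 1e-9)
})

test_that("true strain is zero for rigid motion and 100*eps for lateral stretch", {
  rig <- phantom_spec(64, 64, n_frames = 5,
                      motion_model = "rigid_translation",
                      motion_params = list(du_per_frame = 1.5,
                                           dv_per_frame = -0.5),
                      rng_seed = 2)
  expect_equal(generate_sequence(rig)$ground_truth$gs_curve, rep(0, 5))
  st <- phantom_spec(64, 64, n_frames = 5,
                     motion_model = "uniform_lateral_stretch",
                     motion_params = list(eps_max = 0.04), rng_seed = 2)
  gs <- generate_sequence(st)$ground_truth$gs_curve
  expect_equal(gs, 100 * 0.04 * (0:4) / 4, tolerance = 1e-9)
})

test_that("identical spec and seed reproduce a sequence bit for bit", {
  spec <- phantom_spec(48, 48, n_frames = 3,
                       motion_model = "rigid_translation",
                       motion_params = list(du_per_frame = 0.3,
                                            dv_per_frame = 0.1),
                       rng_seed = 23)
  s1 <- generate_sequence(spec)
  s2 <- generate_sequence(spec)
  expect_identical(s1$stack$frames, s2$stack$frames)
})
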