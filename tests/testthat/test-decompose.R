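test_that("eye reaction is recovered from a rigid-translation phantom", {
  spec <- translation_spec()
  truth <- synthesize_contour(spec)
  seq <- render_sequence(truth, spec)
  contours <- detect_contour_sequence(seq)
  L_q <- separate_eye_reaction(contours)
  expect_lt(max(abs(L_q - truth$L_q)), 0.5)
})

test_that("static sequences have zero eye reaction", {
  truth <- synthesize_contour(static_spec())
  cs <- contour_series(truth$contour, dt_ms = 0.23, cal = truth$cal)
  expect_equal(separate_eye_reaction(cs), rep(0, 20))
})

test_that("a central indentation does not masquerade as eye motion", {
  spec <- phantom_spec(eye_amplitude_px = 0, drift_mm = 0, vibrations = list())
  truth <- synthesize_contour(spec)
  cs <- contour_series(truth$contour, dt_ms = spec$dt_ms, cal = truth$cal)
  expect_lt(max(abs(separate_eye_reaction(cs))), 0.5)
})

test_that("deformation is baseline-referenced and tracks the injected depth", {
  spec <- phantom_spec(eye_amplitude_px = 0, drift_mm = 0, vibrations = list())
  truth <- synthesize_contour(spec)
  cs <- contour_series(truth$contour, dt_ms = spec$dt_ms, cal = truth$cal)
  L_q <- separate_eye_reaction(cs)
  cd <- compute_deformation(cs, L_q)
  expect_equal(cd$L_d[, 1], rep(0, nrow(cd$L_d)))
  ctr <- round(truth$center_col[which.max(truth$depth_px)])
  expect_lt(max(abs(cd$L_d[ctr, ] - truth$depth_px)), 1)

  # pure translation: essentially no deformation survives
  tr2 <- synthesize_contour(translation_spec())
  cs2 <- contour_series(tr2$contour, dt_ms = 0.23, cal = tr2$cal)
  cd2 <- compute_deformation(cs2, separate_eye_reaction(cs2))
  expect_lt(max(abs(cd2$L_d)), 1)
})

test_that("the band split separates slow and fast motion and conserves the signal", {
  fs <- 1000 / 0.23
  t <- frame_time(1:140, 0.23) / 1000
  slow <- matrix(sin(2 * pi * 50 * t), 8, 140, byrow = TRUE)
  fast <- matrix(sin(2 * pi * 400 * t), 8, 140, byrow = TRUE)

  sp_s <- split_frequency(slow, fs, 100)
  expect_lt(max(abs(sp_s$L_H)), 0.05)

  sp_f <- split_frequency(fast, fs, 100)
  expect_lt(max(abs(sp_f$L_L)), 0.05)
  expect_gt(max(abs(sp_f$L_H)), 0.95)

  # exact complement, scaling linearity, zero net phase
  x <- matrix(rnorm(10 * 140), 10, 140)
  sp <- split_frequency(x, fs, 100)
  expect_lt(max(abs(sp$L_L + sp$L_H - x)), 1e-6)
  sp3 <- split_frequency(3 * x, fs, 100)
  expect_equal(sp3$L_L, 3 * sp$L_L, tolerance = 1e-9)
  cc <- stats::ccf(sp_s$L_L[1, ], slow[1, ], lag.max = 5, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)

  expect_error(split_frequency(x[, 1:5], fs, 100), "insufficient frames")
  expect_error(split_frequency(x, fs, fs), "Nyquist")
})

test_that("decompose_contours assembles consistent components", {
  rec <- default_recovery()
  d <- rec$decomp
  expect_lt(max(abs(d$L_L + d$L_H - d$L_d)), 1e-6)
  expect_equal(d$L_d[, 1], rep(0, nrow(d$L_d)))
  expect_equal(d$L_c, sweep(rec$contours$values, 2, d$L_q))
  expect_equal(d$fs_hz, 1000 / 0.23)
})
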