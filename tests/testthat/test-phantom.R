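test_that("the synthetic contour matches its declared geometry and timing", {
  truth <- default_truth()
  expect_identical(dim(truth$contour), c(576L, 140L))
  i_peak <- which.max(truth$depth_px)
  expect_lt(abs(frame_time(i_peak, 0.23) - 15.5), 0.5)   # mid-sequence pulse peak
  expect_true(truth$ap1 < i_peak && i_peak < truth$ap2)

  flat <- synthesize_contour(static_spec())
  expect_true(all(flat$contour == flat$contour[, 1]))

  # injected quarter vibration carries its stated frequency
  vib <- truth$vib_traces$vib3_quarter_left
  sp <- abs(fft(c(vib * signal::hanning(140), rep(0, 4096 - 140))))
  freqs <- (seq_len(2048) - 1) * (1000 / 0.23) / 4096
  expect_lt(abs(freqs[which.max(sp[1:2048])] - 400), 20)
})

test_that("rendering is deterministic under the spec seed", {
  spec <- phantom_spec(n_frames = 10, t_on_ms = 0.5, duration_ms = 1.5,
                       vibrations = list())
  s1 <- render_sequence(synthesize_contour(spec), spec)
  s2 <- render_sequence(synthesize_contour(spec), spec)
  expect_identical(s1$frames, s2$frames)
  expect_identical(dim(s1$frames), c(200L, 576L, 10L))

  spec2 <- spec; spec2$seed <- 99
  s3 <- render_sequence(synthesize_contour(spec2), spec2)
  expect_false(identical(s1$frames, s3$frames))
})

test_that("recovery degrades monotonically with rendering noise", {
  rms_err <- vapply(c(0, 3, 9), function(ns) {
    spec <- phantom_spec(n_frames = 24, t_on_ms = 1, duration_ms = 4,
                         drift_mm = 0, eye_amplitude_px = 0, vibrations = list(),
                         noise_sd = ns, blur_sigma_px = 1, seed = 21)
    truth <- synthesize_contour(spec)
    seq <- render_sequence(truth, spec)
    det <- detect_contour_sequence(seq)
    sqrt(mean((det$values - truth$contour)^2))
  }, numeric(1))
  expect_true(all(diff(rms_err) > 0))
})

test_that("inconsistent phantom specs are refused", {
  expect_error(phantom_spec(vibrations = list(list(location = "nowhere",
                                                   frequency_hz = 100, amplitude_px = 1,
                                                   phase_rad = 0))),
               "inconsistent spec")
  expect_error(phantom_spec(vibrations = list(list(location = "peak_left",
                                                   frequency_hz = 3000, amplitude_px = 1,
                                                   phase_rad = 0))),
               "Nyquist")
  expect_error(phantom_spec(depth_mm = 0),
               "requires an indentation")
})

test_that("the end-to-end harness recovers the injected parameters", {
  rec <- default_recovery()
  rep <- rec$report
  expect_identical(sort(rep$type), c("peak", "quarter"))
  expect_true(all(abs(rep$recovered_hz - rep$injected_hz) < 20))
  q <- rep[rep$type == "quarter", ]
  expect_lt(abs(q$recovered_p2p_px - q$injected_p2p_px), 1)
})

test_that("phantom specs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_frames = 12, noise_sd = 0, depth_mm = 0,
                        eye_amplitude_px = 3, vibrations = list()), f)
  spec <- read_phantom_spec(f)
  expect_s3_class(spec, "phantom_spec")
  expect_identical(spec$n_frames, 12)
  expect_identical(spec$noise_sd, 0)
  expect_identical(spec$rows, 200)   # defaults retained
})
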