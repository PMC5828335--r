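fs <- 1000 / 0.23

test_that("the fundamental of a short sinusoid is located within the padded-bin error", {
  tt <- (0:47) * 0.23 / 1000
  f <- fundamental_frequency(sin(2 * pi * 400 * tt), fs)
  expect_lt(abs(f$fundamental_hz - 400), 15)
  expect_equal(f$resolution_hz, fs / 48)
  expect_identical(f$n_samples, 48L)

  mix <- 3 * sin(2 * pi * 300 * tt) + sin(2 * pi * 600 * tt)
  expect_lt(abs(fundamental_frequency(mix, fs)$fundamental_hz - 300), 15)

  expect_error(fundamental_frequency(rep(2, 48), fs), "no harmonic")
  expect_error(fundamental_frequency(sin(1:100), fs, band = c(100, 100)), "empty search band")
})

test_that("frequency estimates ignore scaling, offsets and modest gaps", {
  tt <- (0:47) * 0.23 / 1000
  x <- sin(2 * pi * 400 * tt)
  f0 <- fundamental_frequency(x, fs)$fundamental_hz
  expect_equal(fundamental_frequency(7 * x + 3, fs)$fundamental_hz, f0)
  gappy <- x; gappy[c(5, 20, 33)] <- NA
  expect_lt(abs(fundamental_frequency(gappy, fs)$fundamental_hz - 400), 30)
  allgap <- x; allgap[1:20] <- NA
  expect_error(fundamental_frequency(allgap, fs), "too many gaps")
})

test_that("the all-harmonics amplitude is the peak-to-peak excursion", {
  tt <- (0:199) * 0.23 / 1000
  expect_equal(amplitude_all_harmonics(3.5 * sin(2 * pi * 400 * tt)), 7, tolerance = 0.01)
  expect_identical(amplitude_all_harmonics(rep(4, 10)), 0)
  # on a single-harmonic phantom it is at least the first harmonic's peak-to-peak
  rec <- default_recovery()
  q <- rec$spectra$amplitude[rec$spectra$vibration == "quarter"]
  ps <- pixel_size(rec$seq$cal)
  expect_gte(q / ps[["height_um"]], 4 * 0.95)
})

test_that("case summaries aggregate mean and SD per vibration type", {
  rec <- default_recovery()
  s <- rec$spectra
  tab <- summarize_cases(list(s, s, s))
  expect_identical(unique(tab$n_cases), 3L)
  expect_true(all(tab$frequency_hz_sd == 0, na.rm = TRUE))

  two <- list(dplyr::mutate(s, fundamental_hz = 300),
              dplyr::mutate(s, fundamental_hz = 500))
  tab2 <- summarize_cases(two)
  expect_equal(unique(tab2$frequency_hz_mean), 400)
  expect_equal(unique(round(tab2$frequency_hz_sd, 1)), 141.4)
  expect_error(summarize_cases(list(s)), "at least 2")

  # frequencies drawn around 400 Hz are recovered with their spread
  tt <- (0:60) * 0.23 / 1000
  freqs <- withr::with_seed(9, rnorm(10, 400, 60))
  est <- vapply(freqs, function(fr)
    fundamental_frequency(sin(2 * pi * fr * tt), fs)$fundamental_hz, numeric(1))
  expect_lt(abs(mean(est) - mean(freqs)), 20)
  expect_lt(abs(sd(est) - sd(freqs)), 25)
})

test_that("the pipeline spectral summary sits in the analysis band", {
  rec <- default_recovery()
  sp <- rec$spectra
  expect_setequal(sp$vibration, c("peak", "quarter", "maxdef", "cutoff"))
  expect_true(all(sp$fundamental_hz > 100 & sp$fundamental_hz < fs / 2, na.rm = TRUE))
  expect_true(all(sp$units[sp$axis == "Y"] == "um"))
  expect_true(all(sp$units[sp$axis == "X"] == "mm"))
})
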