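test_that("detector recovers a clean analytic contour to sub-pixel accuracy", {
  cf <- clean_frame()
  det <- detect_outer_contour(cf$frame)
  expect_true(all(det$valid))
  err <- det$contour - cf$contour
  expect_lt(max(abs(err)), 0.25)
})

test_that("frames without a corneal band are rejected", {
  expect_error(detect_outer_contour(matrix(0, 60, 60)), "no cornea found")
})

test_that("isolated bright pixels do not perturb the contour", {
  cf <- clean_frame()
  base <- detect_outer_contour(cf$frame)$contour
  noisy <- cf$frame
  withr::with_seed(7, {
    for (k in 1:50) {
      j <- sample.int(ncol(noisy), 1)
      top <- floor(cf$contour[j]) - 5
      if (top >= 1) noisy[sample.int(top, 1), j] <- 255
    }
  })
  shifted <- detect_outer_contour(noisy)$contour
  expect_lt(max(abs(shifted - base)), 0.1)
})

test_that("a second, smaller bright blob below the cornea is ignored", {
  cf <- clean_frame()
  base <- detect_outer_contour(cf$frame)$contour
  withblob <- cf$frame
  withblob[150:170, 200:260] <- 220     # below the band, smaller than it
  det <- detect_outer_contour(withblob)$contour
  expect_equal(det, base, tolerance = 1e-12)
})

test_that("smooth illumination gain fields leave the contour in place", {
  cf <- clean_frame()
  base <- detect_outer_contour(cf$frame)$contour
  M <- nrow(cf$frame); N <- ncol(cf$frame)
  gain <- 0.6 + 0.4 * outer(0.5 + 0.5 * sin(seq(0, pi, length.out = M)),
                            0.5 + 0.5 * cos(seq(-2, 2, length.out = N)))
  gain <- 0.6 + 0.4 * (gain - min(gain)) / diff(range(gain))  # smooth, in [0.6, 1]
  det <- detect_outer_contour(round(cf$frame * gain))$contour
  expect_lt(max(abs(det - base)), 0.5)
})

test_that("detection is deterministic and the otsu fallback works on clean frames", {
  cf <- clean_frame()
  d1 <- detect_outer_contour(cf$frame)
  d2 <- detect_outer_contour(cf$frame)
  expect_identical(d1, d2)
  otsu <- detect_outer_contour(cf$frame, contour_params(method = "otsu"))
  expect_lt(max(abs(otsu$contour - cf$contour)), 1)
})

test_that("sequence detection matches phantom truth and flags bad frames", {
  rec <- default_recovery()
  err <- rec$contours$values - rec$truth$contour
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_lt(max(abs(err)), 1)

  # identical frames give identical contours
  cf <- clean_frame()
  seq <- image_sequence(array(rep(cf$frame, 8), dim = c(dim(cf$frame), 8)),
                        dt_ms = 0.23,
                        cal = calibration(nrow(cf$frame), ncol(cf$frame),
                                          3.3, 9.05))
  cs <- detect_contour_sequence(seq)
  expect_true(all(cs$values == cs$values[, 1]))

  # a frame with a mostly-destroyed band aborts with its index
  bad <- seq
  bad$frames[, 1:400, 3] <- 0
  expect_error(detect_contour_sequence(bad), "frame 3")
})
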