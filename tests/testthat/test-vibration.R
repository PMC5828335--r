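test_that("peak positions match a brute-force scan on random vectors", {
  v <- rep(0, 576); v[100] <- -5
  pk <- peak_positions(v)
  expect_equal(pk[c("m_kl", "n_kl")], list(m_kl = -5, n_kl = 100L))

  v2 <- rep(1, 576); v2[c(50, 80)] <- -2
  expect_identical(peak_positions(v2)$n_kl, 50L)   # leftmost tie-break

  ok <- withr::with_seed(42, vapply(1:1000, function(k) {
    N <- sample(10:60, 1) * 2
    x <- round(rnorm(N), 2)   # ties occur
    pk <- peak_positions(x)
    # exhaustive scan oracle, leftmost-on-tie
    N2 <- N %/% 2
    best_l <- 1; for (j in 1:N2) if (x[j] < x[best_l]) best_l <- j
    best_r <- N2 + 1; for (j in (N2 + 1):N) if (x[j] < x[best_r]) best_r <- j
    identical(pk$n_kl, as.integer(best_l)) && identical(pk$m_kl, x[best_l]) &&
      identical(pk$n_kr, as.integer(best_r)) && identical(pk$m_kr, x[best_r])
  }, logical(1)))
  expect_true(all(ok))
})

test_that("quarter points use floor rounding of the midpoints", {
  expect_identical(quarter_points(100, 500, 300)$n_fl, 200L)
  expect_identical(quarter_points(101, 500, 300)$n_fl, 200L)   # floor of 200.5
  expect_identical(quarter_points(100, 500, 300)$n_fr, 400L)
  expect_identical(quarter_points(101, 500, 302)$n_fl, 201L)              # floor of 201.5
  expect_identical(quarter_points(101, 500, 302, rounding = "nearest")$n_fl, 202L)
  expect_error(quarter_points(300, 500, 200), "ordering")
})

test_that("the maximum-deformation column is found by the windowed argmax", {
  x <- seq_len(576)
  ld <- exp(-((x - 288) / 40)^2)
  md <- max_deformation_position(ld, ld, n_kl = 150, n_kr = 430)
  expect_identical(md$n_d, 288L)

  # when the global max lies inside the window, restriction changes nothing
  rec <- default_recovery()
  idx <- seq(rec$appl$ap1 + 5, rec$appl$ap2 - 5, by = 5)
  for (i in idx) {
    glob <- which.max(rec$decomp$L_d[, i])
    if (glob > rec$traces$n_fl[i] && glob < rec$traces$n_fr[i]) {
      expect_identical(rec$traces$n_d[i], as.integer(glob))
    }
  }
})

test_that("cutoff columns bracket the deformed region", {
  ld <- rep(0, 576); ld[200:370] <- 5
  co <- cutoff_points(ld, p_r = 2)
  expect_true(co$n_bl >= 198 && co$n_bl <= 202)
  expect_true(co$n_br >= 368 && co$n_br <= 372)
  expect_null(cutoff_points(rep(0, 576)))       # no event: flagged gap

  # monotonically widening indentation keeps |n_bl - n_br| non-decreasing
  x <- seq_len(576)
  widths <- seq(20, 120, length.out = 12)
  spans <- vapply(widths, function(w) {
    co <- cutoff_points(10 * exp(-((x - 288) / w)^2))
    co$n_br - co$n_bl
  }, numeric(1))
  expect_true(all(diff(spans) >= 0))
})

test_that("the measurement error is the reciprocal deformed-column count", {
  expect_identical(measurement_error(rep(0, 576)), 1)
  ld <- rep(0, 576); ld[101:110] <- 5
  expect_identical(measurement_error(ld), 0.1)
  areas <- c(5, 20, 80, 300)
  deltas <- vapply(areas, function(k) {
    v <- rep(0, 576); v[seq_len(k) + 50] <- 3; measurement_error(v)
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
  expect_error(measurement_error(rep(0, 10), p_r = 0), "positive")
})

test_that("vibration angles follow the four-quadrant convention", {
  expect_identical(vibration_angle(0, 0, 110, 100), 0)
  expect_equal(vibration_angle(5, 0, 105, 100), pi / 4)
  expect_equal(vibration_angle(5, 0, 100, 100), pi / 2)
  deg <- vibration_angle(0, 0, 100, 100)
  expect_identical(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("the cumulative angle is a prefix sum with zero-filled gaps", {
  expect_equal(cumulative_angle(rep(0.2, 7))[7], 1.4)
  expect_identical(cumulative_angle(numeric(0)), numeric(0))
  withr::with_seed(3, {
    lam <- rnorm(60); lam[sample(60, 10)] <- NA
    beta <- cumulative_angle(lam)
    oracle <- numeric(60); acc <- 0
    for (i in 1:60) { if (!is.na(lam[i])) acc <- acc + lam[i]; oracle[i] <- acc }
    expect_equal(beta, oracle)
  })
})

test_that("peak-quarter correlation behaves like Pearson r", {
  x <- sin(1:50)
  expect_equal(peak_quarter_correlation(x, x), 1)
  expect_equal(peak_quarter_correlation(x, -x), -1)
  withr::with_seed(11, {
    a <- rnorm(1000); b <- rnorm(1000)
    expect_lt(abs(peak_quarter_correlation(a, b)), 0.1)
  })
  expect_error(peak_quarter_correlation(rep(1, 50), x), "undefined correlation")
})

test_that("per-frame constant offsets in L_d leave all four traces unchanged", {
  rec <- default_recovery()
  shifted <- rec$decomp
  withr::with_seed(5, offs <- rnorm(ncol(shifted$L_d), sd = 3))
  shifted$L_d <- sweep(shifted$L_d, 2, offs, "+")
  tr2 <- compute_vibration_traces(shifted, rec$appl)
  expect_equal(tr2$peak_vib_px, rec$traces$peak_vib_px, tolerance = 1e-12)
  expect_equal(tr2$quarter_vib_px, rec$traces$quarter_vib_px, tolerance = 1e-12)
  expect_identical(tr2$maxdef_vib_mm, rec$traces$maxdef_vib_mm)
  expect_identical(tr2$cutoff_vib_mm, rec$traces$cutoff_vib_mm)
  expect_equal(tr2$lambda_rad, rec$traces$lambda_rad, tolerance = 1e-12)
})

test_that("traces are confined to the open applanation interval with coherent columns", {
  rec <- default_recovery()
  tr <- rec$traces
  inside <- tr$i > rec$appl$ap1 & tr$i < rec$appl$ap2
  expect_true(all(is.na(tr$m_kl[!inside])))
  expect_true(all(!is.na(tr$peak_vib_px[inside])))
  N <- nrow(rec$decomp$L_d)
  expect_true(all(tr$n_kl[inside] <= N %/% 2 & tr$n_kr[inside] > N %/% 2))
  expect_true(all(tr$n_fl[inside] >= tr$n_kl[inside] & tr$n_fl[inside] <= tr$n_d[inside]))
  expect_true(all(tr$n_fr[inside] >= tr$n_d[inside] & tr$n_fr[inside] <= tr$n_kr[inside]))
  expect_true(all(tr$n_bl[inside] <= tr$n_kl[inside]))
  expect_true(all(tr$n_br[inside] >= tr$n_kr[inside]))
  expect_true(all(tr$delta_px[inside] > 0 & tr$delta_px[inside] <= 1))
  # delta * deformed-column count == 1 whenever deformation exists
  i0 <- rec$appl$peak_frame
  expect_equal(tr$delta_px[i0] * sum(rec$decomp$L_d[, i0] > 2), 1)
})
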