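#' Peak positions of one deformation frame
#'
#' The "peaks" are the raised rims beside the indentation. In image-row
#' orientation they are the topmost contour points, i.e. the minima of the
#' deformation: `m_kl` is the minimum of `L_d` over the left half of the
#' columns (1..floor(N/2)) with `n_kl` its leftmost argmin; `m_kr`/`n_kr`
#' mirror this on the right half. For odd N the middle column belongs to the
#' left half.
#'
#' @param ld_frame Numeric vector: one frame of `L_d` (length N).
#' @return List `m_kl`, `n_kl`, `m_kr`, `n_kr`, and `flat` (TRUE when either
#'   half is constant, in which case that argmin is the half's center).
#' @export
peak_positions <- function(ld_frame) {
  N <- length(ld_frame)
  N2 <- N %/% 2
  left <- ld_frame[1:N2]
  right <- ld_frame[(N2 + 1):N]
  flat_l <- diff(range(left)) == 0
  flat_r <- diff(range(right)) == 0
  n_kl <- if (flat_l) as.integer(ceiling(N2 / 2)) else which.min(left)
  n_kr <- if (flat_r) as.integer(N2 + ceiling((N - N2) / 2)) else N2 + which.min(right)
  list(m_kl = ld_frame[n_kl], n_kl = as.integer(n_kl),
       m_kr = ld_frame[n_kr], n_kr = as.integer(n_kr),
       flat = flat_l || flat_r)
}

#' Quarter columns
#'
#' The quarter points sit midway between each peak column and the
#' maximum-deformation column. Floor rounding by default (configurable to
#' nearest integer).
#'
#' @param n_kl,n_kr Peak columns (left, right).
#' @param n_d Maximum-deformation column.
#' @param rounding `"floor"` (default) or `"nearest"`.
#' @return List `n_fl`, `n_fr` (integer columns).
#' @export
quarter_points <- function(n_kl, n_kr, n_d, rounding = c("floor", "nearest")) {
  rounding <- match.arg(rounding)
  if (!(n_kl < n_d && n_d < n_kr)) stop("ordering violated: need n_kl < n_d < n_kr")
  rnd <- if (rounding == "floor") floor else round
  list(n_fl = as.integer(rnd((n_kl + n_d) / 2)),
       n_fr = as.integer(rnd((n_kr + n_d) / 2)))
}

#' Maximum-deformation column of one frame
#'
#' The deepest-indentation column. Its defining window `[n_fl, n_fr]` itself
#' depends on `n_d`, so the position is bootstrapped from the global argmax
#' of the low band (the slow indentation shape, free of high-frequency
#' vibration), the quarter window computed from it, and the argmax of `L_d`
#' re-evaluated inside that window, with one fixed-point refinement. Ties
#' break to the leftmost column.
#'
#' @param ld_frame One frame of `L_d` (length N).
#' @param ll_frame Matching frame of the low band `L_L`.
#' @param n_kl,n_kr Peak columns for this frame.
#' @param rounding Quarter-point rounding, see [quarter_points()].
#' @return List `n_d`, `n_fl`, `n_fr`; `NULL` if the peak/maximum ordering
#'   cannot be established (flagged frame).
#' @export
max_deformation_position <- function(ld_frame, ll_frame, n_kl, n_kr,
                                     rounding = "floor") {
  n_d <- which.max(ll_frame)
  for (k in 1:2) {
    if (!(n_kl < n_d && n_d < n_kr)) return(NULL)
    qp <- quarter_points(n_kl, n_kr, n_d, rounding)
    n_d <- qp$n_fl - 1L + which.max(ld_frame[qp$n_fl:qp$n_fr])
  }
  if (!(n_kl < n_d && n_d < n_kr)) return(NULL)
  qp <- quarter_points(n_kl, n_kr, n_d, rounding)
  list(n_d = as.integer(n_d), n_fl = qp$n_fl, n_fr = qp$n_fr)
}

#' Cutoff columns of one frame
#'
#' The junction columns where the deformed contour departs from its resting
#' position: scanning from the left image edge toward the center, `n_bl` is
#' the last column before the deviation `|L_d(n,i)|` first exceeds the
#' threshold `p_r`; `n_br` mirrors this from the right edge. For odd N the
#' middle column belongs to the left half.
#'
#' Any rigid per-frame offset remaining in the deformation (residual eye
#' motion) is removed first, estimated as the mean of the outermost margin
#' columns: the junction points measure where the cornea *deformed*, so they
#' are exactly invariant to per-frame constant shifts.
#'
#' @param ld_frame One frame of `L_d` (length N).
#' @param p_r Binarization threshold in px (default 2).
#' @param margin_cols Columns per side used to estimate the residual offset
#'   (default 10).
#' @return List `n_bl`, `n_br` (integer columns), or `NULL` when either half
#'   never exceeds the threshold (no junction point; flagged frame).
#' @export
cutoff_points <- function(ld_frame, p_r = 2, margin_cols = 10) {
  N <- length(ld_frame)
  N2 <- N %/% 2
  offset <- mean(ld_frame[c(seq_len(margin_cols), N - seq_len(margin_cols) + 1L)])
  dev <- abs(ld_frame - offset)
  exc_l <- which(dev[1:N2] > p_r)
  exc_r <- which(dev[(N2 + 1):N] > p_r)
  if (length(exc_l) == 0 || length(exc_r) == 0) return(NULL)
  n_bl <- exc_l[1] - 1L
  n_br <- N2 + exc_r[length(exc_r)] + 1L
  if (n_bl < 1L || n_br > N) return(NULL)
  list(n_bl = as.integer(n_bl), n_br = as.integer(n_br))
}

#' Per-frame measurement error
#'
#' The error of the vibration point measurements shrinks as the deformed
#' area grows: `delta = 1 / (number of columns whose deformation exceeds
#' p_r)`, and 1 px (the worst case) when no column exceeds it.
#'
#' @param ld_frame One frame of `L_d`.
#' @param p_r Binarization threshold in px (default 2).
#' @return Error `delta` in pixels, in (0, 1].
#' @export
measurement_error <- function(ld_frame, p_r = 2) {
  if (p_r <= 0) stop("p_r must be positive")
  s <- sum(ld_frame > p_r)
  if (s == 0) 1 else 1 / s
}

#' Instantaneous vibration angle
#'
#' Four-quadrant angle of the segment joining the two quarter points,
#' `atan2(m_fl - m_fr, n_fl - n_fr)`, in (-pi, pi]. Both arguments are in
#' pixels by default (a mixed-axis angle); converting the axes to physical
#' units changes the angle, so the unit choice is explicit.
#'
#' @param m_fl,m_fr High-band values at the quarter columns (px).
#' @param n_fl,n_fr Quarter columns.
#' @param units `"px"` (default) or `"physical"`; for `"physical"` both
#'   differences are converted to micrometres using `cal`.
#' @param cal A [calibration()] (required for `"physical"`).
#' @return Angle lambda in radians; 0 (flagged via attribute) when both
#'   differences are zero.
#' @export
vibration_angle <- function(m_fl, m_fr, n_fl, n_fr,
                            units = c("px", "physical"), cal = NULL) {
  units <- match.arg(units)
  dm <- m_fl - m_fr
  dn <- n_fl - n_fr
  if (units == "physical") {
    stopifnot(inherits(cal, "calibration"))
    ps <- pixel_size(cal)
    dm <- dm * ps[["height_um"]]
    dn <- dn * ps[["width_um"]]
  }
  if (dm == 0 && dn == 0) return(structure(0, degenerate = TRUE))
  atan2(dm, dn)
}

#' Cumulative vibration angle
#'
#' Running sum of the instantaneous angle from the first analyzed frame;
#' undefined frames contribute 0.
#'
#' @param lam Numeric vector of angles (NA allowed).
#' @return Numeric vector `beta` of the same length.
#' @export
cumulative_angle <- function(lam) {
  if (length(lam) == 0) return(numeric(0))
  lam[is.na(lam)] <- 0
  cumsum(lam)
}

#' Correlation between peak and quarter vibrations
#'
#' Pearson correlation of the two amplitude traces over their common defined
#' frames.
#'
#' @param peak_vib,quarter_vib Numeric vectors (NA outside the analysis
#'   interval).
#' @return Pearson r.
#' @export
peak_quarter_correlation <- function(peak_vib, quarter_vib) {
  ok <- stats::complete.cases(peak_vib, quarter_vib)
  if (sum(ok) < 3) stop("undefined correlation: fewer than 3 common frames")
  if (sd(peak_vib[ok]) == 0 || sd(quarter_vib[ok]) == 0) {
    stop("undefined correlation: constant trace")
  }
  cor(peak_vib[ok], quarter_vib[ok])
}

#' Compute all vibration traces between the applanations
#'
#' Evaluates, for every frame strictly between `A_p1` and `A_p2`, the four
#' vibration measures and their supporting points: peak positions
#' (`m_kl`/`m_kr` with columns `n_kl`/`n_kr`), the maximum-deformation
#' column `n_d`, the quarter columns and high-band values there
#' (`n_fl`/`n_fr`, `m_fl`/`m_fr`), the cutoff columns (`n_bl`/`n_br`), the
#' per-frame error `delta`, and the angles `lambda` and `beta`. Frames
#' outside the interval are present but empty (NA), mirroring that the
#' definitions only apply between applanations.
#'
#' @param decomp A `decomposed_signals` from [decompose_contours()].
#' @param appl An `applanation_pair`.
#' @param p_r Binarization threshold in px (default 2).
#' @param angle_units `"px"` or `"physical"`, see [vibration_angle()].
#' @param rounding Quarter-point rounding, see [quarter_points()].
#' @return A tibble of class `vibration_traces` with one row per frame and
#'   columns `i, t_ms, m_kl, n_kl, m_kr, n_kr, n_d, n_fl, n_fr, m_fl, m_fr,
#'   n_bl, n_br, peak_vib_px, peak_vib_um, quarter_vib_px, quarter_vib_um,
#'   maxdef_vib_mm, cutoff_vib_mm, delta_px, lambda_rad, beta_rad`.
#'   Attributes carry the applanation pair, calibration and sampling info.
#' @export
compute_vibration_traces <- function(decomp, appl, p_r = 2,
                                     angle_units = c("px", "physical"),
                                     rounding = "floor") {
  stopifnot(inherits(decomp, "decomposed_signals"), inherits(appl, "applanation_pair"))
  angle_units <- match.arg(angle_units)
  nf <- ncol(decomp$L_d)
  N <- nrow(decomp$L_d)
  ps <- pixel_size(decomp$cal)
  pw_mm <- decomp$cal$field_width_mm / decomp$cal$cols
  idx <- seq(appl$ap1 + 1L, appl$ap2 - 1L)
  if (length(idx) < 1) stop("empty analysis interval")

  tr <- tibble::tibble(
    i = seq_len(nf), t_ms = frame_time(seq_len(nf), decomp$dt_ms),
    m_kl = NA_real_, n_kl = NA_integer_, m_kr = NA_real_, n_kr = NA_integer_,
    n_d = NA_integer_, n_fl = NA_integer_, n_fr = NA_integer_,
    m_fl = NA_real_, m_fr = NA_real_, n_bl = NA_integer_, n_br = NA_integer_,
    peak_vib_px = NA_real_, peak_vib_um = NA_real_,
    quarter_vib_px = NA_real_, quarter_vib_um = NA_real_,
    maxdef_vib_mm = NA_real_, cutoff_vib_mm = NA_real_,
    delta_px = NA_real_, lambda_rad = NA_real_, beta_rad = NA_real_
  )

  for (i in idx) {
    ld <- decomp$L_d[, i]
    ll <- decomp$L_L[, i]
    tr$delta_px[i] <- measurement_error(ld, p_r)

    pk <- peak_positions(ld)
    tr$m_kl[i] <- pk$m_kl; tr$n_kl[i] <- pk$n_kl
    tr$m_kr[i] <- pk$m_kr; tr$n_kr[i] <- pk$n_kr
    tr$peak_vib_px[i] <- abs(pk$m_kl - pk$m_kr)
    tr$peak_vib_um[i] <- tr$peak_vib_px[i] * ps[["height_um"]]

    md <- max_deformation_position(ld, ll, pk$n_kl, pk$n_kr, rounding)
    if (!is.null(md)) {
      tr$n_d[i] <- md$n_d; tr$n_fl[i] <- md$n_fl; tr$n_fr[i] <- md$n_fr
      tr$maxdef_vib_mm[i] <- (md$n_d - 1) * pw_mm
      tr$m_fl[i] <- decomp$L_H[md$n_fl, i]
      tr$m_fr[i] <- decomp$L_H[md$n_fr, i]
      tr$quarter_vib_px[i] <- abs(tr$m_fl[i] - tr$m_fr[i])
      tr$quarter_vib_um[i] <- tr$quarter_vib_px[i] * ps[["height_um"]]
      tr$lambda_rad[i] <- vibration_angle(tr$m_fl[i], tr$m_fr[i], md$n_fl, md$n_fr,
                                          units = angle_units, cal = decomp$cal)
    }

    co <- cutoff_points(ld, p_r)
    if (!is.null(co)) {
      tr$n_bl[i] <- co$n_bl; tr$n_br[i] <- co$n_br
      tr$cutoff_vib_mm[i] <- abs(co$n_br - co$n_bl) * pw_mm
    }
  }
  tr$beta_rad[idx] <- cumulative_angle(tr$lambda_rad[idx])

  structure(tr,
            class = c("vibration_traces", class(tr)),
            appl = appl, cal = decomp$cal, dt_ms = decomp$dt_ms,
            fs_hz = decomp$fs_hz, cutoff_hz = decomp$cutoff_hz, p_r = p_r)
}
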