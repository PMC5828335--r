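#' Detect the two applanation frames
#'
#' During an air-puff measurement the central cornea passes through two
#' momentarily flat configurations: inward (first applanation, `A_p1`) and
#' outward (second, `A_p2`). Flatness is scored per frame as the RMS residual
#' of a straight-line fit to the corrected contour `L_c` over a central
#' window (default 3 mm). `A_p1` is the flattest frame before the frame of
#' maximal central deformation, `A_p2` the flattest frame after it.
#'
#' @param decomp A `decomposed_signals` object from [decompose_contours()].
#' @param window_mm Width of the central flatness window in mm (default 3).
#' @param p_r Deformation threshold in px; if no frame deforms beyond it the
#'   sequence has no indentation episode and detection fails (default 2).
#' @return An object of class `applanation_pair`: list with `ap1`, `ap2`
#'   (frame indices), `ap1_ms`, `ap2_ms`, `peak_frame` and the per-frame
#'   `flatness` vector (px RMS).
#' @export
detect_applanations <- function(decomp, window_mm = 3, p_r = 2) {
  stopifnot(inherits(decomp, "decomposed_signals"))
  if (max(abs(decomp$L_d)) < p_r) stop("no deformation event")
  N <- nrow(decomp$L_d); nf <- ncol(decomp$L_d)
  pw_mm <- decomp$cal$field_width_mm / decomp$cal$cols
  center <- (N + 1) / 2
  half <- (window_mm / 2) / pw_mm
  cols <- max(1, round(center - half)):min(N, round(center + half))

  slow <- decomp$L_c[cols, , drop = FALSE]
  x <- seq_along(cols) - mean(seq_along(cols))
  X <- cbind(1, x)
  hat <- X %*% solve(crossprod(X), t(X))
  resid <- slow - hat %*% slow
  flatness <- sqrt(colMeans(resid^2))

  depth <- apply(decomp$L_d[cols, , drop = FALSE], 2, max)
  peak_frame <- which.max(depth)
  if (peak_frame < 3 || peak_frame > nf - 2) {
    stop("no deformation event: indentation peak too close to the sequence ends")
  }
  ap1 <- which.min(flatness[2:(peak_frame - 1)]) + 1L
  ap2 <- which.min(flatness[(peak_frame + 1):(nf - 1)]) + peak_frame
  structure(
    list(ap1 = as.integer(ap1), ap2 = as.integer(ap2),
         ap1_ms = frame_time(ap1, decomp$dt_ms),
         ap2_ms = frame_time(ap2, decomp$dt_ms),
         peak_frame = as.integer(peak_frame), flatness = flatness),
    class = "applanation_pair"
  )
}

#' Build an applanation pair from known times
#'
#' Devices report applanation times directly; this bypasses detection.
#'
#' @param ap1_ms,ap2_ms Applanation times in ms.
#' @param dt_ms Inter-frame interval in ms.
#' @param n_frames Number of frames in the sequence.
#' @return An `applanation_pair` (frame-quantized to the nearest frame).
#' @export
applanation_pair <- function(ap1_ms, ap2_ms, dt_ms = 0.23, n_frames = 140) {
  ap1 <- as.integer(round(ap1_ms / dt_ms) + 1)
  ap2 <- as.integer(round(ap2_ms / dt_ms) + 1)
  if (!(1 < ap1 && ap1 < ap2 && ap2 < n_frames)) {
    stop("applanations must satisfy 1 < A_p1 < A_p2 < frame count")
  }
  structure(
    list(ap1 = ap1, ap2 = ap2,
         ap1_ms = frame_time(ap1, dt_ms), ap2_ms = frame_time(ap2, dt_ms),
         peak_frame = as.integer(round((ap1 + ap2) / 2)),
         flatness = NULL),
    class = "applanation_pair"
  )
}

#' @export
print.applanation_pair <- function(x, ...) {
  cat(sprintf("<applanation_pair> A_p1 = frame %d (%.2f ms), A_p2 = frame %d (%.2f ms)\n",
              x$ap1, x$ap1_ms, x$ap2, x$ap2_ms))
  invisible(x)
}
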