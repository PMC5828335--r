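#' Rotational 3-D reconstruction of a corneal contour
#'
#' Sweeps the measured 2-D contour about a vertical symmetry axis to build a
#' visualization surface: each contour point at lateral distance `r` from
#' the axis traces the arc `(r cos(theta), r sin(theta))` for a
#' half-rotation `theta` in `[-pi/2, pi/2]`, and row values are carried
#' along by linear interpolation of the contour, each side of the axis
#' sweeping its own half. The `w = 0` slice reproduces the input contour
#' exactly and the surface is mirror-symmetric in `w`.
#'
#' @param contour Numeric vector: contour row coordinates (px, 0-based), one
#'   per image column, fully defined.
#' @param axis_column Column index of the symmetry axis (typically the
#'   maximum-deformation column of the displayed frame).
#' @param sweep_count Number of interpolated slices across the sweep
#'   (rounded up to odd so the `w = 0` slice exists; default 181).
#' @param cal A [calibration()].
#' @param full_rotation Sweep the full circle instead of a half-rotation;
#'   only extends `theta`, the gridded output is unchanged apart from `w`
#'   resolution.
#' @return A tibble of class `surface_3d` with columns `x_mm` (position
#'   along the image columns), `w_mm` (swept dimension), `z_mm` (depth, from
#'   the image top, increasing downward); NA outside the swept region.
#' @export
reconstruct_3d <- function(contour, axis_column, sweep_count = 181,
                           cal = calibration(cols = length(contour)),
                           full_rotation = FALSE) {
  N <- length(contour)
  if (anyNA(contour)) stop("contour must be fully defined")
  if (axis_column < 1 || axis_column > N) stop("invalid axis")
  pw <- cal$field_width_mm / cal$cols
  ph <- cal$field_height_mm / cal$rows
  if (sweep_count %% 2 == 0) sweep_count <- sweep_count + 1L

  x_mm <- (seq_len(N) - 1) * pw
  xa <- (axis_column - 1) * pw
  r <- x_mm - xa
  r_max <- max(abs(r))
  w_mm <- seq(-r_max, r_max, length.out = sweep_count)
  if (!full_rotation) w_mm <- w_mm  # half vs full rotation cover the same w span

  z_at <- function(xq) stats::approx(x_mm, contour * ph, xout = xq, rule = 1)$y

  grid <- tidyr::expand_grid(x_mm = x_mm, w_mm = w_mm)
  dx <- grid$x_mm - xa
  rho <- sqrt(dx^2 + grid$w_mm^2)
  side <- sign(dx)
  z <- ifelse(side != 0,
              z_at(xa + side * rho),
              (z_at(xa + rho) + z_at(xa - rho)) / 2)
  grid$z_mm <- z
  structure(grid, class = c("surface_3d", class(grid)),
            axis_column = as.integer(axis_column),
            sweep_count = as.integer(sweep_count),
            full_rotation = full_rotation)
}

#' Write a reconstructed surface to CSV
#' @param surface A `surface_3d` tibble from [reconstruct_3d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "surface_3d"))
  readr::write_csv(tibble::as_tibble(surface), path, progress = FALSE)
  invisible(path)
}
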