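#' Pixel calibration of a Scheimpflug image field
#'
#' Describes the physical extent of the imaged cross-section. The Corvis-class
#' acquisition geometry is a 200 x 576 px frame covering 3.3 x 9.05 mm, which
#' is the default.
#'
#' @param rows Number of image rows (vertical, Y axis).
#' @param cols Number of image columns (horizontal, X axis).
#' @param field_height_mm Physical height spanned by the rows, in mm.
#' @param field_width_mm Physical width spanned by the columns, in mm.
#'
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration()
#' pixel_size(cal) # 16.5 um x 15.7 um
#' @export
calibration <- function(rows = 200, cols = 576,
                        field_height_mm = 3.3, field_width_mm = 9.05) {
  if (rows <= 0 || cols <= 0) stop("invalid calibration: rows and cols must be positive")
  if (field_height_mm <= 0 || field_width_mm <= 0) {
    stop("invalid calibration: field dimensions must be positive")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         field_height_mm = field_height_mm, field_width_mm = field_width_mm),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  ps <- pixel_size(x)
  cat(sprintf("<calibration> %d x %d px over %.3g x %.3g mm (%.4g x %.4g um/px)\n",
              x$rows, x$cols, x$field_height_mm, x$field_width_mm,
              ps[["height_um"]], ps[["width_um"]]))
  invisible(x)
}

#' Physical pixel size
#'
#' Exact quotient of the field extent by the pixel count, no rounding: 200
#' rows over 3.3 mm give 16.5 um per row step, 576 columns over 9.05 mm give
#' 15.712 um (reported rounded as 15.7) per column step.
#'
#' @param cal A [calibration()] object.
#' @return Named numeric vector `c(height_um, width_um)`, micrometres per
#'   pixel along the row (Y) and column (X) axes.
#' @export
pixel_size <- function(cal) {
  stopifnot(inherits(cal, "calibration"))
  c(height_um = 1000 * cal$field_height_mm / cal$rows,
    width_um  = 1000 * cal$field_width_mm / cal$cols)
}

#' Acquisition time of a frame
#'
#' Frames are 1-based and equally spaced: frame 1 is t = 0, frame i is
#' `(i - 1) * dt_ms`.
#'
#' @param i 1-based frame index (vectorised).
#' @param dt_ms Inter-frame interval in milliseconds.
#' @return Time in milliseconds.
#' @examples
#' frame_time(3, 0.23) # 0.46 ms
#' @export
frame_time <- function(i, dt_ms = 0.23) {
  if (any(i < 1)) stop("invalid index: frame indices are 1-based")
  if (dt_ms <= 0) stop("dt_ms must be positive")
  (i - 1) * dt_ms
}
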