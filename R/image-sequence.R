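#' Construct an image sequence
#'
#' Container for a stack of grayscale frames with temporal and spatial
#' calibration attached. Frames are stored as a 3-D numeric array
#' `[row, column, frame]` with intensities on the 0-255 scale; the frame
#' index is 1-based, row coordinates used elsewhere in the package are
#' 0-based from the top of the image and increase downward.
#'
#' @param frames 3-D numeric array `[row, column, frame]`, or a list of
#'   identically sized matrices.
#' @param dt_ms Inter-frame interval in ms.
#' @param cal A [calibration()] object; its `rows`/`cols` must match the
#'   frame shape.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, dt_ms = 0.23, cal = NULL) {
  if (is.list(frames)) {
    shp <- vapply(frames, dim, integer(2))
    if (ncol(shp) > 1 && any(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])) {
      stop("shape mismatch: frames differ in size")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shp[1, 1], shp[2, 1], length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[1] < 20 || dim(frames)[2] < 20) {
    stop("frames must be at least 20 x 20 pixels")
  }
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (is.null(cal)) {
    cal <- calibration(rows = dim(frames)[1], cols = dim(frames)[2])
  }
  if (cal$rows != dim(frames)[1] || cal$cols != dim(frames)[2]) {
    stop("shape mismatch: calibration does not match frame dimensions")
  }
  ps <- pixel_size(cal)
  structure(
    list(frames = frames, dt_ms = dt_ms, cal = cal,
         pixel_height_um = unname(ps["height_um"]),
         pixel_width_um = unname(ps["width_um"])),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d frames of %d x %d px, dt = %g ms (fs = %.1f Hz)\n",
              d[3], d[1], d[2], x$dt_ms, 1000 / x$dt_ms))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) dim(x$frames)[3]

#' Extract one frame as a matrix
#' @param seq An [image_sequence()].
#' @param i 1-based frame index.
#' @return Numeric matrix `[row, column]`, intensities 0-255.
#' @export
get_frame <- function(seq, i) {
  stopifnot(inherits(seq, "image_sequence"))
  if (i < 1 || i > dim(seq$frames)[3]) stop("invalid index")
  seq$frames[, , i]
}

# Read one image file into a [row, col] matrix on the 0-255 scale.
# EBImage stores images [x = column, y = row]; transpose to matrix convention.
read_frame_file <- function(path) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "luminance")
  }
  a <- EBImage::imageData(img)
  if (length(dim(a)) > 2L) a <- a[, , 1]
  # 8-bit files decode to k/255; restore integer gray levels exactly
  m <- t(a) * 255
  round(m, 6)
}

#' Load an image sequence from a directory of frames
#'
#' Reads every JPG/PNG/TIFF file in `path` in lexicographic order, converts
#' colour frames to luminance, and attaches calibration. Video files are not
#' decoded; extract frames to a directory first.
#'
#' @param path Directory containing one image file per frame.
#' @param dt_ms Inter-frame interval in ms (default 0.23).
#' @param cal A [calibration()]; defaults to the frame dimensions over a
#'   3.3 x 9.05 mm field scaled to the actual pixel counts.
#' @return An [image_sequence()].
#' @export
load_sequence <- function(path, dt_ms = 0.23, cal = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.(avi|mp4|mov)$", path, ignore.case = TRUE)) {
      stop("video decoding is not supported; extract frames to a directory of images first")
    }
    stop("no frames: '", path, "' is not a directory")
  }
  files <- sort(list.files(path, pattern = "\\.(jpe?g|png|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no frames found in '", path, "'")
  mats <- lapply(files, read_frame_file)
  shp <- vapply(mats, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])) {
    stop("shape mismatch: frames in '", path, "' differ in size")
  }
  image_sequence(mats, dt_ms = dt_ms, cal = cal)
}
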