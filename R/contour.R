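#' Contour series container
#'
#' The outer corneal contour for every frame: a matrix of row coordinates
#' (pixels, 0-based from the image top, fractional) with one row per image
#' column and one column per frame, plus a validity mask recording which
#' entries were detected directly (before gap interpolation).
#'
#' @param values Numeric matrix `[image column, frame]` of row coordinates.
#' @param valid Logical matrix of the same shape; `TRUE` where detection
#'   succeeded before interpolation.
#' @param dt_ms Inter-frame interval in ms.
#' @param cal A [calibration()].
#' @return An object of class `contour_series`.
#' @export
contour_series <- function(values, valid = NULL, dt_ms = 0.23, cal = NULL) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(all(dim(valid) == dim(values)))
  if (is.null(cal)) cal <- calibration(cols = nrow(values))
  structure(
    list(values = values, valid = valid, dt_ms = dt_ms, cal = cal),
    class = "contour_series"
  )
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour_series> %d columns x %d frames (%.1f%% detected directly)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid)))
  invisible(x)
}

#' Default contour-detection settings
#'
#' @param threshold_frac Fraction of each column's dynamic range used as the
#'   adaptive binarization threshold for the corneal band (default 0.3).
#' @param min_dynamic Minimum column dynamic range (gray levels) for a column
#'   to be considered at all; columns flatter than this are invalid.
#' @param method `"band"` for the adaptive column-wise detector; `"otsu"`
#'   for a global Otsu-threshold fallback usable on clean phantoms.
#' @param median_filter Apply a 3-column median filter to each frame's
#'   contour to suppress single-column outliers.
#' @param max_invalid_frac Largest tolerated fraction of undetected columns
#'   per frame before the frame is rejected as unreliable.
#' @return A list of settings for [detect_outer_contour()].
#' @export
contour_params <- function(threshold_frac = 0.3, min_dynamic = 20,
                           method = c("band", "otsu"), median_filter = TRUE,
                           max_invalid_frac = 0.2) {
  list(threshold_frac = threshold_frac, min_dynamic = min_dynamic,
       method = match.arg(method), median_filter = isTRUE(median_filter),
       max_invalid_frac = max_invalid_frac)
}

# Vertical 3-point median filter with edge replication: removes isolated
# bright pixels while leaving monotone intensity edges untouched.
median3_rows <- function(m) {
  up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
  up + m + dn - pmax(up, m, dn) - pmin(up, m, dn)
}

# 8-connected component labels. EBImage::bwlabel is 4-connected; merge
# label pairs that touch diagonally with a small union-find pass.
label8 <- function(mask) {
  lab <- t(EBImage::bwlabel(t(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  a1 <- lab[-nrow(lab), -ncol(lab)]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -ncol(lab)];         b2 <- lab[-nrow(lab), -1]
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  lab
}

# Pick the largest component; on a size tie keep the upper one (smaller
# mean row), so a second equally sized blob below the cornea never wins.
largest_component <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(0L)
  sizes <- vapply(ids, function(id) sum(lab == id), integer(1))
  best <- ids[sizes == max(sizes)]
  if (length(best) > 1) {
    mr <- vapply(best, function(id) mean(row(lab)[lab == id]), numeric(1))
    best <- best[which.min(mr)]
  }
  best[1]
}

#' Detect the outer corneal contour in one frame
#'
#' Column-wise detector for the upper edge of the bright corneal band: each
#' column's intensity profile is despeckled with a 3-pixel median filter,
#' binarized at an adaptive threshold (a fraction of that column's dynamic
#' range, so smooth uneven illumination cancels), and only candidates on the
#' largest 8-connected bright component are kept, which suppresses isolated
#' bright noise pixels and secondary blobs. The edge is then refined to
#' sub-pixel precision by linearly interpolating the crossing of the midpoint
#' between the column's background and band plateau levels, the unbiased edge
#' location for a symmetric blur kernel.
#'
#' @param frame Numeric matrix `[row, column]`, intensities 0-255.
#' @param params Settings from [contour_params()].
#' @return List with `contour` (numeric, 0-based row per column, `NA` where
#'   invalid) and `valid` (logical).
#' @export
detect_outer_contour <- function(frame, params = contour_params()) {
  M <- nrow(frame); N <- ncol(frame)
  sm <- median3_rows(frame)
  col_min <- apply(sm, 2, min)
  col_max <- apply(sm, 2, max)
  dyn <- col_max - col_min
  usable <- dyn >= params$min_dynamic
  if (!any(usable)) stop("no cornea found: no column has a bright band")

  if (params$method == "otsu") {
    thr <- rep(255 * EBImage::otsu(EBImage::Image(t(frame) / 255)), N)
  } else {
    thr <- col_min + params$threshold_frac * dyn
  }
  mask <- sweep(sm, 2, thr, ">=")
  mask[, !usable] <- FALSE
  lab <- label8(mask)
  keep <- largest_component(lab)
  if (keep == 0L) stop("no cornea found: no connected bright object")
  comp <- lab == keep

  contour <- rep(NA_real_, N)
  for (j in which(usable)) {
    rows_in <- which(comp[, j])
    if (length(rows_in) == 0) next
    m0 <- rows_in[1]
    level <- (col_min[j] + col_max[j]) / 2
    # walk down from the component's top row to the first sample >= level
    m_hi <- m0
    while (m_hi < M && sm[m_hi, j] < level) m_hi <- m_hi + 1L
    if (sm[m_hi, j] < level) next
    if (m_hi == 1L) { contour[j] <- 0; next }
    lo <- sm[m_hi - 1L, j]; hi <- sm[m_hi, j]
    frac <- if (hi > lo) (level - lo) / (hi - lo) else 0
    contour[j] <- (m_hi - 2L) + frac   # 0-based row coordinate
  }
  valid <- !is.na(contour)
  if (!any(valid)) stop("no cornea found: no column yielded an edge")
  if (mean(!valid) > params$max_invalid_frac) {
    stop(sprintf("contour unreliable: %.1f%% of columns invalid", 100 * mean(!valid)))
  }
  list(contour = contour, valid = valid)
}

#' Detect the outer contour across a whole sequence
#'
#' Applies [detect_outer_contour()] to every frame, fills undetected columns
#' by linear interpolation across columns, and (optionally) median-filters
#' each frame's contour over 3 columns.
#'
#' @param seq An [image_sequence()].
#' @param params Settings from [contour_params()].
#' @return A [contour_series()].
#' @export
detect_contour_sequence <- function(seq, params = contour_params()) {
  stopifnot(inherits(seq, "image_sequence"))
  nf <- length(seq)
  N <- dim(seq$frames)[2]
  values <- matrix(NA_real_, N, nf)
  valid <- matrix(FALSE, N, nf)
  for (i in seq_len(nf)) {
    det <- tryCatch(detect_outer_contour(seq$frames[, , i], params),
                    error = function(e) stop("frame ", i, ": ", conditionMessage(e), call. = FALSE))
    v <- det$contour
    if (anyNA(v)) v <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
    if (params$median_filter) v <- stats::runmed(v, 3, endrule = "keep")
    values[, i] <- v
    valid[, i] <- det$valid
  }
  contour_series(values, valid, dt_ms = seq$dt_ms, cal = seq$cal)
}

#' Write a contour series to CSV
#'
#' One row per frame: the 1-based frame index, then one column per image
#' column holding the contour row coordinate in pixels.
#'
#' @param contours A [contour_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contours, path) {
  stopifnot(inherits(contours, "contour_series"))
  df <- tibble::as_tibble(t(contours$values), .name_repair = ~ sprintf("c%04d", seq_along(.x)))
  df <- dplyr::mutate(df, frame = dplyr::row_number(), .before = 1)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a contour series from CSV
#'
#' @param path CSV written by [write_contour_csv()] (or any file with a
#'   `frame` column followed by one column per image column).
#' @param dt_ms Inter-frame interval in ms.
#' @param cal A [calibration()]; defaults to the column count over the
#'   standard field.
#' @return A [contour_series()].
#' @export
read_contour_csv <- function(path, dt_ms = 0.23, cal = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- df[order(df$frame), , drop = FALSE]
  vals <- t(as.matrix(df[, setdiff(names(df), "frame"), drop = FALSE]))
  rownames(vals) <- NULL
  if (is.null(cal)) {
    cal <- calibration(cols = nrow(vals),
                       field_width_mm = 9.05 * nrow(vals) / 576,
                       field_height_mm = 3.3)
  }
  contour_series(vals, dt_ms = dt_ms, cal = cal)
}
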