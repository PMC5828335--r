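#' Analyse a deformation sequence end to end
#'
#' The full measurement chain: outer-contour detection (skipped when the
#' input is already a contour series), decomposition into eyeball reaction,
#' deformation and frequency bands, applanation detection, the four
#' vibration traces with error bounds and angles, and spectral summaries.
#'
#' @param x An [image_sequence()] or [contour_series()].
#' @param params Contour-detection settings ([contour_params()]); ignored
#'   for contour input.
#' @param edge_cols Margin columns per side for the eyeball-reaction
#'   estimate (default 10).
#' @param cutoff_hz Band split frequency in Hz (default 100).
#' @param window_mm Applanation flatness window (default 3 mm).
#' @param p_r Binarization threshold in px (default 2).
#' @param ap_override Optional `c(ap1_ms, ap2_ms)` device-supplied
#'   applanation times bypassing detection.
#' @param angle_units `"px"` or `"physical"`, see [vibration_angle()].
#' @return An object of class `corvib_analysis`: list with `contours`,
#'   `decomp`, `appl`, `traces` (tibble), `spectra` (tibble) and the
#'   parameters used. Use [tidy()] for the per-frame traces, [glance()] for
#'   a one-row summary, [autoplot()] for diagnostics.
#' @export
analyze_sequence <- function(x, params = contour_params(), edge_cols = 10,
                             cutoff_hz = 100, window_mm = 3, p_r = 2,
                             ap_override = NULL,
                             angle_units = c("px", "physical")) {
  angle_units <- match.arg(angle_units)
  contours <- if (inherits(x, "image_sequence")) {
    detect_contour_sequence(x, params)
  } else if (inherits(x, "contour_series")) {
    x
  } else {
    stop("x must be an image_sequence or contour_series")
  }
  decomp <- decompose_contours(contours, edge_cols = edge_cols, cutoff_hz = cutoff_hz)
  appl <- if (is.null(ap_override)) {
    detect_applanations(decomp, window_mm = window_mm, p_r = p_r)
  } else {
    applanation_pair(ap_override[1], ap_override[2], dt_ms = contours$dt_ms,
                     n_frames = ncol(contours$values))
  }
  traces <- compute_vibration_traces(decomp, appl, p_r = p_r, angle_units = angle_units)
  spectra <- summarize_spectra(traces)
  structure(
    list(contours = contours, decomp = decomp, appl = appl,
         traces = traces, spectra = spectra,
         params = list(edge_cols = edge_cols, cutoff_hz = cutoff_hz,
                       window_mm = window_mm, p_r = p_r,
                       angle_units = angle_units)),
    class = "corvib_analysis"
  )
}

#' @export
print.corvib_analysis <- function(x, ...) {
  cat("<corvib_analysis>\n")
  print(x$appl)
  print(tibble::as_tibble(x$spectra))
  invisible(x)
}

#' @rdname analyze_sequence
#' @param x A `corvib_analysis`.
#' @param ... Unused.
#' @export
tidy.corvib_analysis <- function(x, ...) {
  tibble::as_tibble(x$traces)
}

#' @rdname analyze_sequence
#' @export
glance.corvib_analysis <- function(x, ...) {
  sp <- tibble::as_tibble(x$spectra)
  wide <- tidyr::pivot_wider(
    sp[, c("vibration", "fundamental_hz", "amplitude")],
    names_from = "vibration",
    values_from = c("fundamental_hz", "amplitude")
  )
  r <- tryCatch(peak_quarter_correlation(x$traces$peak_vib_px, x$traces$quarter_vib_px),
                error = function(e) NA_real_)
  dplyr::bind_cols(
    tibble::tibble(n_frames = nrow(x$traces),
                   ap1_ms = x$appl$ap1_ms, ap2_ms = x$appl$ap2_ms,
                   peak_quarter_r = r,
                   mean_delta_px = mean(x$traces$delta_px, na.rm = TRUE)),
    wide
  )
}

#' Write vibration traces to CSV (plus an optional spectral sidecar)
#'
#' One row per frame with the exact column set `i, t_ms, m_kl, n_kl, m_kr,
#' n_kr, n_d, n_fl, n_fr, m_fl, m_fr, n_bl, n_br, peak_vib_px, peak_vib_um,
#' quarter_vib_px, quarter_vib_um, maxdef_vib_mm, cutoff_vib_mm, delta_px,
#' lambda_rad, beta_rad`; frames outside the applanation interval are
#' written as empty fields. When `spectra` is supplied a JSON sidecar
#' (same path, `.json` extension) holds the spectral summary.
#'
#' @param traces A `vibration_traces` tibble.
#' @param path Output CSV path.
#' @param spectra Optional `spectral_summary` for the sidecar.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, spectra = NULL) {
  stopifnot(inherits(traces, "vibration_traces"))
  if (all(is.na(traces$delta_px))) stop("traces populated for no frame")
  readr::write_csv(tibble::as_tibble(traces), path, na = "", progress = FALSE)
  if (!is.null(spectra)) {
    write_spectral_json(spectra, sub("\\.[^.]+$", ".json", path))
  }
  invisible(path)
}

#' Read vibration traces written by [write_traces()]
#' @param path CSV path.
#' @return A tibble (without the analysis attributes).
#' @export
read_traces <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' Write a spectral summary as JSON
#'
#' Format: `{vibration: {fundamental_hz, resolution_hz, amplitude, units,
#' n_samples}}` plus an `analysis_interval_ms` entry.
#'
#' @param spectra A `spectral_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_json <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectral_summary"))
  per_type <- purrr::map(split(tibble::as_tibble(spectra), spectra$vibration),
                         function(d) as.list(d[, c("axis", "fundamental_hz", "resolution_hz",
                                                   "amplitude", "units", "n_samples")]))
  per_type$analysis_interval_ms <- c(attr(spectra, "ap1_ms"), attr(spectra, "ap2_ms"))
  jsonlite::write_json(per_type, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a spectral summary written by [write_spectral_json()]
#' @param path JSON path.
#' @return A `spectral_summary`-shaped tibble.
#' @export
read_spectral_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$analysis_interval_ms <- NULL
  out <- dplyr::bind_rows(purrr::imap(j, ~ tibble::tibble(
    vibration = .y,
    axis = .x$axis %||% NA_character_,
    fundamental_hz = as.numeric(.x$fundamental_hz %||% NA),
    resolution_hz = as.numeric(.x$resolution_hz %||% NA),
    amplitude = as.numeric(.x$amplitude %||% NA),
    units = .x$units, n_samples = as.integer(.x$n_samples %||% NA))))
  structure(out, class = c("spectral_summary", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
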