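#' Phantom specification
#'
#' Parameters of a ground-truthed synthetic air-puff deformation sequence
#' emulating the Corvis-class acquisition geometry (200 x 576 px over
#' 3.3 x 9.05 mm, 140 frames every 0.23 ms). The synthetic cornea is a
#' circular arc; the air-puff indentation has a Ricker ("Mexican hat")
#' spatial profile — central indentation plus the raised rims the peak
#' vibrations are defined on — and a raised-cosine depth pulse timed so the
#' flatness crossings fall near 10 and 21 ms; the apex drifts 0.3 mm during
#' the pulse; the eyeball recedes along a slow ramp. Antiphase vibration
#' pairs are injected at the peak (350 Hz, 3 px) and quarter (400 Hz, 2 px)
#' locations by default.
#'
#' @param rows,cols,n_frames,dt_ms Acquisition geometry and timing.
#' @param field_height_mm,field_width_mm Physical field size.
#' @param apex_row_px Baseline apex row (0-based px from the image top).
#' @param radius_mm Corneal radius of curvature.
#' @param center_start_mm Indentation center at pulse onset (mm from the
#'   left edge).
#' @param drift_mm Lateral drift of the indentation center over the pulse.
#' @param sigma_mm Spatial width of the Ricker indentation profile.
#' @param depth_mm Peak indentation depth.
#' @param t_on_ms,duration_ms Onset and duration of the raised-cosine depth
#'   pulse.
#' @param eye_amplitude_px,eye_t_on_ms Eyeball-reaction ramp amplitude and
#'   onset.
#' @param vibrations List of vibration components, each a list with
#'   `location` (`"peak_left"`, `"peak_right"`, `"quarter_left"`,
#'   `"quarter_right"`, `"whole_contour"`), `frequency_hz`, `amplitude_px`,
#'   `phase_rad`, and optional `sigma_mm` (spatial footprint, default 0.4).
#' @param band_thickness_px,intensity,background Corneal band rendering.
#' @param gain_range Smooth illumination gain field range `c(low, high)`.
#' @param blur_sigma_px Gaussian blur of the rendered frame.
#' @param noise_sd Additive Gaussian noise SD (gray levels).
#' @param isolated_noise_count Number of isolated bright speckle pixels per
#'   frame, placed above the cornea.
#' @param seed Seed controlling all rendering randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 200, cols = 576, n_frames = 140, dt_ms = 0.23,
                         field_height_mm = 3.3, field_width_mm = 9.05,
                         apex_row_px = 40, radius_mm = 7.8,
                         center_start_mm = field_width_mm / 2, drift_mm = 0.3,
                         sigma_mm = 1.0, depth_mm = 1.0,
                         t_on_ms = 9.16, duration_ms = 12.68,
                         eye_amplitude_px = 15, eye_t_on_ms = 8,
                         vibrations = list(
                           list(location = "peak_left", frequency_hz = 350,
                                amplitude_px = 3, phase_rad = 0),
                           list(location = "peak_right", frequency_hz = 350,
                                amplitude_px = 3, phase_rad = pi),
                           list(location = "quarter_left", frequency_hz = 400,
                                amplitude_px = 2, phase_rad = 0),
                           list(location = "quarter_right", frequency_hz = 400,
                                amplitude_px = 2, phase_rad = pi)
                         ),
                         band_thickness_px = 25, intensity = 230, background = 15,
                         gain_range = c(0.7, 1.0), blur_sigma_px = 1,
                         noise_sd = 3, isolated_noise_count = 30, seed = 17) {
  spec <- mget(names(formals()))
  fs <- 1000 / dt_ms
  locs <- c("peak_left", "peak_right", "quarter_left", "quarter_right", "whole_contour")
  for (v in vibrations) {
    if (!v$location %in% locs) stop("inconsistent spec: unknown vibration location '", v$location, "'")
    if (v$frequency_hz >= fs / 2) stop("inconsistent spec: vibration frequency above Nyquist")
    if (v$amplitude_px >= band_thickness_px) stop("inconsistent spec: vibration amplitude exceeds band thickness")
    if (v$location != "whole_contour" && depth_mm <= 0) {
      stop("inconsistent spec: localized vibration requires an indentation")
    }
  }
  structure(spec, class = "phantom_spec")
}

#' Read a phantom spec from YAML or JSON
#'
#' Top-level keys override the [phantom_spec()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  do.call(phantom_spec, cfg)
}

# Raised-cosine (Hann) pulse fraction in [0, 1]. A single-lobed raised
# cosine has one spectral line, at 1/duration (~64 Hz for the default
# pulse), safely below the 100 Hz band split: the pulse itself contributes
# essentially nothing to the vibration band.
pulse_fraction <- function(t_ms, t_on, duration) {
  inside <- t_ms >= t_on & t_ms <= t_on + duration
  out <- numeric(length(t_ms))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t_ms[inside] - t_on) / duration))
  out
}

# Ricker (Mexican hat) profile: +1 at the center (indentation, toward larger
# rows) with raised rims (negative side lobes) at |u| = sqrt(3).
ricker <- function(u) (1 - u^2) * exp(-u^2 / 2)

#' Synthesize the ground-truth contour of a phantom
#'
#' Builds the analytic contour `baseline + eyeball reaction + indentation +
#' vibrations` and every truth the recovery tests need: the applanation
#' frames (where the central curvature of the synthetic contour crosses
#' zero), the per-frame deepest-deformation column, the injected vibration
#' traces, and the deformation support interval at threshold 2 px.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `contour`
#'   (`[column, frame]` matrix, 0-based rows px), `L_q` (px per frame),
#'   `ap1`, `ap2` (frames), `center_col` (injected indentation center per
#'   frame), `n_d` (per-frame argmax of the analytic deformation, NA outside
#'   the pulse), `L_d` (analytic deformation), `vib_traces` (tibble, one
#'   column per injected vibration), `support` (columns), `depth_px`, `cal`,
#'   and the spec.
#' @export
synthesize_contour <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cal <- calibration(spec$rows, spec$cols, spec$field_height_mm, spec$field_width_mm)
  ph_mm <- spec$field_height_mm / spec$rows   # mm per row
  pw_mm <- spec$field_width_mm / spec$cols    # mm per column
  N <- spec$cols; nf <- spec$n_frames
  t <- frame_time(seq_len(nf), spec$dt_ms)
  x <- (seq_len(N) - 1) * pw_mm

  # baseline circular arc, apex at the field center
  xa <- spec$field_width_mm / 2
  sag <- spec$radius_mm - sqrt(pmax(spec$radius_mm^2 - (x - xa)^2, 0))
  baseline <- spec$apex_row_px + sag / ph_mm

  # depth pulse and drifting center
  frac <- pulse_fraction(t, spec$t_on_ms, spec$duration_ms)
  depth_px <- spec$depth_mm * frac / ph_mm
  in_pulse <- t >= spec$t_on_ms & t <= spec$t_on_ms + spec$duration_ms
  # smooth, slow (raised-cosine) drift spread over the whole post-onset
  # recording: a fast or kinked center trajectory would intermodulate with
  # the depth pulse into spurious high-band motion antisymmetric about the
  # indentation center, contaminating the vibration truth
  s_drift <- pmin(pmax((t - spec$t_on_ms) / max(t[nf] - spec$t_on_ms, 1e-9), 0), 1)
  center_mm <- spec$center_start_mm + spec$drift_mm * 0.5 * (1 - cos(pi * s_drift))

  # eyeball reaction: slow raised-cosine ramp
  t_end <- t[nf]
  s <- pmin(pmax((t - spec$eye_t_on_ms) / max(t_end - spec$eye_t_on_ms, 1e-9), 0), 1)
  L_q <- spec$eye_amplitude_px * 0.5 * (1 - cos(pi * s))

  contour <- matrix(baseline, N, nf) + matrix(L_q, N, nf, byrow = TRUE)
  deform <- matrix(0, N, nf)
  for (i in seq_len(nf)) {
    if (depth_px[i] > 0) {
      u <- (x - center_mm[i]) / spec$sigma_mm
      deform[, i] <- depth_px[i] * ricker(u)
    }
  }

  # vibration component centers, relative to the drifting indentation
  loc_mm <- function(location, i) {
    off <- sqrt(3) * spec$sigma_mm
    switch(location,
           peak_left = center_mm[i] - off,
           peak_right = center_mm[i] + off,
           quarter_left = center_mm[i] - off / 2,
           quarter_right = center_mm[i] + off / 2,
           whole_contour = NA_real_)
  }
  vib_traces <- tibble::tibble(i = seq_len(nf), t_ms = t)
  for (k in seq_along(spec$vibrations)) {
    v <- spec$vibrations[[k]]
    sig_v <- if (is.null(v$sigma_mm)) 0.4 else v$sigma_mm
    # vibrations are deformation-driven: their amplitude grows and decays
    # smoothly with the pulse (abrupt gating would leak a switching
    # transient into both frequency bands)
    s_t <- v$amplitude_px * sin(2 * pi * v$frequency_hz * t / 1000 + v$phase_rad) * frac
    for (i in which(in_pulse)) {
      w <- if (v$location == "whole_contour") rep(1, N) else
        exp(-(x - loc_mm(v$location, i))^2 / (2 * sig_v^2))
      deform[, i] <- deform[, i] + s_t[i] * w
    }
    vib_traces[[paste0("vib", k, "_", v$location)]] <- s_t
  }
  contour <- contour + deform

  # applanation truth: the analytically flattest frames of the noise-free
  # slow contour (baseline + indentation, no vibrations) on each side of
  # the pulse peak, with flatness measured exactly as the detector measures
  # it -- RMS residual of a line fit over the central 3 mm window
  win <- abs(x - xa) <= 1.5
  xw <- x[win] - xa
  Xl <- cbind(1, xw)
  qr_X <- qr(Xl)
  flat_rms <- vapply(seq_len(nf), function(i) {
    prof <- baseline[win] + if (depth_px[i] > 0) {
      depth_px[i] * ricker((x[win] - center_mm[i]) / spec$sigma_mm)
    } else 0
    sqrt(mean(qr.resid(qr_X, prof)^2))
  }, numeric(1))
  i_peak <- which.max(depth_px)
  ap1 <- ap2 <- NA_integer_
  if (any(depth_px > 0) && i_peak > 2 && i_peak < nf - 1) {
    ap1 <- which.min(flat_rms[2:(i_peak - 1)]) + 1L
    ap2 <- which.min(flat_rms[(i_peak + 1):(nf - 1)]) + i_peak
  }

  n_d <- rep(NA_integer_, nf)
  n_d[in_pulse & depth_px > 0] <- apply(deform[, in_pulse & depth_px > 0, drop = FALSE], 2, which.max)
  exceed <- abs(deform) > 2
  support <- if (any(exceed)) range(which(rowSums(exceed) > 0)) else c(NA_integer_, NA_integer_)

  structure(
    list(contour = contour, L_q = L_q, ap1 = ap1, ap2 = ap2,
         center_col = 1 + center_mm / pw_mm, n_d = n_d, L_d = deform,
         vib_traces = vib_traces, support = as.integer(support),
         depth_px = depth_px, cal = cal, spec = spec),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d columns x %d frames; applanations at frames %s, %s; support [%s, %s]\n",
              nrow(x$contour), ncol(x$contour), x$ap1, x$ap2, x$support[1], x$support[2]))
  invisible(x)
}

# Deterministic smooth illumination gain field in [lo, hi].
gain_field <- function(M, N, lo, hi) {
  gm <- 0.5 + 0.5 * cos(pi * (seq_len(M) - 1) / M - 0.4)
  gn <- 0.5 + 0.5 * cos(2 * pi * (seq_len(N) - 1) / N - 1.1)
  lo + (hi - lo) * (0.3 + 0.7 * outer(gm, gn))
}

#' Render a phantom sequence to images
#'
#' Draws, for each frame, a bright corneal band of the specified thickness
#' below the truth contour (with exact area-coverage anti-aliasing of the
#' top edge), applies the smooth illumination gain field, Gaussian blur,
#' additive Gaussian noise and isolated bright-pixel speckle, and quantizes
#' to 8 bits. Fully deterministic under the spec's seed.
#'
#' @param truth A `phantom_truth` from [synthesize_contour()].
#' @param spec The matching [phantom_spec()] (defaults to the one stored in
#'   `truth`).
#' @return An [image_sequence()].
#' @export
render_sequence <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "phantom_truth"))
  M <- spec$rows; N <- spec$cols; nf <- spec$n_frames
  gain <- gain_field(M, N, spec$gain_range[1], spec$gain_range[2])
  y <- seq_len(M) - 1
  frames <- array(0, dim = c(M, N, nf))
  withr::local_seed(spec$seed)
  for (i in seq_len(nf)) {
    r <- truth$contour[, i]
    d <- outer(y, r, "-")
    cov <- pmin(pmax(pmin(d + 0.5, spec$band_thickness_px) - pmax(d - 0.5, 0), 0), 1)
    img <- spec$background + (spec$intensity - spec$background) * cov
    img <- img * gain
    if (spec$blur_sigma_px > 0) {
      img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img) / 255),
                                                 sigma = spec$blur_sigma_px))) * 255
    }
    if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(M * N, 0, spec$noise_sd), M, N)
    if (spec$isolated_noise_count > 0) {
      cols_sp <- sample.int(N, spec$isolated_noise_count, replace = TRUE)
      for (j in seq_along(cols_sp)) {
        top <- floor(r[cols_sp[j]]) - 8
        if (top >= 2) img[sample.int(top, 1), cols_sp[j]] <- 255
      }
    }
    frames[, , i] <- pmin(pmax(round(img), 0), 255)
  }
  cal <- calibration(M, N, spec$field_height_mm, spec$field_width_mm)
  image_sequence(frames, dt_ms = spec$dt_ms, cal = cal)
}

#' Write a phantom to disk
#'
#' Writes one lossless 8-bit PNG per frame (`frame0001.png`, ...), the truth
#' contour as CSV, and a JSON truth summary.
#'
#' @param seq Rendered [image_sequence()].
#' @param truth Matching `phantom_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(seq, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- length(seq)
  for (i in seq_len(nf)) {
    png::writePNG(get_frame(seq, i) / 255,
                  file.path(dir, sprintf("frame%04d.png", i)))
  }
  cs <- contour_series(truth$contour, dt_ms = seq$dt_ms, cal = seq$cal)
  write_contour_csv(cs, file.path(dir, "contour_truth.csv"))
  meta <- list(
    ap1 = truth$ap1, ap2 = truth$ap2, support = truth$support,
    L_q = truth$L_q, n_d = truth$n_d,
    vibrations = truth$spec$vibrations,
    dt_ms = truth$spec$dt_ms,
    field_mm = c(truth$spec$field_height_mm, truth$spec$field_width_mm)
  )
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Injected-versus-recovered recovery report for a phantom
#'
#' Runs the full pipeline (render, contour detection, decomposition,
#' applanation detection, vibration traces, spectra) on a phantom and
#' compares recovered quantities to the injected truth: frequency and
#' peak-to-peak amplitude per vibration pair, cutoff columns against the
#' truth junctions, and the maximum-deformation column trace against the
#' truth deepest-point trajectory.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional seed overriding the spec's.
#' @return List with `report` (tibble: one row per injected vibration pair),
#'   `cutoff` (tibble of truth vs recovered junction columns per frame),
#'   `n_d_max_abs_err` (columns), plus the intermediate objects (`truth`,
#'   `seq`, `contours`, `decomp`, `appl`, `traces`, `spectra`).
#' @export
end_to_end_recovery <- function(spec = phantom_spec(), seed = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  truth <- synthesize_contour(spec)
  seq <- render_sequence(truth, spec)
  contours <- detect_contour_sequence(seq)
  decomp <- decompose_contours(contours)
  appl <- detect_applanations(decomp)
  traces <- compute_vibration_traces(decomp, appl)
  spectra <- summarize_spectra(traces)
  ps <- pixel_size(seq$cal)
  pw_mm <- seq$cal$field_width_mm / seq$cal$cols

  # group injected vibrations into peak / quarter pairs
  vibs <- purrr::map_dfr(spec$vibrations, ~ tibble::tibble(
    type = sub("_(left|right)$", "", .x$location),
    frequency_hz = .x$frequency_hz, amplitude_px = .x$amplitude_px))
  inj <- vibs |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(injected_hz = mean(.data$frequency_hz),
                     injected_p2p_px = sum(.data$amplitude_px), .groups = "drop")
  rec <- tibble::as_tibble(spectra) |>
    dplyr::transmute(type = .data$vibration,
                     recovered_hz = .data$fundamental_hz,
                     recovered_p2p_px = dplyr::case_when(
                       .data$units == "um" ~ .data$amplitude / ps[["height_um"]],
                       .data$units == "mm" ~ .data$amplitude / pw_mm
                     ))
  report <- dplyr::inner_join(inj, rec, by = "type")

  # cutoff truth from the analytic deformation, same junction rule
  idx <- seq(appl$ap1 + 1L, appl$ap2 - 1L)
  cutoff <- purrr::map_dfr(idx, function(i) {
    tc <- cutoff_points(truth$L_d[, i])
    tibble::tibble(i = i,
                   truth_n_bl = if (is.null(tc)) NA_integer_ else tc$n_bl,
                   truth_n_br = if (is.null(tc)) NA_integer_ else tc$n_br,
                   n_bl = traces$n_bl[i], n_br = traces$n_br[i])
  })
  nd_err <- abs(traces$n_d[idx] - truth$n_d[idx])
  list(report = report, cutoff = cutoff,
       n_d_max_abs_err = max(nd_err, na.rm = TRUE),
       truth = truth, seq = seq, contours = contours, decomp = decomp,
       appl = appl, traces = traces, spectra = spectra)
}
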