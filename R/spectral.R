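#' Fundamental frequency of a vibration trace
#'
#' The dominant spectral component above the band split: the trace is
#' gap-interpolated, mean-subtracted, Hann-windowed and zero-padded to at
#' least 4096 points, and the frequency of the maximum-magnitude bin inside
#' `band` is returned. Zero padding interpolates the spectrum but cannot
#' beat the Rayleigh limit of the short inter-applanation window, so the
#' pre-padding resolution `fs / n` is reported alongside.
#'
#' @param trace Numeric vector (NA marks flagged frames; more than 30%
#'   gaps is refused).
#' @param fs_hz Sampling rate in Hz.
#' @param band Frequency search band `c(low, high)` in Hz; default 100 Hz
#'   to Nyquist.
#' @param n_pad Minimum FFT length after zero padding (default 4096).
#' @return List `fundamental_hz`, `resolution_hz`, `n_samples`.
#' @export
fundamental_frequency <- function(trace, fs_hz, band = c(100, fs_hz / 2),
                                  n_pad = 4096) {
  if (mean(is.na(trace)) > 0.3) stop("too many gaps: more than 30% of frames flagged")
  x <- zoo::na.approx(trace, na.rm = FALSE, rule = 2)
  n <- length(x)
  if (n < 8) stop("insufficient frames: need at least 8 samples")
  if (diff(range(x)) == 0) stop("no harmonic: constant trace")
  x <- (x - mean(x)) * signal::hanning(n)
  nfft <- max(n_pad, 2^ceiling(log2(n)))
  spec <- abs(fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  freqs <- (seq_len(nfft %/% 2) - 1) * fs_hz / nfft
  in_band <- freqs > band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no harmonic: empty search band")
  k <- which(in_band)[which.max(spec[in_band])]
  list(fundamental_hz = freqs[k], resolution_hz = fs_hz / n, n_samples = n)
}

#' Peak-to-peak vibration amplitude over all harmonics
#'
#' The recorded vibrations consist of several harmonics of comparable size,
#' so the amplitude is defined on the full multi-harmonic signal as
#' `max(trace) - min(trace)` over the analysis interval, not from the first
#' harmonic alone.
#'
#' @param trace Numeric vector (NA ignored).
#' @return Peak-to-peak amplitude in the trace's units.
#' @export
amplitude_all_harmonics <- function(trace) {
  x <- trace[!is.na(trace)]
  if (length(x) < 2) stop("insufficient frames: need at least 2 samples")
  max(x) - min(x)
}

#' Spectral summary of the four vibration traces
#'
#' Frequency is estimated on the *signed* left-right difference traces
#' (`m_kl - m_kr`, `m_fl - m_fr`, `n_d`, `n_br - n_bl`): taking the absolute
#' value first would rectify an antiphase oscillation and double its
#' apparent frequency. Amplitudes are peak-to-peak of the reported traces in
#' their Table-style units (um for row-axis vibrations, mm for column-axis
#' ones).
#'
#' @param traces A `vibration_traces` tibble from
#'   [compute_vibration_traces()].
#' @param band Frequency search band in Hz; defaults to (cutoff, Nyquist).
#' @return A tibble of class `spectral_summary` with one row per vibration
#'   type: `vibration`, `axis`, `fundamental_hz`, `resolution_hz`,
#'   `amplitude`, `units`, `n_samples`.
#' @export
summarize_spectra <- function(traces, band = NULL) {
  stopifnot(inherits(traces, "vibration_traces"))
  fs_hz <- attr(traces, "fs_hz")
  cutoff <- attr(traces, "cutoff_hz")
  cal <- attr(traces, "cal")
  appl <- attr(traces, "appl")
  if (is.null(band)) band <- c(cutoff, fs_hz / 2)
  pw_mm <- cal$field_width_mm / cal$cols
  sub <- traces[traces$i > appl$ap1 & traces$i < appl$ap2, ]

  defs <- list(
    peak    = list(signed = sub$m_kl - sub$m_kr, amp = sub$peak_vib_um,
                   axis = "Y", units = "um"),
    quarter = list(signed = sub$m_fl - sub$m_fr, amp = sub$quarter_vib_um,
                   axis = "Y", units = "um"),
    maxdef  = list(signed = as.numeric(sub$n_d), amp = sub$maxdef_vib_mm,
                   axis = "X", units = "mm"),
    cutoff  = list(signed = as.numeric(sub$n_br - sub$n_bl), amp = sub$cutoff_vib_mm,
                   axis = "X", units = "mm")
  )
  rows <- purrr::imap(defs, function(d, nm) {
    ff <- tryCatch(fundamental_frequency(d$signed, fs_hz, band),
                   error = function(e) list(fundamental_hz = NA_real_,
                                            resolution_hz = fs_hz / sum(!is.na(d$signed)),
                                            n_samples = sum(!is.na(d$signed))))
    amp <- tryCatch(amplitude_all_harmonics(d$amp), error = function(e) NA_real_)
    tibble::tibble(vibration = nm, axis = d$axis,
                   fundamental_hz = ff$fundamental_hz,
                   resolution_hz = ff$resolution_hz,
                   amplitude = amp, units = d$units,
                   n_samples = ff$n_samples)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("spectral_summary", class(out)),
            ap1_ms = appl$ap1_ms, ap2_ms = appl$ap2_ms, fs_hz = fs_hz)
}

#' Aggregate spectral summaries across cases
#'
#' Mean and standard deviation, per vibration type, of the fundamental
#' frequency and amplitude over a set of analysed cases — the shape of a
#' multi-subject results table.
#'
#' @param summaries List of `spectral_summary` tibbles (one per case).
#' @return Tibble with columns `vibration`, `axis`, `units`, `n_cases`,
#'   `frequency_hz_mean`, `frequency_hz_sd`, `amplitude_mean`,
#'   `amplitude_sd`.
#' @export
summarize_cases <- function(summaries) {
  if (length(summaries) < 2) stop("need at least 2 cases")
  dplyr::bind_rows(summaries, .id = "case") |>
    dplyr::group_by(.data$vibration, .data$axis, .data$units) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      frequency_hz_mean = mean(.data$fundamental_hz, na.rm = TRUE),
      frequency_hz_sd = sd(.data$fundamental_hz, na.rm = TRUE),
      amplitude_mean = mean(.data$amplitude, na.rm = TRUE),
      amplitude_sd = sd(.data$amplitude, na.rm = TRUE),
      .groups = "drop"
    )
}
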