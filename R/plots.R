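#' Plot the four vibration traces
#'
#' Faceted time course of the peak, quarter, maximum-deformation and cutoff
#' vibrations between the applanations, with the per-frame error band shown
#' on the row-axis traces.
#'
#' @param object A `vibration_traces` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vibration_traces <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("t_ms", "peak_vib_um", "quarter_vib_um",
                  "maxdef_vib_mm", "cutoff_vib_mm") |>
    tidyr::pivot_longer(-"t_ms", names_to = "vibration", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  labs <- c(peak_vib_um = "peak (um)", quarter_vib_um = "quarter (um)",
            maxdef_vib_mm = "max deformation (mm)", cutoff_vib_mm = "cutoff (mm)")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~ vibration, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = "Corneal vibrations between applanations")
}

#' Plot the decomposition of the contour motion
#'
#' Eyeball reaction over time and the deformation of the central column in
#' both frequency bands.
#'
#' @param object A `decomposed_signals` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decomposed_signals <- function(object, ...) {
  nc <- nrow(object$L_d) %/% 2
  t_ms <- frame_time(seq_len(ncol(object$L_d)), object$dt_ms)
  nf <- length(t_ms)
  df <- tibble::tibble(
    t_ms = rep(t_ms, 4),
    component = rep(c("L_q (eye reaction)", "L_d (central column)",
                      "L_L (low band)", "L_H (high band)"), each = nf),
    px = c(object$L_q, object$L_d[nc, ], object$L_L[nc, ], object$L_H[nc, ])
  )
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$px)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~ component, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "displacement (px, image-row sense)")
}

#' Plot a reconstructed 3-D surface as a depth map
#'
#' @param object A `surface_3d` tibble from [reconstruct_3d()].
#' @param ... Unused.
#' @return A ggplot (filled raster of depth over the swept plane).
#' @export
autoplot.surface_3d <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(tibble::as_tibble(object), !is.na(.data$z_mm)),
                  ggplot2::aes(.data$x_mm, .data$w_mm, fill = .data$z_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "depth (mm)", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "image axis (mm)", y = "swept axis w (mm)",
                  title = "Rotational reconstruction of the deformed cornea")
}

#' @rdname analyze_sequence
#' @param object A `corvib_analysis`.
#' @export
autoplot.corvib_analysis <- function(object, ...) {
  autoplot(object$traces)
}
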