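# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

# Full default phantom run through the whole pipeline, with wall time.
default_recovery <- function() fixture("rec", {
  t0 <- Sys.time()
  rec <- end_to_end_recovery(phantom_spec())
  rec$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  rec
})

default_truth <- function() fixture("truth", synthesize_contour(phantom_spec()))

# Quiet phantom: no motion at all.
static_spec <- function(n_frames = 20) {
  phantom_spec(n_frames = n_frames, depth_mm = 0, eye_amplitude_px = 0,
               drift_mm = 0, vibrations = list())
}

# Rigid vertical translation only (eyeball reaction, no indentation).
translation_spec <- function(n_frames = 60, amp = 12) {
  phantom_spec(n_frames = n_frames, depth_mm = 0, drift_mm = 0,
               eye_amplitude_px = amp, eye_t_on_ms = 2, vibrations = list())
}

# Clean render settings: no noise, no blur, flat illumination.
clean_spec <- function(...) {
  phantom_spec(noise_sd = 0, blur_sigma_px = 0, isolated_noise_count = 0,
               gain_range = c(1, 1), ...)
}

# One mid-pulse frame of a clean phantom plus its truth contour.
clean_frame <- function() fixture("clean_frame", {
  spec <- clean_spec(n_frames = 12, t_on_ms = 0.3, duration_ms = 4,
                     eye_amplitude_px = 0, drift_mm = 0, vibrations = list())
  truth <- synthesize_contour(spec)
  seq <- render_sequence(truth, spec)
  i <- which.max(truth$depth_px)
  list(frame = get_frame(seq, i), contour = truth$contour[, i], spec = spec)
})
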