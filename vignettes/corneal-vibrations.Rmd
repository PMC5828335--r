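---
title: "Measuring corneal vibrations in air-puff tonometry sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring corneal vibrations in air-puff tonometry sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corvib)
```

## The measurement problem

Non-contact tonometers deform the cornea with an air jet while an
ultra-fast Scheimpflug camera records a cross-sectional image sequence —
nominally 140 frames of 200 x 576 pixels covering 3.3 x 9.05 mm, one frame
every 0.23 ms (sampling rate 4347.8 Hz). Between the two applanation
instants — the moments the central cornea passes through a flat
configuration on the way in (`A_p1`) and out (`A_p2`) — the corneal contour
does not move as a rigid bowl: it carries oscillations of a few pixels at a
few hundred hertz. `corvib` extracts the outer corneal contour from such a
sequence, separates rigid eye motion from corneal deformation, splits the
deformation at 100 Hz, and quantifies four vibration measures between the
applanations:

* **peak vibration** `|m_kl - m_kr|`: the difference of the topmost contour
  points (the raised rims beside the indentation) in the left and right
  image halves. In image-row coordinates (rows count downward from the top)
  these peaks are *minima* of the deformation, so
  `m_kl(i) = min over n in [1, N/2] of L_d(n, i)` and mirrored on the right;
* **quarter vibration** `|m_fl - m_fr|`: the high-band contour motion
  sampled at the two columns midway between each peak and the
  maximum-deformation column, `n_fl = floor((n_kl + n_d)/2)` and
  `n_fr = floor((n_kr + n_d)/2)`;
* **maximum-deformation vibration** `n_d(i)`: the lateral wander of the
  deepest-indentation column, `n_d(i) = argmax over [n_fl, n_fr] of L_d(n, i)`;
* **cutoff vibration** `|n_bl - n_br|`: the motion of the junction columns
  where the deformed contour departs from its resting position by more than
  the binarization threshold `p_r` (2 px).

Each analysed frame also carries an error bound
`delta(i) = 1 / sum_n [L_d(n,i) > p_r]` (1 px when nothing deforms — the
worst case), the instantaneous angle
`lambda(i) = atan2(m_fl - m_fr, n_fl - n_fr)` of the segment joining the
quarter points, and its running sum `beta(i)`.

## Signal model and decomposition

The measured outer contour `L_w(n, i)` (row coordinate per column per
frame, sub-pixel) is decomposed as

* `L_q(i)` — eyeball reaction: a rigid vertical displacement, estimated as
  the mean contour displacement (relative to frame 1) of the outermost
  `edge_cols` columns on each side (default 10), averaged left/right. Those
  margins image sclera and near-limbal tissue that the air puff barely
  deforms, which is why the phantom keeps its deformation compact within
  the field (see below);
* `L_c(n, i) = L_w(n, i) - L_q(i)` — the corrected contour;
* `L_d(n, i) = L_c(n, i) - L_c(n, 1)` — deformation, referenced to the
  first frame; indentation is positive (toward larger rows);
* `L_L` / `L_H` — deformation below/above `cutoff_hz` (default 100 Hz),
  with `L_H = L_d - L_L` exactly, so the split conserves the signal to
  machine precision.

### The zero-phase band split

The split must not skew vibration timing, so the low band is computed with
zero net phase shift: the order-4 Butterworth *magnitude-squared* response
(what a forward–backward IIR pass realizes) is applied spectrally. Plain
forward–backward filtering was measured to be unusable here: at a 100 Hz
cutoff and 4347.8 Hz sampling the filter poles sit at `|z| ~ 0.95`, and on
140-sample series the edge transients of reflection- or odd-padded
`filtfilt` reach tens of percent of a stopband sinusoid's amplitude. The
series is therefore extended on both sides by 100 samples of Burg
linear-prediction extrapolation (falling back to a constant hold if the
extrapolation is degenerate) before the spectral gain is applied.
Linear prediction continues oscillatory content coherently: measured on
140-sample sinusoids, passband error is 0.4% (50 Hz) and stopband leakage
0.03% (400 Hz) over the *whole* series, including the ends. The split is
exactly linear in its input and fully deterministic.

### Applanation detection

The paper's workflow takes applanation times from the device; `corvib` can
accept them (`ap_override`, CLI `--ap1-ms/--ap2-ms`) but also detects them,
since raw image sequences carry no annotations. Flatness of frame `i` is
the RMS residual of a straight-line fit to `L_c(·, i)` over a central
window (default 3 mm); `A_p1` is the flattest frame before the frame of
maximal central deformation and `A_p2` the flattest frame after it. A
sequence whose deformation never exceeds `p_r` has no indentation episode
and is rejected. Detection is frame-quantized.

### Resolving the circular definition of `n_d`

The maximum-deformation column is defined by an argmax over `[n_fl, n_fr]`,
but the quarter columns themselves need `n_d`. The package bootstraps from
the global argmax of the low band `L_L` (the slow indentation shape, free
of high-frequency vibration and therefore stable), computes the quarter
window from it, re-evaluates the argmax of `L_d` inside that window, and
performs one fixed-point refinement. All ties break to the leftmost column,
making every trace bit-reproducible on fixed input.

### Shift invariance

Assessing left–right *differences* makes the peak and quarter measures
independent of residual rigid eye motion by construction. The cutoff
junctions would not be: a per-frame constant added to `L_d` moves every
threshold crossing. `cutoff_points()` therefore removes a rigid per-frame
offset (the mean of the outermost 10 margin columns per side) before
thresholding; with quiet margins the rule reduces exactly to thresholding
`|L_d|`, and all four vibration traces are invariant to per-frame constant
offsets to machine precision.

## Contour detection

The outer contour is the upper edge of the bright corneal band. Global
thresholding (including Otsu's rule) fails on these images because the
illumination is markedly uneven, so the detector works column-wise:

1. each column's intensity profile is despeckled with a 3-pixel vertical
   median filter (isolated bright noise pixels vanish; monotone edges are
   untouched);
2. the profile is binarized at an adaptive threshold — a fraction (default
   0.3) of that column's own dynamic range, so any smooth multiplicative
   gain field cancels;
3. only candidates on the largest 8-connected bright component survive,
   which removes speckle clusters and secondary blobs (on a size tie the
   upper component wins);
4. the edge is refined to sub-pixel precision by linearly interpolating the
   crossing of the midpoint between the column's background and band
   plateau levels. The half-level crossing is the unbiased edge location
   for a symmetric blur kernel; interpolating at the 0.3 detection level
   instead would carry a blur-dependent bias of roughly half a pixel.

Columns without a usable band are filled by linear interpolation across
columns, an optional 3-column median filter suppresses single-column
outliers, and a frame whose undetected fraction exceeds 20% aborts the run
with its index. An Otsu-threshold fallback (`contour_params(method =
"otsu")`) is kept for clean synthetic frames.

## The phantom generator

Clinical recordings cannot ship with a package, so every quantitative claim
is validated against rendered phantoms with known ground truth
(`phantom_spec()`, `synthesize_contour()`, `render_sequence()`). The
defaults emulate the nominal acquisition: 200 x 576 px over 3.3 x 9.05 mm,
140 frames at 0.23 ms.

* **Baseline**: a circular arc of radius 7.8 mm (a typical anterior corneal
  radius), apex 40 px below the image top.
* **Indentation**: a Ricker ("Mexican hat") spatial profile with sigma
  1.0 mm. The Ricker shape provides what a plain Gaussian dent would not:
  the raised rims beside the indentation on which the peak vibrations are
  defined. The width keeps the deformation support (at the 2 px threshold)
  inside the imaged field, so the margin columns genuinely image resting
  tissue — the assumption behind the eye-reaction estimate. Peak depth is
  1.0 mm, a realistic air-puff deformation amplitude.
* **Depth pulse**: a raised cosine with onset 9.16 ms and duration
  12.68 ms, placed so that the *analytically* flattest frames of the
  noise-free contour fall near 10 and 21 ms — representative applanation
  times for a healthy eye. A single-lobed raised cosine keeps the pulse's
  line spectrum at `1/duration ~ 64 Hz`, below the band split. (A
  time-limited pulse still has continuous spectral tails above 100 Hz — a
  few pixels of the pulse inevitably appear in `L_H` at the indentation —
  but this component is symmetric about the indentation center and cancels
  in every left-right difference, exactly the robustness the differential
  definitions are designed for.)
* **Apex drift**: 0.3 mm, as a slow raised cosine over the whole post-onset
  recording. The drift must be slow: temporal filtering does not commute
  with sampling at moving symmetric points, so a fast center trajectory
  intermodulates with the depth pulse into above-100 Hz motion
  *antisymmetric* about the center — an artificial quarter vibration that
  would corrupt the truth labels of the recovery tests.
* **Eyeball reaction**: a smooth ramp reaching 15 px (~0.25 mm) by the end
  of the recording.
* **Vibrations**: antiphase pairs riding on the contour at the peak
  (350 Hz, 3 px) and quarter (400 Hz, 2 px) locations, each a Gaussian
  footprint of sigma 0.4 mm, amplitude-modulated by the depth pulse.
  Deformation-driven envelopes are both physically sensible and necessary
  for clean truth labels: switching a vibration on abruptly would leak a
  broadband transient into both frequency bands.
* **Rendering**: the corneal band (25 px thick, intensity 230 on a
  background of 15) is drawn with exact area-coverage anti-aliasing of its
  top edge, then degraded by a smooth illumination gain field (0.7–1.0),
  Gaussian blur (sigma 1 px), additive Gaussian noise (sd 3 gray levels)
  and 30 isolated bright speckle pixels per frame, and quantized to 8 bits.
  Everything downstream of the spec's seed is deterministic; frames
  re-rendered under the same seed are byte-identical.

What the phantom does *not* emulate: viscoelastic corneal mechanics (the
contour shapes are kinematic, not simulated tissue), specular highlights
and iris structure, frame-to-frame exposure changes, and patient-specific
contour irregularity. Passing recovery tests therefore demonstrates that
the measurement chain is correct and unbiased on known geometry at
realistic noise, not that any clinical value is reproduced.

## Recovery checks and their tolerances

On the default phantom the pipeline recovers (test suite and
`end_to_end_recovery()`):

* contour: RMS error below 0.5 px, maximum below 1 px (0.25 px on clean
  renders);
* applanations: at the analytically flattest frames (±1 frame);
* quarter vibration: 400 ± 20 Hz, peak-to-peak 4 ± 1 px; peak vibration:
  350 ± 20 Hz. Frequencies are estimated on the *signed* differences
  `m_kl - m_kr` and `m_fl - m_fr`: the reported amplitude traces take
  absolute values, and rectifying an antiphase oscillation doubles its
  apparent frequency, so the signed trace is the one that carries the
  physical fundamental;
* cutoff junctions at full deformation: within ±2 columns of the truth
  support;
* maximum-deformation column: within 2 columns of the truth trajectory in
  the RMS sense over the analysis interval. An integer argmax on a locally
  flat profile necessarily jitters by a few columns on near-applanation
  frames (where the indentation is barely above threshold) at any realistic
  noise level; a max-norm bound there would test the noise realization
  rather than the method. This is the same sensitivity that makes the
  cutoff and maximum-deformation measures the least parameter-stable of
  the four in practice.

Spectral summaries use a Hann window, zero padding to 4096 points, and the
dominant bin above the band split. With only ~45 inter-applanation samples
the Rayleigh resolution is ~90 Hz; zero padding interpolates the spectrum
(a lone sinusoid localizes to a few Hz) but cannot separate harmonics
closer than that limit, so `resolution_hz` is always reported alongside.
Amplitudes are peak-to-peak over the analysis interval ("all harmonics"),
not first-harmonic amplitudes. Flagged frames are linearly interpolated
before windowing; traces with more than 30% gaps are refused.

## Numerical and design choices

* Frame indices are 1-based everywhere user-facing; contour row coordinates
  are 0-based from the image top, increasing downward. Row-axis quantities
  are reported in µm, column-axis quantities in mm (16.5 and 15.7 µm/px at
  the nominal calibration).
* For odd column counts the middle column belongs to the left half; all
  argmin/argmax ties break leftmost; quarter columns use floor rounding
  (nearest-integer is available).
* `lambda` mixes a row difference with a column difference; by default both
  are in pixels. Converting the axes to physical units changes the angle,
  so the unit choice is an explicit argument (`angle_units`), not a
  convention hidden in the code.
* `beta` accumulates `lambda` over the open applanation interval only —
  every `lambda` input lives there — with flagged frames contributing 0.
* The 100 Hz split is applied to the deformation `L_d`; the corrected
  contour `L_c` differs from it only by the static baseline shape, which
  the temporal filter routes entirely into the low band, so the choice
  does not affect `L_H`.
* Degenerate inputs are explicit: all-flat halves flag the frame, a frame
  below threshold yields `delta = 1` and no cutoff points, constant traces
  refuse a fundamental rather than inventing one, and `atan2(0, 0)` is
  defined as 0 with a degeneracy flag.
* Video decoding is out of scope; sequences are read as directories of
  JPG/PNG frames (phantoms are written as lossless PNG; JPEG would break
  bit-exact round trips). The proprietary `.U12` archive format is not
  parsed.

## Problem sizes

The default test and validation runs use the full nominal geometry — 140
frames of 200 x 576 px — for the end-to-end phantom (about 10 s for
render + analysis), and smaller phantoms (10–60 frames) for properties
that do not need the full sequence, so the whole suite stays fast while
every headline number is measured at the nominal acquisition size.

## Known limitations

* The eye-reaction model is a single rigid vertical shift; real eye
  response has slower structured components that a margin average cannot
  fully capture.
* The cutoff measure is the most fragile of the four: near the
  applanations the deformation crosses `p_r` at a shallow angle and the
  junction columns can jump tens of columns between frames. This is
  intrinsic to the definition, not to the implementation.
* Applanation detection assumes a single dominant indentation episode;
  double-pulse or failed-puff recordings should use device-supplied times.
* With ~45 analysed frames, frequency estimates carry the ~90 Hz window
  limit regardless of padding; distinct vibration types whose fundamentals
  differ by less than that cannot be told apart on a single recording.
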