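# corvib

Corneal vibration analysis for air-puff tonometry image sequences.

During non-contact intraocular-pressure measurement, an air jet indents the
cornea while an ultra-fast Scheimpflug camera records a cross-sectional
image sequence (nominally 140 frames of 200 × 576 px over 3.3 × 9.05 mm,
one frame every 0.23 ms). Between the two applanation instants `A_p1` and
`A_p2` — when the central cornea is momentarily flat — the contour carries
oscillations of a few pixels at a few hundred hertz that standard tonometer
software never reports. `corvib` is for researchers in corneal biomechanics
who want those oscillations quantified, reproducibly, from raw frame
sequences or pre-extracted contour matrices.

## What it measures

From each frame the package extracts the outer corneal contour
`L_w(n, i)` with sub-pixel precision, removes the rigid eyeball reaction
`L_q(i)` (estimated from the scleral image margins), forms the deformation
`L_d(n, i) = L_w(n, i) − L_q(i) − L_w(n, 1)`, and splits it at 100 Hz into
a slow band `L_L` and a vibration band `L_H`. Between the applanations it
computes four vibration traces:

| trace | definition | axis |
|---|---|---|
| peak | `\|m_kl(i) − m_kr(i)\|`, `m_kl(i) = min over n ≤ N/2 of L_d(n, i)` (topmost rim points; minima in image-row coordinates) | Y (µm) |
| quarter | `\|m_fl(i) − m_fr(i)\|`, `m_f·(i) = L_H(n_f·, i)` at the columns midway between each peak and the deepest point | Y (µm) |
| maximum deformation | `n_d(i) = argmax over [n_fl, n_fr] of L_d(n, i)`, the wander of the deepest-indentation column | X (mm) |
| cutoff | `\|n_bl(i) − n_br(i)\|`, the junction columns where `\|L_d\|` first exceeds the threshold `p_r = 2` px | X (mm) |

plus the per-frame error bound `δ(i) = 1 / Σ_n [L_d(n,i) > p_r]` (1 px when
nothing deforms), the quarter-segment angle
`λ(i) = atan2(m_fl − m_fr, n_fl − n_fr)` and its running sum `β(i)`, and a
spectral summary per trace (dominant frequency above 100 Hz, reported with
its resolution, and peak-to-peak amplitude over all harmonics).

A ground-truthed phantom generator renders synthetic deformation sequences
(arc baseline, Ricker indentation with raised rims, eyeball recession,
injected vibration pairs, realistic rendering noise), so the whole pipeline
is testable with no clinical data.

## Worked example

Render the default phantom (antiphase 350 Hz / 3 px vibrations at the
rims, 400 Hz / 2 px at the quarter points) and analyse it:

```r
library(corvib)

spec  <- phantom_spec()
truth <- synthesize_contour(spec)
seq   <- render_sequence(truth, spec)
seq
#> <image_sequence> 140 frames of 200 x 576 px, dt = 0.23 ms (fs = 4347.8 Hz)

ana <- analyze_sequence(seq)
ana
#> <corvib_analysis>
#> <applanation_pair> A_p1 = frame 46 (10.35 ms), A_p2 = frame 91 (20.70 ms)
#> # A tibble: 4 × 7
#>   vibration axis  fundamental_hz resolution_hz amplitude units n_samples
#>   <chr>     <chr>          <dbl>         <dbl>     <dbl> <chr>     <int>
#> 1 peak      Y               350.          98.8    93.9   um           44
#> 2 quarter   Y               398.          98.8    78.2   um           44
#> 3 maxdef    X               102.          98.8     0.236 mm           44
#> 4 cutoff    X               101.          98.8     2.18  mm           44
```

The applanations are found at 10.35 and 20.70 ms; the injected 350 and
400 Hz vibrations are recovered at 350 and 398 Hz (the ~99 Hz
`resolution_hz` is the honest window limit of ~44 analysed frames — zero
padding localizes a lone fundamental far more finely). The `maxdef` and
`cutoff` rows sit at the bottom of the search band: in this phantom those
traces are dominated by the slow pulse geometry, not an injected tone.
Per-frame traces come via `tidy()`, a one-row summary via `glance()`:

```r
tidy(ana)[68:70, c("i", "t_ms", "peak_vib_um", "quarter_vib_um", "n_d", "delta_px")]
#> # A tibble: 3 × 6
#>       i  t_ms peak_vib_um quarter_vib_um   n_d delta_px
#>   <int> <dbl>       <dbl>          <dbl> <int>    <dbl>
#> 1    68  15.4        65.4           68.0   291  0.00806
#> 2    69  15.6        21.2           62.3   291  0.00806
#> 3    70  15.9        26.9           50.0   293  0.00806
```

`autoplot(ana)` draws the four traces; `reconstruct_3d()` +
`autoplot()` gives the rotational 3-D surface of any frame;
`write_traces()` / `write_spectral_json()` export results.

## Command line

`inst/cli/corvib.R` is a thin Rscript wrapper over the same functions:

```sh
Rscript inst/cli/corvib.R phantom --out phantom_dir --seed 17
Rscript inst/cli/corvib.R analyze --frames phantom_dir --dt-ms 0.23 --field-mm 3.3x9.05 --out results_a
Rscript inst/cli/corvib.R analyze --contour phantom_dir/contour_truth.csv --out results_b
Rscript inst/cli/corvib.R summarize results_a results_b --out table.csv
```

`analyze` writes `traces.csv` (one row per frame, the full column set in
pixels and physical units), `spectral.json`, `summary.json` and a log;
repeated runs are byte-identical. Device-supplied applanation times can be
passed with `--ap1-ms/--ap2-ms` to bypass detection.

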