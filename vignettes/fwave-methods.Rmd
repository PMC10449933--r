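---
title: "F-wave corridor extraction, repeater detection and F-MUNE: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{F-wave corridor extraction, repeater detection and F-MUNE: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwavekit)
```

This vignette documents the signal model behind `fwavekit`, every tunable
parameter with its unit and default, the numerical choices made where the
design was genuinely open, what the synthetic generator does and does not
emulate, and the known limitations.

## Signal model and pipeline

A recording is a matrix of `n_traces × n_samples` amplitudes in µV
(`trace_set()`), typically 300 consecutive traces of 100 ms sampled at
50 kHz. Each trace contains a large (≥ 1 mV) M-response at a fixed early
latency, and possibly an F-wave — the superposition of the surface
potentials of the motor units that backfired on that stimulus — at
20–50 ms. The pipeline (`run_pipeline()`) is:

denoise → trim stimulus artifact → sum traces → autocorrelation →
locate F-maximum → cut corridor → per-trace linear baseline correction →
measure → filter → two-pass repeater detection → group → features/MUNE.

All user-facing locations are reported in *post-trim* time (milliseconds
from the first retained sample) and in *raw* time (post-trim plus the
2 ms artifact trim). Windows are half-open `[start, stop)`;
millisecond-to-sample conversion rounds to the nearest sample, and
sample-to-millisecond conversion is exact.

## Denoising

Each trace undergoes Daubechies-12 wavelet shrinkage. The shrinkage
details are a design choice (the filter family was fixed, the threshold
rule was open): soft thresholding with the universal threshold
σ√(2 ln n), σ estimated per trace as the median absolute deviation of
the finest-detail coefficients, decomposition depth 6, symmetric
boundary extension. This combination is standard, fully deterministic,
and preserves the band-limited F-wave while suppressing wide-band noise.
The transform keeps `floor((n + L − 1)/2)` coefficients per level
(L = 24 taps), which makes reconstruction after trimming sample-exact
for any trace length; the analysis step is verified in the tests against
an externally computed reference and by exact round-trip.

Denoising precedes summation and all feature extraction. Traces shorter
than one decomposition level pass through unchanged with a warning.

## Corridor location

The sum signal is the exact column sum of all (denoised, trimmed)
traces. Its raw autocorrelation r(k) = Σᵢ s(i)·s(i+k) (unnormalized,
zero-padded, non-negative lags; computed by FFT and checked against the
O(n²) definition in the tests) always has its global maximum at lag 0 —
that is the "first peak". Candidate "second peaks" are local maxima with
prominence at least `ac_prominence_frac` (default 10⁻³) of r(0); the
F-wave echo is small relative to the M-response energy at lag 0, which
is why the default is small. Candidates are tried in lag order, at most
`max_ac_attempts` (default 10) of them, each validated by five rules
(rejection reasons as logged):

| rule | rejects when | default |
|---|---|---|
| `spacing<12ms` | candidate lag < `min_ac_peak_spacing_ms` — an artificial peak from M-response fluctuation | 12 ms |
| `no_positive_peak` | no positive local maximum of the sum signal inside `[approx − 7.5, approx + 15)` ms, where approx = M-peak location + lag | 7.5/15 ms |
| `amplitude_floor` | sum-signal value at the refined location < `floor_sum_uv` (near the M-response global minimum) | −100 mV |
| `latency<16ms` | refined location < `min_f_latency_ms` post-trim (18 ms raw; median/ulnar F-waves appear after 20 ms) | 16 ms |
| `slope>16deg` | the 15 ms segment centred on the refined location slopes more steeply than `slope_limit_deg` — its left part is M-response | 16° |

The refined location is the highest-amplitude positive local maximum in
the search window (ties → earliest sample). Design notes:

* *"Positive peak"* means a local maximum of the sum signal itself with
  value > 0; a monotone stretch at a window edge never counts.
* The slope threshold is display-geometry dependent (a 16° line on an
  instrument screen at 500 µV gain and 10 ms/division). The package maps
  45° to `slope_scale_uv_per_ms_45deg` = 50 µV/ms for a single trace and
  50·n µV/ms for a sum of n traces; both are configurable. Slopes are
  least-squares fits and the comparison uses the *signed* angle: the
  rules target the sum signal rising steeply out of the M-response
  minimum.
* The amplitude floor defaults to −100 mV on the sum signal. With a
  negative floor and positive refined peaks the rule is a safeguard that
  cannot fire; it is kept configurable because it scales with the number
  of traces summed, and a raised floor makes the rejection path
  testable.
* The slope rule may reject at most one candidate per run; a second hit
  aborts the search ("repeated for the last time"). All other rules
  iterate freely. An aborted or exhausted search raises a no-corridor
  error that carries the full attempt log and points the user to manual
  cut locations.

The corridor is `[Fmax − cut_back_ms, Fmax + cut_fwd_ms)` (10/20 ms,
30 ms total); `trim_piece_ms` = 0.25 ms pieces are dropped from its left
edge while they slope more steeply than 16°. If trimming would consume
the whole pre-peak region the left cut stops at Fmax − 0.5 ms and the
result is flagged degenerate. Manual mode applies the user's cuts
verbatim.

## Baseline correction

Each corridor trace gets its own ordinary least-squares line (over the
full corridor, F-wave included — the line follows the whole trace),
subtracted point by point. The residuals are orthogonal to {1, t}, so
the summed distances above and below the line are equal in magnitude;
the correction is idempotent and exactly invertible (input = output +
fitted line), i.e. it cannot distort the waveform. Robust or flanking-
segment variants were deliberately not used.

## Measurement, filtering, repeater detection

Per trace: global maximum and minimum amplitude with earliest-tie
locations, peak-to-peak amplitude, and power. *Power* is defined here as
the mean squared amplitude over the corridor (scale-free under
trace-length changes; the term was otherwise unspecified).

Filters, in order: peak-to-peak ≤ 40 µV (`min_fwave_pp_uv`; acceptance
is strictly greater-than) → `low_amplitude`; otherwise, amplitude change
< 40 µV within 3 ms (`noise_window_ms`) of the peak on *both* sides
(windows clipped at corridor edges) → `noise`. The order matters: any
trace below 40 µV trivially satisfies the noise predicate, so the
amplitude rule must be evaluated first for the two categories to be
meaningful.

Repeater detection runs in two passes over `ok` traces. Location
differences (Fmax, Fmin) are measured on corridor-relative peak
locations *before* alignment (afterwards they would be zero by
construction). For each candidate pair the traces are shifted so the
chosen peak coincides; Pearson correlation and the power ratio are
computed on the overlapping region (pairs overlapping less than
`min_overlap_frac` = 50 % of the corridor are not comparable). The
similarity coefficient is `(1 − amplitude ratio) + (1 − power ratio)` —
a normalized reading of "sum of the amplitude difference and power
difference"; under the default pass-one thresholds it is mathematically
non-binding (≤ 0.3 < 0.6) and is retained for fidelity and
configurability. Pass one requires dmax < 0.5 ms, dmin < 0.5 ms,
amplitude ratio > 0.9, power ratio > 0.8, correlation > 0.9, similarity
< 0.6. Pass two re-examines only traces not in any confirmed pass-one
pair, aligned by the F-minimum, with amplitude ratio > 0.95 and power
ratio > 0.9 and *no* correlation criterion. Every comparison is strict,
exactly as the thresholds are printed. Confirmed pairs sharing a member
merge (connected components); the pair with the smallest similarity
coefficient is flagged most similar.

## Features and MUNE

The M-response is measured on the pointwise mean trace over
`[0, min_f_latency_ms)` post-trim (a per-trace-then-average variant is a
config away): peak-to-peak amplitude, positive-peak area Σ max(x,0)·Δt
and total rectified area Σ|x|·Δt. Group sMUP descriptors are member-wise
means of the per-trace corridor measures. With K groups:

* MUNE₁ = M peak-to-peak / mean sMUP peak-to-peak,
* MUNE₂ = M positive-peak area / mean sMUP positive-peak area,
* MUNE₃ = M total area / mean sMUP total area.

Persistence is the number of post-filter `ok` F-waves over the number of
recorded traces (the filtered count, not the raw count, is what the
analysis actually uses). With no repeater groups the MUNE values are
missing with an explicit reason string in the report.

## The synthetic generator

`synthesize()` builds recordings with known ground truth: an M-response
template (windowed sinusoid, default 2 mV peak-to-peak at 5 ms) on every
trace; a pool of `n_units` (default 20) motor-unit surface potentials —
smooth zero-mean biphasic/triphasic waves of 5–15 ms support with
stratified supports, random asymmetry and a small second-harmonic
admixture, peak-to-peak amplitudes drawn from `unit_amp_range_uv`
(default 50–150 µV); per trace each unit backfires with probability
`unit_fire_prob` (default 0.05, giving expected persistence
1 − (1 − p)^K ≈ 0.64); fired templates are added *peak-aligned* at the
trace latency, so a trace's F latency is the location of its F-wave
peak. Latency jitter is truncated-Gaussian (sd `jitter_ms`/2, bounded at
± `jitter_ms`, default 1 ms): physiological latency scatter is peaked,
which also gives the per-trace peak distribution a well-defined mode.
Optional fixed per-unit latency offsets (`unit_latency_spread_ms`,
default 0) model that each motor neuron has its own conduction latency.

Repeaters: a `repeater_frac` (default 0.2) fraction of F-wave-bearing
traces reuse an earlier trace's exact unit set; any trace whose unit
combination identically repeats an earlier one re-fires within
min(0.1 ms, `jitter_ms`) of it — the same backfiring neuron has a fixed
conduction path, so the same combination implies the same latency. The
ground-truth grouping is the partition of F-bearing traces by identical
unit set. Unit templates are forced to have a dominant positive lobe and
a dominant trough (near-tied lobes would make the measured extremum
locations flip under noise, which real motor-unit potentials do not do).

Baseline drift is `none`, `linear` or `sigmoid` with magnitude capped at
200 µV; additive noise is Gaussian (`noise_sd_uv`, default 10 µV).
Structure (fired sets, latencies, repeats) and nuisance (drift, noise)
come from two independent RNG streams, so changing only the noise level
leaves the planted truth bit-identical — tests can vary noise at fixed
truth.

What the generator does **not** emulate: motor-unit firing-rate
dynamics, A-waves, per-unit waveform variability across stimuli,
electrode drift within a session, or power-line interference. Passing
tests therefore demonstrate correctness of the algorithmic chain under
the stated signal model, not clinical performance on real recordings.

## Study sizes used in the checks

The property-based checks run at the sizes the method targets: corridor
localization over 50 seeded 300-trace recordings (noise 10 µV, F-peaks
at 28 ± 1 ms); repeater recovery over 20 seeded recordings with five
planted groups (sizes 2–5) among 40 distinct F-waves, with per-unit
latency offsets of ± 2 ms (distinct motor neurons have distinct
latencies; without this, "distinct" units implausibly share one latency
distribution and chance look-alikes inflate false merges); the
all-distinct control uses the same conditions. The MUNE-recovery check
uses an equal-amplitude 20-unit pool at `unit_fire_prob` = 0.02 —
strongly submaximal stimulation, where single-unit F-waves dominate and
the mean sMUP approaches the true unit amplitude. At the default firing
probability about 1.6 units fire per F-bearing trace and multi-unit
combinations inflate the mean sMUP by ~50 %, biasing MUNE low by about a
third; this combination bias is inherent to F-MUNE, not a defect of the
implementation.

## Known limitations

* In proximal muscles the F-wave can overlap the M-response minimum; the
  corridor search then fails by design (no-corridor error) and manual
  cuts are the supported path.
* The similarity coefficient's exact normalization in its source was not
  restated; the definition here is a documented, configurable choice.
* The 16° slope threshold is tied to an assumed display geometry; other
  gains/time bases require adjusting `slope_scale_uv_per_ms_45deg`.
* MUNE inherits the combination bias discussed above, and all clinical
  thresholds (40 µV, 0.5 ms, ratio cut-offs) are used exactly as
  printed, strict comparisons included.
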