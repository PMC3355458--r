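---
title: "Methods: signal model, segmentation and classification rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, segmentation and classification rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skitech)
```

## The measurement model

A single inertial unit on the upper back records six channels at 100 Hz:
forward/backward, sideways and up/down acceleration (`fwd_a`, `side_a`,
`up_a`, in g) and the three angular rates (`roll`, `pitch`, `yaw`, in
degrees per second, d/s). Two physical facts anchor the analysis:

* **Gravity projection.** The mounting is such that an upright athlete
  reads +1 g on `fwd_a`; rotating the unit fully forward moves the 1 g
  reading to `up_a`. We model intermediate trunk lean $\theta$ as
  $\mathrm{fwd} = \cos\theta$, $\mathrm{up} = \sin\theta$, with no
  gravity on `side_a` (`gravity_components()`). No gravity correction is
  applied anywhere in the pipeline — the offsets are informative (they
  encode lean, and steeper terrain shifts the balance from `fwd_a`
  toward `up_a`) and the cycle analysis works on the oscillatory part.
* **Cyclical signatures.** Every technique is periodic at the cycle
  rate (0.6–1 Hz at moderate intensity). Poling appears as large pitch
  peaks; kicks as roll/yaw excursions that alternate sign with the leg;
  skating as a regular alternating `side_a` peak/trough cycle. The
  classifier consumes only these low-frequency features, which is why
  aggressive low-pass filtering is appropriate.

## Filtering

All channels pass through a low-pass Butterworth filter before any
peak-based analysis: cutoff 2.0 Hz for the accelerometer channels and
1.0 Hz for the gyroscope channels. The filter order is 4 (a common
biomechanics choice; configurable) and application is forward–backward,
so the effective magnitude response is the squared single-pass response
and the net phase delay is zero — filtered peaks stay aligned with the
movement events that caused them, which the downstream timing features
require. `measure_cutoff()` verifies the realised −3 dB point of the
design by bisection on the evaluated response rather than trusting the
request.

Numerical handling: the input is extended by odd reflection about each
endpoint before filtering and trimmed afterwards. The extension length
is $6 f_s / f_c$ samples — scaled to the filter's time constant, since
the transient of a 1 Hz order-4 design lasts on the order of a second
and a fixed handful of samples would leave visible end ripple. With this
padding a constant input is reproduced to better than $10^{-5}$
relative (DC gain 1), and energy at twice the cutoff is attenuated by
more than 40 dB. Pipeline code additionally trims 0.5 s from each end
after filtering before segmenting.

## Cycle segmentation

Cycles are half-open peak-to-peak intervals on an anchor channel:

* **Skating:** `side_a` peaks (one per full left+right cycle), minimum
  prominence 0.1 g. Left/right half-cycles are windows centred on the
  alternating `side_a` peaks (left) and troughs (right).
* **Classical:** `yaw` kick peaks when their median level reaches
  20 d/s (DS and KDP; the double-pole yaw stays below 20 d/s, which is
  also the published bound for "minimal" roll/yaw). For DP the anchor
  falls back to the `pitch` poling peak and no side labels exist.

The 20 d/s yaw test is on the peak *level*, not on topographic
prominence: a ±10 d/s oscillation already has ~20 d/s prominence, so a
prominence test would wrongly promote DP's minimal yaw to an anchor.
The same level-vs-prominence distinction applies to poling detection
(below). Peak detection itself (`detect_peaks()`) uses topographic
prominence with a minimum separation of 0.5 s between anchor peaks
(cycle periods are ≥ 1 s at realistic rates), breaks plateau ties toward
the earlier sample, and requires at least two anchor peaks — otherwise
segmentation fails with "no cyclical structure", which the end-to-end
classifier converts into a label-none result rather than an error.

## Feature definitions and thresholds

All per-cycle quantities are summarised by **medians** across cycles;
real athletes show visible cycle-to-cycle irregularity and a single odd
cycle should not flip a feature. The discriminative set:

| feature | definition | role |
|---|---|---|
| `pitch_peak_dps` | median per-cycle max |pitch| | poling bounds: > 75 d/s poling (DP/KDP/G3/G4), > 50 d/s for G2, < 50 d/s DS, < 40 d/s G5 |
| `roll_peak_dps`, `yaw_peak_dps` | same for roll/yaw | kick present ≥ 20 d/s; G2/G5 roll > 50 d/s |
| `sidea_regular` | alternating `side_a` extrema with amplitude CV < 0.5 and median ≥ 0.1 g | family split: skating vs classical |
| `fwd_peaks_per_cycle`, `fwd_major_minor` | peaks with prominence ≥ 25% of the cycle maximum; "minor" = 25–75% of the major | 1 peak (DP), 2 even (DS/G3/G5), major+minor (KDP/G4), double peak (G2) |
| `pitch_yaw_ratio` | poling-level pitch peaks per yaw peak | 2 for G3, 1 for G2/G4, 0 without poling |
| `yaw_pitch_lag` | circular median lag from each pitch peak to the **nearest** yaw extremum, in cycle fractions | negative = yaw precedes pitch (G4), positive = yaw follows (G2) |
| `pitch_precedes_fwd` | lag from each pitch peak to the nearest `fwd_a` peak is positive | sanity property of every poling technique |

Two deliberate conventions need justification:

* **Nearest extremum, not peak, for timing.** An athlete leading on the
  left inverts the yaw and roll curves, swapping peaks and troughs. A
  peak-to-peak lag would then jump by half a cycle and flip the G2/G4
  decision; the nearest-extremum lag is invariant under the inversion,
  so offset skate classifies identically for either lead side.
* **Nearest `fwd_a` peak, not "main" peak, for poling order.** For
  techniques with two even `fwd_a` peaks the larger one is decided by
  noise, which would randomise a main-peak lag between +0.15 and −0.35
  cycles. The nearest-peak lag is stable for every technique.

Poling peaks are pitch peaks whose *level* reaches 45 d/s — between the
G5 bound (40 d/s, no poling) and the lowest poling bound (50 d/s, G2) —
detected at a 20 d/s prominence floor. Timing features use the 20 d/s
floor directly so that weak-poling techniques (DS at 40 d/s) still yield
timing events.

## The decision tree

1. `sidea_regular` → skating, else classical.
2. Classical: pitch < 50 ∧ roll ≥ 20 → DS; pitch ≥ 75 → KDP if
   roll ≥ 20 else DP.
3. Skating: pitch < 40 → G5; |ratio − 2| ≤ 0.35 → G3; otherwise the lag
   sign: < −0.02 → G4, > +0.02 → G2; inside the ±0.02 band the `fwd_a`
   pattern breaks the tie (major+minor → G4, double peak → G2).

G5 is tested before any poling bound, so G2's intermediate pitch level
(50–75 d/s) is never rejected. `ratio_tol = 0.35` and
`lag_zero_band = 0.02` cycles are package conventions — the published
ordering is qualitative — and live in `rule_thresholds()` /
`ski_config()` like every other tunable. Any feature combination that
matches no branch returns a label-none result carrying the evidence
collected, never an exception. Confidence is the fraction of consulted
rules passed; it is a diagnostic, not a calibrated probability.

The end-to-end entry `classify_series()` trims the tap marker plus the
2 s of quiet standing that follows it, filters, segments under **both**
family hypotheses, and keeps the labelled result with the higher
confidence (ties resolved toward the segmentation whose family matches
the feature-implied family).

## Asymmetry

For each labelled half-cycle the peak amplitude of `fwd_a`, `up_a`
(mean-centred, removing gravity) and `roll` (raw: a genuine amplitude
asymmetry shifts the roll mean, and centring would fold that shift back
into the peaks) is collected per side. The index per channel is the
symmetric limb-symmetry form $(\bar L - \bar R)/((\bar L + \bar R)/2)$,
zero for symmetry, bounded by ±2; the report is flagged when any
|index| exceeds 0.15 (a convention, configurable). If the left-side
amplitudes are scaled by $r$, the index recovers $2(r-1)/(r+1)$.

Note that the one-sided skating gears (G2, G4) and KDP are intrinsically
asymmetric — their major `fwd_a` peak sits on the poling side — so a
flagged index there reflects the technique, not a deficiency. The
left/right comparison is most meaningful for the symmetric-template
techniques (DS, G3, G5).

## The synthetic generator

`generate_imu()` synthesises each channel as a sum of 1–3 harmonics of
the cycle rate, with per-technique peak positions encoding the timing
relations (pitch 0.15 cycles before the `fwd_a` peak in all poling
techniques; yaw 0.10 before pitch in G4 and 0.05 after in G2; pitch at
twice the cycle frequency in G3), plus gravity offsets, white noise
(0.05 g / 5 d/s), and an 8 Hz contaminating harmonic (0.1 g / 10 d/s)
that the default filters remove. Default cycle rates are 0.8 Hz
(classical) and 0.7 Hz (skating) — typical moderate-intensity values,
configurable. The tap marker is three 5 g, 50 ms half-sine spikes at
0.5 s spacing, followed by 2 s of quiet standing, prepended to the
movement.

**Amplitudes are specified on the analysis (filtered) scale.** The
published signature levels describe *filtered* curves, and an order-4
zero-phase 1 Hz filter passes only ~6% of a component at 1.4 Hz — the
frequency of G3's two-peaks-per-cycle pitch. Raw-scale amplitudes could
therefore never satisfy the table bounds after filtering. The generator
instead expands each channel's target waveform (template × the
left-side asymmetry envelope) into its Fourier lines over one cycle and
pre-equalises every line by the inverse zero-phase response of the
default filters, so that default filtering returns the parameterised
waveform exactly (plus residual noise). Lines that would need more than
a 300× boost are dropped unless they belong to the core template; their
contribution to the target is negligible and the cap keeps raw
amplitudes bounded. A side effect is that raw second-harmonic gyro
amplitudes become much larger than their filtered counterparts — as
with real unfiltered gyro data, though the synthetic raw scale is not
calibrated to any sensor.

The left-side asymmetry is a smooth half-cycle envelope
$1 + (r-1)\max(\cos 2\pi(v - v_L), 0)$ on `fwd_a`, `up_a` and `roll`,
centred on the left anchor event, so the left peak scales by exactly
$r$ while the right peak is untouched. For G2, `lead_side = "L"`
negates yaw and roll (the lead-left signature). All randomness flows
from one seed through a fixed stream order (noise channel by channel in
container order, then the six contaminant phases); the caller's RNG
state is saved and restored.

**What the generator does not emulate:** terrain and speed variation
within a recording, gear changes, stride-to-stride timing jitter (only
amplitude noise), individual style beyond amplitude/rate/lean jitter,
sensor drift or saturation, and the G6/G7/Herringbone techniques. A
classifier that is perfect on this substrate is therefore validated for
the *rule logic and signal plumbing*, not for field robustness.

## Problem sizes and determinism

Recordings default to 20 s (≈ 14 classical / 12 skating cycles), the
scale at which all package checks run: the generator→classifier round
trip over all 7 techniques × 20 seeds, a 7 × 10 jittered fixture grid
(cycle rate ±20%, lean 0–30°, noise ×0.5–2, amplitudes ×0.8–1.2, random
G2 lead side), cycle-rate recovery within 3%, asymmetry recovery within
0.05 of the closed form, and a peak-detector equivalence sweep against
an exhaustive $O(n^2)$ prominence oracle on 50 random series. Every
stochastic test fixes its seed.

## Known limitations

* Thresholds are calibrated to the published signature tables; real
  recordings from other mounting positions or athletes at race
  intensity may need the `ski_config()` tunables adjusted.
* KDP's "slight hump" kick signature in pitch is resolution-dependent
  (it splits into minor/major peaks only at a 2 Hz gyro cutoff), so KDP
  is discriminated from DP by its roll/yaw kick signature instead.
* Cycle *length* (metres) requires position data and is out of scope;
  so is continuous sliding-window classification over mixed-technique
  recordings.
* The asymmetry flag threshold (0.15) has no clinical validation; treat
  flagged recordings as prompts for video review, not verdicts.
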