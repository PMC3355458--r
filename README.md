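# skitech

Rule-based technique classification and left/right asymmetry analysis for
six-channel inertial (IMU) recordings of cross-country skiing, from a
single micro-sensor unit worn on the upper back.

## The problem

Cross-country skiers switch constantly between sub-techniques: the
classical gears — double pole (DP), kick double pole (KDP), diagonal
stride (DS) — and the skating gears G2 (offset, steep uphill), G3 (double
time), G4 (single time) and G5 (free skate, no poling). Coaches want to
know which technique was used when, at what cycle rate, and whether the
left and right sides contribute evenly. A trunk-mounted unit sampling
tri-axial acceleration (`FwdA`, `SideA`, `UpA`, in g) and angular rate
(`Roll`, `Pitch`, `Yaw`, in degrees/second) at 100 Hz captures all of
this: each technique leaves a distinctive cyclical signature in the six
filtered channels.

`skitech` implements that analysis as a tested pipeline:

1. **Conditioning** — zero-phase low-pass Butterworth filters, 2.0 Hz for
   the accelerometer channels and 1.0 Hz for the gyroscope channels
   (order 4); a three-tap synchronisation marker locator; ten-second
   analysis-block extraction.
2. **Segmentation** — movement cycles from the anchor channel (`SideA`
   peaks for skating; `Yaw` kick peaks for classical, falling back to
   `Pitch` for DP), with left/right half-cycle labels.
3. **Features** — per-cycle medians of the discriminative quantities:
   pitch/roll/yaw peak levels, `SideA` regularity, `FwdA` peak
   multiplicity (major/minor/double-peak patterns), poling-to-cycle peak
   ratios, and the yaw–pitch timing lag.
4. **Classification** — a decision tree over the published signature
   thresholds (poling pitch > 75 d/s, G2 poling > 50 d/s, DS pitch
   < 50 d/s, G5 pitch < 40 d/s, kick roll ≥ 20 d/s, G2 roll > 50 d/s;
   G3 shows 2 pitch peaks per yaw peak, G4 one with the yaw peak
   *preceding* the pitch peak, G2 one with the yaw peak just *after*),
   returning a label plus a full rule-by-rule evidence trail.
5. **Asymmetry** — the limb-symmetry index
   `(mean_L − mean_R) / ((mean_L + mean_R)/2)` of per-half-cycle peak
   amplitudes of `FwdA`, `UpA` and `Roll`, which exposes one-sided kicks
   (lower `FwdA`, higher `UpA` on the weak side).

Because no public recordings exist for this sensor configuration, the
package includes a first-class synthetic generator (`generate_imu()`)
whose harmonic templates reproduce every quantitative signature above on
the filtered scale, including gravity projection under trunk lean, the
tap marker, sensor noise, and configurable left/right asymmetry. It is
the test substrate for the whole pipeline.

## Worked example

Simulate a diagonal-stride recording with a 20% weaker left kick,
classify it, and quantify the asymmetry:

```r
library(skitech)

s <- generate_imu(default_params("DS", asymmetry_ratio = 0.8, seed = 42))
res <- classify_series(s)
summary(res)
#> <ski_classification> label: DS (confidence 1.00)
#>   14 cycles at 0.80 Hz (anchor yaw, classical family)
#>   evidence:
#>     family_classical          0.000 eq 0  [pass]
#>     pitch_below_ds_max       40.745 lt 50  [pass]
#>     kick_roll_present        40.896 ge 20  [pass]

f <- apply_lowpass(select_block(s, 3.2, 20))   # skip marker + quiet standing
seg <- segment_cycles(f, "classical")
asymmetry_index(side_profiles(f, seg))
#> <asymmetry_report> FLAGGED
#>   fwd_a  L 0.244  R 0.308  index -0.234
#>   up_a   L 0.167  R 0.201  index -0.184
#>   roll   L 32.327  R 40.727  index -0.230
#>   half-cycles: L 15, R 14; flag threshold 0.15
```

Reading the output: the filtered pitch peak (40.7 d/s) is below the
50 d/s diagonal-stride bound while the roll kick signature (40.9 d/s)
clears 20 d/s, so the rule tree lands on DS; 14 cycles at 0.80 Hz is the
cadence. The asymmetry indices are negative on `fwd_a` and `roll` —
close to the theoretical `2(r−1)/(r+1) = −0.22` for the injected ratio
`r = 0.8` — and exceed the 0.15 flag threshold, so the left kick is
flagged as weaker.

A command-line wrapper over the same functions is installed with the
package (`system.file("cli", "skitech.R", package = "skitech")`):

```sh
Rscript skitech.R simulate --technique G3 --seed 1 --out g3.csv
Rscript skitech.R classify g3.csv --out report.json   # exit 0, label G3
```

Exit codes: 0 classified, 2 no label, 1 processing error, 64 usage.

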