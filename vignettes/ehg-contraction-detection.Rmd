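---
title: "Detecting uterine contractions from multichannel EHG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uterine contractions from multichannel EHG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgdetect)
```

## The problem

The electrohysterogram (EHG) records the electrical activity of the uterine
muscle from electrodes on the maternal abdomen. Counting contractions
automatically from the EHG — without a tocodynamometer and without a human
reader — is a prerequisite for outpatient and home monitoring of pregnancies
at risk of preterm delivery. The physical signature this package exploits is
*spatial synchronization*: during a contraction the myometrial burst is
picked up, with different gains and small propagation delays, by many
electrodes at once, so signals from neighbouring electrode pairs become
strongly mutually predictable; between contractions each electrode mostly
sees its own local noise.

## The detection chain

1. **Bipolar derivation.** The 16 unipolar electrodes of the 4×4 abdominal
   grid (13 mm diameter, 17.5 mm pitch, 200 Hz) are subtracted vertically,
   `Vb(r,c) = E(r,c) − E(r+1,c)`, giving 12 bipolar signals with improved
   signal-to-noise ratio. Bipolar channels are numbered column-major
   (`Vb1..Vb3` down column 1, etc.).
2. **Band-pass 0.1–3 Hz.** A 4th-order Butterworth (second-order sections,
   bilinear design) applied forward–backward, selecting the frequency band
   of uterine electrical bursts.
3. **Sliding-window H².** A window of 800 samples (4 s) advancing by 400
   samples scans the 12 bipolar signals. At each position the nonlinear
   correlation coefficient H² is computed for each of the 36 laterally
   adjacent ordered pairs, and the number of pairs with `H² > S1` is
   counted, yielding the correlated-pair count curve (values 0–36).
4. **Event detection.** Maximal runs of windows with `count > S2` become
   candidate events; an event spans from the first window's start to the
   last window's start plus the window length.
5. **Fusion (D1).** Consecutive events separated by a gap strictly less than
   `D1` seconds are merged — a single contraction is often oversegmented
   into several bursts of correlation.
6. **Elimination (D2).** Events whose duration does not exceed `D2` seconds
   are removed — brief correlated transients are typically fetal or maternal
   movements or instrumental artifacts, not contractions.

### The H² statistic

For signals $x$ (driver) and $y$ (response),

$$H^2_{y|x} = \max\!\left(0,\; 1 - \frac{\sum_i (y_i - f(x_i))^2}
{\sum_i (y_i - \bar y)^2}\right)$$

where $f$ is a piecewise-linear regression curve: the range of $x$ is split
into `bins` equal-width bins, a knot is placed at the (mean $x$, mean $y$)
of each non-empty bin, and $f$ interpolates the knots linearly. H² ranges
from 0 (no statistical relation) to 1 (exact functional dependence); unlike
the squared Pearson correlation it captures non-monotone, nonlinear
relations, and it is asymmetric in its arguments — which is why the pair
topology takes each of the 18 same-row column pairs in **both** directions,
giving exactly 36 ordered pairs.

Two choices here were genuinely open:

* **Extrapolation beyond the outer knots.** We extend the outer segments
  *linearly*. Constant extrapolation would leave points beyond the
  outermost bin means with systematic residuals, so even an exactly affine
  relation $y = ax + b$ would score below 1; linear extension makes the
  affine case score exactly 1, which we treat as part of the statistic's
  contract (and which the biosignal-coupling literature also uses).
* **Degenerate inputs.** Constant $y$, constant $x$, or fewer than two
  non-empty bins return 0 rather than an error: a flat window carries no
  evidence of coupling.
* **No delay scan.** Some formulations maximize H² over a time shift
  between the signals; with 17.5 mm inter-electrode pitch and ≤4 s windows
  the propagation delay is a small fraction of a burst period, so the
  zero-lag coefficient is used. The sliding-count implementation leaves
  this as an extension point.

### Pair topology: why 36

"Laterally adjacent" pairs sharing a bipolar row number 9 if read strictly
(neighbouring columns only), which cannot produce 36 H² values. The only
reading consistent with a count of 36 — and with the worked examples
(Vb1–Vb4, Vb4–Vb7, Vb2–Vb5) — is *all* same-row column pairs
(3 rows × C(4,2) = 18), each ordered pair counted separately because H² is
asymmetric: 18 × 2 = 36.

## Parameters

| parameter | default | units | provenance |
|---|---|---|---|
| `window_len` | 800 | samples (4 s) | published method |
| `window_step` | 400 | samples (2 s) | published method |
| `band_low`, `band_high` | 0.1, 3 | Hz | published method |
| `s1` | 0.5 | – | package calibration |
| `s2` | 10 | pairs (of 36) | package calibration |
| `d1` | 15 | s | package calibration |
| `d2` | 30 | s | package calibration |
| `h2_bins` | 10 | – | ~80 samples/bin at the default window |
| `tolerance` | 10 | s | package choice (evaluation margin) |

The thresholds S1, S2, D1, D2 were tuned in the original study on a private
clinical database and never published; the defaults above were chosen on
the synthetic benchmark (below) and are deliberately exposed everywhere
(config file keys and CLI flags), so no claim of parameter parity with the
clinical study is made. `s2 = 10` sits well above the baseline count level
(the noise floor rarely pushes more than a few of 36 pairs past
`s1 = 0.5`) and well below the in-contraction level (typically >25 of 36
at high SNR). `d2 = 30` s lies between the longest plausible artifact
transient (~8 s) and the shortest clinically meaningful contraction
(~40 s). The 10 s evaluation tolerance is of the order of a few window
steps and is documented as arbitrary.

All comparisons follow the method's wording literally: `H² > S1` (strict),
`count > S2` (strict), gap `< D1` (strict), and survival requires duration
`> D2`.

## Evaluation taxonomy

Each detected event overlapping at least one reference contraction is
assigned to the reference of greatest overlap (earliest reference on ties).
A reference is a **full detection** if some assigned event matches both its
boundaries within the tolerance, **partial** if it is overlapped but not
boundary-matched, **missed** otherwise; unassigned events are **false
alarms**. Several events on one contraction count that reference once, and
the extra events are neither false alarms nor separate detections — this
matches how the published tables can report a total detection count equal
to the number of contractions while thousands of raw events exist. The
false-alarm rate is quoted *per reference contraction* and can exceed
100%.

```{r table-arithmetic}
# the worked example from the package README: the published H2-only counts
summarize_counts(n_full = 313, n_partial = 188, n_missed = 0,
                 n_false_alarms = 3918)
```

## The synthetic benchmark: what it does and does not establish

Clinical EHG databases with expert contraction labels are not
redistributable, so the package ships a seeded generator
(`synthetic_config()`, `generate_recording()`) whose defaults state a
30-minute, 200 Hz, 16-channel monitoring session:

* **Contractions:** 10 per recording, 40–90 s long, ≥60 s apart, as a
  shared band-limited (0.2–0.8 Hz) Gaussian burst with a tapered-cosine
  envelope (flat over the central 70%, so detected durations track
  annotated ones), propagated across the grid with ≤0.25 s diagonal delay,
  soft-saturated (`tanh`) by default so inter-channel coupling is
  nonlinear, and scaled to 20 dB mean burst-to-background power on the
  unipolar channels — a clean recording with good skin preparation.
* **Electrode gains:** a fixed vertical gradient (1.6, 1.0, 0.62, 0.38)
  times per-electrode log-normal jitter (σ = 0.3). The gradient is a
  physical-plausibility requirement, not a tuning knob: electrodes sit at
  different distances from the active region, and without a vertical gain
  difference the shared burst would cancel exactly in the bipolar
  derivation and no bipolar method could see it.
* **Background:** independent per-channel Gaussian noise with a 1/f-like
  spectrum (knee 0.05 Hz, support 0.01–10 Hz), emulating baseline drift
  plus instrumentation noise.
* **Artifacts:** Poisson arrivals (6/h), 2–8 s long, coherent across all
  channels at 3× burst power — stand-ins for fetal/maternal movements and
  lead motion. They trigger raw detections (emulating the very high raw
  false-alarm regime) and are removed by the D2 elimination, which makes
  the false-alarm-reduction narrative testable. They are excluded from the
  ground-truth annotations.

One measured property of this world is worth stating explicitly: with a
1/f-like background, two *independent* channels in a 4 s window are both
smooth, slowly varying curves, and a binned regression of one on the other
has a nonzero floor — mean baseline H² ≈ 0.11 with occasional windows near
0.5. Baseline H² is **not** ≤ 0.2 uniformly, and no choice of realistic
low-frequency background makes it so; this floor is precisely why a per-pair
cutoff as high as S1 = 0.5 is needed before counting. The tests therefore
assert the distributional behaviour (mean, 99th percentile, and all values
below S1 at a fixed seed) rather than a uniform 0.2 bound.

What a green synthetic benchmark establishes: the chain recovers known
correlated bursts at realistic SNR, suppresses brief coherent artifacts,
and is deterministic and internally consistent. What it does **not**
establish: clinical performance. The generator has no fetal ECG, no
electrode detachment, no slow SNR drift, no Braxton-Hicks vs labour
distinction, and its artifacts are simplistic; the published clinical
percentages (100% detection with 782% false alarms raw; 96% with ~1 false
alarm per contraction after post-processing) come from a 51-recording,
501-contraction private database and are reproduced here only as
*arithmetic* on the published counts, never as a simulation claim.

## Numerical and implementation notes

* **Filter design.** The Butterworth band-pass is designed by the standard
  analog-prototype → low-pass-to-band-pass → bilinear-transform route and
  realised as second-order sections (numerically stable at a 0.1 Hz edge
  and 200 Hz rate, where an order-8 polynomial form would be fragile). The
  design was cross-checked against an independent reference implementation
  to 1e-6 in magnitude response during development; the tests assert
  response levels (pass-band ≥ 0.9 at 1 Hz, ≤ 0.2 at 0.02 Hz, DC < 1%).
* **Zero-phase filtering** runs the cascade forward and backward over an
  odd-reflection extension of one settling length (3/`band_low` seconds ≈
  30 s at the default band) at each end, so recordings must be longer than
  ~30 s and onset transients do not masquerade as correlated activity at
  the edges. A `causal` single-pass mode exists for real-time parity; it
  delays the burst envelope as any causal filter must.
* **EDF round-trips** quantize to 16-bit integers over each channel's
  physical range (error ≤ range/2¹⁶ per sample); the true sample count is
  stored in the reserved header field because EDF pads to whole data
  records. CSV round-trips are exact to double precision.
* **Degenerate inputs.** Empty count curves yield empty event lists; empty
  event lists pass unchanged through fusion and elimination; an empty
  reference set is an error in evaluation (the percentages are undefined),
  not a silent zero.
* **Performance.** The H² sliding count and the SOS filter are the only
  hot spots and are implemented in C++; a 30-minute 16-channel recording is
  processed in a few seconds on one CPU. Results are independent of
  execution order; the brute-force R implementation in the test suite must
  (and does) reproduce the C++ counts exactly.

## Known limitations

* Thresholds are calibrated on the synthetic world, not on clinical data.
* No discrimination of labour vs Braxton-Hicks contractions, no
  frequency-domain (wavelet) features, no post-classification of false
  alarms — all are extensions of the method beyond its core.
* The grid-to-channel map defaults to row-major; if an acquisition montage
  differs, pass a custom `electrode_grid()`.
* The evaluation implements one deterministic matching rule
  (maximal-overlap, earliest-on-ties); other many-to-many matching rules
  would give slightly different partial/full splits.
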