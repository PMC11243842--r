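---
title: "Fuzzy stress assessment from wearable vitals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy stress assessment from wearable vitals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzphys)
```

## The inference model

Stress is scored on a continuous 1–3 scale from eight physiological
parameters. Each parameter has a clinical reference band $[L, H]$
(`reference_ranges()`): HR 60–90 beats/min, PRV (RMSSD) 32–77 ms, RR 12–18
breaths/min, SpO2 97–99 %, GSR 30–50 kOhm, BT 36.5–37.5 °C, SBP 90–120 and
DBP 60–80 mmHg. A value is fuzzified into Low/Normal/High degrees with a
right-shoulder trapezoid, a triangle peaking at the band midpoint, and a
left-shoulder trapezoid; all three shapes share a transition half-width
$\delta = f\,(H - L)$ with $f = 0.10$ by default. The fraction $f$ is an
artifact parameter: reference tables publish only crisp cut points, so the
shape of the transition has to be chosen. We chose a width proportional to
the band so that every parameter transitions over a comparable relative
scale, and we keep $f$ configurable because the choice is behaviourally
testable — as $f \to 0$ the fuzzy classifier must coincide with the crisp
band classifier on direction-consistent samples, which the test suite
verifies at $f = 10^{-9}$.

Two band-specific adjustments are worth noting. The published BT rows are
internally inconsistent (Low "<36.5" against a normal band starting at
36.0); we adopt 36.5 as the lower normal cut so the Low band and the Normal
band meet at one point. SpO2 is physically capped at 100 %, and the sample
validator rejects values above it; with $f = 0.10$ the High shoulder
saturates at 99.2 %, comfortably below the ceiling.

Three rules map the fuzzified sample to the three classes. Calm conjoins
Low(HR), Low(PRV), Low(RR), High(SpO2), High(GSR), High(BT), Low(SBP),
Low(DBP); Normal conjoins the eight Normal degrees; Stressed is the mirror
of Calm. GSR enters as skin *resistance*, so stress-induced sweating drives
it Low — the sign conventions of the rule base and of the cohort simulator
agree on this. The rule conjunction is configurable (`engine_config()`):
`min`, `product`, or arithmetic `mean`, with `mean` as the default. The
source material does not define its conjunction operator, and the choice
matters: under an eight-way `min` or `product`, any single parameter that
disagrees with a rule's direction zeroes the whole rule, and for realistic
mixed samples all three rules vanish — the weighted-average denominator
becomes zero and the score is undefined. The test suite exhibits exactly
this on its mixed fixture. The mean keeps activations graded and the
denominator positive for any sample that is not simultaneously outside
every transition region of every band, which is why it is the default; the
conjunctive t-norms remain available for fidelity experiments.

Defuzzification is the weighted average of singleton consequents,
$\mathrm{score} = (R_1 + 2R_2 + 3R_3)/(R_1 + R_2 + R_3)$ — a Sugeno-style
rule-consequent average rather than a geometric centroid, implemented as
printed in the source material. Its two useful identities — bounds
$[1, 3]$ whenever the denominator is positive, and exact symmetry (equal
activations give exactly 2) — are asserted property-style over randomised
activations. When all three activations are zero the default policy scores
the sample 2 (Normal) and flags it `degenerate = TRUE`; a strict mode
errors instead. The fallback is deliberate: an all-zero pattern carries no
directional evidence, and Normal is the only class that does not raise or
dismiss an alarm. Score-to-label thresholds are 1.5 and 2.5 (nearest
integer on the 1–3 scale), with boundaries assigned to Normal.

## Clinical bands

Crisp banding (`classify_parameter()`) assigns the cut points themselves to
Normal, following the strict inequality signs of the reference table (Low
"<60" means 60 is not Low). Glucose banding is prandial-state-specific:
fasting 70/99/125 mg/dL, post-meal 70/139/199 mg/dL for the
hypoglycemia/normal/pre-diabetes/diabetes boundaries. The fasting table
leaves the open interval (99, 100) unassigned; we classify it normal,
taking the pre-diabetes band to start at 100. The overall blood-pressure
band (High if either component is High, else Low if either is Low) is
package plumbing — component bands are the primary output.

## PPG synthesis and parameter extraction

The estimator algorithms of the original sensing chain are not published,
so standard textbook methods are fixed here and documented as design
choices; fidelity to the original firmware is not claimed.

The generator (`synthesize_ppg()`) produces two channels at 300 samples/s:
Gaussian pulses at the requested heart rate (optionally with fractional
inter-beat jitter), multiplied by a respiratory amplitude modulation (depth
0.15) and added to a respiratory baseline wander, on a unit DC level. The
red channel scales the *entire* pulsatile component of the IR channel by
the ratio-of-ratios $R$ obtained by inverting the calibration line, so any
linear AC measure recovers $R$ exactly on clean signals.

Extraction: peaks are local maxima of the one-second moving-average
detrended signal above 40 % of its 99.5th percentile, with a 0.25 s
refractory period (the local-maxima primitive is `pracma::findpeaks`). HR
is $60000/\overline{\mathrm{IBI}}$; PRV is RMSSD by definition,
$\sqrt{\mathrm{mean}(\Delta \mathrm{IBI}^2)}$. RR interpolates the detected
peak heights onto a uniform 4 Hz grid and takes the dominant
zero-padded-periodogram frequency in the respiratory band 0.1–0.5 Hz; the
dominant line's share of in-band power is reported as a confidence, and
below 0.2 the estimate is flagged low-confidence (an unmodulated pulse
train has no respiratory information). SpO2 uses the ratio-of-ratios with
AC = per-window standard deviation, DC = per-window mean, mapped through
the default calibration $110 - 25R$ (configurable), clipped to $[0, 100]$.
The windowed driver (`extract_vitals()`) uses an 8 s window with a 0.5 s
hop — two estimates per second of signal, matching a front end that reports
each parameter twice per second — with RR computed on a 32 s trailing
window since the respiratory band needs several breathing cycles.

Round-trip accuracy on clean synthetic signals (HR within 2 beats/min, RR
within 1 breath/min, SpO2 within 0.5 %) is asserted in the tests. These
tolerances bound generator-plus-estimator consistency, not accuracy on real
PPG: the synthetic waveforms have no motion artifacts, no sensor coupling
drift, and a noiseless calibration.

## The synthetic cohort

`generate_cohort()` draws 128 subjects (68 male, 60 female) with ages from
a normal distribution (mean 42, SD 17) truncated to 12–75 years — the
demographics of the study population the package emulates. The published
per-sex means (41/43) are collapsed to the overall distribution by default.
Truncation to an asymmetric window shifts the realised mean slightly above
42 (the lower tail loses more mass); the acceptance tolerance of ±2 years
absorbs this. Per-subject baselines span the normal-to-diabetic range:
fasting glucose from a truncated normal (mean 125, SD 30, on 80–190
mg/dL), with resting blood pressure mildly coupled to the glucose baseline.

`generate_series()` emits 5 days × 4 daily phases per subject: 40 min
after breakfast, after the morning medication has taken effect, before
lunch, and 40 min after lunch (clock times 08:40, 10:00, 12:20, 13:10 with
breakfast 08:00, medication 08:30, lunch 12:30 — the published protocol is
ambiguous about clock times, so these defaults are documented and
configurable through the phase table). Glucose follows baseline + a
piecewise-linear meal pulse peaking 40 min after eating (default rise 55
mg/dL, decaying over two hours) − a medication effect ramping to full over
60 min (default 40 mg/dL), + stress coupling + noise. The 40 and 60 min
latencies are the physiological anchors of the protocol; the magnitudes
are chosen so post-meal readings cross glucose bands for diabetic
baselines.

The latent stress class is an iid per-record categorical with uniform
prevalence by default — the emulated study had no instrumental stress
ground truth beyond self-assessment, so nothing in the data constrains a
richer latent process. One consequence is worth spelling out: because meal
and medication pulses move glucose independently of stress, the
within-subject stress–glucose rank correlation is exactly 1 at zero noise
only *within a protocol phase* (where glucose = baseline + a phase
constant + coupling × stress is strictly monotone in stress); pooled
across phases it is positive but below 1. The tests check the within-phase
identity.

Each of the eight parameters is placed at a representative point inside
the band its latent class implies — the band midpoint for Normal, or 30 %
of the band width beyond the cut for the open Low/High bands — plus
Gaussian noise. The 30 % offset is deliberately larger than the 10 % fuzzy
transition half-width, so at zero noise every sample is crisply in band
and the engine must recover the latent class; this parameter-recovery
property (accuracy ≥ 0.95, realised at 1.0) is the package's main
validation surface, since the original study's confusion matrix was
computed on a non-redistributable patient database and cannot be
reproduced. Blood pressure additionally receives the stress coupling
(default 2 mmHg per level, half for diastolic) and the glucose-excursion
coupling (default 0.05 mmHg per mg/dL), both small enough to stay within
the class band at zero noise. Default noise SDs (HR 2, PRV 3, RR 0.8,
SpO2 0.3, GSR 2, BT 0.15, SBP 3, DBP 2, glucose 6, in parameter units) are
plausible short-term measurement scatter for wearable sensors;
`noise_scale` multiplies them globally, and recovery accuracy is checked
to degrade monotonically in it (averaged over ten seeds at scales 0, 1,
2.5, 5 on 16-subject cohorts — sizes chosen to keep the full suite under
half a minute; the zero-noise check runs at the full 128 × 20).

What the simulator does *not* model: pharmacokinetics beyond the
piecewise-linear pulses, circadian rhythm beyond the four phases,
inter-parameter correlations within a class other than through the latent
class itself, autocorrelated measurement error, or missing data. Passing
recovery tests therefore demonstrates the engine's correctness on data
matching its own band conventions, not clinical accuracy.

## Evaluation metrics

`confusion()` cross-tabulates true against predicted classes;
`per_class_metrics()` derives one-vs-rest TP/TN/FP/FN per class and
sensitivity, specificity, precision, accuracy and F1. "Accuracy" is
per-class one-vs-rest accuracy $(TP + TN)/N$ — the only reading under
which a five-metric-per-class table is coherent. Any ratio with a zero
denominator is reported as `NA`, never 0, so a class absent from both
truth and prediction cannot masquerade as perfectly classified. The
published metric table itself is checked only for internal consistency
(its F1 row is the harmonic mean of its precision and sensitivity rows to
two decimals), which is the strongest check available without the original
database. Correlations (`correlate()`) report both Pearson and Spearman;
constant series are flagged rather than silently returned as zero.

## Numerical and degenerate-input conventions

- Membership degrees are clipped into $[0, 1]$ after the piecewise-linear
  evaluation, so floating-point overshoot at vertices cannot escape the
  unit interval; at most two of the three degrees are nonzero because the
  transition half-width is constrained below half the band width.
- Score-to-label boundaries (exactly 1.5 or 2.5) are assigned to Normal.
- All-zero rule activations follow the configured degenerate policy; the
  vectorised path (`predict.stress_fis`) applies the same policy row-wise.
- `sbp > dbp` is enforced by the validator, and the simulator clamps
  diastolic below systolic after adding noise.
- Seeds: the cohort seed fixes subject generation; per-subject series use
  a seed derived from the cohort seed and the subject index, so a subject's
  series is reproducible independent of how many subjects are generated.

## Known limitations

The rule base treats the eight parameters symmetrically and the PRV rule
direction follows the published rule table (High PRV under stress), which
disagrees with the common clinical observation that stress depresses
short-term HRV; users fitting real data may want to flip that direction
and re-validate. The three-class scale has no severity gradation within
Stressed. The engine performs no learning: membership parameters are fixed
by the reference ranges, and tuning them to a labelled dataset is out of
scope.
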