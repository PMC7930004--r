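---
title: "Classifying driver mental workload from physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver mental workload from physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A driver in a conditionally automated vehicle may be resting or absorbed in
a demanding secondary task, and the two states call for different takeover
expectations. `physiowork` studies whether that binary mental-workload state
can be read from three peripheral channels — electrocardiogram (ECG),
electrodermal activity (EDA) and respiration (RESP) — recorded over a 5-min
rest baseline followed by a 20-min drive at 1000 Hz. The pipeline is: raw
channels → derived event series → a 61-indicator catalog per analysis
window → baseline-delta features → ANOVA selection → cross-validated
classification across all sensor fusions and segmentation levels.

Because raw recordings of this kind are rarely shareable, the package ships
a synthetic cohort generator with full ground truth. Everything downstream
of the generator treats its output exactly as it would treat imported
recordings (`read_recording()` accepts the same CSV + manifest format that
`write_recording()` emits).

## The synthetic cohort and what it does (not) emulate

`sim_config()` encodes the protocol: 300 s baseline, 1200 s drive, 1000 Hz,
and two `sim_params()` sets. The baseline is always generated from
control-condition parameters; the drive uses the condition-specific set.
The task condition shifts four parameters upward, in the directions
consistently reported for cognitive load on peripheral physiology: heart
rate (+7 beats/min, i.e. shorter inter-beat intervals), tonic skin
conductance (+0.5 uS), non-specific skin-conductance response (SCR) rate
(+5/min) and breathing rate (+2 cycles/min). The magnitudes are package
defaults, chosen once as mid-sized effects a cognitive secondary task
plausibly produces; no published magnitudes exist for this protocol, so
they are overridable in `sim_config()`.

Subject heterogeneity matters more than channel noise for this design.
Stable traits (`between_sd`: e.g. 7 beats/min across subjects) are drawn
once per subject and shared by both phases, so baseline-delta features
cancel them; per-phase offsets (`within_sd`: e.g. 3 beats/min) model
session-level drift and are what ultimately limits classification accuracy
in the simulator. With the defaults, the standardised group separation of
the heart-rate delta feature is ~1.6, and multi-signal fusion pushes
cross-validated accuracy above 0.9 — comparable to what driving studies
report, though the simulator is not calibrated to any one of them.

Mechanisms emulated: respiratory sinus arrhythmia (heart periods modulated
sinusoidally within each breath cycle, peak-to-trough `rsa_gain`),
breath-cycle jitter, a Bateman-shaped SCR train with a refractory period
over a random-walk tonic level, and white channel noise. Not emulated:
ECG morphology beyond the QRS deflection (the pipeline only detects
R-peaks), motion artifacts, ectopic beats, electrode drift/detachment,
stimulus-locked SCRs, and any coupling of physiology to driving events.
Green tests therefore certify the computational pipeline, not robustness to
real-world artifact; on real data the range gates (inter-beat intervals
outside 300–2000 ms, breath-to-breath intervals outside 1.5–15 s are
flagged) are the only artifact defence provided.

## Preprocessing chain

* **ECG** — zero-phase windowed-sinc FIR band-pass, 3–45 Hz, kernel length
  set by a 2 Hz transition width. R-peaks: rectified derivative, 80 ms
  moving-window integration, block-adaptive threshold, 250 ms refractory,
  then relocation to the extremum of the filtered signal. On clean
  synthetic input the round trip recovers peak times within 10 ms.
* **EDA** — block-mean decimation to 50 Hz, FIR low-pass at 5 Hz, box
  smoothing over 37 samples (three quarters of the 50 Hz rate).
* **RESP** — second-order Butterworth band-pass 0.1–0.35 Hz applied through
  its squared magnitude response in the frequency domain (the
  forward–backward equivalent, numerically safe at cut-offs this far below
  Nyquist), optionally followed by a 3 s rectangular smoothing window
  (`preprocess_resp(smooth = TRUE)`, the default). The box window is a
  blunt instrument: it attenuates a 0.25 Hz tone to ~0.30 amplitude and its
  first spectral null falls at 1/3 Hz — 20 cycles/min, a physiological
  breathing rate — so the cohort pipeline segments breath cycles on the
  band-passed signal *without* it; fast breathers would otherwise lose most
  of their cycles. Breath cycles are segmented trough-to-trough with a
  1.5 s minimum cycle and low-amplitude cycles merged away; inspiration is
  trough→peak.

All filters are zero-phase; a causal chain would shift events relative to
ground truth and complicate the round-trip tests without adding realism.

## The electrodermal decomposition

The filtered 50 Hz signal is modelled as tonic + phasic + noise, with the
phasic term a non-negative sparse driver convolved with a bi-exponential
kernel (0.7 s rise, 2 s decay constants) and the tonic term a cubic
B-spline with 10 s knots. The decomposition solves the convex program

$$\min_{q \ge 0,\, l}\ \tfrac12\lVert y - Hq - Bl\rVert^2
  + \alpha\, 1^\top q + \tfrac{\gamma}{2}\lVert l\rVert^2$$

by block coordinate descent implemented in C++: exact non-negative
soft-threshold updates on a 0.5 s driver grid alternate with the
closed-form ridge solution for the spline, with over-relaxation
(`omega = 1.9`) on the tonic block — the two blocks share a low-frequency
subspace along which plain alternation converges slowly. The ridge is
applied to the mean-centred signal so boundary coefficients shrink toward
the signal mean rather than 0 uS. Defaults: `alpha = 0.5` (in uS·samples;
the induced soft threshold is ~0.01 uS, far below the SCR criterion),
`gamma = 1e-2`, tolerance 5e-4 uS on the largest update. On noise-free
input the residual RMS is well under 1% of signal RMS.

SCR events are read from the phasic trace: alternating extrema are
simplified by prominence merging (swings under half the amplitude criterion
are staircase artifacts of the discrete driver grid), and each remaining
trough→peak deflection of at least 0.05 uS (configurable; the literature
reports no single standard) becomes an event with onset, peak, amplitude,
rise time and half-recovery time. Two true SCRs closer than a few seconds
merge into one detected event; the generator's refractory spacing keeps
this rare at the default rates.

## The indicator catalog

Exactly 61 indicators per window: 10 electrodermal (level statistics of the
filtered and tonic traces, mean NS-SCR amplitude, NS-SCR frequency), 27
cardiac, 19 respiratory and 5 respiratory-sinus-arrhythmia values. Cardiac
and respiratory interval series share a 16-indicator core: mean rate
(60000/mean interval in ms), mean, median, MAD, SD, SDSD, CV, mCV, RMSSD,
CVSD, LF/HF band powers and their ratio, and the Poincare axes SD1, SD2,
SD2/SD1. Conventions worth stating:

* **MAD** is the *mean* absolute deviation about the median (a
  `mad_type` switch gives the median absolute deviation); mCV = MAD/Median.
  The median indicator is the median of the intervals themselves.
* **SD1 = RMSSD/√2 exactly.** The variance-of-differences estimator
  differs when the mean successive difference is non-zero; the RMSSD-based
  form keeps the identity `SD1 = RMSSD/√2` exact, which the test suite
  asserts. SD2 = √(2·Var − SD1²); CSI = SD2/SD1, CVI = log10(16·SD1·SD2),
  modified CSI = 4·SD2²/SD1 (ellipse axes 4·SD1, 4·SD2).
* **Spectra** are Welch estimates (Hann, 120 s segments, 50% overlap,
  per-segment linear detrend) of the interval series cubic-spline resampled
  at 4 Hz; bands LF 0.04–0.15, HF 0.15–0.4, VHF 0.4–0.5 Hz, normalised
  powers dividing by the 0.04–0.5 Hz total. The very-low band is never
  computed: it is uninterpretable on sub-5-min windows. Windows under 60 s
  or 16 intervals yield missing values — at segmentation level 40 (30 s
  windows) the frequency-domain indicators are structurally absent.
* **pNNx** uses strict inequality with a 1e-9 ms epsilon against float
  noise from time arithmetic. The interval histogram uses 1/128 s bins;
  HTI = n/modal count; TINN is the base of the least-squares triangle with
  apex fixed at the mode.
* **DFA2** (box sizes 16–64) is reported only beyond 640 breath cycles,
  which a 20-min session cannot reach — within-session windows carry a
  missing value by design, and the imputation/selection stages downstream
  handle the resulting constant column.
* **RSA**: the peak-to-trough estimate per breath cycle subtracts the
  shortest heart period ending during inspiration from the longest ending
  in the cycle; cycles with fewer than two heart periods in the cycle or in
  its inspiration are invalid and counted in `rsa_norsa`. The band-variance
  estimate is ln of the variance (ms²) of the 0.12–0.40 Hz band of the
  resampled heart-period series.

Missing indicator values are sentinels (`NA`), imputed downstream by the
training-fold median (all-`NA` columns fall back to 0 and are then
constant, hence never ANOVA-selected).

## Features, selection and validation

The drive is split into L equal contiguous windows (levels 1, 2, 5, 10, 20,
40 by convention; any positive integer works). Baseline indicators are
computed once over the full 5-min baseline regardless of L. Each indicator
contributes its window value and its baseline delta, so all three signals
give 122 features; RSA features require both ECG and RESP and are included
in exactly those selections.

Per-feature one-way ANOVAs across the two conditions keep features with
p < 0.05. By default selection is re-fitted inside every training fold, and
min-max scaling (for the scale-sensitive SVC and MLP) is learned on
training rows only; `pooled_mode = TRUE` reproduces the simpler global
variant (selection and scaling fitted once on all rows, row-level folds),
which is how such pipelines are often described but leaks validation
information at segmentation levels above 1. Folds are stratified by class
and grouped by subject — windows of one subject never straddle folds —
because at L > 1 row-level folding lets a classifier recognise subjects
rather than states.

Classifiers are deliberately the field's stock choices behind a thin
wrapper: random forest (`ranger`, √p features per split), C-support vector
classification (`e1071`, linear or RBF), and a single-hidden-layer
perceptron (`nnet`, which optimises by quasi-Newton BFGS; the grid's
`solver` field is accepted for completeness but both labels map to that
optimiser, and `random_state` seeds the weight initialisation). The
two-stage search mirrors common practice: a wide stage-1 grid screened on a
75/25 split (candidates within 2 accuracy points of the best are retained —
a numeric stand-in for narrowing "by inspection"), then one full k-fold
pass per stage-2 combination, reporting the set with the best mean
accuracy; ties break in declared enumeration order. Decade-stepped ranges
are interpreted multiplicatively (×10).

## Problem sizes used by the tests and acceptance script

The statistical checks run the full study conditions — 90 subjects, 5 + 20
min at 1000 Hz, default effect sizes — which the package processes at
roughly 2.5 s per subject. To keep the whole-design evaluation proportional
to what the checks actually assert, the acceptance test evaluates the
7-selection × 3-classifier grid at segmentation level 1 (with the one-point
reduced grid) over three cohort seeds plus one null cohort, and the
acceptance script evaluates levels 1 and 5 on one cohort seed plus a null.
The nominal-level property of the ANOVA selector under exchangeable groups
is averaged over 20 reduced-duration null cohorts, since exchangeability
does not depend on recording length. Oracle-equivalence checks compare
every time-domain and Poincare indicator against independently coded
brute-force evaluation at 1e-9 relative tolerance, and Welch band powers
against an explicit-DFT reference.

## Known limitations

* EDF input is not supported; recordings move as CSV + JSON manifest.
* The MLP has no stochastic-gradient (adam) path; iteration-limited BFGS
  stands in for both solver labels.
* Closely overlapping SCRs merge; amplitudes under the 0.05 uS criterion
  are invisible by construction.
* The simulator's independence assumptions (white IBI noise beyond RSA, no
  LF cardiovascular rhythms, context-free SCR timing) make frequency-domain
  and nonlinear indicators less informative than they may be in real data;
  accuracy figures from synthetic cohorts characterise the pipeline, not
  the sensors.
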