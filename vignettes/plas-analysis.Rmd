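---
title: "Simulating and analysing phase-locked acoustic stimulation of sleep slow waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing phase-locked acoustic stimulation of sleep slow waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaslab)
```

## The problem

Phase-locked acoustic stimulation (PLAS) presents brief sounds timed to the
peaks of sleep slow waves (~1 Hz oscillations of deep non-REM sleep) in order
to amplify slow-wave activity and its downstream benefits for memory
consolidation and amyloid clearance. Multi-night intervention studies in older
adults compare a baseline (sham) night, on which the detection algorithm
places markers silently, against consecutive experimental nights with real
stimulation, and relate the evoked electrophysiological response to memory
gains and to the change in the plasma amyloid-beta 42/40 ratio. Cognitively
impaired participants are expected to respond with a *delay*: their evoked
response grows across nights, and their behavioural and biomarker
associations surface only at late follow-up.

`plaslab` implements this whole chain as testable code. Because raw data
from such studies are generally not deposited, the package's first module
is a synthetic-data generator that reproduces the statistical structure the
analysis assumes; every downstream stage is exercised against it.

## The synthetic cohort and what it emulates

`generate_cohort()` draws participant profiles for a healthy (HC) and a
cognitively impaired (CI) group. The defaults encode the study conditions:

* group sizes 18 HC / 16 CI, HC ages ~N(68.3, 5.1), CI ~N(71.9, 4.0) years,
  gender probabilities matching the reported 14/18 vs 6/16 female imbalance;
* a latent **responsiveness** (unitless, >= 0) — the participant's evoked
  second-slow-wave-peak magnitude per unit stimulation;
* **night gains** scaling the evoked response per experimental night:
  constant `c(1, 1, 1)` for HC and the non-decreasing ramp
  `c(0.4, 0.7, 1.0)` for CI. This is the delayed-response mechanism; it is a
  modelling choice calibrated only against the qualitative claims (CI
  response rises across nights, group difference shrinks by night 3), since
  no quantitative ramp is established in the literature;
* slow-wave event densities (mean 5/min of N2+N3 for HC, 3/min CI) and
  amplitudes (75 vs 50 uV at the frontal maximum, SD 15). The clinical
  literature agrees that impaired individuals show fewer and smaller slow
  waves but offers no canonical numbers; these are plausible defaults,
  exposed in `plas_config()`.

`generate_night()` renders one participant-night: a fixed-proportion
hypnogram cycling W -> N1 -> N2 -> N3 -> N2 -> REM (a deliberate
simplification — the analysis only needs credible N2/N3 segments, not
realistic sleep microarchitecture), independent 1/f background noise per
channel (20 uV SD), slow-wave events at a Poisson rate within N2/N3 epochs,
and centroparietal 12–16 Hz spindle bursts within N2. The 128-channel layout
is a golden-angle spherical spiral with `Fz` and `Cz` snapped to canonical
positions; real geodesic net coordinates are proprietary, so electrode
subsets ("17 frontal around Fz", "13 centroparietal around Cz") are defined
by spherical distance to the anchors.

The slow-wave kernel is an asymmetric biphasic raised cosine: a shallow
0.65 s descent into the down-state trough, a steep 0.3 s rise to the
up-state peak, and a 0.25 s decay (~1.1 s total, i.e. ~0.9 Hz). The short
trough-to-peak rise mirrors real slow-oscillation morphology and is what
makes a stimulus delay of at most a couple hundred milliseconds able to
coincide with the predicted peak; a symmetric cycle would put the criterion
crossing ~0.4 s ahead of the peak, outside any sensible delay calibration.

Simulation runs directly at the 200 Hz analysis rate; `raw_rate` can be set
higher to exercise the anti-alias downsampler.

### What passing tests do and do not show

The generator contains exactly the structure the pipeline estimates:
rank-one evoked responses with known topography, linear outcome models,
Gaussian/Poisson noise. Green tests therefore demonstrate *correctness of
the estimators under the assumed model* — detector timing, unbiased slope
recovery, calibrated error rates. They do not demonstrate robustness to
real-EEG pathologies the generator omits: non-stationary artifacts, K
complexes and arousals, correlated channel noise, electrode drift, or
staging errors.

## The online peak-prediction algorithm

`detect_stream()` is a causal re-implementation of the template-based
stimulation algorithm. Per sample it tracks the mean voltage of the frontal
channel subset and the topographic similarity of the instantaneous scalp
map to a canonical slow-wave template (`build_template()`: a unit-norm
frontal-positive/posterior-negative gradient). A peak prediction is scored
when, over the trailing 120 ms window, the average sign of the first
derivative of *each* series exceeds 0.75 (the ambiguity between a joint and
per-series average is resolved to per-series, the stricter reading), and
the current map is positively template-correlated. The stimulus marker is
emitted `delay_ms` later; `calibrate_delay()` estimates that delay as the
median crossing-to-peak lead time, clipped to [0, 200] ms. A 2.5 s
refractory lockout (matching the post-stimulus analysis window, a choice this package
makes) prevents retriggering on the algorithm's own evoked response.
No audio is synthesised — the marker carries a stimulus descriptor (50 ms
pink noise) instead.

Numerical choices worth knowing:

* **Similarity.** The default is the centred covariance of the map with
  the template (a matched-filter projection). The spatial Pearson
  correlation (`similarity = "pearson"`) saturates at +-rho whenever one
  spatial pattern dominates, which makes its derivative uninformative on
  clean signals; the projection preserves the monotone rise in all regimes.
* **Polarity gate.** Rising voltage plus rising similarity alone cannot
  distinguish a template-matching wave from an anticorrelated pattern whose
  projection is merely decaying back to baseline (both series are
  proportional for any rank-one signal). Predictions therefore additionally
  require positive instantaneous similarity.
* **Front-end smoothing.** A 40 ms causal moving average precedes the sign
  criterion. On broadband background noise the raw per-sample derivative
  sign is noise-dominated; closed-loop systems operate on delta-band-limited
  signals, and the trailing average is the causal equivalent. Its group
  delay is absorbed by the calibrated stimulus delay.
* Windows are half-open `(t - 120 ms, t]`, evaluated every sample; sham
  markers are placed with identical logic on the baseline night.

`evaluate_detection()` benchmarks markers against ground truth by greedy
one-to-one matching within a tolerance, and `offline_peak_oracle()` provides
the non-causal argmax reference the online algorithm is compared with.

## Preprocessing

`downsample()` applies a zero-phase 8th-order Butterworth low-pass (0.8 of
the target Nyquist) before integer decimation. `reject_artifacts()` is a
deliberately simplified stand-in for a full preprocessing pipeline:
per-channel amplitude (300 uV) and jump (50 uV/sample) limits with 250 ms
padding, a per-channel z > 5 outlier rule on 1 s high-frequency activity
windows, bad channels by flatline or > 30 % masked samples, and a global
mask as the union over good channels. `gate_stages()` restricts analysis to
N2/N3 samples, excluding artifacts; epochs overlapping any artifact sample
are dropped before averaging (whether the original pipeline excluded them
before epoching or only from spectral estimates is unstated; dropping whole
epochs is the conservative reading).

## ERP analysis and the response score

`epoch_recording()` cuts trials at [-1.5, 3] s around each marker
(inclusive endpoints: 901 samples at 200 Hz). `baseline_correct()`
subtracts each trial-channel's mean over the *whole epoch*, so each trace
has exactly zero mean. Note this baselines on the *whole epoch*, not a
pre-stimulus window. The per-participant electrophysiological response
(`erp_response_score()`) is the mean Fz voltage difference between each
experimental night's ERP and the baseline night's ERP over 1–1.5 s
post-stimulus (the induced second slow-wave peak; the mean, not the peak,
following the "averaged voltage" phrasing), combined across nights E1–E3
weighted by each night's stimulation count.

## Cluster-based permutation statistics

`cluster_permutation()` implements the cluster-mass permutation scheme:
bin-wise pooled two-sample t statistics over trials; thresholding at the
point-wise two-tailed p < 0.05 t value (the conventional cluster-forming
default); sign-consistent connected
components under channel adjacency (spherical distance <= 0.6 rad by
default) plus +-1 adjacency along time and frequency; cluster mass as the
summed t; and a null distribution of the maximum absolute cluster mass over
random relabelings of trials (1000 by default, with the RNG seed under the
caller's control). Cluster p values are floored at `1/(n_perm + 1)`;
degenerate-variance bins never enter a cluster. The permutation core is
compiled (Rcpp) so that calibration studies — 500 null simulations at a
reduced 8-channel grid with 200 permutations — run in minutes. ERP
contrasts use alpha = 0.05; time-frequency contrasts use alpha = 0.01
(`tfr_cluster()`).

## Time-frequency analysis

`morlet_tfr()` computes complex Morlet power per trial (FFT convolution),
averaged over trials, on a 0.5–20 Hz grid with cycles increasing linearly
3 -> 7 across the grid, a common compromise between temporal and spectral
resolution at the low end; the cycle mapping is recorded in the output
metadata. Wavelets are normalised to unit gain at their centre
frequency; bins within two envelope SDs of the epoch edges are flagged.
`baseline_db()` expresses power as `10*log10(P / mean P over 2–2.5 s)`, the
quietest window of the epoch. Band scores (`band_response_score()`) subtract
the baseline-night median from each experimental night's median over fixed
band definitions (slow waves 0.75–1.5, delta 1–4, theta 4–8, spindle 12–16,
beta 16–20 Hz; spindle over the 13 centroparietal electrodes, all others
over the 17 frontal ones) and weight nights by stimulation counts. Where a
printed band table once says beta is 12–16 Hz, the 16–20 Hz definition is
used.

`summed_activity()` is the per-participant-night statistic capturing both
height and extent of the induced spectral change: the group-level
significant-cluster mask restricted to 0–2.5 s and 0–16 Hz (intersected
with the computed grid, so effectively 0.5–16 Hz); per masked bin the
absolute dB ratio `|10*log10(P_exp / P_bl)|`; exclusion of bins more than
1.5 SD above the participant-night mean (the values are absolute
magnitudes, so pruning extremes means a one-sided upper cut; `two_sided = TRUE` is available, and the mean/SD are
computed per participant-night rather than pooled across nights);
remaining bins summed. `night_trend_and_group_tests()` then fits, per
group, an OLS of summed activity on night index (E1=1..E3=3) pooled over
participants and runs pooled-variance t tests between groups per night.

## Cohort statistics

`two_sample_t()` is the pooled-variance Student t with df = n1 + n2 - 2
(the printed degrees of freedom imply pooled, not Welch, variances),
accepting either raw vectors or printed summary statistics so published
group comparisons can be recomputed exactly. `yates_chi2()` and
`holm_bonferroni()` delegate to `chisq.test(correct = TRUE)` and
`p.adjust("holm")`. `sleep_architecture_contrasts()` forms per-participant
difference scores (mean of E1–E3 minus baseline) and applies
Holm-corrected between-group and within-group tests, one family per test
battery. `response_regression()` fits the OLS of a memory gain or the
amyloid change score on the response score, whole-sample or per group, with
optional age and gender covariates (gender as a binary indicator, age in
years uncentered), always reporting the unadjusted model alongside;
`baseline_independence_check()` regresses the response on the
pre-intervention amyloid ratio. Two-tailed p values are the default, with
one-tailed options flagged in the output (printed one-tailed p values in
summary tables can otherwise look inconsistent with the t statistic).

## Outcome models and calibration studies

`generate_behavior_and_biomarker()` produces session scores t0–t7 on a
40-item associative memory task: a group-specific saturating learning curve
(feedback sessions t1–t4 act as additional learning runs; scores decay
toward the follow-ups), plus a response-score effect expressed at t5/t6 for
HC and at the 3-month follow-up t7 only for CI, with scores rounded and
clipped to [0, 40]. The amyloid change score is
`abeta_slope * response_score + noise`, with slope 0.002 per uV for CI and
0 for HC, noise SD 0.005, around a pre-intervention ratio of ~0.0695. The
memory effect (1.5 items/uV against ~3-item session noise) and the amyloid
slope were chosen so group-level adjusted R-squared values land in the
0.2–0.35 regime reported for multi-night stimulation studies at
n = 16–18.

For replicate-level studies (hundreds of cohorts), the signal-level chain
would be needlessly expensive, so the synth module also exposes the
cohort-level outcome model directly: `simulate_response_scores()` (measured
score = evoked amplitude x responsiveness x mean night gain + 1 uV
measurement noise) and `simulate_summed_activity()` (50 + 100 x
responsiveness x night gain + 25 noise, floored at zero). These are the
same latent quantities the pipeline estimates, with the estimation error
collapsed into a noise term. `run_participant_pipeline()` runs the full
signal-level chain end-to-end and is validated at reduced scale (16
channels, 8–10 minute nights) in the test suite.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 16–32 channel layouts and
8–20 minute nights for signal-level checks; 500 simulated cohorts (n = 34)
for slope-recovery and null-calibration rates; 500 null simulations on an
8 x 50 (and 8 x 10 x 50) grid with 200 permutations for family-wise-error
calibration; and 200 cohort replicates for the delayed-response pattern.
These sizes give binomial 99 % confidence intervals tight enough to detect
miscalibration while keeping a full run in the minutes range.

Conventions: voltages in uV, times in seconds (marker-relative for epochs),
frequencies in Hz; window endpoints inclusive; all random draws flow from a
single user-supplied seed and RNG state is restored after each generator
call, so every recording, marker set and cohort is exactly reproducible
from `(profile, night, config, seed)`.

## Known limitations

* The canonical template map is a constructed frontal gradient, not the
  original system's calibrated map; it is configurable for that reason.
* The artifact stage is a simplification; it is not a substitute for
  inspecting real recordings.
* The hypnogram model has no transitions within blocks, no arousals and no
  night-to-night variability beyond the random seed.
* Permutation exchange is over trials within participant; the package does
  not implement group-level (participant-as-unit) cluster statistics,
  although `cluster_permutation()` accepts any observations x grid arrays.
* Recordings serialise to a plain-text container (TSV + JSON sidecar),
  not EDF.
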