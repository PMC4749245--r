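---
title: "Methods: AMSA, previous-shock features, and defibrillation outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMSA, previous-shock features, and defibrillation outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amsaShock)
```

# Overview

`amsaShock` implements a complete pipeline for predicting whether a
defibrillation attempt in out-of-hospital cardiac arrest (OHCA) will
convert ventricular fibrillation (VF) into an organized rhythm. The
pipeline has five stages: waveform quantification (AMSA), within-patient
feature construction (PSI, ΔAMSA), model fitting (a small feed-forward
network and a random-intercept logistic model), threshold-based ROC
evaluation at a fixed training specificity, and a synthetic cohort
generator that makes the whole chain testable without clinical
recordings. This vignette documents the models, the tunable parameters,
the numerical decisions, and what the synthetic cohorts can and cannot
tell you about real data.

# Waveform quantification

## The episode

The analysis unit is a 2.05 s ECG segment ending 0.5 s before the shock
(`extract_episode()`, half-open window `[t−2.55, t−0.5)` s). The 0.5 s
guard keeps the charge artifact out of the window; the sample count is
`round(duration × fs)` (512 samples at the 250 Hz default). Any sampling
rate above 96 Hz is accepted so that the 48 Hz band edge stays below
Nyquist.

## Filtering

VF analysis uses a 2–48 Hz band: below 2 Hz lives baseline wander from
chest compressions and pad motion, above 48 Hz mains interference and
EMG. The band-pass is the squared magnitude response of a 4th-order
Butterworth — the exact response of a forward–backward (zero-phase) pass —
applied **in the frequency domain** over the analysis window. Zero phase
matters because AMSA is computed from the same short window; a causal
filter would smear energy asymmetrically across it. The frequency-domain
application is a deliberate numerical choice: on a 512-sample window a
time-domain forward–backward IIR pass has edge transients at the 2 Hz
edge whose broadband leakage measurably biases AMSA, while the
frequency-domain application has the identical nominal response and no
transients. The trade-off is circular (periodic) boundary behaviour,
which is benign for a stationary 2 s VF segment. `bandpass_gain()`
exposes the applied response so it can be verified directly (≥ 20 dB
attenuation at 1 Hz and 96 Hz, ≤ 1 dB ripple mid-band at the defaults).

## Spectrum and AMSA

`amplitude_spectrum()` takes the FFT with a rectangular window and no
zero-padding and returns the single-sided spectrum with the `2|X_k|/N`
normalization (DC and Nyquist bins not doubled), so a bin-aligned
sinusoid of amplitude A mV appears as amplitude A mV at its bin and the
spectral power reproduces the time-domain power (a Parseval check is in
the test suite). AMSA is then literally `sum(A_i * F_i)` over bins with
2 ≤ F_i ≤ 48 Hz, in mV·Hz.

Two conventions deserve emphasis because neither is universal:

- **Window**: rectangular, because the AMSA definition is stated directly
  on FFT amplitudes. A Hann option (amplitude-corrected) is provided; it
  reduces leakage from non-bin components at the price of a wider main
  lobe. With the rectangular window, strong *non-bin-aligned* out-of-band
  interference (e.g. mains hum at an arbitrary frequency) leaks some
  energy into the band even after filtering — a known limitation.
- **Normalization**: absolute AMSA values are meaningful only for
  mV-calibrated input; different devices (and different FFT conventions in
  other software) scale AMSA differently. Within-package values are
  internally consistent; cross-device comparability is not guaranteed.

# Previous-shock features

For a patient's k-th shock:

- `PSI_k` = 0 if k = 1, +1 if shock k−1 succeeded, −1 if it failed;
- `ΔAMSA_k` = 0 if k = 1, else `AMSA_k − AMSA_{k−1}`.

Both are defined on *actual consecutive* shocks. If a shock's episode is
unanalyzable the record is dropped **without re-indexing** (the features
of later shocks keep referring to their true predecessors); a strict mode
treats gaps as an error (`compute_psi()` / `compute_delta_amsa()` refuse
non-consecutive indices). Shock success is the positive class (coded 1)
everywhere.

The four feature sets are `AMSA` = {amsa}, `C1` = {amsa, psi},
`C2` = {amsa, delta_amsa}, `C3` = {amsa, psi, delta_amsa}, in fixed
column order.

# Models

## The feed-forward network

The combiner is intentionally tiny: inputs → 3 logistic-sigmoid units →
2 linear units → 1 logistic-sigmoid output, giving a success probability.
Inputs are z-scored with training-set mean/SD; a zero-variance column
(PSI and ΔAMSA on first shocks) gets scale 1 and hence no influence, which
is why first-shock predictions from C1/C2/C3 reduce to functions of AMSA
alone.

Training minimizes mean cross-entropy plus an L2 penalty `λ Σ w²` over
the connection weights (biases unpenalized). Cross-entropy was chosen
over squared error because the output is a probability feeding an ROC
analysis; a squared-error mode is not provided but the penalty policy is.
Under the default `"evidence"` policy λ is re-estimated between
optimization cycles by the evidence-style update on the summed-likelihood
scale:

- γ = Σᵢ eᵢ / (eᵢ + 2λ), with eᵢ the (positive part of the) eigenvalues
  of the data-misfit Hessian — the effective number of parameters;
- λ ← γ / (2 n Σ w²).

Two safeguards stabilize the fixed-point iteration, which otherwise can
spiral into pruning the entire network when the class signal is weak:
γ is floored at 1 (at least one effective parameter) and λ may grow at
most fourfold per update. The initial λ = 0.001 is deliberately weak —
mean cross-entropy of a near-balanced problem is O(0.7), and a stronger
initial penalty makes the all-zero-weights saddle (where the gradient of
every hidden weight vanishes) the nearest basin before any evidence
estimate exists.

The optimizer runs quasi-Newton (BFGS) segments with monotone acceptance:
a segment's result is kept only if it lowers the objective, so the stored
per-cycle trace is non-increasing by construction. Plain gradient descent
was tried first and stalls on sigmoid plateaus. Training is a pure
function of data and seed; three seeded restarts are run and the best
final objective kept, which guards the 23-parameter network against poor
local minima. Non-convergence within the segment budget flags the model
and warns rather than failing silently. `write_bp_network()` serializes a
model to full-precision JSON (doubles as `%.17g` strings) for bit-exact
reload.

Networks are trained separately per stratum (first vs subsequent
shocks). The stratified ROC analysis implies stratum-specific models, and
pooling would let the abundant subsequent shocks dominate the first-shock
fit.

## Logistic models

`fit_logistic()` wraps `glm` (pooled) and `lme4::glmer` (patient
random-intercept, adaptive Gauss–Hermite quadrature with 15 nodes).
Repeated shocks within a patient are dependent; the random intercept
`b ~ N(0, σ_b²)` is the textbook representation, and the Hausman check
(below) tests that specification. Odds ratios are reported with Wald 95%
intervals on the log scale. Zero-variance covariates are dropped (and
recorded), which keeps first-stratum fits well-posed.

Validation predictions are **marginal**: the random intercept of an
unseen patient is set to its prior mean 0, because it is unobservable at
prediction time. A sequential-update variant
(`predict(..., re_update = TRUE)`) replaces it with its posterior mode
given the same patient's *earlier* shocks — usable in real time, where
previous outcomes are known by the time the next shock is scored. The
marginal rule is the default; on our synthetic cohorts the ranking
difference is minor, and the marginal rule makes no assumption about
which earlier outcomes were observed.

In `run_experiment()` the random intercept is used for the subsequent
stratum only: on first shocks every patient contributes a single row, so
σ_b is not identifiable.

# Evaluation

`roc_curve()` scans all distinct score thresholds with the rule
`score ≥ threshold ⇒ predict success`; the AUC is the Mann–Whitney
concordance (ties count ½), which equals the trapezoidal area of the
stored points exactly.

The operating point is the threshold at 90% **training** specificity.
Exact equality is rarely attainable on finite data, so the rule is: the
smallest threshold whose training specificity is ≥ the target — among
qualifying thresholds this maximizes sensitivity, since sensitivity is
non-increasing in the threshold. The threshold is then frozen and applied
to the validation scores.

Comparisons mirror a clinical-paper test battery:

- paired AUCs: z-test with the placement-value (DeLong-type) covariance
  for correlated curves, since both scores are computed on the same
  validation shocks; an unpaired variant is available and the paired
  variance reduces to it when the placement covariance vanishes;
- proportions (sensitivity, NPV, PPV, accuracy): 2×2 chi-square
  **without** Yates continuity correction by default (correction
  available by flag);
- association among features: Kendall tau-b (tie-corrected — PSI is
  ternary), normal-approximation p;
- group AMSA comparisons: pooled-variance t-test (Welch by flag);
- specification: Hausman test comparing the conditional-logistic
  (fixed-effects, via the exact-ties Cox likelihood stratified by
  patient) and random-intercept estimates,
  `H = (β_FE − β_RE)² / (var_FE − var_RE)` on χ²₁. A non-positive
  variance difference — possible in finite samples — is reported as
  inconclusive with a flag rather than as a number.

Degenerate inputs are handled explicitly: single-class label vectors are
an error for ROC quantities; zero-denominator rates (e.g. PPV with no
predicted positives) are `NaN` with a warning; constant vectors give
Kendall tau 0 with a flag; identical groups give t = 0, p = 1.

# The synthetic cohort generator

## Latent model

Each patient carries a random log-odds intercept `b ~ N(0, σ_patient²)`.
The first shock succeeds with probability `p_success_first`, and its AMSA
is drawn from the outcome-conditional normal (success ≈ 15.9 ± 9.0,
failure ≈ 9.3 ± 5.8 mV·Hz, truncated below at 0.5 mV·Hz — negative
spectral energy is unphysical). Subsequent AMSA follows an AR(1)
carryover with outcome-dependent drift,

AMSA_k = c·AMSA_{k−1} + drift(outcome_{k−1}) + ε,  ε ~ N(0, σ_noise²),

and subsequent outcomes follow

outcome_k ~ Bernoulli( logistic(β₀ + β_amsa·AMSA_k + β_psi·PSI_k + b) ).

Sequence continuation: after a success the patient refibrillates (needs a
further shock) with probability `p_refib`; after a failure resuscitation
continues with probability `p_continue_after_fail`; a hard cap
`max_shocks = 8` applies (the per-patient shock-count distribution of
real series is not well documented; the cap is a guess and flagged as
such).

Three structural choices deserve justification:

- **Refibrillation** (`p_refib > 0`). A model in which sequences stop at
  the first success makes PSI ≡ −1 on all subsequent shocks —
  uninformative by construction, and inconsistent with real series in
  which many subsequent shocks follow a success (recurrent VF). With
  refibrillation, PSI takes both values and its outcome-conditional means
  land on realistic values. `p_refib = 0` recovers the stop-at-success
  model.
- **Censoring after failures** (`p_continue_after_fail < 1`). Without it
  every initially-failing patient runs to `max_shocks`, inflating shocks
  per patient to ~4 against the ~2.6 of real series. It models
  termination of the resuscitation effort; 1 recovers the uncensored
  model.
- **A direct previous-outcome effect** (`β_psi > 0`). With outcome
  depending on AMSA and `b` alone, PSI is conditionally almost
  uninformative given AMSA (the AR carryover puts the relevant history
  *into* AMSA), and no combination could beat AMSA alone — contradicting
  the within-patient-information premise the pipeline exists to test.
  Clinically, a previous successful conversion marks shock-responsive VF
  (e.g. VF type, substrate) beyond what the current waveform shows; β_psi
  is that pathway. `β_psi = 0` recovers the reduced model and is used
  together with `σ_patient = 0` as the no-signal control in the tests.

## Calibration

The defaults (`p_success_first = 0.53`, `p_refib = 0.45`,
`p_continue_after_fail = 0.82`, `c = 0.75`, drifts 4.2/2.1 mV·Hz,
`σ_noise = 4`, `β₀ = −3.9`, `β_amsa = 0.25` per mV·Hz, `β_psi = 0.8`,
`σ_patient = 1`) were fixed once by matching, on a large (2000-patient)
simulation, the joint summary structure of a real 528-shock OHCA series:
overall per-shock success near 38%, subsequent-shock success near 29%,
roughly two thirds of patients needing repeat shocks, ~2.6–3 shocks per
patient, subsequent AMSA ≈ 16–17 vs 8 mV·Hz by outcome, PSI group means
≈ +0.26/−0.81, and Kendall tau(AMSA, PSI) ≈ 0.38 with tau(ΔAMSA, PSI)
≈ 0. The drifts are set near `(1−c)` times the stationary group means so
that ΔAMSA is centered at zero for both previous outcomes, which is what
keeps PSI and ΔAMSA nearly uncorrelated. `calibration_report()` prints
the realized values of all these quantities for any cohort.

Note one deliberate inconsistency with published single-variable
regression results: a conditional AMSA effect of the order 1.03 per mV·Hz
cannot produce the observed ~8 mV·Hz group separation (AUC ≈ 0.82); the
generator is calibrated to the *distributional* summaries, which are what
determine discrimination, so its conditional odds ratios come out larger.

## Waveform synthesis

`generate_vf_waveform()` builds a VF surrogate as ≥ 8 cosines at
frequencies aligned to DFT bins of the analysis window, confined to
3.2–36 Hz (comfortably inside the filter passband), with random phases
and a VF-like spectral envelope peaking near 5 Hz. Amplitudes are
pre-compensated by the known filter response and scaled so that the
measured AMSA equals the target; because every component sits on a bin,
the rectangular-window spectrum has no leakage and the round trip is
exact to machine precision. The surrogate reproduces the *amplitude
spectrum* of VF, not its morphology: no chest-compression artifact, no
non-stationarity, no device transfer function, no VF-type structure.
Passing tests therefore validate the signal-processing and statistical
chain, not clinical performance on real recordings.

# The experiment pipeline

`run_experiment()` wires the stages together: generate (or accept) a
cohort → optionally re-measure AMSA from the episodes through the
waveform path → features → patient-level 50/50 split → per stratum, train
all four feature sets → freeze thresholds at 90% training specificity →
validation metrics plus paired AUC and proportion comparisons against
AMSA. The split is by patient, never by shock: shock-level splitting
would put correlated shocks of one patient on both sides and leak exactly
the within-patient signal the combination features exploit. A single
top-level seed fans out as: generator = seed, split = seed + 1, network
for stratum s / feature set j = seed + 100·s + j; identical configs give
identical results (a determinism test runs the pipeline twice and
compares everything).

# Problem sizes used by the test suite

The suite's simulation scales were chosen as the smallest designs whose
statistical checks are well-powered rather than coin flips: coefficient
recovery uses 300 patients × 8 shocks with AMSA SD 12 (estimator SD
≈ 0.005 around the true 0.03, so the [0.02, 0.04] acceptance band is a
~95% event per replicate, checked over 100 replicates); null calibration
of the paired AUC test uses 1000 replicates of n = 150; the Hausman
type-I check uses 500 replicates of 200 patients × 3 shocks; the
directional end-to-end claim uses 50 replicate cohorts of 199 patients.
The replicate experiments feed the generator's latent AMSA directly to
the feature stage (`use_episodes = FALSE`): the waveform round trip is
exact to ~1e−14 relative and is validated separately, so synthesizing
half a million samples per replicate would add cost without information.

# Known limitations

- Absolute AMSA values are convention- and calibration-dependent;
  only mV-calibrated input gives the usual clinical 5–25 mV·Hz range.
- Rectangular-window leakage from strong non-bin out-of-band interference
  can inflate AMSA; use the Hann option if mains hum survives the
  front-end.
- The generator emulates summary structure, not VF morphology or CPR
  artifacts; conclusions about real-world sensitivity gains require real
  recordings.
- Rhythm classification (shockable vs not) and compression-artifact
  suppression are out of scope; outcome labels are inputs.
- The random-intercept model assumes exogenous patient effects; the
  Hausman test is provided precisely because that assumption can fail,
  and on cohorts with a direct previous-outcome pathway it should (and
  does) flag the reduced specification.
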