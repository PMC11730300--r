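---
title: "Electrocardiographic aging effects: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrocardiographic aging effects: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep models that predict a person's age from their 12-lead ECG ("ECG-age")
read out a biological property of the myocardium: when the predicted age
exceeds the chronological age by more than 8 years ("Overestimation",
δ_age = predicted − chronological > 8 y), subjects carry an elevated risk of
atrial fibrillation, heart failure and death, while δ_age < −8 y
("Underestimation") is protective. Repeating the ECG 5–6 years later and
requiring a *consistent* group assignment across both exams strengthens the
association further.

`ecgaging` packages this analysis chain as reusable, tested components:

1. a seeded synthetic 12-lead ECG and longitudinal cohort generator,
2. signal-quality scoring, per-lead R-peak detection, 7-lead/10-ms consensus
   and 650-ms beat segmentation,
3. a differentiable surrogate ECG-age model with δ_age grouping, the 40–75 y
   screening filter, serial-consistency categories and validation metrics,
4. integrated-gradients relevance maps, beat-aligned aggregation and lead
   importance,
5. clinical interval measurement (P, PR, QRS, QT/QTc) with group tests,
6. Kaplan–Meier, Cox and logistic risk models plus the serial analysis with
   its label-leakage guard.

Real study data of this kind are access-restricted, and the published deep
network is out of scope here; the generator + surrogate pair is the test
harness on which every pipeline property is verified.

## The synthetic cohort generator

**Waveforms.** Each beat is a sum of smooth Gaussian deflections (P, R, S, T)
placed so that the 5%-of-peak onsets and offsets realise the configured
intervals exactly: a deflection of nominal duration *d* gets
σ = *d* / (2·√(−2·ln 0.05)). Per-lead amplitudes come from a fixed canonical
12-lead projection table; the R amplitude interpolates between a
left-precordial-dominant and a V1–V3-dominant template with the
`r_progression` factor (early R progression, a correlate of right-ventricular
remodelling, increases with age). Lead II carries a pure R deflection so that
threshold-based interval measurement on lead II is exact by construction.
White Gaussian noise of configurable sd (a scalar, or a per-record range to
emulate varying signal quality) is added last.

**Intervals.** All four intervals are strictly increasing affine functions of
biological age with Gaussian jitter (sd 5 ms by default):
P = 85 + 0.35·a, PR = 130 + 0.60·a, QRS = 80 + 0.25·a and, at 60 bpm,
QT = 360 + 0.70·a ms (+10 ms QTc for females), with QT Bazett-scaled by √RR.
These slopes reproduce the direction of the published age trends without
claiming their (unprinted) magnitudes. Heart rate is 62 ± 3 bpm; the T-wave
width is fixed at 160 ms so that the QT information is carried by the T-wave
*position* — this keeps the interval features of the surrogate identifiable.

**Cohort.** Baseline ages are uniform on 38–72 y; each subject receives a
persistent latent aging offset from a three-component mixture
(N(+14, 4) / N(0, 5) / N(−14, 4) years at equal weights — the ±14 y centres
clear the ±8 y grouping threshold with margin). Per-exam latent groups add a
transient N(0, 6 y) wobble, emulating the exam-to-exam instability of a
predictor whose single-exam MAE is of the order of 8 years; this is what
creates group transitions between exams. Survival is exponential with
administrative censoring at 21 y; the hazard multiplies a baseline rate
(0.012/y) by the latent-group multiplier (defaults 1.4 / 1.0 / 0.65), a
log-linear age term (0.07/y), male sex (×1.49) and comorbidity multipliers.
With `hazard_scope = "serial"` the multiplier is keyed to the (baseline,
follow-up) group *pair* instead, so consistent Overestimation carries more
risk than transient Overestimation. AF/HF/MI prevalence and incidence flags
are Bernoulli with group-dependent odds (default OR 2.5 for AF given
Overestimation). Subjects who die before the follow-up exam have no
follow-up row — no ECG can be recorded after death — which is exactly why
the serial risk models must exclude them.

**Reproducibility.** The cohort table is drawn vectorised from the master
seed; per-subject seeds (drawn once from the same stream) drive waveform
synthesis, so tables are identical whether or not waveforms are generated,
and any single record can be regenerated in isolation.

## Preprocessing

SNR is the ratio of in-band (0.66–2.5 Hz, i.e. 40–150 bpm) to out-of-band
discrete Fourier power per lead, in dB, with the DC bin excluded from the
noise and a Hann window applied by default (configurable off); without the
window, spectral leakage from strong out-of-band components floods the
narrow band. R-peaks are found per lead by a Pan–Tompkins-style envelope
detector (5–15 Hz band-pass, derivative, squaring, 150 ms integration,
adaptive threshold, 200 ms refractory period) behind a plain function
interface, so any detector with the same contract can substitute; each
detection is refined to the local maximum of the squared raw signal, making
the times polarity-insensitive. Consensus requires the same beat in at least
7 of 12 leads within 10 ms; clusters are formed by single linkage on the
pooled sorted times, each lead contributes at most one member, and the
median member time is emitted (the median is robust to one outlier lead).
Beat segments are half-open windows [R − 250 ms, R + 400 ms); "overlap"
means non-empty intersection, so two beats exactly 650 ms apart touch and
are both retained, and an overlapping segment invalidates *both* neighbours
(the strictest reading: every analysed heartbeat is independent).

## The surrogate ECG-age model

The surrogate stands in for a trained network while being fully inspectable.
It must be deterministic, accurate on generator output, and *differentiable*
so that integrated gradients is exact. Its features are computed from the
beat-averaged all-lead energy e(τ) = Σ_leads ȳ(τ)² on the 650-ms beat frame
(anchors from the scale-invariant detector enter as locally constant; the
beat average is smoothed by a 5-sample symmetric boxcar, which suppresses
the residual white-noise floor and passes gradients through unchanged since
it is linear and self-adjoint):

* `occ_p`, `occ_qrs` — soft occupancies Σ σ((e − θ)/s)·Δτ over the P and QRS
  windows: smooth versions of "time above an absolute threshold", linear in
  the corresponding interval;
* `pr_timing` — difference of energy centroids of the QRS and P windows,
  affine in PR;
* `qtc_timing` — (T centroid − QRS centroid) · √f₀, a Bazett-style
  rate-corrected QT reading, where f₀ is the spectral centroid of the
  composite periodogram in the 0.66–2.5 Hz band, regularised as
  (ΣfP + κ·f_ref)/(ΣP + κ) so that it is smooth down to the all-zero input;
* `rate` — √f₀ itself;
* `r_prog` — the precordial energy ratio (E_V1–V3 − E_V4–V6)/(E + κ) over
  the QRS window, reading the R-progression age signal.

A design trap worth recording: pure ratio-of-quadratics features are
invariant to amplitude scaling, hence constant along the ray from an
all-zero baseline — their integrated gradients from that baseline would be
identically zero while f(x) − f(0) is not, destroying completeness. The
absolute thresholds in the occupancies and the κ regularisers are what break
scale invariance and make the completeness axiom hold numerically (relative
gap ≤ 10⁻³ at 256 midpoint steps).

The features are mapped to an age by ordinary least squares on a fixed-seed
calibration cohort of 500 noise-free subjects (biological ages uniform on
35–90 y, morphology jitter on — jitter is what breaks the collinearity of
the interval features). In-sample MAE is ≈ 3.1 y (the information-theoretic
floor given 5 ms interval jitter); on jitter-free records single-subject
errors are below 3 y. Because the model cannot see sex, the female +10 ms
QTc offset induces a small (≈ ±1.5 y) sex bias — the same qualitative bias
discussed for the real network, and a documented limitation here. Gradients
of every feature are implemented in closed form and are checked against
central differences (relative error ≤ 10⁻³; in practice ≈ 10⁻⁶).

δ_age grouping uses strict inequalities on the outside and a closed middle
interval (−8 ≤ δ ≤ 8 → "Correct prediction"), the screening filter keeps
40 ≤ age ≤ 75 closed on both ends, and r² is reported as the square of
Pearson's r. In the serial analysis, exams are filtered by age individually;
a subject whose follow-up age drifts beyond 75 is dropped from follow-up
models only.

## Explainability

`integrated_gradients()` uses the midpoint Riemann rule with an all-zero
baseline record by default (steps = 64; a mean-beat baseline can be passed
explicitly). Maps are normalised per record to [−1, 1] before averaging
(normalise-then-average), then aligned by the detected R-peaks using only
retained segments and averaged lead-wise across all beats and records;
window summaries use the P / PQ / QRS / ST_T partition of the 650-ms frame.
Lead importance adds relevance lead-wise and normalises by the total of the
absolute lead sums (signed sums can cancel and cannot form a weight
distribution; a signed variant is available). Ablating the model's
P-duration weight (`ablate_features(model, "occ_p")`) removes most of the
P-window relevance; `"p_wave"` ablates the full P-reading pathway (`occ_p`
and `pr_timing`, whose P-centroid term also lives in the P window) and
removes it almost entirely — the package's operational definition of
"the model stops using P-wave information".

## Clinical features and risk models

Intervals are measured on lead II (configurable) by 5%-of-local-peak
threshold crossings of the lightly smoothed absolute signal, beat by beat,
with the beat median reported; QTc uses Bazett (QT/√RR; Fridericia behind a
flag). The generator's lead II has no S deflection, so the widest-QRS-lead
refinement is unnecessary on synthetic data and a single measurement lead
keeps the round-trip property sharp (noise-free recovery within ±5 ms for
heart rates up to 90 bpm). Group comparisons use Welch's two-sided t-test
(unequal group sizes are the norm in this design).

Risk estimation goes through the survival package and `glm`: Kaplan–Meier
product-limit curves per group; Cox partial likelihood with Breslow tie
handling (Efron behind a flag) and Wald 95% intervals; logistic ORs with
Wald intervals, reference level "Correct prediction" everywhere, optional
sex stratification (sex removed from the covariates). No multiple-testing
correction is applied by default (per-outcome p-values are reported as is;
a Benjamini–Hochberg helper is provided). The serial analysis fits three
models — Baseline (group and clock from exam 0), Follow-up (group and clock
from exam 1) and Serial (ordered group pair, reference "Correct prediction,
correct prediction", clock from exam 1) — and asserts the label-leakage
guard: nobody contributes follow-up time accrued before their group-defining
exam, so every time-at-risk equals the death-or-censor time minus the exam-1
time and is nonnegative.

## Problem sizes, numerical choices, degenerate inputs

The test-suite simulations use sizes chosen to make each property decisive
at desk scale: estimator-recovery checks run 100 replicates at n = 3000
(Cox, generator multipliers 1.4/1.0/0.65) and n = 5000 (logistic, generator
OR 2.5), with nominal 95% coverage accepted in [90, 99]; the
serial-consistency ordering uses 100 replicates at n = 6000 under the
pair-keyed hazard; consensus detection is checked against an independent
pairwise union-find oracle on 1000 random small instances; interval
round-trips scan ages 40–75. The acceptance script runs the waveform
pipeline at 600 subjects (≈ 1100 records after follow-up attrition) and the
risk analyses at 12 000 subjects.

Degenerate inputs are defined rather than left to chance: an all-zero lead
yields the −Inf SNR sentinel and is dropped from the record mean; a flat
signal yields an empty peak list; a record with no detectable beats falls
back to fixed anchors inside the surrogate (its features then reduce to
window constants); an all-zero relevance map normalises to itself with a
warning and yields uniform lead importance; tolerance comparisons in the
consensus step carry a 10⁻¹² guard against floating-point ties; serial pair
categories without subjects or without events are dropped and reported.

## What the generator does and does not emulate

It emulates: P-QRS-T morphology whose intervals drift with a controllable
biological-age offset; two exams 5–6 years apart with realistic attrition;
covariate prevalences of screening-cohort order; proportional-hazards
survival keyed to aging-effect groups; variable record quality. It does not
emulate: conduction pathology, arrhythmia (AF is a covariate flag, never a
waveform feature), baseline wander or electrode artefacts, beat-to-beat
variability within a record, or the S-curve saturation of real age
predictors at the extremes. Two visible consequences: validation r² on the
synthetic cohort (≈ 0.35 at these mixture settings) is below published
values because the latent offsets are large relative to a 40–75 y age
window, and the SNR-vs-δ_age correlation retains a small positive
morphology-driven component (older waveforms put more power into the
0.66–2.5 Hz band) that electrode-noise-dominated real recordings do not
show. Passing tests therefore demonstrate the correctness of the pipeline's
logic and estimators, not clinical performance on real ECGs.

## Worked example

```{r, eval = FALSE}
library(ecgaging)
library(dplyr)

model <- surrogate_model(400)                 # calibrates once, then cached
sim <- simulate_cohort(cohort_config(n_subjects = 300, seed = 1))

preds <- predict_ecg_age(sim$records, model) |>
  filter_age_range(40, 75)
val <- delta_and_validate(preds)
glance(val)                                   # MAE, r, r2, n
autoplot(val)                                 # predicted vs chronological age

base <- filter(sim$cohort, exam == 0) |>
  inner_join(tidy(val) |> filter(exam == 0) |>
               select(subject_id, group), by = "subject_id")
tidy(cox_hr(base, covariates = c("age_at_exam", "sex")))
autoplot(km_estimate(base))
```
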