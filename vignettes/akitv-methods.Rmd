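---
title: "Methods: interpretable 48-hour-lead AKI prediction"
author: "akitv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable 48-hour-lead AKI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It contains no results that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The prediction problem

Hospital-acquired acute kidney injury (AKI) is defined here purely from
serial serum creatinine, by the KDIGO 2012 creatinine criteria: a point
is AKI-defining if some earlier measurement within 168 h is exceeded by
a factor of at least 1.5 (relative criterion, non-strict, "at least 1.5
times"), or some measurement within 48 h is exceeded by more than
26.5 µmol/L (absolute criterion, strict, "greater than"). The reference
measurement inside the criterion window is the *baseline creatinine*.
We take the minimum creatinine inside the widest qualifying look-back
window (168 h when a relative pair exists, else 48 h), the earliest on
ties; the KDIGO wording fixes only that the baseline lies in the
window, and the minimum maximizes the detected rise, which is the
conservative choice for staging. Initial severity is staged 1–3 from
the defining/baseline pair, including the auxiliary stage-3 rule
(defining ≥ 353.6 µmol/L with a qualifying absolute rise);
staging by initiation of renal replacement therapy and the
urine-output criterion are out of scope. Qualifying points within 168 h
of an onset are absorbed into that episode; a later episode requires a
fresh qualifying pair whose reference lies at or after the previous
episode's last qualifying point. A qualifying point that satisfies
neither condition (residue of an old rise) opens nothing. The 7-day
window is a rolling 168 h, not calendar days.

Each analyzable admission contributes one supervised sample. Cases are
anchored at the onset of their first episode; controls at their final
in-hospital creatinine. A control without any creatinine cannot be
anchored and is dropped with a logged count — the exclusion rules only
remove admissions with *no* laboratory results at all, so this is a
deliberate extra rule, recorded in the feature-set metadata.

## Windowing, normalization, imputation

The 48 h before the reference point are the *prediction window*: no
event inside it is ever used, which is what guarantees the alert lead
time. The preceding 168 h form the *feature window*, cut into seven
24-h bins anchored at the reference time (not calendar midnight) so
every sample is structurally identical. Bins are half-open,
`[ref − 48 − (T−k+1)·24, ref − 48 − (T−k)·24)` hours, so an event at
exactly 48 h before the reference already belongs to the prediction
window. Per bin and analyte, values are averaged; the observation mask
records which cells were measured.

Min–max normalization uses per-analyte minima and maxima of the binned
means *from the training split only*, applied with clipping to [0, 1]
elsewhere; a degenerate analyte (min = max) maps to 0. Missing cells
are zero-imputed after normalization. The feature vocabulary is the set
of analytes seen in the training split, ordered by descending
training-split prevalence (fraction of admissions with at least one
event), ties alphabetical. The 80/10/10 split shuffles admissions
deterministically under one seed; `floor(n·0.8)` and `floor(n·0.1)` go
to training and validation, the remainder to testing (20,732 samples
split 16,585/2,073/2,074). Splitting is admission-level by default —
every case admission is a sample — with an optional patient-grouped
mode for studies of cross-split patient leakage.

## The TITV model

The model has three modules operating on the T×F sample `X` with mask
`M`.

**Time-invariant module.** Each feature's pooled summary is the masked
mean over time, `u_f = Σ_t M_tf X_tf / max(1, Σ_t M_tf)`. A two-layer
scalar network, shared across features and followed by a per-feature
gain and bias, maps `u_f` to a scale `γ_f` and a shift `δ_f`; the input
is feature-wise linearly modulated, `X̃_t = γ ⊙ X_t + δ`, and the
reported time-invariant importance is `β = |γ| / Σ_f |γ_f|` (scales are
what modulate the input; shifts do not enter importance). The map is
deliberately *feature-wise* rather than a dense F→F network: with a
dense map the pooled summary of one analyte can be written into another
analyte's scale or shift, so the network can smuggle the entire
prediction through the modulation while `β` and the attention point
anywhere. We observed exactly this failure (importance mass parked on
hemoglobin, the most reliably measured analyte) before restricting the
map. With the feature-wise map, `γ_f` can only encode evidence carried
by analyte f itself.

**Time-variant module.** A bidirectional GRU runs over
`(X̃_1 … X̃_T)`. Window attention is
`a_t = softmax_t(vᵀ tanh(W_a h_t))`; within-window feature weights are
`b_tf = softmax_f((W_b h_t)_f + s_b,f · X̃_tf)` — a recurrent key plus
a direct salience term on the modulated value itself, which gives
attention a gradient path that points at elevated cells rather than
encoding risk in arbitrary ones. The time-variant importance is the
factorized product `α_tf = a_t · b_tf`, which sums to one over all
cells.

**Prediction head.** `logit = Σ_{t,f} w_f β_f α_tf X̃_tf + b₀`,
`risk = logistic(logit)`. The per-cell products are *exact additive
attributions* of the logit; `titvForward()` returns them together with
`β`, `α` and the bias, and the identity `Σ contributions + b₀ = logit`
holds to numerical precision by construction.

### Training

All four models (TITV, logistic on the flattened T·F vector, GRU and
BGRU reading the last hidden state(s)) minimize class-weighted binary
cross-entropy with Adam on minibatches, early-stopping on validation
AUROC and returning the best-validation checkpoint. The positive-class
weight defaults to n_neg/n_pos (≈ 22 at 4.4% prevalence). After
training, the intercept is shifted by −log(weight) so risks sit on the
cohort prevalence scale; this affects calibration only, never ranking.
Everything runs on a small reverse-mode autodiff engine written for
this package; its gradients are pinned down by finite-difference tests
at 1e-4 for every model kind.

Three regularizers keep the interpretation honest, all tunable in
`titvConfig()`:

* `shift_decay` (default 1): L2 on `δ`. An unpenalized shift is a
  per-feature bias channel through which the pooled summary can carry
  the prediction into cells the attributions then mislabel.
* `head_decay` (default 0.001): light L2 on `w`, pushing feature
  selection into the reported `γ` rather than the silent head weights.
* `attn_warmup` (default 10 epochs): the attention and recurrent
  parameters stay frozen at initialization while the modulation and
  head train; during warm-up the model is a feature-wise-modulated
  near-linear classifier, so `γ` must align with the informative
  analytes before the higher-capacity time-variant machinery moves.
  Without the warm-up the flexible attention wins the optimization race
  and becomes a risk encoder.

A `beta_entropy` sparsity knob exists but defaults to 0: in our
experiments entropy pressure concentrated `β` on whichever feature the
attention had chosen as an encoder, i.e. it sharpened the wrong
solution.

Defaults (hidden 24 per direction, modulation hidden 16, attention 8,
learning rate 0.015, batch 256, patience 15, max 100 epochs) were
selected on validation AUROC, mirroring the usual protocol of tuning on
the validation split only. All stochastic operations derive from the
single config seed; fits are bit-reproducible.

## Evaluation

AUROC is the Mann–Whitney probability that a random case outranks a
random control, ties counted ½, computed from midranks. Its 95%
confidence interval is a percentile bootstrap over samples (default
2000 resamples, deterministic given a seed; degenerate single-class
resamples are redrawn and counted); a DeLong interval is available
behind `ci_method = "delong"`. The threshold sweep predicts an alert
when risk ≥ threshold (a score exactly at threshold alerts) across
5%–30% in 5% steps, reports precision/recall/F1 and the confusion
matrix per row, and selects the operating threshold by highest F1,
lowest threshold on ties. Undefined precision (no alerts) is reported
as 0 with an explicit flag rather than NaN.

## The synthetic cohort generator

The generator emulates the study conditions every test runs under:
admission-level AKI prevalence 4.4%; AKI onset log-normal with median
6 days from admission (IQR roughly 3–10); length of stay log-normal
with median 5 days, at least 48 h unless a short stay is planted;
roughly thirty analytes whose daily ordering probabilities follow the
familiar hospital hierarchy (complete blood count ~0.85/day,
electrolytes/urea/creatinine ~0.8, liver panel ~0.45, blood gas and
lactate ~0.1–0.15, monitored assays such as troponin and vancomycin
trough ~0.25); log-normal values in native units with multiplicative
draw noise. Planted exclusion admissions (short stays, early-onset AKI,
admission eGFR below 15 via an exact CKD-EPI inversion, prior-RRT codes
with eGFR 15–30, no labs) are emitted at configurable fractions and
must be recovered exactly by the exclusion cascade.

AKI cases carry a creatinine course that is flat at baseline until 48 h
before the planted onset and then rises quadratically to 1.6× baseline
exactly at onset. Because the entire rise sits inside the prediction
window, the label never leaks into the feature window through
creatinine itself. Control creatinine noise is ratio-clipped
(`min(0.07, 12/baseline)`) so that neither KDIGO criterion can fire
spuriously — the false-trajectory rate is zero by construction, and
case baselines are capped at 110 µmol/L so the mid-rise cannot trigger
the absolute criterion more than 24 h early.

Each case draws a clinical archetype — sepsis (CRP, neutrophils, WBC;
weight 0.40), hepatic/multiorgan (lactate, transaminases, bilirubin,
INR; 0.25), cardiac (troponin-I, CK; 0.20), nephrotoxic (vancomycin
trough; 0.15) — plus a shared renal prodrome (urea, the pre-renal
azotemia that precedes a creatinine rise) present in every case. Signal
analytes drift upward by 2 SD on the log scale, ramping linearly over
5 days from the feature-window start and persisting through onset. The
effect size is calibrated so that a logistic model fitted on the *true*
signal summaries (`effectSizeOracle()`, the achievable-AUROC bound)
reaches ≥ 0.9; the TITV model is then required to come within 0.05 of
that bound and within 0.02 of the logistic baseline, and the mean
per-case β mass on a case's own planted analytes must exceed three
times its uniform share.

Two generator choices exist purely to keep the *leakage canary* honest.
The canary plants the signal only inside the prediction window and
requires test AUROC ≈ 0.5: any systematic difference between cases and
controls other than the planted signal would fail it. First, kept
controls draw a pseudo-onset from the same distribution as case onsets
and their creatinine monitoring stops there, so the admission-to-
reference gap (and hence the bin-occupancy pattern) is
label-independent; this lengthens control stays slightly (median ≈ 6
days rather than 5). Second, both arms receive an identically-noised
guaranteed creatinine draw 72 h before their (pseudo-)onset, so neither
the observation pattern nor the value distribution differs by label in
the feature window. With ~20 positives in a 10% test split, the null
sampling standard deviation of the AUROC is about 0.07, so the
0.5 ± 0.05 hygiene band is asserted on the mean over five seeds, not
per seed.

What the generator does **not** emulate: physiology or pharmacokinetics
(signals are log-scale drifts, not mechanistic trajectories);
inter-analyte correlation beyond the planted archetypes; demographic
confounding (age and sex do not modulate risk); informative test
ordering (an `informative_ordering` switch exists for stress tests but
defaults to off, because ordering intensity coupled to outcome would
defeat the canary); and the ~709-analyte width of a real laboratory
catalog. Passing tests therefore demonstrate that the pipeline recovers
planted structure under clean conditions — they do not certify
performance on real EHR data, where informative missingness,
concept drift and coding noise all operate.

## Numerical and degenerate-input conventions

* Timestamps are normalized to timezone-naive UTC; parsing is
  element-wise so that a vector mixing date-only and full stamps is
  never truncated wholesale. Lab rows with non-finite values,
  unparseable stamps, or stamps outside
  [admit − 24 h, discharge] are rejected row-by-row with reasons, never
  silently.
* The admission eGFR uses the *first* creatinine within 48 h of
  admission; when none exists the eGFR-based exclusion clauses cannot
  fire. The CKD-EPI 2009 equation omits the race coefficient by
  default (the source cohort protocol does not state race handling);
  pediatric admissions run through the same adult equation and are
  flagged.
* Exclusion rules are evaluated in fixed order and the first match is
  the recorded reason; exclusions are per admission, never per patient.
* `minmaxNormalize` clips out-of-range values instead of extrapolating;
  degenerate ranges map to 0. Zero imputation happens strictly after
  normalization.
* Ties: baseline creatinine takes the earliest minimum; best-F1
  threshold takes the lowest tied threshold; score ties at a threshold
  alert deterministically (≥).
* All randomness (simulation, splitting, initialization, shuffling,
  bootstrap) derives from user-supplied seeds through a deterministic
  child-seed scheme, and every seeded routine restores the caller's RNG
  state.

## Problem sizes used by the checks

The packaged checks run the full pipeline at 5,000 admissions per seed
for five seeds (signal recovery and canary), 800–3,000 admissions for
the data-contract tests, an exhaustive-plus-sampled set of about 10⁴
creatinine series against the brute-force KDIGO oracle, 1,000 random
draws against the independent CKD-EPI implementation, and 100 random
inputs for the attribution identity at 1e-5. These sizes were chosen so
the whole suite completes in minutes on a single CPU while keeping
every stochastic criterion's sampling error well inside its asserted
margin.

## Known limitations

* The TITV equations are this package's concrete instantiation of the
  three-module design (modulation from a pooled summary, bidirectional
  recurrence, factorized self-attention, bilinear aggregation); other
  instantiations of the same design exist, and numerical equivalence
  with them is neither claimed nor checkable.
* Attention weights remain descriptive rather than causal: the
  regularizers and warm-up make the honest pathway the easiest one, but
  no architecture can guarantee attention never encodes.
* Real-cohort performance figures are not reproducible here because the
  institutional EHR data are not deposited; model-quality checks are
  therefore property-based on the synthetic cohort.
* Real-time deployment, concept-drift adaptation, urine-output
  criteria, medication/diagnosis features and biomarker augmentation
  are out of scope.
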