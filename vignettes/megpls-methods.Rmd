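---
title: "Methods: source-space band power, PLS inference and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space band power, PLS inference and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megpls)
```

## The scientific problem

Children born very preterm (at or below 32 weeks of gestation) are at
elevated risk of cognitive, behavioral and motor difficulties at school age,
even without overt brain lesions. One candidate mechanism is disrupted
thalamocortical development: the thalamus regulates cortical oscillatory
activity, and thalamic injury is classically associated with *alpha
slowing* — a shift of resting spectral power away from the alpha band toward
theta and delta. `megpls` implements an analysis chain that asks, on a
cohort with MEG, structural MRI and neonatal chart data:

1. Does resting source-space relative band power differ between extremely
   preterm (ELGA), very preterm (VLGA) and term-born children?
2. Is the spatial/spectral pattern of that difference associated with
   neurocognitive outcome scores?
3. Is it associated with structural measures of the thalamus — normalized
   thalamic intensity (a proxy for myelination) and thalamic volume relative
   to cortical gray matter volume (the TV-CGV ratio)?
4. Are those thalamic measures in turn predicted by adverse neonatal
   exposures (gestational age, sex, infection, illness severity, morphine,
   skin-breaking procedures)?

Because cohorts of this kind are not publicly deposited, the package ships a
synthetic cohort generator that reproduces the *statistical structure* the
analyses assume, with the planted ground truth recorded, so every stage can
be exercised and calibrated end to end.

## From sensors to relative band power

**Motion rejection.** Continuous head localization gives three fiducial
coil positions over time. A sample is retained iff every fiducial's
Euclidean displacement from its per-recording median position is at most
5 mm (`reject_motion_segments()`, threshold configurable).

**Epoching.** Retained runs are cut into contiguous, non-overlapping 4 s
windows aligned to each run start; partial windows are dropped
(`segment_epochs()`). Non-overlap is the natural reading of a protocol in
which a two-minute recording yields at most 30 trials; overlap would
inflate trial counts.

**Band power.** Five canonical bands are used: delta 1–4, theta 4–8, alpha
8–12, beta 12–25, gamma 25–55 Hz, with half-open edges `[lo, hi)` so shared
edges are counted once. Band power is the variance of the band-pass
filtered signal, averaged over epochs. The filters are windowed-sinc FIR
designs (Hamming window; passband ripple far below 1%) with transition
widths of 0.5–2 Hz chosen per band so the equivalent noise bandwidth stays
within a few percent of the nominal bandwidth. Filters are applied with
exactly zero phase. Within fixed-length epochs the filter is applied under
periodic extension (the epoch's DFT is multiplied by the filter's real,
delay-compensated frequency response): for stationary signals this
estimates band variance without edge transients, which would otherwise bias
slow-band power on 4 s windows. A 60 Hz FIR notch (`notch_line_noise()`) is
provided for laboratory data and is inert on synthetic recordings.

An independent choice had to be made about whether power is computed per
epoch and then averaged, or from spectra averaged first; the package
averages per-epoch variances, which matches the per-band beamformer design
below.

**Relative power.** Absolute band power is divided by the summed power over
the five bands per source (`relative_power()`), giving a compositional
(sum-to-one) quantity invariant to any global rescaling of the signal. This
is what makes beamformer depth bias — a multiplicative gain factor per
source — drop out, so no weight normalization is applied to the spatial
filters.

## LCMV beamforming

Source activity is reconstructed on a grid with a linearly constrained
minimum-variance spatial filter: weights `w = C⁻¹l / (lᵀC⁻¹l)` for the
oriented lead-field column `l`, which pass the target source with unit gain
while minimizing output variance from everywhere else. Choices:

- **Covariance.** Pooled over epochs after per-epoch mean removal, with
  diagonal loading equal to 5% of the mean sensor power by default
  (`reg_fraction`, configurable). 5% is the conventional default where no
  value is dictated by the data.
- **Per-band weights.** The covariance is estimated from band-filtered
  epochs and weights are recomputed per band, so each filter is optimized
  for the spectral content it reconstructs.
- **Scalar beamformer.** The dipole orientation at each source is the unit
  vector maximizing beamformer output power — the eigenvector of the
  smallest eigenvalue of `LᵀC⁻¹L` — restricted to the magnetically visible
  subspace of the lead field. In a spherical conductor the radial
  orientation produces no external magnetic field; it is excluded
  numerically by a rank check on the 3-column lead field.

The forward model for synthetic data is the closed-form magnetic field of a
current dipole in a homogeneous conducting sphere. A realistic single-shell
or boundary-element head model depends on individual anatomy and is out of
scope; the sphere preserves the property the beamformer code must respect
(radial silence) and is exact, which makes it ideal as a test substrate.

## Mean-centered and behavioral PLS

Both analyses decompose a small cross-block matrix by SVD into latent
variables (LVs): a feature-side *salience* (left singular vector), a
singular value, and a group- or variable-side *contrast* (right singular
vector).

**Mean-centered PLS** (`mean_centered_pls()`) decomposes the
groups-by-features matrix of group means after centering each feature by
the grand mean of group means. The grand mean is *unweighted* by group size
by default, so the contrast is not dominated by the largest group; the
subject-weighted variant is available via `weighted = TRUE`. With `g`
groups at most `g − 1` singular values are non-zero.

**Behavioral PLS** (`behavioral_pls()`) decomposes the features-by-variables
Pearson correlation matrix computed across all included subjects pooled
over groups (pooling maximizes statistical power and matches the analysis
design this package follows; a stacked within-group variant is not
implemented). Contrast elements, scaled by their singular value, are read
as the correlation pattern of the variables with the latent brain pattern.

**Sign conventions.** The SVD is sign-arbitrary per LV. Point estimates fix
each LV so its largest-magnitude contrast element is positive. Bootstrap
replicates are sign-aligned to the original by flipping any LV whose
resampled salience has negative dot product with the original salience —
axis reflection is the dominant bootstrap instability when only the leading
LV is interpreted. A full Procrustes rotation across LVs was considered and
deliberately left out: the analyses here interpret LV1 only, and rotation
couples LVs in ways that complicate the bootstrap-ratio interpretation.

**Permutation test** (`permutation_test()`). Group labels (mean-centered)
or behavior rows (behavioral) are permuted without replacement, the full
decomposition is recomputed, and the p-value of LV *k* is the smoothed
exceedance proportion `(#{s_perm(k) ≥ s_obs(k)} + 1) / (n_perm + 1)`. The
smoothing avoids p = 0 and is the standard convention for Monte-Carlo
tests. One p-value per LV means no multiple-comparison correction across
features is needed.

**Bootstrap** (`bootstrap_inference()`). Subjects are resampled with
replacement *within group*; a resample that collapses a group to a single
unique subject is redrawn (at most 100 times). The bootstrap ratio of a
feature is its original salience divided by the bootstrap standard error of
the aligned saliences, and is read as a z-score of feature reliability.
Where the SE vanishes (e.g. a feature constant across subjects, or fully
degenerate within-group data) the ratio is reported as 0 — "no observed
variability" is deliberately not presented as infinite reliability.
Contrast confidence intervals are percentile (2.5/97.5) intervals of the
aligned bootstrap contrasts; intervals excluding zero are read as
significant. Defaults are 500 permutations and 500 bootstrap resamples,
both configurable.

**Brain scores** (`brain_scores()`) are the dot products of the
subjects-by-features matrix with each salience — how strongly each subject
expresses an LV's pattern. They are the bridge to the volume analyses:
correlating LV1 brain scores with TV and CGV separately
(`correlate_scores_with_volumes()`) asks which volume drives a ratio
association.

## Post-hoc analyses

- **Salience-map correlations** (`correlate_zmaps()`): the Pearson
  correlation over all source-by-band features of two bootstrap-ratio maps,
  used to quantify how similar, e.g., the intensity-association map is to
  the group-difference map. Because each analysis fixes its LV sign by its
  own contrast, the *sign* of this correlation is orientation-dependent;
  its magnitude is the meaningful quantity.
- **Tail-power associations** (`tail_power_association()`): per band, the
  `ceiling(fraction × n_sources)` locations in the *skewed* tail of the
  band's z-scores are selected (most-negative tail if the bias-corrected
  Fisher–Pearson sample skewness is negative, most-positive otherwise; ties
  at the cutoff break by ascending source index, so selection is
  deterministic), each subject's relative power is averaged over the
  selection, and the average is correlated with a covariate per group and
  pooled. Default fraction 0.025. Pearson correlation is used throughout,
  matching the linear best-fit framing of the analysis; no correction is
  applied across the per-group tests.
- **Neonatal regressions** (`neonatal_regression()`): OLS with intercept of
  TI or the TV-CGV ratio on GA, sex, infection, SNAP, log morphine, log
  pain count and the sex×GA interaction, on complete cases; per-coefficient
  two-sided t-tests, overall F with (7, n − 8) degrees of freedom, and R².
  With the canonical 37 complete cases this is F(7, 29). The reporting
  table labels outputs by outcome variable; where a published table header
  and the accompanying text disagree about which outcome a coefficient set
  belongs to, the text's attribution (the TI model) is followed.

## The synthetic cohort generator

`generate_power_cohort()` draws cohorts at the level the statistics
consume. Its model, per subject *i* in group *g*:

- Band-power logits: `z_i = b₀ + (Δ·1[g = ELGA] + u_i)·w + ε_i`, where `w`
  is the planted salience (unit Frobenius norm over sources × bands;
  default: raised delta/theta, lowered alpha/beta on 30% of sources — a
  slowing pattern), `Δ` is `contrast_effect`, `u_i ~ N(0, latent_sd²)` is a
  subject-level expressiveness of the pattern, and `ε` is i.i.d. feature
  noise with SD `noise_sd`. The baseline `b₀` encodes a delta-dominant
  school-age resting composition (32/23/22/15/8% across bands).
- Powers: softmax of the logits per source, so non-negativity and
  sum-to-one hold *by construction* — relative power is compositional, and
  planting effects on an unconstrained scale then renormalizing is the only
  way to keep the constraint exact.
- The **latent score** is the realized projection of the logit deviations
  on `w`; outcome variable *v* is `μ_v + σ_v(λ_v t* + √(1 − λ_v²) e)` with
  `t*` the standardized latent score, so `λ_v` is the planted outcome–brain
  correlation. Defaults give modest negative loadings for IQ and
  visuomotor scores and positive loadings for behavior-problem scores.
- Structural variables (TV, CGV, ICV, TI, CGI, CWI) are drawn from
  group-specific means and SDs typical of school-age preterm cohorts, with
  configurable correlation ("coupling") to the latent factor (defaults:
  TV −0.4, TI −0.5, CGI/CWI +0.3, CGV/ICV 0) — reduced thalamic volume and
  intensity accompany more slowing.
- Neonatal predictors are drawn per group (GA truncated to the group's
  definition range, infection and illness-severity rates typical of
  extremely vs very preterm infants, log-transformed morphine and
  skin-break counts), and thalamic intensity additionally carries the
  configured linear neonatal effects (`neonatal_betas`), mean-centered so
  group means stay near their configured values.
- Missingness mirrors a realistic cohort: all subjects have MEG and
  neurocognitive scores; a per-group subset (default 13/24/13 of 23/36/39)
  has MRI; neonatal chart data exist for preterm subjects with MRI,
  giving 37 complete cases for the neonatal regression and hence F(7, 29).

**Noise scales.** `noise_sd = 0.15` on the logit scale corresponds to
roughly 15% multiplicative residual noise on power ratios, consistent with
the high test–retest stability of relative band power; `latent_sd = 0.5`
adds subject-level variation in how strongly the pattern is expressed.
These were fixed by a design calculation — at these scales a planted
standardized contrast of 1.0 with 20 subjects per group is reliably
detectable and its salience map recoverable, which is the regime the
recovery tests operate in — and are configurable for harder regimes.

**What the generator does not emulate.** No 1/f spectral background, no
physiological artifacts (cardiac, ocular, muscle) beyond white sensor
noise, no realistic head geometry or cortical surfaces, and a single latent
factor linking brain to outcomes (the analyses interpret one LV;
multi-factor generation is deferred). Passing recovery tests on this
generator therefore demonstrates the statistical machinery is correct and
calibrated — not that the pipeline is robust to artifacts it never sees.

## Numerical choices and degenerate inputs

- Epoch filtering is periodic (circular); continuous series use reflection
  padding. Filters are truncated only if longer than the signal permits.
- The permutation p floor is `1/(n_perm + 1)`; LVs beyond `g − 1` have
  singular values at numerical zero and their p-values are not meaningful.
- Bootstrap SE of exactly zero yields a bootstrap ratio of 0 (documented
  convention, see above).
- All-zero band power vectors raise an error rather than returning NaN;
  constant features/variables are rejected by name in behavioral PLS, but
  tolerated inside bootstrap resamples (zero-variance pairs contribute
  correlation 0 to the resampled matrix).
- Rank-deficient regression designs and singular covariances raise explicit
  errors; diagonal loading is the supported remedy for the latter.
- Problem sizes used by the shipped tests and the acceptance script — null
  calibration on 200 cohorts of 60 subjects × 50 features with 500
  permutations, recovery on 50 replicates of 60 × 250 with 500
  permutations and 500 bootstraps — were chosen as the smallest designs
  that make the calibration and recovery properties statistically sharp.

## Known limitations

- The spherical forward model is a deliberate toy; no coregistration,
  realistic head modelling, or vendor MEG format support is provided.
- ICA-based artifact removal is out of scope; the motion mask is the only
  automated data-quality gate.
- Behavioral PLS pools subjects across groups; the stacked within-group
  correlation variant is not implemented.
- The TV printed by structural pipelines may be a bilateral sum or a
  hemispheric mean; the package assumes hemispheric-mean inputs and leaves
  averaging to the data preparer.
- Tail-selection uses only the sign of the sample skewness; heavily
  multimodal z-score distributions could make the side choice unstable
  near zero skewness.
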