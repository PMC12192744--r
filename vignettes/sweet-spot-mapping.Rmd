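---
title: "Probabilistic sweet-spot mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic sweet-spot mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intra-operative stimulation tests in deep brain stimulation (DBS) surgery
for essential tremor produce, per patient, a few dozen labelled
stimulations: at each explored position along two parallel tracts the
current is ramped in 0.2 mA steps and the *motor threshold* — the lowest
amplitude at which the best tremor improvement is observed — is recorded
together with that improvement, rated on a discrete clinical scale
(0/25/50/75/100 %). Each stimulation has a simulated electric-field (EF)
norm volume on a common 0.5 mm grid; thresholding the EF at 0.2 V/mm gives
the volume of tissue activated (VTA). Stacking all labelled VTAs voxel by
voxel yields, at every voxel, a sample of improvement scores, and the
question becomes statistical: *which voxels are associated with at least
"good" (75 %) improvement?* The binary answer, after multiple-comparison
control and plausibility masking, is the probabilistic sweet spot (PSS).

This package implements that pipeline end to end — four voxel-wise
statistics, two type-I-error corrections, masking and cluster filtering,
and an evaluation suite — together with a synthetic cohort generator, so
every stage is testable without clinical data.

## The voxel-wise statistics

All four methods test, per voxel with at least `min_n = 3` observations
(voxels below that are *invalid*, not p = 1, so corrections never count
them):

* **t map** — one-sided one-sample t-test of H0: mean improvement < 75
  against H1: ≥ 75. Zero-variance samples are common on a 5-level scale
  and are kept with the convention p = 0 if the sample mean exceeds 75,
  p = 1 otherwise; discarding them would silently delete the strongest
  voxels.
* **Wilcoxon map** — one-sided signed-rank test of the same hypotheses.
  Zero differences follow the Pratt rule (ranked with the rest, then
  dropped from the statistic); the null distribution is exact for up to
  25 non-zero differences via dynamic programming over doubled midranks
  (ties handled exactly), and a tie-corrected normal approximation with
  continuity correction beyond. Exactness was preferred over the faster
  approximation because the discrete scale makes ties and zeros the rule,
  not the exception.
* **Bayesian map** — a directional ("encompassing prior") Bayesian
  t-test. Model: observations Normal(μ, σ²); prior μ ~ Normal(75, 25)
  (centred at the tested threshold, scale one rating-scale step); σ²
  carries a weakly informative scaled inverse-χ² prior (ν₀ = 1,
  s₀ = 12.5, half a scale step). The variance is marginalized
  analytically and the one-dimensional posterior over μ is integrated by
  deterministic quadrature on a grid symmetric about 75, so maps need no
  seed. Then

  BF₁₀ = [P(μ ≥ 75 | data) / P(μ < 75 | data)] / [P(μ ≥ 75) / P(μ < 75)],

  which is 1 exactly for samples symmetric about 75 (the prior odds are
  1 by construction — the property that motivated centring the prior at
  the threshold, which the source protocol leaves unspecified). Voxels
  with BF₁₀ ≥ 10 (strong evidence) are selected. A seeded Gibbs sampler
  implements the same model as a stochastic cross-check; it agrees with
  the quadrature to within 10 % on log BF wherever the Bayes factor is
  within the sampler's Monte-Carlo resolution (|log BF| ≤ log 50). A
  prior-sensitivity helper recomputes BF₁₀ under Normal, Cauchy and
  Student-t priors of the same centre and scale.
* **LMM map** — per voxel, improvement ~ EF norm with per-patient random
  intercepts and slopes; on singular or non-convergent fits the model
  falls back to random intercepts only, and a voxel is invalid only if
  both fail. The reported p is the two-sided Satterthwaite test on the
  fixed slope; selection additionally requires slope > 0 (one-sidedness
  via the sign rule, since the source protocol does not state the
  sidedness). For tractability the LMM is fitted only on voxels that
  survive the frequency masks; this ordering is recorded in provenance.

## Corrections

* **BH-FDR** over the valid voxels only; a voxel is significant iff its
  BH-adjusted p ≤ q = 0.05.
* **Voxel-wise permutations** — improvement labels are reshuffled across
  all records (200 replicates by default) with the EF geometry fixed; the
  map is recomputed per replicate, and a voxel's corrected p is the
  fraction of replicates in which its permuted p ≤ its true p. Voxels
  with corrected p ≥ 0.05 are *discarded from the significant set*: the
  corrected significant voxels are those with raw p < 0.05 **and**
  corrected p < 0.05. The plain count/n convention is the default (the
  ≥ 0.05 discard boundary presumes it); (count+1)/(n+1) is available
  behind a flag. The unrestricted shuffle exchanges labels both between
  and within leads; a lead-stratified mode is available but not default.

Only the t and Wilcoxon maps are corrected; the Bayesian and LMM maps are
used as-is.

## From map to sweet spot

The extraction order is fixed: significance threshold → frequency masks →
cluster filter. The frequency masks discard voxels activated in fewer
than 25 % of patients or by fewer VTAs than 10 % of the maximum
stimulation count, with strict-less comparisons on exact fractions (no
rounding of patient counts). The cluster filter removes connected
components below 8 voxels (1 mm³ at 0.5 mm), 26-connectivity by default
(6/18 available); ordering matters and is asserted by a test where a
9-voxel cluster loses 2 voxels to masking and is then removed. An
amplitude-weighted mean-improvement map (weights EF/amplitude) is
computed as an auxiliary output but plays no role in masking: the masking
rules operate on raw counts, the only reading consistent with "number of
VTAs".

## The synthetic cohort generator

The generator emulates the protocol geometry exactly: 23 patients,
15 ± 6 explored positions drawn from a 2 × 15 lattice (two tracts 2 mm
apart, depths −10..+4 mm in 1 mm steps), amplitude ramp 0.2–5.0 mA in
0.2 mA steps, motor-threshold record selection, one record per explored
position.

*EF model.* An idealized inverse-square point source,
EF = 0.8 · I / max(r², r_min²) V/mm, calibrated so 1 mA reaches the
0.2 V/mm activation threshold at r = 2 mm (VTA radius ≈ 2 mm at 1 mA,
amplitude-monotone). It stands in for patient-specific finite-element
field simulation, which is out of scope; it reproduces realistically
sized VTAs but none of the tissue heterogeneity, anisotropy or electrode
geometry of the real fields.

*Response model.* A latent ellipsoidal effective region; latent
improvement = background + (max − background) · coverage +
patient effect + test noise, clamped to [0, 100] and snapped to the
nearest rating level (midpoints round up), where coverage is the covered
fraction of the ellipsoid. The patient effect is drawn once per patient
(mirroring the LMM's random-intercept assumption).

*Calibration (done once, then frozen).* With background 25 % and maximum
100 %, a sweep set patient_sd = 16, noise_sd = 3 and the default
ellipsoid centre at (1, 2.5, −2) mm — 2.7 mm lateral of either tract —
so that default cohorts reproduce the clinical record-level summary
(improvement ≈ 58 ± 28 vs the reported 54.5 ± 32; within-band across
seeds). The small test-level noise reflects a single experienced rater;
most variability is between patients and from scale discretization.
Note the best-of-ramp selection makes the recorded score the maximum of
~25 noisy tests, so large test noise would inflate every record — the
reason noise_sd is small.

*Recovery configuration.* Stimulation mapping can only resolve structure
the VTAs sample, at a resolution bounded by the VTA radii (1–4.5 mm
here). The default, laterally offset hotspot is deliberately *not*
voxel-recoverable: the extracted PSS lands between the tracts and the
hotspot (Dice ≈ 0.33 against the generating ellipsoid, centroid pulled
~2.5 mm toward the tracts) — a resolution property of the method, not a
defect. Recovery experiments therefore use `recovery_ground_truth()`: an
in-plane hotspot (centre (1, 0, −2) mm, 3 mm semi-axes) whose volume is
commensurate with that resolution. This configuration was fixed after a
single calibration run and not revisited; with it, the Bayesian and
permutation-corrected t/Wilcoxon pipelines reach Dice ≈ 0.5–0.6 against
the truth with centroid errors ≈ 0.1–0.2 mm, and TPerm/WPerm sweet spots
coincide at Dice ≈ 0.98.

*Null mode.* With max_effect = background_effect the response is
independent of position. Because the best-of-ramp selection would push a
boundary-null marginal (level 75) to ~100, null mode draws a single test
per position with a uniformly drawn ramp amplitude; `null_sim_config()`
additionally sets patient_sd = 0 and noise_sd = 15, so per-voxel samples
are i.i.d. snapped Normal(75, 15) — scores 50/75/100 with probabilities
≈ 0.2/0.6/0.2 — exactly on the H0 boundary. These are the conditions
under which nominal test levels are meaningful.

## What the type-I experiments do and do not show

Three structural findings, documented here because they bound what
"passing" means on synthetic data:

1. The one-sided t-test on 5-level snapped scores is conservative at
   small n, and the *fraction* of significant voxels in one cohort is a
   highly variable quantity (0.001–0.067 over ten seeds at nominal 0.05):
   neighbouring voxels share records, so the whole map moves with the
   realized cohort mean. The across-seed average is ≈ 0.03.
2. The exact signed-rank test is structurally conservative under heavy
   ties: with three observations the smallest attainable one-sided p is
   1/8, so small-n voxels can never reject; the observed fraction is
   ≈ 0.01. No null noise level repairs this — less spread degenerates to
   all-zero differences, more spread does not remove the atoms.
3. The voxel-wise permutation correction compares each voxel with its own
   permutation distribution, so under exchangeability its corrected p is
   uniform *by construction* and ~5 % of raw-significant voxels always
   survive; spatial correlation clusters the survivors past the 8-voxel
   filter. A boundary null with score spread therefore yields a non-empty
   corrected sweet spot in a substantial fraction of cohorts (6/10 seeds
   here). Requiring simultaneously a nominal 5 % voxel-level rate and an
   almost-always-empty corrected sweet spot is contradictory: the spread
   that produces the former creates the survivors that defeat the latter.

## Evaluation suite

Dice overlap (0 when both masks are empty), voxel-centre centroids,
volumes; leave-one-out cross-validation over patients, pooling per-VTA
(overlap, improvement) pairs across folds, trimming pairs at or above the
pooled 95th percentile of overlap (one pooled distribution per method,
matching the singular "the distribution"; when the percentile collapses
onto the minimum there is nothing to trim and all pairs are kept), then
Spearman's ρ. Folds with an empty sweet spot contribute zero-overlap
pairs by default so chronically failing variants are visibly penalized; a
drop-fold mode mirrors exclusion instead. Consistency over the
leave-one-out sweet spots: volume coefficient of variation
(100 · sd/mean, sample sd — the convention is recorded here since the
formula's source leaves it open), pairwise Dice, and pairwise centroid
distances normalized by the larger *equivalent-sphere* diameter
d = (6V/π)^{1/3} of the pair (robust for ragged voxel clusters; a
max-extent definition would be the alternative). Between-method
comparison: Shapiro-Wilk on residuals and Levene's test at 0.05 decide
between one-way ANOVA (+ Tukey when significant) and Kruskal-Wallis (no
post-hoc is run after Kruskal-Wallis; the omission is noted in the
result).

## Numerical and scale choices

* Quadrature grid for the Bayes factor: step 0.2 % over ±160 % around
  75, symmetric with no node at 75, so the directional split is clean and
  symmetric samples give BF = 1 to machine-level accuracy; the posterior
  scale is never below s₀/√n ≈ 1.2 %, several nodes wide.
* Permutation indices derive from one seeded RNG stream per run; every
  stochastic stage takes an explicit seed and records it in provenance,
  and reruns are bit-identical.
* Problem sizes: the full study scale (23 patients, ~330 records, 48³
  voxels at 0.5 mm, 200 permutations) is used for the end-to-end
  property checks and the acceptance script; unit tests use an
  8-patient cohort on a 32³ grid at 0.75 mm (same 24 mm physical
  extent), sizes chosen so the whole suite stays interactive.
* Volumes are NIfTI-1 (sform = qform = the grid affine, axis-aligned);
  masks round-trip exactly, scalar maps to float precision. Tables are
  CSV with improvement in percent; sidecars are JSON.

## Known limitations

The generator's response model is a stand-in: no claim is made that its
parameters estimate the clinical data-generating process, and the
clinical headline numbers (28/30/20/21 mm³ sweet-spot volumes, LOOCV
ρ ≈ 0.15–0.18) are properties of a specific clinical cohort that a
synthetic cohort is not expected to reproduce — synthetic signal is far
cleaner, so synthetic LOOCV correlations are much higher. Hemispheres are
analysed independently and no anatomical-atlas localization is performed
(registration is out of scope); recovery is instead judged against the
generating ellipsoid. The LMM map inherits the known weakness of mixed
models on few-level discrete outcomes with ~15 points per patient.
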