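---
title: "Visual attention parameters and intrinsic network connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual attention parameters and intrinsic network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvanet)
```

## Overview

`tvanet` implements two linked analyses and a synthetic-data module that ties
them together with known ground truth:

1. **Behavioral side.** Maximum-likelihood estimation of the four independent
   visual-attention parameters of the theory of visual attention (TVA) from
   whole-report and partial-report letter tasks: visual processing speed *C*
   (items/s), visual short-term memory (VSTM) storage capacity *K* (items),
   top-down control α (distractor-to-target weight ratio) and spatial
   laterality *w*~lat~ (left-hemifield share of attentional weight), together
   with the nuisance timing parameters *t*~0~ (minimum effective exposure, ms)
   and *m*~μ~ (iconic-memory prolongation for unmasked displays, ms).
2. **Imaging side.** A resting-state functional-connectivity group pipeline:
   nuisance regression, Gaussian smoothing, motion and tSNR quality control,
   group decomposition into spatial components, template matching, two-stage
   dual regression, and group statistics — median-split two-sample designs
   with covariates, permutation cluster-extent family-wise-error control,
   Bonferroni correction across networks, one-tailed inter-network Fisher-z
   tests, and intra- vs inter-network partial correlations.

Because no subject-level data are available for this design, every stage is
exercised on synthetic data whose generating parameters are known, so the
package's tests are statements about *calibration and recovery*, not about
any real cohort.

## The race model

A display of *n* items is processed as a race of independent exponential
clocks. Item *i* receives the attentional weight *w*~*i*~ determined by its
role (target/distractor) and hemifield (left/right), and its encoding rate is

$$v_i = C \frac{w_i}{\sum_j w_j},$$

so the *total* rate across the display always equals *C*. An item is encoded
if its clock rings within the effective exposure τ, and at most *K* items are
retained in VSTM — the *first K finishers*. The effective exposure is
τ = max(0, *t* − *t*~0~)/1000 for masked displays and
τ = max(0, *t* − *t*~0~ + *m*~μ~)/1000 for unmasked displays (seconds; *t*,
*t*~0~, *m*~μ~ in ms at every interface).

Two exact consequences drive the implementation:

* **Whole report** scores only *how many* items were encoded, and
  min(#finished, *K*) does not depend on the finishing order. The score
  distribution is therefore the Poisson-binomial distribution of the encoding
  indicators (a binomial when weights are equal, which is always the case
  here because each whole-report display is a single-hemifield column),
  censored at the capacity draw. No enumeration over finishing orders is
  needed.
* **Partial report** scores *which* targets were retained, and there order
  matters. The probability that target *j* is reported is
  P(*T*~*j*~ ≤ τ and rank(*j*) ≤ *K*), computed exactly by
  inclusion–exclusion over the subsets of competing items; each term is a
  hypoexponential expression of the form *v*~*j*~(1 − e^−Rτ^)/R. Displays
  have at most 3 items (one or two targets, at most one distractor), so the
  enumeration is tiny.

Both routes are validated against an independent Monte-Carlo race simulator
(10^6 samples per condition) that implements the race directly, with no
shared code.

Non-integer capacities such as *K* = 3.03 are realised as the two-point
mixture on {⌊K⌋, ⌈K⌉} with mean *K* — the simplest integer-capacity mixture
consistent with non-integer whole-report asymptotes. Weights are scale
invariant (only ratios matter), so one weight — the right-hemifield target
weight — is pinned to 1 during fitting.

### Design and calibration

The simulated tasks reproduce the study design exactly: 192 whole-report
trials in 12 conditions (2 masking × 3 exposures × 2 hemifields; 4 blocks of
48, balanced within block) and 288 partial-report trials in 16 conditions
(4 single-target, 8 target-plus-distractor, 4 dual-target on the corners of
an imaginary square; 6 blocks of 48, balanced). Exposures are individually
calibrated the way the tasks' pretests do it: the whole-report anchor *t*\*
solves E[masked score] = 1 letter (bisection to 0.1 ms) and the task uses
{0.5 *t*\*, *t*\*, 2 *t*\*}; the partial-report exposure solves
P(single-target report) = 0.80. The letter count per whole-report column (6)
is a configuration choice.

### Estimation

Fitting proceeds in two stages mirroring the two tasks. The whole-report
likelihood over score counts yields (*C*, *K*, *t*~0~, *m*~μ~); the
partial-report likelihood over per-target report indicators — with capacity
fixed from the whole-report fit and its own sensory rate and *t*~0~, since
the tasks' display regimes differ — yields the four weights and hence α and
*w*~lat~. Each stage minimises the negative log-likelihood with bounded
L-BFGS-B from a deterministic Latin-hypercube of starting points (10 for
whole report, 6 for partial report), seeded by the subject id. Bounds:
*C* ∈ [1, 100] items/s, *K* ∈ [0.5, 6], *t*~0~ ∈ [0, 60] ms,
*m*~μ~ ∈ [0, 500] ms, free weights ∈ [10^−3^, 30]. The weight upper bound is
deliberately far above 1: with the right target weight pinned, representing a
left-ward laterality (*w*~lat~ > 0.5) requires a left weight above 1, and
about half of a population centred at *w*~lat~ ≈ 0.49 sits there.

Two properties of this design are worth knowing. First, because all 16
partial-report conditions share a single calibrated exposure, the partial
sensory rate and its *t*~0~ are only jointly identified (their product with τ
is what matters); the weight *ratios* — the quantities of scientific interest
— remain identified through the accuracy differences between condition
types. Second, α estimates from a single 288-trial session carry appreciable
sampling noise (SD ≈ 0.18 at α = 1); the estimator is unbiased, and tests
that assert α-recovery average over replicate sessions.

Dual-target outcomes are generated from the *joint* race (both targets
compete for capacity), while the likelihood uses the exact per-target
marginals — a composite likelihood, consistent because the marginals are
exact.

## The synthetic population

Subjects are drawn independently per parameter (the parameters are
empirically uncorrelated) from truncated normals with means and SDs matching
the published cohort: *C* 25.89 ± 7.34, *K* 3.03 ± 0.47, α 0.52 ± 0.21,
*w*~lat~ 0.49 ± 0.06, n = 31. The published summary does not report *t*~0~
and *m*~μ~ distributions; the generator uses 10 ± 5 ms and 150 ± 50 ms,
values in the range typical of healthy young adults, fixed once. Education
(integers 9–13 years) and gender (balanced binary) are generated as pure
nuisance covariates with no effect on connectivity. Truncation keeps every
draw inside the model's valid ranges (e.g. *K* ≥ 1.2 so the one-letter
calibration criterion is attainable).

## The synthetic resting-state scene

Each subject's 4D image is

$$Y(v, t) = 100 + \sum_g \mathrm{template}_g(v)\, \mathrm{gain}_{s,g}\,
\mathrm{tc}_{s,g}(t)\cdot s_{\mathrm{sig}} + \mathrm{drift}(t) +
\mathrm{artifact}(t) + \varepsilon,$$

with smooth nonnegative unit-peak blob templates (pairwise spatial |r| <
0.3), network time courses drawn from a specified G×G correlation structure
(baseline inter-network r = 0.15, mildly AR(1)-smoothed, which preserves
contemporaneous correlations), per-subject coupling gains ~ N(1, 0.25),
linear-plus-cosine drift, a global intensity artifact locked to the
displacement speed of simulated random-walk motion traces, and white
Gaussian noise (signal scale 2, noise SD 1). The default grid is 24×24×12
voxels with 250 volumes at TR = 2.608 s — the acquisition length of the
study, on a grid scaled far below MNI resolution so a 31-subject scene
simulates in seconds.

Group effects are planted in two ways:

* **Intra-network**: the coupling gain of one network gets a between-group
  mean shift of *d* × gain-SD; the default direction plants *lower* coupling
  in the "high" group, matching the observed higher-speed/lower-intra-FC
  pattern.
* **Inter-network**: the generating Fisher-z correlation of one network pair
  differs by group (defaults 0.269 vs 0.116, the reported group means for
  the ventral-attention/right-frontoparietal pair).

What the generator does **not** emulate: hemodynamic response shapes,
physiological noise spectra, spatial noise correlations, susceptibility
artifacts, registration error. Passing tests therefore demonstrate that the
*analysis chain* is correct and calibrated under exchangeable Gaussian
noise, not that it is robust to every property of real BOLD data.

## Pipeline choices

* **Nuisance regression before smoothing**, with the six motion parameters
  and the global signal (the synthetic scene has no tissue compartments, so
  white-matter/CSF regressors have no analogue). Global-signal regression
  removes some genuinely shared network variance — visible as a downward
  bias of inter-network z estimates relative to the generating values; group
  *differences* are preserved.
* **Smoothing**: separable Gaussian, σ = FWHM/(2√(2 ln 2)), reflective
  boundaries (conserves the image sum exactly); default 4-mm FWHM at 2-mm
  voxels.
* **Motion QC**: cumulative translation/rotation = maximum Euclidean
  displacement from the first volume; point-to-point = mean volume-to-volume
  displacement; exclusion at 3 mm / 3° / 0.15 mm / 0.1°. Extreme-value
  screening flags subjects beyond the 5th/95th percentile of tSNR, mean
  volume-to-volume motion, or outlier-volume proportion.
* **Group decomposition**: per-voxel variance normalisation, incremental
  (memory-bounded) group PCA over temporally concatenated subjects, then a
  symmetric fixed-point ICA rotation (logcosh contrast) to spatially
  independent maps, signs fixed by positive skewness, deterministic given
  the seed. This is a deliberate simplification of probabilistic ICA: the
  scientific content exercised downstream is the
  decomposition-then-dual-regression pattern, not noise-floor estimation or
  mixture-model map thresholding. Group maps can also be injected directly
  (`use_planted_maps`), which makes the downstream stages fully
  deterministic — the configuration used for acceptance runs.
* **Dual regression**: stage 1 regresses every volume on all maps jointly;
  stage 2 regresses every voxel on all variance-normalised stage-1 time
  courses jointly and standardises coefficients by the residual noise
  (t-type Z-maps). Near-collinear map sets (condition number > 10^8) are
  rejected.
* **Cluster inference**: one-sided height threshold t at p < 0.001 with
  df = n − 7, 26-connected components (configurable to 18 or 6), and
  cluster-extent FWE by permutation of the group labels with covariates
  held fixed — exact under exchangeability, replacing random-field theory.
  Corrected p-values use the add-one estimator
  (1 + #{perm max ≥ observed})/(1 + n~perm~), which can never be
  anti-conservative. Bonferroni across the 6 networks (0.05/6 = 0.0083) and
  across the 5 tested pairs (0.01) sit on top, as in the original design.
* **Median splits**: rank by performance (higher is better for *C* and *K*,
  lower for α; for *w*~lat~ the split separates right- from left-preference),
  ties broken by subject id, top ⌈n/2⌉ labelled "high" — 16/15 at n = 31.
  The group factor enters the GLM as two cell-mean columns plus five
  mean-centred covariates (the three remaining TVA parameters, education,
  gender), matching the 24 residual df reported for this design at n = 31.
* **Fisher z**: inter-network connectivity is atanh(r) of stage-1 time
  courses; |r| is capped at 1 − 10^−15^ and flagged. One-tailed pooled-
  variance t-tests (df = n − 2) compare groups, the direction being
  high > low.

## Problem sizes and determinism

All simulations are pure functions of (specification, seed); per-subject
streams are derived from the subject id so that cohort composition does not
perturb individual subjects. The shipped tests run the race-model oracle at
10^6 samples per condition, parameter recovery at the full trial counts over
50 subjects, FWE calibration over 200 null scenes on a 12×12×6 grid, and
planted-effect sign recovery over 100 scenes on a 16×16×8 grid — sizes
chosen so the whole suite completes on a laptop-class single core in a few
minutes while keeping Monte-Carlo error well below the asserted margins. The
replicated sign-recovery experiment derives its median splits from the
generating *C* values; the measurement stage (fit, then split) is validated
separately by the recovery experiment, which shows ≳80% split concordance
between fitted and generating parameters, and the single full study run
(`run_study` with `fit_tva = TRUE`) exercises the complete chain including
estimation.

## Known limitations

* The partial-report sensory rate and *t*~0~ are not separately identified
  at a single exposure duration (by design of the original task); only their
  combination and the weight ratios are interpretable.
* α estimates from one session are noisy (SD ≈ 0.2); studies needing tight
  α should average sessions.
* Cluster-extent significance for a single 31-subject cohort at d = 1.2 is
  variable (the planted effect's *direction* is recovered essentially
  always; its cluster-level p fluctuates around the threshold when the
  median split is taken from fitted rather than generating parameters).
* The ICA stage assumes spatially sparse (super-Gaussian) sources; grossly
  overlapping templates or very low dimensionality will degrade matching.
* Permutation inference assumes exchangeability of subjects under the null;
  it is exact for the synthetic scenes and approximate whenever real
  covariate structure breaks exchangeability.
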