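---
title: "Modelling individualized antihypertensive response in arterial stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individualized antihypertensive response in arterial stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvrec)
library(dplyr)
```

## The problem

Arterial stiffness, measured by pulse wave velocity (PWV), is an independent
cardiovascular risk factor, and different antihypertensive drug classes
reduce PWV to different degrees in different patients. `pwvrec` implements a
complete analysis for asking, per patient: *which of six drug classes (ACEI,
ARB, beta-blocker, diuretic, diuretic+ACEI, diuretic+ARB) is predicted to
reduce this patient's PWV the most?*

The design is a T-learner: one outcome model per treatment arm, each fitted
only on the patients who actually took that drug, predicting the
standardized one-year change in PWV from 64 baseline covariates. Querying
all six models for one patient yields six counterfactual predictions; the
recommendation is the argmax. Because real multicohort data of this design
is not publicly deposited, the package ships a synthetic cohort generator
with *known* heterogeneous effect functions, so that the whole pipeline is
testable against a ground-truth policy.

## The outcome and its preprocessing

Both carotid-femoral PWV (cfPWV, SphygmoCor-style) and brachial-ankle PWV
(baPWV, VaSera-style) are primary outcomes. baPWV devices estimate velocity
from the arm-ankle transit time and a height-based path length,
`baPWV = (0.5934 * height_cm + 14.4724) / t_ba` (cm/s); `compute_bapwv()`
exposes that conversion as a standalone utility (the transit time itself is
not part of the modelling data).

The two modalities live on different scales (cfPWV around 9.5 m/s, baPWV
around 14 m/s), so each is standardized by the mean and SD of its *baseline*
distribution in the training partition; follow-up values reuse the baseline
parameters, so the change score is on one coherent z-scale. We use the
population SD convention (denominator `n`). The per-arm target is

> target = z(baseline) − z(follow-up), averaged over the two modalities,

so **positive values mean PWV reduction**, and the recommender maximizes.
Averaging the two standardized changes is a deliberate resolution of an
ambiguity — one target per arm is needed but both modalities are primary
outcomes; a `modality` switch allows cf-only or ba-only targets for
sensitivity analyses. Outcome values are never imputed: a patient lacking
follow-up PWV is excluded (imputing a target would leak the imputation model
into the evaluation). Covariates are imputed with per-column medians
(midpoint convention; binary covariates get the majority value as their
median), and the training medians are reused verbatim on held-out data.

Patients on drug classes outside the six modelled groups, or in classes with
fewer than 10 patients, are excluded; a class with exactly 10 is retained.

## Per-arm models and feature reduction

Each arm's model is a bagged regression forest (via `ranger`) with
feature-subsampled splits. Defaults follow common regression-forest
practice: 300 trees, `mtry = p/3`, minimum node size 5, bootstrap
resampling. Two importance measures are computed on the fitted full-feature
model:

* **MDI** — impurity (variance-reduction) credit accumulated over splits,
  normalized to sum to one; fast but biased towards high-cardinality
  features.
* **Permutation importance** — mean increase in squared-error loss when one
  feature column is shuffled (`n_repeats` shuffles, baseline computed
  once); computed on the training partition. A feature the forest never
  uses scores exactly zero.

Selection uses the *consensus rank* — the mean of the two ranks, ties broken
by the better MDI rank, then alphabetically — keeping the top 10 features
per arm, and the arm model is refitted on those 10 features only. MDI-only
or permutation-only selection is available (`measure`); which single
measure "the" published ranking would correspond to is not determinable, so
exports label all three rankings. Feature selection happens inside the
training fold, after the holdout split, so selection cannot leak test
information into the internal validation.

Counterfactual predictions for patients who took a different drug are plain
model extrapolations — no propensity correction is attempted, matching the
source design. This is defensible in the synthetic study (assignment is
multinomial, independent of covariates by default; an `age_tilt` option can
break this) but is a known limitation on observational data.

## Validation schemes

* **Internal**: a stratified 80/20 holdout. Stratification by drug class is
  an addition: per-arm test metrics are reported, and an unstratified split
  of a small cohort would routinely leave arms without test patients.
* **External**: the EVIDENT-labelled cohort is reserved untouched as the
  test set; the pooled EVA+LOD patients form the training set, enlarged by
  SMOTE-style interpolation to roughly four times the test size (an 80/20
  balance), proportionally over arms.

Metrics are R² (`1 − SS_res/SS_tot`, test-set mean in `SS_tot`) and MSE,
per arm, on the standardized-change scale.

### SMOTE for regression data

SMOTE is a classification technique; here the drug class plays the role of
the class label, and the interpolation
`synthetic = parent + u · (neighbor − parent)`, `u ~ U[0,1]`, is applied to
the **joint (features, target) vector**, so the synthetic target inherits
the same convex combination and the local feature-outcome relationship is
preserved. (Copying the seed point's target unchanged was the alternative;
interpolation was chosen and is flagged as an interpretation.) Neighbors
are the `k = 5` nearest same-arm points by Euclidean distance on z-scored
features, so no covariate dominates the metric. Binary features are
interpolated and thresholded at 0.5. Every synthetic sample's parentage and
interpolation coefficient are recorded, which is what makes the convexity,
class-purity, and no-test-leakage invariants *exhaustively checkable* in
the test suite.

## The recommender and its surrogate

`recommend()` takes the row-wise argmax of the n×6 prediction matrix, ties
broken towards the canonical drug order (deterministic; the source is
silent on ties). There is no minimum-benefit threshold by default — some
drug is always recommended — but `require_benefit = TRUE` withholds
recommendations when no predicted change is positive. Match rate (share of
patients whose actual drug is also the recommended one, per arm) and the
recommendation distribution are computed in exact fractions before any
formatting.

The policy is distilled into a from-scratch CART classifier
(`fit_surrogate()`): greedy binary splits on midpoint thresholds maximizing
the count-weighted Gini decrease, with a distinctive stopping rule — a node
becomes a leaf when its Gini impurity is **≤ 0.20**, alongside the usual
depth cap (10) and no-improving-split conditions. The impurity rule is
interpreted as a leaf condition on node impurity, not a minimum split gain.
Split ties go to the lower feature index, then the lower threshold, making
the tree fully deterministic. The surrogate is trained on the full feature
set (not only the per-arm selected features), since the distilled policy
may reuse any covariate. Fidelity — the fraction of patients where the tree
reproduces the forest recommendation — is reported both in-sample (the
apparent-accuracy convention) and on the held-out fold, since the
convention behind a single published in-sample-looking number cannot be
verified. Rendering truncates to 5 levels by default for interpretability;
JSON and Graphviz DOT exports carry the full tree.

The test suite checks the implementation against an independent
exhaustive-enumeration CART oracle on small datasets, node for node.

## The synthetic cohort generator

`generate_cohort()` emulates the pooled three-cohort design:

* **Covariates**: the 64 candidates of `feature_schema()` (demographics,
  lifestyle, medication flags, anthropometrics, hemodynamics including
  baseline cfPWV/baPWV, biochemistry) drawn independently — truncated
  Gaussians at the published pooled means/SDs with physiological ranges,
  Bernoulli for binaries. The truncated normals are location-corrected so
  the *truncated* mean equals the target mean (one-sided floors on skewed
  biomarkers such as insulin or GGT would otherwise bias the marginal);
  the SD of heavily truncated covariates shrinks somewhat, which we accept.
  Independence is a documented simplification: no attempt is made to
  reproduce the real correlation structure (e.g. height–weight), which is
  sufficient for exercising the pipeline but means the generator does not
  test robustness to collinear importance attribution.
* **Assignment**: multinomial at the observed arm proportions
  (44/47/17/14/28/44 of 194); cohort labels at the observed 29/29/42 split.
  An optional logistic `age_tilt` mimics non-randomized allocation.
* **Effects**: each arm's true effect is
  `g_d(x) = base + Σ β_k · z(modifier_k)`, with modifiers mirroring the
  top-ranked predictors reported per class (weight and HbA1c for ACEI,
  baseline cfPWV and LDL for ARB, TSH and DBP for BB, CAVI and waist for
  diuretics, AIx75 and uric acid for diuretic+ACEI, basophils and MPV for
  diuretic+ARB) and standardized coefficients (0.6, 0.4, 0.2, 0.1) m/s per
  SD. The base reduction is a common 0.6 m/s — keeping arm *means* equal so
  that the oracle policy is driven by effect heterogeneity, which is the
  phenomenon under study, not by a uniformly dominant arm. These magnitudes
  are of the order reported for antihypertensive PWV reductions in
  longitudinal studies.
* **Outcomes**: `followup = baseline − g_d(x) − ε` per modality,
  `ε ~ N(0, noise_sd)` independently per modality (default 0.2 m/s, about a
  quarter of the effect spread). Baseline PWV is drawn truncated to
  [5, 30] m/s so noiseless follow-ups stay physiological without any
  clamping — clamping would break the exact identity
  `baseline − followup = g_d(x)` at `noise_sd = 0` that the tests rely on.
* **Truth object**: the generator returns the full n×6 effect matrix and
  the oracle policy (row argmax), so policy recovery is measurable.
* **Cohort shift**: `cohort_shift_sd` shifts all continuous covariates of
  EVIDENT patients by a fixed number of SDs, creating a controlled
  external-validation gap.
* A single drug per patient is assigned; how patients who switched drugs
  during follow-up should enter the per-arm outcome vectors is unresolved
  in the source design, and the generator deliberately does not model
  switching.

What passing tests on this generator do **not** show: performance on real
data with correlated covariates, informative missingness, measurement
drift between devices, or confounded treatment assignment.

## Problem sizes and numerical choices

The simulation studies in the test suite and the acceptance script use
fixed, documented sizes chosen as the package's own study conditions:
policy recovery on cohorts of n = 2000 (10 seeds, noise = 0.25× the effect
spread); counterfactual recovery on n = 1500 at noise ∈ {0, 0.5, 1.0} m/s;
feature-selection recovery on single arms of n = 2000 with 10 informative
and 54 noise covariates; external-degradation on n = 900 with a 0.5 SD
EVIDENT shift. For these studies the forests use 100–250 trees,
`mtry_frac = 0.6` and minimum node size 2 rather than the package defaults:
after reduction the 10-feature set is mostly informative, so the stronger
split subsampling of `p/3` adds bias without a variance pay-off, and noise
in the targets is modest by construction. Permutation importance uses 2–3
repeats there (default 10): batched-prediction shuffles are stable enough
at these n. All randomness flows from explicit seeds; generator calls
restore the caller's RNG state. Ranger is run single-threaded for exact
reproducibility across machines.

Degenerate inputs are handled explicitly rather than silently: constant
targets yield a warning and a constant predictor; zero-variance PWV,
fully-missing columns, unknown drug classes, non-finite predictions, empty
feature lists, and undersized SMOTE arms are errors naming the offending
object.

## Known limitations

* Independent covariates in the generator (above).
* No causal adjustment: per-arm regressions recover conditional means under
  (near-)randomized assignment only.
* No multi-visit trajectories or drug switching; exactly one baseline and
  one follow-up.
* No cross-validation or bootstrap uncertainty for the validation metrics;
  point values only, matching the reporting convention the package mirrors.
* The SMOTE-for-regression interpretation (joint-vector interpolation) is
  one of several defensible readings.
* Policy recovery is bounded by feature-selection recall: the weakest
  simulated effect modifier (0.1 m/s per SD) explains under 2% of the
  target variance at a few hundred patients per arm, so the top-10
  selection occasionally misses it, and held-out agreement with the oracle
  policy under the default study conditions plateaus just below 80%
  (the simulation study in the test suite computes the exact figures;
  with the true modifiers supplied, the same forests reach ~84%).

## A worked example

```{r example, eval = FALSE}
sim <- generate_cohort(n = 600, seed = 1)
res <- pwv_pipeline(sim$cohort, seed = 1,
                    hyperparams = default_hyperparams(n_trees = 150),
                    n_repeats = 3, min_group_size = 5)
res$validation        # per-arm held-out R2 / MSE
res$match$per_drug    # per-arm match rates
glance(res)           # one-row summary
render_tree(res$surrogate, levels = 3)
```
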