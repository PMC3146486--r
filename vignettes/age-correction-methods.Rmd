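---
title: "Control-only voxel-wise age correction: model, evaluation engines, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-only voxel-wise age correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(agedetrend)
```

## The model

Grey-matter (GM) density maps decline with age, and in dementia the
age-related decline points in the same direction as the disease-related
atrophy.  When patient and control groups cannot be matched subject by
subject — or when a multivariate classifier offers no covariate slot —
this package removes the age-explained component *before* any statistical
evaluation.

At each in-mask voxel $v$ an ordinary-least-squares line is fitted over
healthy controls only:

$$y_i(v) = \beta_0(v) + \beta_{\mathrm{age}}(v)\, a_i + \varepsilon_i,$$

with $a_i$ the age in years.  The estimates are the closed-form
two-parameter solution of the normal equations, computed vectorised across
the mask (`fit_age_model`).  Correction subtracts the age-explained part
from **all** subjects, patients included:

$$y^{c}_i(v) = y_i(v) - \hat\beta_{\mathrm{age}}(v)\, a_i.$$

Assumptions worth stating plainly:

* **Linearity in age** over the cohort's age range.  A linear rather than
  quadratic model follows the large-cohort evidence that quadratic age
  terms in GM are not significant; no nonlinear option is provided.
* **Controls carry the ageing signal.**  Fitting on patients would absorb
  disease-by-age interactions into the "ageing" estimate; the API takes
  controls and patients as separate arguments so this cannot happen by
  accident.
* **Uncentered subtraction.**  The corrected value subtracts
  $\hat\beta_{\mathrm{age}} a_i$ with raw age, exactly as the method's
  formula states.  Relative to mean-centred subtraction this shifts every
  subject by a voxel-wise constant, which cancels in any two-sample
  contrast; `center_age = TRUE` gives the centred alternative.
* **No clipping.**  Corrected densities may leave $[0, 1]$; they are not
  clipped, since all downstream statistics are location/contrast-based.
* Degenerate voxels (zero variance across controls) receive
  $\hat\beta_{\mathrm{age}} = 0$ and $\hat\beta_0 = $ the constant — the
  limit of vanishing signal, avoiding NaN propagation.

### Strict cross-validation

`correct_strict_cv` splits the controls into two seeded halves (odd counts
put the extra subject in half 1, deterministically), fits an age model per
half, and corrects each control only with the *other* half's model.
Patients are randomly halved with the same seed and patient half $k$ is
corrected by model $k$; the 1/2 model assignment is recorded so it can
enter downstream designs as a covariate.  The pooled refit of
cross-corrected controls is unbiased around zero slope but retains the
sampling noise of *two* half-sample estimates weighted by their age
moments — about $7\times10^{-4}$ GM/yr SD at 60 controls and noise 0.02 —
which is why the strict-CV tests assert 50%/90% and 80%/50%
reduction/coverage levels rather than anything sharper.

## Mass-univariate engine

`glm_t_map` computes per-voxel $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\,
c^\top (X^\top X)^{-1} c}$ for any full-rank design; `vbm_design` builds
the standard intercept + group + covariates design with a contrast on the
group column (positive $t$ = first level higher, i.e. controls > patients
for atrophy).  Sex is coded as a single 0/1 column, as is the strict-CV
model indicator.

**Degrees of freedom.**  Nominal df is $n - \mathrm{rank}(X)$.  Because the
age pre-regression consumes a parameter that the final model no longer
sees, `df_adjust` optionally reduces df by the number of pre-regression
parameters; the default is nominal df and the choice is recorded in the
cluster-report metadata.

**Equivalence of regimes.**  With age as covariate (b) and with
age-corrected inputs (c), the two analyses coincide exactly — a
Frisch–Waugh–Lovell argument — only when (i) the fitting set *is* the
analysed set, (ii) group is orthogonal to age (identical age vectors in
both groups), and (iii) df is adjusted by one.  The package asserts this
equivalence in a dedicated test and equally asserts that with the method's
control-only fit on a confounded cohort the regimes genuinely differ:
that difference is the method's point.

**Cluster-extent FWE.**  The original analyses used parametric
random-field cluster p-values; this package deliberately substitutes
permutation-based cluster-extent FWE: threshold at the one-tailed
`voxel_p` quantile of $t(\mathrm{df})$ (default 0.001), label connected
components (connectivity 18 by default; 6 and 26 available), and compare
each observed cluster's size against the permutation distribution of the
*maximum* cluster size.  Permutations follow the Freedman–Lane scheme —
residuals under the nuisance-only model are permuted and the full model
refitted — so covariate structure is preserved.  Corrected p uses the
$(1 + \#\{\max \ge s\})/(n_{\mathrm{perm}} + 1)$ estimator; a map with no
suprathreshold voxel yields an empty report, not an error.

A calibration caveat discovered while validating: on *unsmoothed* iid
noise the max-cluster-size null is concentrated on {0, 1}, making the test
vacuously conservative (observed FWE near 0.005).  This is not an
implementation defect but a property of cluster-extent inference on
spatially unstructured data; the pipeline this engine serves always
smooths first, and on smoothed null phantoms the measured false-positive
rate is ~0.045 against the nominal 0.05.

## Classification engine

`split_half_svm` stratifies a seeded half-split, trains a linear SVM on
each half and classifies the other; accuracy is the percentage of all
subjects correctly labelled across both directions.  The SVM is an
in-package SMO solver (maximal-violating-pair working set, unpenalized
bias — the LIBSVM formulation), exact on the $n \times n$ Gram matrix and
deterministic.  `C = 1` because no tuning protocol is prescribed; features
are raw masked voxel values in fixed grid order (GM maps share units), with
an optional standardization flag whose state is recorded.

`permutation_accuracy` repeats the split `n_repeats` times (repeat $r$
re-seeds with `seed + r`; the *same* split is applied to corrected and
uncorrected features) and compares the two accuracy distributions with an
independent-samples pooled t.  The repeats share the data, so they are not
independent — the independent-samples test is kept as the default because
it is what the evaluation protocol this package reproduces used; a paired
alternative over the shared splits is available (`paired = TRUE`).  The
strict-CV detrending split is held fixed across repeats.

`misclassified_age_test` compares ages of misclassified controls vs
misclassified patients (pooled t, one-tailed in the confound direction:
misclassified controls older).  Too few misclassified subjects raises a
typed condition rather than failing: a (near-)perfect classifier makes the
question unanswerable, which is itself the expected post-correction
outcome.

## The phantom world

`generate_cohort` draws, per subject and voxel,

$$y = \mathrm{baseline}(v) + \beta_{\mathrm{age}}(v)\,a_i +
      \delta\,\mathbf{1}[\mathrm{patient}]\,\mathbf{1}[v \in \mathrm{atrophy}]
      + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$

on a 16³ grid of 1 mm voxels by default: smooth baseline around 0.5,
ages uniform on 60–90 y, slope −0.003 GM/yr, noise SD 0.02, and returns the
ground truth for recovery tests.  All randomness flows from one seed;
identical seeds give bit-identical cohorts.

Two named scenarios instantiate the confound:

* **Classification scenario** (`confounded_phantom_spec`): age-*matched*
  groups, slope −0.005 GM/yr (steep end of reported focal ageing decline)
  in a smooth sphere of radius 6, disease offset −0.05 (≈ a decade of that
  decline) in a nested sphere of radius 3, noise SD 0.06.  The noise level
  was calibrated once, before any acceptance test existed, to the declared
  rule that *uncorrected* split-half accuracy should land near the ~80%
  regime the method was reported in; with the recovery-test noise of 0.02
  the classifier is at 100% in both conditions and no confound can
  manifest.  Age-matching is deliberate: with a group-mean age shift a
  linear classifier exploits the shift itself and the misclassification
  pattern inverts; the reported classification cohort was age-matched and
  its confound acts purely through within-group age variance.
* **Mass-univariate scenario** (`vbm_scenario_spec`): 79 controls vs 25
  patients shifted ±10 y, slope −0.003 GM/yr, disease offset −0.03 — *one
  decade of the modeled ageing*, so that for patients 10 years younger the
  two effects cancel exactly in the group mean and the planted atrophy is
  invisible without correction, while for patients 10 years older healthy
  ageing masquerades as disease throughout the slope region.

What the phantoms do **not** emulate: anatomy, partial-volume effects,
spatially correlated between-subject variability (noise is iid by the
generator's contract), scanner and site effects.  Consequently a green
confound-rescue test establishes the *direction and significance* of the
correction benefit in a world satisfying the model's assumptions exactly —
not the specific percentages reported on real cohorts, which are
data-bound.  Notably, under iid noise at realistic cohort sizes the
split-half accuracy is a sharp function of the noise level (a cliff from
100% to chance), which is why the scenario sizes were fixed at 30 + 30.

## Numerical choices

* OLS via closed forms / `chol2inv(chol(X'X))`; rank checked by QR, rank
  deficiency and exhausted df raise typed conditions.
* Zero residual variance: $t = 0$ where the effect is also numerically
  zero, $\pm\infty$ otherwise (relative thresholds, not exact zero tests).
* Gaussian smoothing is an exact separable zero-padded convolution with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units,
  kernel truncated at $4\sigma$ and renormalized to unit sum; FWHM 0 is
  the identity.  Edge voxels lose mass by construction (no edge
  renormalization), matching common practice.
* Mask threshold is strict (`>`): a voxel at exactly 0.2 is excluded, per
  the rule's wording "exceed".
* NIfTI-1 I/O is a minimal self-contained implementation (no suitable R
  package is available in the target environment): 3-D/4-D single-file
  volumes, either endianness, datatypes uint8/int16/int32/float32/float64,
  `scl_slope`/`scl_inter`, sform affine; written files are float32 with
  sform, validated against nibabel in the test suite.
* The SVM stops at a maximal KKT violation of 1e-6; selection is
  first-index deterministic.

## Known limitations

* Single-covariate pre-regression only; multi-covariate pre-regression
  interacts with downstream covariates and is out of scope.
* Permutation FWE assumes exchangeability of subjects under the reduced
  model; heteroscedastic groups violate this mildly.
* The CLI loads whole cohorts into memory; it is sized for desk-scale
  phantom grids, not 1 mm whole-brain studies.
* Accuracy distributions from repeated splits are dependent; the default
  unpaired comparison inherits that approximation deliberately.
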