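---
title: "Voxel-wise radiogenomic mapping with boosted additive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise radiogenomic mapping with boosted additive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiogam)
```

## The problem

Gliomas are genetically heterogeneous: driver mutations (IDH1, TP53, EGFR,
PIK3CA, NF1, ...) vary between patients and between regions of one tumor,
and they shape the metabolic and cellular phenotypes that multiparametric
MRI (mpMRI) is sensitive to.  When a stereotactic biopsy is taken during
surgery, its coordinate in the presurgical image frame is known, and the
sequenced tissue can be colocated with the MR voxels it came from.  This
package implements that mapping as a reusable pipeline:

1. convert each biopsy's pathology volume into an equal-volume **sphere
   ROI** around the recorded coordinate, and normalize every contrast to
   the mean signal of a normal-appearing white matter (NAWM) region;
2. stack the ROI voxels of all patients into a **feature matrix** (one row
   per voxel: normalized signals per contrast, plus the patient's binary
   mutation status for one gene);
3. fit a **gradient-boosted additive model of decision stumps** predicting
   mutation status from the voxel signals;
4. evaluate every subset of the five standard contrasts (31 combinations)
   for every gene with **leave-one-patient-out (LOPO)** ROC analysis:
   mean TPR/FPR curves with SEM bands, trapezoidal AUC, pooled accuracy at
   FPR 0.2, and a one-way ANOVA comparing AUC across combinations.

Because clinical cohorts of this kind are not publicly shareable, the
package ships a **synthetic cohort generator** whose planted effect sizes
have a closed-form AUC, so every stage of the pipeline can be exercised
and calibrated without patient data.

## The model

The classifier is a regression GAM

$$ y = c + f_1(x_1) + f_2(x_2) + \dots + f_p(x_p), $$

where $x_j$ is the normalized signal of contrast $j$ at a voxel, $y$ is the
binary mutation status treated as a Gaussian regression target, $c$ is the
intercept, and each shape function $f_j$ is a sum of learning-rate-scaled
depth-1 regression trees (decision stumps) grown by gradient boosting.
Goodness of fit is measured by the Gaussian deviance
$D = -2(\log L - \log L_s)$, which under the unit-variance working
likelihood used here equals the residual sum of squares exactly (the
saturated model fits every point).

The boosting loop initializes $c = \bar y$ and then, per round, fits one
stump per feature to the current residuals (cyclic policy; a
best-feature-per-round policy is available).  Each stump's candidate
thresholds are midpoints of consecutive distinct sorted feature values,
its leaf values are mean residuals, and ties in SSE go to the smallest
threshold, so the fit is fully deterministic.  Because leaves are mean
residuals and the learning rate $\eta \in (0, 1]$, every accepted stump
changes the training RSS by $\eta(\eta - 2)\sum_i s_i^2 \le 0$: the
deviance trace is provably non-increasing, and the package asserts this
for every fitted model.

A binary response fitted by a *Gaussian* regression GAM is a deliberate
choice rather than an oversight: the downstream ROC analysis consumes
continuous scores and depends only on their rank order, so a logistic link
would change nothing the evaluation can see while complicating the
deviance accounting.

Key tuning parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `n_rounds` | 300 | boosting rounds; each adds one stump per feature (cyclic) |
| `learning_rate` | 0.1 | shrinkage $\eta$ applied to every stump |
| `feature_policy` | `"cyclic"` | stump scheduling across features |
| `threshold_step` | 0.05 | maximum ROC threshold step after min–max rescaling of scores |
| `min_class` | 2 | minimum mutated and wild-type patients per retained gene |

The defaults are fixed configuration constants: the number of rounds and
the learning rate are not tuned per dataset, and no early stopping or
pruning is applied, keeping every one of the 1,550 study fits identically
specified.

## The synthetic cohort

`generate_cohort()` draws, per patient, a Bernoulli genotype per gene
(default prevalence 0.5, a realistic figure for IDH1-class markers in a
mixed grade II–IV cohort) and one Gaussian signal volume per contrast on a
64³ grid at 1 mm isotropic spacing.  Outside the biopsy sphere — including
the fixed NAWM cuboid in a low-index corner — contrast $c$ is
$\mathcal N(\mu_c, \sigma_c)$; inside the sphere the mean is shifted by
$\sum_g z_g\, d_{g,c}\, \sigma_c$ for genotype $z$, so a mutated gene with
standardized effect $d$ separates tumor from reference voxels by exactly
$d$ noise SDs.  For two homoscedastic Gaussians this gives the closed-form
binormal AUC $\Phi(d/\sqrt 2)$ (`planted_auc()`), the oracle used by the
recovery tests: $d = 0, 0.5, 1, 2 \mapsto 0.5, 0.638, 0.760, 0.921$.

Choices made where the underlying study is silent:

* **Signal model.**  A homoscedastic Gaussian voxel model with additive,
  linearly composable gene-wise mean shifts — the simplest model with an
  exact AUC oracle.  Gene–gene interactions are deliberately excluded.
* **Default biopsy volume** 4.8 cm³ (the study's median pathology
  volume); the sphere radius follows $r = (3V/4\pi)^{1/3} \approx 10.46$
  mm.  Smaller volumes are used in the tests to keep problem sizes
  proportionate (see below).
* **Planted pattern.**  `glioma_effect_sizes()` places effects on
  gene-specific contrast pairs mirroring the qualitative radiogenomic
  findings the pipeline is meant to detect (IDH1 and TP53 on
  T2W-FLAIR + ADC, EGFR on T2W + ADC, PIK3CA on T1W + T1W-CE, NF1 on
  T1W + ADC); `cohort_config()` itself defaults to a null cohort.
* **Reproducibility.**  Each patient consumes an RNG sub-stream derived
  from the master seed, so cohorts are bit-reproducible and adding
  patients never perturbs existing ones.

What the generator does **not** emulate: anatomy, MR physics,
partial-volume effects, scanner/site heterogeneity, spatial correlation of
noise, or patient-level random effects.  Passing tests therefore
demonstrate algorithmic correctness and statistical calibration of the
pipeline under its own assumptions, not clinical performance on real
images.

## Feature extraction choices

* **Voxel membership** uses voxel-center distance — bit-reproducible and
  adequate in the 1 mm³ regime; no partial-volume weighting.
* **Normalization** divides each contrast by its *own* NAWM mean
  (`normalize = "per-contrast"`), because cross-contrast intensities are
  incommensurable; the literal single-scalar variant (all contrasts
  divided by the reference contrast's NAWM mean) is available as
  `normalize = "reference"`.  Both are scale-invariant and idempotent.
* **Substituted acquisitions** (e.g. a contrast-enhanced T2W standing in
  for T2W) are handled by a per-patient `contrast_alias` map rather than a
  renamed file, keeping provenance explicit.
* **Coordinates** are 0-based voxel indices in the reference frame; all
  volumes are assumed co-registered.  Stereotactic placement error is not
  modeled by default.
* A sphere that would leave the grid is an **error**, never silently
  clipped; multiple biopsies contribute the union of their voxels.

## Evaluation choices

Under LOPO a held-out patient carries a single label, so a per-fold ROC is
ill-posed.  The reconstruction used here: each fold contributes its
per-threshold positive-call fractions as a **TPR curve** (mutated patient)
or an **FPR curve** (wild-type); curves are averaged per threshold within
class, with the SEM $\sqrt{\sum_i (x_i - \bar x)^2 / (N(N-1))}$ over the
contributing folds, and the AUC is the trapezoid rule over the
(mean FPR, mean TPR) polyline anchored at (0,0) and (1,1).  A per-fold AUC
is reconstructed by pairing each fold's curve with the opposite class's
mean curve, and a pooled-voxel AUC over all folds is reported alongside as
a secondary diagnostic (`auc_fold_mean` and `auc_pooled` columns).

The threshold grid partitions the pooled score range at steps of 0.05
after min–max rescaling — reading the study's "maximum threshold of 0.05"
as a maximum threshold *step*, the only interpretation consistent with
score-scale ROC sweeps.  Undefined rates (empty denominators, SEM of a
single fold) propagate as `NA`, never as silent zeros.  Genes with fewer
than two mutated or two wild-type patients are excluded with a recorded
skip, mirroring the imbalance rule that excluded PTEN, PIK3R1 and RB1 from
the original analysis.

**Score centering.**  Fold scores are the model prediction *minus the
fold's intercept*.  Under LOPO the intercept equals the training-label
mean, which is $(n_+ - y_{\text{test}})/(n-1)$ — it encodes the held-out
label.  Left in place, this class-prior leakage shifts every mutated
fold's scores down by $1/(n-1)$ relative to wild-type folds and biases the
null AUC far below 0.5.  Subtracting the intercept is rank-preserving
within a fold and restores null calibration (measured null AUC range
0.46–0.52 across seeds); `center = FALSE` reproduces the uncentered
behavior.

**ANOVA caveat.**  The classical one-way ANOVA comparing per-fold AUCs
across combinations assumes independent observations, but LOPO folds share
$n-2$ of $n-1$ training patients, so fold AUCs are positively correlated
within and across combinations.  On null cohorts this makes the F test
strongly anticonservative (in our null calibration runs it is significant
in nearly every seed even though all AUCs lie within [0.45, 0.55]).  The
package reports the ANOVA for parity with the study's procedure, but its
p-values should not be read as calibrated null probabilities; a
heterogeneous real cohort inflates within-group spread and hides the
effect.

## Problem sizes

The study grid is 31 combinations x 5 genes x 10 patients = 1,550 model
fits.  The package's own end-to-end runs use: 2 cm³ spheres (~2,000 voxels
per patient, ~18,000 training rows per fit) with 300 rounds for the full
sweep; 4.8 cm³ spheres on 12 patients (>= 10⁴ pooled voxels per class) for
binormal recovery; and 1 cm³ spheres with 60 rounds across 5 seeds for
null calibration — sizes chosen so the whole suite completes comfortably
on a single CPU while keeping every statistical check at full strength.

## A worked miniature

```{r example, eval = FALSE}
cfg <- cohort_config(n_patients = 10, biopsy_volume_cm3 = 2.0,
                     effect_size = glioma_effect_sizes(1), seed = 42)
cohort <- generate_cohort(cfg)
sweep <- lopo_sweep(cohort, n_rounds = 300)
summary(sweep)
plot(sweep, gene = "IDH1")
plot(sweep$rocs$IDH1[["T2W-FLAIR+ADC"]])
```

## Known limitations

* The boosting schedule (rounds, learning rate, stump-per-feature
  scheduling) follows fixed defaults; no claim of bit-compatibility with
  any particular commercial GAM implementation is made.
* The per-iteration AUC distribution is a reconstruction (see above); the
  original study's construction for single-label test patients is not
  derivable from its description, so both the fold-level and pooled
  variants are reported.
* Image registration, NAWM segmentation, bias-field correction and tumor
  segmentation are upstream of this package and out of scope.
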