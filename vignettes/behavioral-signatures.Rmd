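---
title: "Behavioral signature classification from ADI-R item profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral signature classification from ADI-R item profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adirsig)
```

## The problem

Autism spectrum disorder is genetically heterogeneous, and a common working
assumption is that its many genetic risk factors produce behaviorally
indistinguishable presentations. `adirsig` implements an analysis pipeline
that interrogates that assumption: it asks whether distinct genetic
disorders carrying elevated ASD risk (22q11.2 deletion, Down's syndrome,
Prader-Willi, supernumerary marker chromosome 15, tuberous sclerosis
complex, Klinefelter syndrome) leave *signatures* in the profile of the 37
ordinal items of the ADI-R diagnostic algorithm — and whether a classifier
trained on such signatures says anything useful about idiopathic ASD and
about familiality in affected sibling pairs.

The pipeline has three steps:

1. **Supervised signatures.** A one-vs-one RBF-SVM ensemble is evaluated by
   nested leave-one-out cross-validation on the labeled cohort, with
   per-subject class probabilities obtained by Platt calibration and
   pairwise coupling.
2. **Blind allocation.** The classifier trained on the full labeled cohort
   is applied to unlabeled (idiopathic) profiles; non-randomness is probed
   with an item-permutation null (destroying profile patterns while
   preserving item marginals) and a label-permutation null (destroying the
   label-profile link while preserving label frequencies).
3. **Sibling familiality.** Assigned classes and probabilities of affected
   sibling pairs are compared: concordance chi-square, probability and PC1
   correlations (overall and split by concordance), a variance-equality
   F-test, and severity-versus-specificity regressions.

The clinical cohorts behind the original analysis are access-controlled and
not deposited, so the package ships a synthetic-cohort generator whose
defaults are calibrated to the published per-group summary table
(`adir_reference()`); all property suites run on these synthetic cohorts.

## The item model

The ADI-R algorithm scores 37 items at 0 (absent), 1 (present but
equivocal) or 2 (definitely present); a raw code of 3 (markedly disruptive)
is recoded to 2 so every item carries equal weight, and the conventional
not-applicable codes 7/8/9 score 0 (`recode_item()`). Items group into
domain I (reciprocal social interaction, ceiling 30), domain II
(communication, verbal, ceiling 24) and domain III (restricted/repetitive
behavior, ceiling 14). Two conventions matter (`domain_scores()`):

* items 69/71 and 77/78 enter domain III as the maximum of each pair, so
  domain III has 7 scored elements;
* exactly one of items 64 ("group play with peers", under 10 years) and 65
  ("friendships", 10 years and over) counts toward domain I. The boundary
  at exactly 120.0 months goes to item 65; the convention is ours to fix,
  as the age rule is printed as "<10.0" / ">10.0" with no boundary case.

The item-to-domain mapping is exposed as data (`adir_items()`), not wired
into code, because published algorithm versions differ in detail (e.g. the
domain placement of items 31 and 49); we follow the mapping as printed in
the source table and a user can swap in an alternative.

The ASD classification rule (`classify_asd()`) is the one used in genetic
studies: all three core domains at or above their cut-offs, or two met with
the third within one point, plus the age-of-onset criterion. The standard
verbal cut-offs (10/8/3, onset 1) are defaults of `adir_thresholds()`, not
constants, since they are instrument conventions rather than findings.
Missing item codes are not imputed: the analyses assume complete algorithm
data, and `read_cohort()` rejects incomplete profiles.

## The synthetic-cohort generator

The generator is a latent-severity ordered-threshold (graded-probit) model
— the simplest mechanism that simultaneously produces ordinal items,
inter-item correlation and group-specific signatures:

* each subject has a latent severity `t ~ N(0, severity_sd)` shared by all
  of their items (default `severity_sd = 1`);
* item `j` of group `g` has latent value `t + shift[g, j] + e`,
  `e ~ N(0, 1)`, thresholded at the two cut-points (defaults 0 and 1.2)
  into codes 0/1/2.

Group item shifts decompose into a **domain-level severity** component and
an **item-level signature** component. The domain component is
moment-matched by root finding (`calibrate_specs()`) so that each group's
expected domain means equal the published targets exactly (probit closed
form for simple items; numeric quadrature over `t` for the max-composites;
the item 64/65 branch weighted by the group's probability of being under
120 months). The signature component gives group `g` the offset
`amp * cos(2 * pi * g * j / 37)` on item `j` (`signature_pattern()`):
distinct frequencies give the groups near-orthogonal, equally strong item
patterns. The default amplitude 1.0 — comparable to the spread of the
calibrated domain shifts — is what "well-separated signatures" means in
this package's validation suites, and it is chosen once, here, as a design
parameter.

Demographics are drawn from the published per-group distributions (age,
sex, IQ); the onset score rises with latent severity. Sibling pairs share
a family severity component with intraclass correlation `sib_icc` (default
0.5) and share their latent class with probability `class_share` (default
0.5 — partial concordance, the rate being unreported). Idiopathic blind
samples are mixtures over the six signature classes; the default mixture is
TSC-heavy (0.60 TSC, 0.20 XXY, 0.10 22q11DS, 0.08 SMC15, 0.01 each Down's
and PWS), so the qualitative allocation pattern of the published blind
analysis — a dominant TSC class with occasional 22q11DS/SMC15/XXY — is
reproducible; it is configurable.

What the generator does *not* emulate: real pedigree structure beyond
affected pairs, age or sex effects on item codes, informant/rater effects,
and the richer dependence structure of real interview data (real items
correlate through multiple factors, not one severity trait). Passing the
property suites therefore shows that the *pipeline* recovers structure it
is designed to detect — not that real cohorts contain such structure.

Item permutation (`permute_items()`) shuffles each item column
independently across subjects: marginals are preserved exactly, profile
patterns are destroyed. We chose the marginal-preserving construction
(rather than uniform random codes) so permuted data remain score-like; the
alternative is a one-liner for a user who wants it.

## The classifier

Binary subproblems are solved by libSVM (through \pkg{e1071}) with the RBF
kernel `K(u, v) = exp(-gamma |u - v|^2)`; everything around them is
implemented here:

* **One-vs-one ensemble** (`fit_ovo_svm()`): `k(k-1)/2` binary machines;
  the predicted class is the pairwise-vote winner (`ovo_vote()`). Vote
  ties break by the largest summed signed decision margin, then the lowest
  class index — a documented deterministic rule.
* **Probabilities**: each binary's training decision values get a Platt
  sigmoid (maximum likelihood with Platt's prior-smoothed targets, so
  complete separation is well defined); at prediction time the pairwise
  probabilities are coupled by the second method of Wu, Lin and Weng — the
  libSVM coupling — via its fixed-point iteration
  (`couple_probabilities()`, stationarity tolerance 1e-12, cap 500
  iterations). The coupled vector is asserted nonnegative and
  unit-sum after every call. Note the vote winner and the probability
  argmax can differ in principle; the assigned class is the vote winner,
  and `p_assigned` is its coupled probability.
* **Features** are the raw 0-2 item codes, unscaled — the items already
  share one scale. When IQ is added as a 38th feature it is z-scored with
  training-set statistics only (inside every cross-validation fold, to
  avoid leakage).
* **Hyperparameter selection** (`inner_loocv_select()`): the grid point
  with the highest inner cross-validated accuracy; ties prefer the
  smallest cost, then the smallest gamma (the smoother model). The default
  full grid is `gamma` in `2^-7..2^3`, `cost` in `2^-3..2^7` on log2 steps
  of 2 (36 points); the published analysis names a grid but not its
  values, so these bracket the conventional `1/p` default generously.
* **Nested LOOCV** (`nested_loocv()`): outer leave-one-out for unbiased
  accuracy; inner selection on each `n-1` training set. Exact inner LOOCV
  is the default; `inner = "kfold"` substitutes stratified 10-fold inner
  CV, the documented fast approximation. Fold assignment is deterministic
  and order-invariant (round-robin within class by subject id), so
  repeated runs and row-shuffled cohorts give identical predictions.

On the outer leave-one-out step a 2-member class briefly becomes a
singleton in training; libSVM handles singleton classes, so the ensemble
fitter accepts them there while the user-facing surface keeps the
2-member minimum.

## Nulls and their expectations

Two distinct chance baselines matter and should not be conflated:

* `chance_accuracy(sizes)` = `sum(p_i^2)` is the expected accuracy of
  frequency-matched *random assignment* — about 21% for the study's group
  sizes. This is the published baseline.
* A *trained classifier on label-permuted data* is not random assignment:
  depending on the hyperparameters it drifts between majority-class
  prediction (accuracy `max(p_i)`, about 28% here) and highly local
  prediction (accuracy near `sum(p_i^2)`). The label-permutation suite
  measures where the pipeline actually lands; see the acceptance script
  for the computed gap.

## Sibling statistics

The concordance chi-square is computed directly (Pearson statistic over
cells with positive expectation, `df = (k-1)^2`, no continuity correction)
rather than through `chisq.test()`, because the class dimension `k` is
fixed by the classifier even when some classes are never assigned;
`chisq.test()` cannot hold the df at `(k-1)^2` on tables with empty
margins. On dense tables the two agree exactly (a unit test asserts this).
Sparse tables are flagged — the chi-square approximation is rough there and
the test errs conservative.

Correlation comparisons between concordance strata use Fisher's z (the
published analysis reports a comparison without naming a method).
The variance-equality F-test inherits the usual normality sensitivity:
on strongly platykurtic probability differences it is conservative.
The "severity" covariate in the severity-versus-specificity regressions is
the mean of the 37 recoded codes ("mean items score" with the formula left
unstated in the source; the mean is the natural reading).

PC1 summaries use covariance-matrix PCA (centered, unscaled) fitted on the
pooled sibling cohort, consistent with the common-scale argument above;
a correlation-matrix option and fitting on the labeled training sample are
available flags. PCA signs follow the largest-magnitude-loading-positive
convention so scores are reproducible; blind samples are projected with
the training model's centers and loadings, never refitted.

## Validation-suite problem sizes

The package's heavier checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use sizes chosen to make the Monte-Carlo answer
clear while keeping a full run comfortably interactive on one CPU:

* signal recovery: the calibrated 322-subject cohort, nested LOOCV with the
  reduced 2x2 grid (`signature_grid(reduced = TRUE)`) and inner 10-fold CV;
* label-permutation null: a half-size calibrated cohort (sizes 45, 10, 44,
  11, 25, 25), 20 replicates, fixed hyperparameters (`gamma = 2^-5`,
  `cost = 1`) — the documented cheap null mode;
* blind-allocation contrast: 300 blind subjects against their
  item-permuted copy;
* familiality: 400 pairs for the sharing recovery (class sharing 1.0,
  severity ICC 0.8, uniform class mixture so both concordance strata are
  populated), and 500 replicates of 200 independent pairs for the type-I
  suite (uniform mixture again, keeping the concordance table as dense as
  the design allows).

These sizes are the package's own choices; anything larger is a parameter
change away.

## Known limitations

* The linear item-importance weights are a primal approximation that is
  heuristic for RBF machines; permutation importance (on held-out data —
  on training data the kernel memorizes profiles and importances collapse
  to zero) is the more defensible alternative and is provided.
* Exact inner LOOCV at several hundred subjects is computationally heavy;
  the k-fold inner approximation is the practical default for large grids.
* The concordance chi-square needs a reasonably dense assignment table;
  with a rarely-assigned class (as for Down's syndrome in the published
  confusion table) it is conservative.
* Splitting sibling correlations by assigned-class concordance is not an
  innocuous stratification: conditioning on "both sibs assigned to class
  c" pulls both PC1 scores toward class c's centroid, so the concordant
  stratum shows positive correlation *even for independent siblings*
  whenever class centroids differ. The package's type-I suite measures
  this selection effect directly; concordant-versus-discordant contrasts
  should therefore be read as descriptive, not as calibrated tests.
* Under *full* class sharing, "discordant" pairs are classification errors
  only, and a strong shared severity trait equalizes the strata's PC1
  correlations — the contrast is informative only under partial sharing.
* Published headline numbers (63% overall accuracy, the pairwise table,
  the sibling correlations) were computed on confidential clinical data
  and are not reproduction targets; the package validates arithmetic
  identities on the printed tables and distributional properties on
  synthetic cohorts.
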