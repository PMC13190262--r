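---
title: "Multi-task joint learning for plasma-proteomic diagnosis: models and methods"
author: "ProteoDx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task joint learning for plasma-proteomic diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ProteoDx builds and interrogates a multi-task diagnostic classifier for
high-dimensional plasma proteomics. One blood draw yields thousands of
aptamer-based protein abundances (relative fluorescence units, RFU); the
package turns such a matrix into six simultaneous calibrated probabilities —
cognitively unimpaired control, Alzheimer's disease (AD), Parkinson's
disease (PD), frontotemporal dementia (FTD), amyotrophic lateral sclerosis
(ALS), and previous stroke/TIA. This vignette documents the model, the
assumptions behind every stage, the tunable parameters, and what the
synthetic cohorts used by the test suite can and cannot show.

## Why multi-task, why these losses

Cohorts aggregated across many contributing sites rarely assess every
participant for every condition: a participant diagnosed with AD may never
have been evaluated for PD. A multi-class softmax would force imputation or
exclusion of such rows. ProteoDx instead trains six sigmoid heads on a
shared trunk, and every head learns only from the participants whose label
for that condition is observed (ternary labels: positive / negative /
missing). Co-pathology — genuinely positive for two conditions — is
representable for the same reason.

The training loss combines two terms. First, a label-smoothed binary
cross-entropy over the observed entries,

$$L_\mathrm{BCE} = -\frac{1}{M}\sum_{(k,i)\,\mathrm{obs}}
  \Big[\big(y_{k,i}(1-\alpha)+\tfrac{\alpha}{2}\big)\log \hat y_{k,i}
  + \big((1-y_{k,i})(1-\alpha)+\tfrac{\alpha}{2}\big)\log(1-\hat y_{k,i})\Big],$$

where $M$ is the number of observed label entries. Normalizing by $M$
rather than by participants times tasks keeps the loss scale comparable
across missingness patterns; with complete labels the two coincide up to
the constant factor 6. Label smoothing ($\alpha$, default 0.05) softens
hard targets against noisy clinical annotations. Second, a pairwise rank
hinge across conditions,

$$L_\mathrm{RL} = \frac{1}{N'}\sum_k \sum_{i<j}
  \max\big[0,\ (\hat y_{k,i}-\hat y_{k,j})(y_{k,j}-y_{k,i})
  + \varepsilon\big],$$

restricted to pairs with both labels observed, with margin
$\varepsilon = 0.25$. For a participant positive for $i$ and negative for
$j$ the hinge is zero once $\hat y_{k,i}$ exceeds $\hat y_{k,j}$ by the
margin; this constrains the *ranking* of probabilities within a
participant, which resists the heavy prevalence imbalance across the six
conditions. The formula is kept literal: an equal-label pair contributes
the constant $\varepsilon$ and exactly zero gradient (a configuration
switch drops such pairs instead). $N'$ counts participants with at least
one observed pair, so a participant with no labels leaves both loss terms
unchanged — a property the tests assert. The total loss is
$L = L_\mathrm{BCE} + \lambda L_\mathrm{RL}$ (default $\lambda = 0.5$).
Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logarithms.

## Architecture and training

The network is a fully connected trunk (default widths 128 and 64) with a
smooth GELU-type gate $x\,\sigma(1.702x)$ and dropout (default 0.1) after
each trunk layer, a *linear* embedding layer (default 32 dimensions), and
six linear heads with sigmoids. The heads combine the embedding linearly
by design: that makes the embedding a reusable low-dimensional proteomic
summary and justifies covariance-based interpretation (below). Training
uses Adam (learning rate $10^{-3}$, decoupled weight decay $10^{-4}$,
batch 256) with early stopping on validation loss (patience 8, cap 60
epochs). All randomness — initialization, shuffling, dropout — derives
from the model seed, so two runs at a fixed BLAS thread count produce
identical weights. Per-task probability thresholds are fixed on the
validation split at the best F1 (candidates are the midpoints of sorted
unique validation probabilities; ties take the larger threshold) before
any test evaluation. `tuneHyperparameters()` offers a seeded random search
(default 50 trials) over widths, depth, dropout, $\alpha$, $\lambda$ and
learning rate, scored by mean validation balanced accuracy. Stochastic
forward passes with dropout active (`predictWithDropout`, default 100
repetitions) summarize prediction stability as percentile intervals; wider
intervals flag memorization.

## Preprocessing chain

Transforms are fit on the training split only and applied unchanged to
held-out data, in a fixed order enforced by the chain object:

1. **Outlier masking** (the one dataset-wide, pre-split step, mirroring
   assay-level curation): per protein, entries beyond 6 classical standard
   deviations from the mean become missing, in a single pass. Proteins
   with fewer than 3 observations are left untouched with a warning.
2. **Average-level normalization**: each participant's row is divided by
   its mean over *all* non-missing proteins, removing per-sample intensity
   differences.
3. **Nearest-neighbour imputation** (k = 10): a missing cell takes the
   mean of that protein over the k nearest training participants, with
   distance the mean squared difference over mutually observed proteins;
   donors must have the protein observed. A protein never observed in
   training aborts the fit — fabricating a feature silently would be worse
   than failing. Imputation is idempotent and leaves observed cells
   untouched.
4. **Gaussian rank normalization**: training columns map to normal scores
   $\Phi^{-1}((r-0.5)/n)$ with average ranks for ties; held-out values
   interpolate the training empirical quantile function linearly and clip
   to $[\Phi^{-1}(0.5/n), \Phi^{-1}((n-0.5)/n)]$.

The tree-model path (boosted-tree baseline and selection stages) instead
z-scores by training statistics and lets the tree learner handle missing
values natively.

## Two-stage feature selection

Per train+validation split, the panel reduces ~2,000–7,600 proteins to a
few hundred:

- **Association stage**: per protein and condition, ordinary least squares
  of log abundance on the condition indicator, age, sex, and the
  participant's average (log) protein level. Effects are reported as fold
  changes $e^{\beta}$ — the log link makes the >2 / <0.5 filter a
  symmetric multiplicative criterion — with Benjamini–Hochberg adjustment
  across proteins; survivors of the fold-change filter contribute their
  top 5 smallest adjusted p values.
- **Predictive stage**: the merged train+validation participants are
  resplit into ten stratified subfolds; one boosted-tree classifier per
  rotation, and a protein is kept only if *every* rotation's model uses it
  (positive cumulative split gain). The ten models of a condition share
  one design matrix; each rotation excludes its held-out subfold by
  zeroing instance weights, which removes those rows from the gradient
  exactly. Defaults (60 rounds, learning rate 0.2, per-tree column
  subsample 0.12, 16 histogram bins, balanced class reweighting) make each
  model spread its splits across the informative proteins — the
  all-rotations intersection then removes unstable picks; with full
  columns per tree, greedy boosting concentrates on a handful of proteins
  and the consensus starves.

The panel is the union over six conditions and both stages, deduplicated
in cohort protein order, with provenance recorded. Only train+validation
rows are ever touched: the tests assert that perturbing test rows leaves
the panel bit-identical.

## Splits and evaluation

`makeStratifiedKFold` splits each site's participants into k near-equal
folds (rotated starting offsets balance overall fold sizes; sites smaller
than k are distributed round-robin with a warning), and each of the k
rotations uses one fold for testing, the next for validation and the rest
for training — a 9–1–1 usage at k = 10. `makeLeaveOneSiteOut` reserves a
whole site for testing and splits the remainder site-stratified at 8/9 to
1/9. Balanced classification accuracy (mean of sensitivity and
specificity) is the primary metric — with prevalences down to a few
percent, raw accuracy is misleading and a constant classifier scores
exactly 0.5 — with rank-based AUC (ties half-credit) reported alongside.
Model comparisons across splits use the Nadeau–Bengio corrected resampled
t-test, $t = \bar d / \sqrt{(1/k + n_\mathrm{test}/n_\mathrm{train})
s_d^2}$ with $k-1$ degrees of freedom; the ratio is 1/9 for tenfold use.
The two-model ensemble takes $w\,p_\mathrm{net} + (1-w)\,p_\mathrm{tree}$
per condition, with $w$ grid-searched in steps of 0.01 on validation
balanced accuracy at a re-selected F1 threshold (re-selection is needed
because the mixture's threshold is otherwise undefined; ties go to the
smallest $w$). Because the grid includes both endpoints, the ensemble's
validation score can never fall below either component.

## Interpretation

**Permutation importance.** On each test split, each panel protein is
permuted across participants — on the model's input representation, after
preprocessing; permuting raw values and re-preprocessing would entangle
the imputer — and the per-condition cross-entropy increase is recorded
over 100 permutations. The summary is mean, sd, $z =$ mean/sd and a
one-sided normal p (importance means *increased* loss), BH-adjusted across
the panel per condition; zero-sd proteins get p = 0.5 and a flag.
Aggregation across splits counts the folds where a protein was significant
and averages $z$ over the splits whose panel contained it.

**Haufe covariances.** Because the heads are linear in the embedding,
embedding importance is the covariance between embedding activations and
predicted probabilities over a reference population — more reliable than
reading head weights. For a purely linear readout this equals
$\mathrm{Var}(z)\,w$ exactly, which the tests pin. Per-embedding protein
signatures come from boosted-tree regression of the embedding on the
panel (validation-tuned for mean squared error), keeping proteins with
cumulative split gain above 50; the gain threshold is scale-sensitive
across refits and is therefore configurable.

**Probability map and subtypes.** Participants with exactly one positive
label are embedded from their 6-D probability vectors into 2-D by exact
t-SNE (the input dimension is 6 and map sizes are desk scale, so the
dense $O(n^2)$ gradient is simplest and fast). The requested perplexity
defaults to 1,000 — appropriate at consortium scale — and is capped at
$n/4$ with a warning. t-SNE has no parametric out-of-sample transform;
new probability vectors are placed at the Gaussian-kernel-weighted mean of
their 5 nearest training vectors' coordinates. Per-diagnosis density
contours use a Gaussian KDE with Scott's-rule bandwidths at the 0.01
threshold; the threshold is applied relative to the per-diagnosis density
maximum, since absolute density units depend on arbitrary map scale.
Within a diagnosis, k-means (10 restarts, best inertia) runs for k = 2..10
and the mean silhouette width picks k; identical points refuse to cluster
with an informative error. Cluster differential abundance fits, per
protein, log abundance on cluster indicators + age + sex + site + average
protein level, restricted to that diagnosis's positives, BH-adjusted;
clusters under 5 members are excluded with a warning.

## Translation layer

**Few-shot transfer** adapts the frozen model to a new site from K = 100
participants (20 random repeats, stratified on the joint label pattern):
a ridge-regularized logistic head per condition on the frozen embeddings
("FineTune") is compared against the same classifier on the panel
proteins with K-sample scaling ("Retrain"); both calibrate their
probability threshold by F1 on the K sample and are scored on the
remaining participants. Conditions with fewer than two positives or
negatives in a K sample are skipped and logged, never silently scored.
The ridge penalty is set at the conventional default strength
($\lambda = 1/n$, the default-regularization choice of common logistic
implementations). **Progression prediction** takes baseline embeddings of
participants with baseline CDR 0 and non-decreasing follow-up CDR (a
sequence like 0, 1, 0 is excluded) and cross-validates the same
default-configuration linear classifier. **Two-cutoff calibration**
searches midpoints of sorted unique derivation probabilities for the
largest lower cutoff keeping NPV ≥ 90% below it and the smallest upper
cutoff keeping PPV ≥ 90% above it (alternative targets, e.g. PPV 40%, are
supported); the zone between is indeterminate and the report text
recommends confirmatory testing. A side with no attaining threshold is
reported unattainable rather than forced; crossed cutoffs (separable
derivation data) return with an empty-indeterminate flag. **Individual
reports** attribute each condition's probability to proteins by sampling
Shapley values (default 128 permutations, training participants as the
background; the linear-model closed form pins correctness in tests), list
the top 10 positive and negative contributors, show zero-centered
normalized probabilities $\log(\hat y / \mathrm{threshold})$, and project
the participant onto the fitted probability map.

## The synthetic cohort generator

No public cohort ships with the package; every stage is exercised on
simulated data with known ground truth, and all distributional choices are
stand-ins labelled as such. The generator emulates a multi-site aptamer
consortium: log-normal abundances (baseline log-RFU ~ N(7, 1), biological
log-sd uniform on 0.2–0.5, technical noise log-sd 0.3); per-site additive
log shifts (sd 0.3) and multiplicative log-scale factors (sd 0.1) on
uneven site sizes; condition statuses from thresholded latent liabilities
that are correlated at 0.1 among the five diseases and anti-correlated
with the control axis, so co-pathology occurs without making controls
disease-like; per-condition planted proteins (default 40, disjoint across
conditions) with multiplicative fold changes drawn from 1.5–3, up or down;
small age and sex effects (log-sd 0.05); per-condition label missingness
(default 15%) and 2% missing abundance cells. Default prevalences fall
from 30% (control) to 4–5% (FTD, ALS) to reproduce the imbalance that
motivates the balanced-accuracy metric and the rank loss. MMSE and CDR are
generated consistently with the dementia-driving statuses, which gives the
cognition-derived label rules and the progression task something real to
find. Defaults are the package's fixed study conditions; they were chosen
once, from the description of the cohorts the method targets, and the
acceptance checks run against them unchanged.

What the simulation does *not* emulate: aptamer cross-reactivity,
longitudinal proteomic drift, serum-versus-plasma modality differences,
plate effects within sites, and realistic overlap between condition
signatures (planted sets are disjoint). Passing tests therefore
demonstrate that the pipeline recovers structure it is pointed at under
honest train/test separation — not that the classifier would reach any
particular accuracy on real cohorts, where effect sizes are far smaller
and signatures overlap.

## Numerical choices and degenerate inputs

- Probability clipping $\delta = 10^{-7}$ before logarithms.
- Threshold sweeps use midpoints of sorted unique probabilities; F1 ties
  take the larger threshold, ensemble-weight ties the smaller weight.
- The cognition-derived dementia rule uses MMSE < 19 or CDR ≥ 1 (the
  cutoff is configurable); when MMSE and CDR disagree, the
  clinician-assigned CDR stage wins by default. An MMSE of exactly 19
  with no CDR maps to Unknown.
- Outlier masking uses classical moments (not median/MAD) in a single
  pass.
- Zero-sd columns: z-scoring maps to 0 with a warning; a constant
  training column in the rank normalizer maps everything to 0.
- Rank-deficient association designs abort naming the collinear terms.
- All seeds are integers below $2^{31}$; sub-seeds derive arithmetically
  so every stage is reproducible from one seed.

## Problem sizes used by the test suite

The acceptance tests run the default cohort (4,000 x 2,000, 10 sites) and
evaluate the first five rotations of the tenfold plan (~2,000 scored
held-out participants), with permutation importance on those five test
splits plus one decoy-augmented model for null calibration (the consensus
panels contain almost exclusively planted proteins, so known-null decoys
are appended to one model's input to measure the false-positive rate).
Site-generalization, ensemble, few-shot and subtype checks run on a
1,500 x 300 five-site cohort with strong site effects (log-shift sd 0.8)
and a planted co-pathology subtype: half of the pure-AD participants
carry the full PD signature with their PD label blanked. These sizes are
the package's chosen test conditions; `scripts/acceptance.R` evaluates
six rotations of the same tenfold plan on the default cohort.

## Known limitations

- The joint network is plain R matrix code: fine at panel scale
  (hundreds of proteins), not meant for raw 7k-protein inputs without
  selection.
- Exact t-SNE is quadratic in participants; maps beyond ~5,000 points
  need subsampling.
- The boosted-tree consensus is sensitive to its diversity settings; with
  full columns per tree it under-selects, which is why the defaults
  subsample columns aggressively.
- Cross-site harmonization (e.g. empirical-Bayes batch adjustment) is out
  of scope; the leave-one-site-out gap the tests reproduce is exactly the
  cost of not harmonizing.
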