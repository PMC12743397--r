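---
title: "Discovering biomechanical subpopulations and quantifying surgical response from gait waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering biomechanical subpopulations and quantifying surgical response from gait waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsubpop)
```

## The problem

Patients with end-stage hip osteoarthritis (HOA) do not deviate from healthy
gait in a single, uniform way: some walk with an internally rotated, flexed
hip, others with external rotation and reduced sagittal hip moments, and
these adaptation patterns respond differently to total hip replacement
(THR). `gaitsubpop` implements a workflow for (1) discovering such
biomechanical subpopulations directly from time-normalized gait waveforms,
(2) characterizing each subpopulation with an interpretable linear
classifier against healthy controls (HC), and (3) quantifying each
subpopulation's surgical response with a scalar gait score and
waveform-level statistical inference.

The unit of data is a *study*: per subject, three trials of 18
stance-phase waveforms (11 joint angles in degrees, 7 mass-normalized
external joint moments in N·m/kg), each time-normalized to 101 points,
together with group labels (HOA before surgery, THR after surgery, HC) and
scalar metadata. Because motion-capture cohorts of this kind are rarely
public, the package ships a first-class synthetic generator that emulates
the statistical structure the analysis relies on.

## The model, stage by stage

### Trial averaging and HC-referenced standardization

The three trials are averaged per subject and channel. Every subject-mean
waveform is then z-standardized *pointwise with the healthy-control mean
and standard deviation* (sample SD, denominator $n-1$), so all cohorts are
expressed in units of healthy variability. A variable with zero HC variance
is treated as an error rather than silently dropped: in practice it signals
a degenerate (e.g. noise-free constant) input.

### A shared reduced feature space

The standardized waveforms are flattened channel-major into a
subject-by-variable matrix (with the standard grid,
$18 \times 101 = 1818$ variables) and a PCA is fitted on the *HOA cohort
only*, retaining the smallest number of components whose cumulative
explained variance reaches 90%. THR and HC data are projected into this
space by subtracting the HOA column means and multiplying by the HOA
eigenvector matrix. Two conventions are fixed for reproducibility:

* PCA centering uses the HOA (fitting-cohort) column mean. Standardization
  is HC-referenced, but the eigenbasis is derived from the HOA data, and
  standard PCA requires centering the fitting cohort; the same center is
  subtracted before projecting THR and HC.
* Each eigenvector's largest-magnitude element is made positive, so the
  basis (and every downstream score) is identical across linear-algebra
  backends.

### Subpopulation discovery

The number of clusters $k$ is chosen from a Ward dendrogram
(`ward.D2`, Euclidean distances in PC space) by maximizing the relative
merge-height gap $g(k) = (h_k - h_{k+1})/h_{k+1}$, where $h_k$ is the
fusion height joining $k$ clusters into $k-1$; ties break toward smaller
$k$. The criterion is deterministic and auditable (the gaps and heights are
returned as attributes); the search range is exposed as configuration.

Subjects are then assigned by k-means run five times (k-means++ seeding,
run $r$ seeded with `seed + r`), with labels of runs 2..5 aligned to run 1
by exact maximum-agreement bipartite matching on the confusion matrix. A
subject is kept only if *all* runs agree on its aligned label — the
strictest reproducible reading of "consistently assigned"; everyone else is
excluded from subpopulation-specific analyses. Each run keeps the best of
five k-means++ starts by total within-cluster sum of squares. Without
restarts, a single unlucky initialization out of five runs converges to a
poor local optimum and the unanimity rule then excludes most of the cohort,
so the consistency filter would measure initialization luck rather than
genuine assignment ambiguity. Clusters are canonically renumbered by
decreasing size (ties by smallest subject id), and silhouette values
(Euclidean, singleton clusters scoring 0) describe cluster fit.

### Subpopulation characterization and surgical response

For each subpopulation, a linear soft-margin SVM (box constraint 1, kernel
scale 1 — features are divided by the kernel scale before training) is
trained against HC in PC space. Performance is estimated with seeded,
stratified 10-fold cross-validation: out-of-fold decision values are
pooled, negative values count as pathologic, and the pooled predictions
yield the classification rate, the *pathologic ratio* (share of the
subpopulation classified pathologic), sensitivity, specificity, and a
rank-based ROC-AUC. The fold count drops with a warning when a class has
fewer members than folds. The paired post-surgery subjects are projected
through the *final* model trained on all data — the only model defined for
unseen subjects — so post-surgery rows report no cross-validated
classification rate. Note that with pooled out-of-fold predictions the
sensitivity of the pre-surgery row coincides with the pathologic ratio by
construction; reports in which the two differ must have been computed with
per-fold averaging, which this package does not use.

Two explainability layers sit on top of the classifier:

* **Shapley back-projection.** For a linear decision function with an
  independent-features background, the Shapley value of component $i$ is
  exactly $\phi_i = w_i (x_i - b_i)$, where the background $b$ is the
  training-set feature mean. Per subject, each component's $|\phi_i|$ is
  multiplied by the PC score, the weighted score vector is back-projected
  through the eigenvector matrix to waveform space, and a channel's
  contribution is the mean absolute reconstructed value over the stance
  grid (absolute values prevent cancellation between stance sub-phases).
  Averaging contributions over the subpopulation's subjects gives one
  importance per channel; the top five characterize the subpopulation. The
  importance factor *is* $|\phi_i| \cdot x_i$; no second scaling is
  applied.
* **COGS.** The classifier-oriented gait score is the signed orthogonal
  distance $(w \cdot x + b)/\lVert w \rVert$ of a subject to the SVM
  hyperplane, oriented so positive values lie on the healthy side: larger
  is healthier, and an increase after surgery reads as gait normalization.

### Waveform-level inference

Whole-trajectory comparisons (subpopulation vs HC, unpaired; pre vs post
surgery, paired) use pointwise t-statistics with family-wise error control
by *max-statistic permutation*: the null distribution of the maximum
absolute t over the 101-point grid is built from group-label permutations
(unpaired) or sign flips of paired differences (paired), and the critical
value is its $1-\alpha$ empirical quantile ($\alpha = 0.05$, two-sided).
All distinct permutations are enumerated when there are at most `n_perm` of
them; otherwise `n_perm` random permutations including the observed one are
used. This is a deliberate divergence from parametric random-field-theory
inference: the permutation variant is assumption-light and exactly valid at
desk scale. Significant fractions use all 101 grid points in the
denominator, and reported regions are 0-based half-open intervals.

## The synthetic generator

`generate_cohort()` draws cohorts with exactly the structure the analysis
assumes:

* smooth per-channel healthy templates (superpositions of Gaussian bumps
  with physiologically plausible magnitudes);
* smooth between-subject deviation curves from a squared-exponential
  covariance (default lengthscale 0.3 of the stance phase, default SD 1 in
  raw units), independent across channels;
* independent per-trial noise (default SD 0.5);
* planted subpopulation effects confined to chosen channels, expressed in
  HC standard-deviation units of the trial-averaged waveform so that
  `magnitude` reads directly as a standardized effect size;
* a paired post-surgery cohort in which each THR subject reuses the
  pre-surgery partner's deviation curves (it is the same person walking),
  receives fresh trial noise, and has the planted effect shrunk by a
  per-subpopulation `recovery_fraction`.

The default cohort mirrors a 109/63/56 (HOA/THR/HC) study with three
subpopulations of decreasing separability (magnitudes 3, 2, 1.5) and
recovery fractions 0.8/0.4/0.7, echoing the clinical observation that the
most impaired group normalized most and the mildest group showed a ceiling
effect. Metadata are generated from group-level distributions but never
influence the waveforms: the clustering is driven by biomechanics alone.

What the generator does *not* emulate: within-subject trial correlation
beyond the shared subject curve, skewed or heteroscedastic noise,
metadata-waveform coupling (age or mass never shift the curves), missing
trials, and any contralateral-limb structure. Passing tests therefore show
that the pipeline recovers structure *of the kind it assumes*; they cannot
certify performance on real motion-capture data.

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
report <- run_pipeline(cfg)
report$classification
make_figures(report, "figures/")
```

## Numerical and design choices

* **Trial-variance identity.** The HC variance of the trial-averaged
  waveform is `subject_variation_sd^2 + trial_noise_sd^2 / n_trials`; the
  planted-effect scale uses this quantity, so effects survive trial
  averaging at their nominal standardized size.
* **Retention rule.** The retained component count is the smallest $P$
  with cumulative ratio `>= threshold - 1e-12`; the tolerance guards
  against floating-point near-misses at exactly 90%.
* **Label matching.** Maximum-agreement matching is exact (branch and
  bound over permutations), not greedy, so consensus never depends on the
  order clusters happen to be numbered in.
* **Ties.** Importance ties break by channel-list order; Ward gap ties
  break toward smaller $k$; eigenvector signs and cluster numbering are
  canonical.
* **Degenerate inputs.** Zero HC variance, zero paired-difference variance
  with nonzero mean, single-class SVM training sets, zero weight vectors,
  and too-few permutation units all raise informative errors instead of
  propagating NaNs. A paired comparison of identical matrices returns a
  zero trajectory (the 0/0 convention) rather than an error.
* **Seeds.** One master seed drives everything; stages derive their own
  seeds by fixed offsets so stages stay reproducible in isolation.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: elementwise
means against loops, PCA against an eigendecomposition of the sample
covariance, the SVM against a hand-written SMO solver on small instances,
linear Shapley values against brute-force coalition enumeration, silhouette
values against the closed form on fixed points, t-trajectories against
scalar `t.test`, and region extraction against a run-length scan.
Property-based suites use simulated cohorts of 30 subjects per
subpopulation (50 seeds) for clustering and importance recovery, 500-1000
smooth-noise datasets with 1000 permutations for the family-wise error
calibration, and 100 seeds for the surgical-response direction. These sizes
were chosen to keep the whole suite fast on a laptop while leaving the
Monte-Carlo bands (e.g. FWER within 0.05 ± 0.02) comfortably resolvable.

Two empirical notes from this validation are worth recording. First, the
importance formula $|\phi| \cdot \text{score}$ needs between-subject
variance along the effect direction to carry signal: in a degenerate cohort
with a *single* subpopulation, a planted constant offset adds no
within-HOA variance, the fitting cohort's scores center at zero along the
effect direction, and recovery degrades; in realistic heterogeneous
cohorts (several subpopulations, as in the recovery tests) the ranking
recovers the planted channels essentially always. Second, the unanimity
consistency rule is only meaningful when each k-means run reports its best
local optimum, hence the within-run restarts described above.

## Known limitations

* The Ward gap criterion assumes reasonably balanced, convex clusters; it
  inherits Ward's bias toward equal-sized groups.
* Class weights are not adjusted for the subpopulation-vs-HC imbalance
  (the reference settings fix the box constraint at 1).
* Importance values are model-specific and not comparable across
  subpopulations; only rankings are interpreted.
* The permutation tests exchange whole subjects; they do not model
  within-subject temporal autocorrelation beyond what the trajectories
  themselves carry (which is what the max-statistic construction
  accounts for).
* The pipeline starts at time-normalized waveforms: no marker processing,
  filtering, or inverse dynamics.
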