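---
title: "Graph distance profiles for supervised gene-regulatory network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph distance profiles for supervised gene-regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradis)
```

## The problem

A gene-regulatory network (GRN) is a directed graph in which transcription
factors (TFs) regulate target genes. Experimentally verified interactions are
scarce and expensive, so a central task in systems biology is to predict new
TF→gene edges from genome-wide expression data. Supervised approaches treat
this as link prediction: known interactions form a positive class, each
candidate (TF, gene) pair is turned into a feature vector, and a classifier
decides whether the pair interacts. Two obstacles dominate:

1. **Representation.** A single similarity score (correlation, mutual
   information) between a TF and a gene collapses the whole expression
   relationship into one number.
2. **No negatives.** Databases record interactions, not verified
   *non*-interactions, so the negative training class has to be mined from
   the unlabelled pairs (positive-unlabelled learning).

This package addresses both with the GRADIS strategy: a graph-distance
representation of each pair, and an iterative scoring scheme that extracts a
trustworthy negative class from the unlabelled pool.

## The model

### Step 1 — sample compression by k-means

The number of features scales with the number of samples, so the samples
(columns of the genes × samples matrix) are first clustered into $k$ groups
with k-means in gene-dimensional space (`cluster_samples()`), and each gene
is summarised by its mean expression per cluster:
$\mathbf{x}_g = (x_g^1, \dots, x_g^k)$. This removes redundancy among
similar samples while keeping the between-condition structure. One clustering
is computed per dataset and shared by *all* pairs.

Because raw k-means labels are arbitrary but feature coordinates are indexed
by cluster, clusters are relabelled canonically (decreasing size, ties broken
by the lexicographically smallest member sample id). Empirically this, plus a
fixed seed and `restarts` initialisations scored by within-cluster sum of
squares, makes the entire downstream feature matrix reproducible.

Defaults: `restarts = 10`, 300 Lloyd iterations, samples clustered on raw
expression (`standardize_samples = FALSE` — the metric the original analysis
used is unstated, and raw Euclidean k-means is the conventional default).
The default cluster count is $k = \min(50, \lfloor n_{\text{samples}}/2
\rfloor)$; on the real benchmark data sets the cross-validated AUC rises
with $k$ and saturates at about $k = 50$, and with 210 samples $k = 30$
gives $\binom{30}{2} = 435$ features, comparable to the $2 \times 210 = 420$
of expression-concatenation baselines.

### Step 2 — the graph distance profile

Each gene's $k$-vector is min-max rescaled to $[0,1]$ (`rescale_profile()`),
which removes magnitude differences between a TF and its putative target. A
pair (TF, $G$) then defines $k$ points $(x_{TF}^i, x_G^i)$ in the unit
square — one per sample cluster. The feature vector is the upper triangle
(diagonal excluded, row-major order) of the complete weighted graph over
these points, with edge weights

$$w(n_i, n_j) = \sqrt{(x_{TF}^i - x_{TF}^j)^2 + (x_G^i - x_G^j)^2}$$

for the Euclidean metric, or $w_m(n_i,n_j) = |x_{TF}^i - x_{TF}^j| +
|x_G^i - x_G^j|$ for Manhattan (`pair_feature()`), giving $k(k-1)/2$
features bounded by $\sqrt 2$ (respectively $2$). The vector captures the
*between-sample* geometry of the joint TF–gene profile — information a
single similarity coefficient discards. The two metrics produce nearly
interchangeable geometry (Mantel correlations above 0.95 on both real and
synthetic data), so Euclidean is the default.

The feature is exactly symmetric under swapping its two arguments; the
direction of an inferred edge comes from the *ordered* training labels (only
pairs with a TF in the first position are ever labelled or scored), never
from the feature itself. `predict_network()` asserts this symmetry is
preserved for TF–TF pairs.

Degenerate inputs: a constant profile is mapped to all 0.5 — the centre of
the unit interval — rather than 0 or 1, so a flat gene does not fabricate
extreme coordinates. Rescaling is per gene over its $k$ centroid values
(not jointly per pair), so a gene's scaled profile is pair-independent and
cached once in `featurize_pairs()`; either convention keeps all points in
the unit square.

### Step 3 — mining negatives from the unlabelled pool

With positives $P$ (the gold standard) and unlabelled pairs $U$, the pool is
partitioned into $\lfloor |U|/|P| \rfloor$ random subsets of size $|P|$
(`partition_uncharacterized()`, remainder absorbed by the last subset). Each
iteration treats one subset as the provisional negative class, trains an
RBF-kernel SVM on $P$ (+1) versus that subset (−1), and classifies every
unlabelled pair outside the subset; pairs predicted positive have an integer
score incremented (`iterative_negative_scoring()`). After all iterations a
*zero* score marks a pair that every classifier configuration called
negative — these form the negative training class
(`extract_negative_class()`, with an upward threshold relaxation if a
minimum pool size is requested). Conversely the highest-scoring pairs are
candidate undiscovered interactions; `enrichment_null_test()` quantifies
their overlap with a truth set against 1000 uniform same-size draws,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{random}} + 1)$.

Two conventions deserve note:

* **Maximum score.** By default a pair is not assessed by the one iteration
  that used it as a training negative, so the maximum attainable score is
  $n_{\text{iterations}} - 1$. Published descriptions of this scheme count a
  maximum equal to the number of iterations; `score_own_iteration = TRUE`
  reproduces that arithmetic by letting each classifier also score its own
  subset. The default is the cleaner test-only convention.
* **Per-iteration CV.** Tenfold cross-validation *within* an iteration can
  only mean hyperparameter selection (CV does not yield a single
  classifier). Grid selection of $(C, \gamma)$ is available via
  `inner_cv = TRUE`; the default is a single fit per iteration with fixed
  hyperparameters, which keeps the $\sim$tens-of-iterations scheme fast
  without measurably changing the score ranking on the synthetic fixtures.

### Classification and prediction

The final classifier (`train_classifier()`) is an RBF-kernel SVM with
decision function $f(p) = \sum_i \alpha_i K(p_i, p)$; continuous margins
(`decision_scores()`) rank candidate edges. Defaults: $C = 1$ and
$\gamma = 1/(d \cdot \mathrm{Var}(X))$ with $d$ the feature dimension — the
standard scale heuristic. Features are used as-is: they are homogeneous and
bounded by the unit-square geometry, so no additional standardisation is
applied. A random-forest backend (500 trees, $\sqrt d$ features per split)
is included for comparison; on the graph features it does not outperform the
SVM, which the test suite guards as a soft regression check.
`predict_network()` scores every (TF, gene) pair over a regulator set and
gene universe (self-pairs excluded by default) and returns a ranked edge
list in the DREAM dialect.

## Evaluation protocol

`balanced_cv_evaluate()` implements stratified tenfold cross-validation with
ten repetitions. The class imbalance (many more negatives than positives) is
handled at *training* time: each fold's classifier sees all training
positives and an equal-size uniform sample of training negatives. Held-out
folds are scored **unbalanced** by default — all their negatives — so the
reported AUC/AUPR reflect the true class ratio (`balanced_test = TRUE`
switches to balanced test folds). Held-out scores are pooled per repetition,
giving one AUC and one AUPR per repetition; `confidence_interval()` fits a
normal distribution to the run statistics and reports mean
$\pm z_{0.975}\,\mathrm{sd}$.

Numerical conventions, chosen so numbers are reproducible across
implementations: AUC is the rank (Wilcoxon–Mann–Whitney) statistic with ties
credited $1/2$; AUPR is the step-wise sum over distinct score thresholds
with no interpolation between PR points (a perfect ranker gives 1, a
constant ranker the positive prevalence). Both are checked against
brute-force counting oracles in the tests.

`per_tf_auc_distribution()` gives the local (TF-centric) view: per TF and
repetition, the AUC over that TF's held-out pairs when both classes are
present; TFs missing a class in a repetition are skipped for that
repetition. `mantel_correlation()` (via \pkg{vegan}) measures metric
concordance, and `combine_score_matrices()` implements the
wisdom-of-crowds conjunction: each method's score matrix is scaled by its
global maximum and combined by the entrywise minimum, which is the exact
logical equivalent of "all scaled scores above the threshold" and therefore
supports ordinary ROC/PR sweeps.

## The synthetic-data generator

`generate_network()` plants a sparse directed TF→gene network:
edges are drawn by a random-permutation scan of the allowed pairs under an
in-degree cap (default 3, so regulatory inputs stay unsaturated).
TF→TF edges are only drawn from a lower-indexed TF to a higher-indexed one,
which makes the planted network **acyclic**. This is deliberate:
`simulate_expression()` then generates, per sample, standard-normal levels
for unregulated TFs and computes each regulated gene in one topological pass
as

$$x_g = \tanh\Big(\sum_{r \in \mathrm{reg}(g)} \beta_{rg}\, x_r\Big) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with observed regulator levels feeding downstream — so a regulated TF's
outgoing edges remain statistically detectable, which an independent-TF
formulation would break. Effect magnitudes $|\beta|$ are uniform in
`effect_range` (default $[0.5, 2]$) with activating sign probability
`activation_fraction` (default 0.7, reflecting the activator bias of
curated regulons); unregulated non-TF genes are standard-normal noise; the
matrix is shifted to non-negative values. The $\tanh$ saturation keeps the
relationships nonlinear enough that the graph features have something to add
over plain correlation, without being pathological. Default
`noise_sd = 0.3` puts edge-wise TF–target correlations in a realistic
0.4–0.8 band.

`make_benchmark_fixture()` provides three shapes: `dream4_like` (100 genes,
40 TFs, 150 edges, 210 samples — the scale of the small synthetic
benchmarks, whose TF counts run in the mid-thirties to mid-forties),
`dream5_like` (1643 genes, 178 TFs, 4012 edges, 805 samples) and `tiny`
(20 genes, 8 TFs, 15 edges, 30 samples) for fast tests.

**What the generator is not.** It is a minimal dependence-planting model,
*not* a kinetic/ODE simulator of the kind behind the published DREAM
benchmarks: no time courses, no knockouts, no combinatorial promoter logic,
no measurement-model noise. Passing tests on these fixtures demonstrate that
the pipeline recovers planted statistical dependencies end to end — they do
not certify benchmark AUC values on real data. One visible consequence: on
the synthetic fixtures the cross-validated AUC is already high at small $k$
(the planted monotone relationships survive aggressive sample compression),
whereas on real data the AUC keeps improving up to $k \approx 50$. The
`choose_k_report()` sweep is therefore advisory and its tests assert shape
and error handling, not a particular $k$ optimum.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything on the `tiny` and
`dream4_like` fixtures with tenfold CV at 2–3 repetitions and an unlabelled
pool of roughly 3,900 pairs (about 25 scoring iterations) — sizes chosen so
a full run of suite plus script completes in a couple of minutes on one core
while still exercising every stage at realistic ratios. Every stochastic
step (network, expression, k-means restarts, subset partition, fold
assignment, negative subsampling, forest growth) is governed by an explicit
seed; `run_gradis()` derives per-stage seeds from one master seed, records
them in its manifest alongside parameter values and per-file checksums, and
two runs with the same inputs and configuration are byte-identical — a
property the test suite asserts on the whole output directory.

## Known limitations

* Negative selection assumes the unlabelled pool is overwhelmingly true
  negatives; in a densely regulated genome the zero-score pool could still
  contain undiscovered interactions (the enrichment test quantifies, but
  does not remove, this).
* The feature is symmetric, so when both genes of a pair are TFs the method
  cannot orient the edge from expression alone; direction comes from the
  regulator list.
* k-means with Euclidean geometry on raw expression implicitly weights
  high-variance genes; `standardize_samples = TRUE` is available but changes
  only the clustering, never the centroid values.
* The normal-fit confidence intervals treat the 10 repetition statistics as
  independent, which repeated CV does not strictly satisfy; they are
  comparison aids, not calibrated coverage statements.
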