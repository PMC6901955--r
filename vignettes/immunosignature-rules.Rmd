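---
title: "Expression-rule discovery for immunosignatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-rule discovery for immunosignatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunorules)
```

## The problem

An immunosignature is the pattern of antibody-binding intensities a serum
sample produces across a random-sequence peptide microarray. Peptides that
mimic epitopes of tumour-derived antigens light up differently across
disease groups, so a labeled intensity matrix (samples × peptides, one
disease label per sample) supports two complementary analyses:

1. a *predictive* arm — find a small peptide subset on which a standard
   classifier separates the groups as well as possible, and
2. an *interpretable* arm — distil the discriminative peptides into ordered
   IF–THEN threshold rules (e.g.
   `IF Peptide1<=0.7 AND Peptide2>=1.02 THEN type = "Brain cancer"`) that a
   clinician can read as quantitative antigen criteria.

`immunorules` implements both arms behind one reproducible pipeline:
KNN imputation → Monte Carlo Feature Selection (MCFS) → a label-permutation
cutoff for the informative peptides → two-stage incremental feature
selection (IFS) with a random forest or one-vs-rest SVM → Johnson-reducer +
RIPPER rule induction, all scored with the Gorodkin multi-class Matthews
correlation coefficient (MCC).

## Relative importance: the MCFS score

MCFS ranks all $M$ peptides by aggregating over many small random
experiments. Each of $t$ iterations draws a feature subset of size $m \ll
M$; on each subset, $p$ binary decision trees are grown, each on a
bootstrap resample of the samples. A peptide's relative importance is

$$
RI_g \;=\; \sum_{\tau=1}^{p\,t} (wAcc_\tau)^u
  \sum_{n_g(\tau)} IG\!\big(n_g(\tau)\big)
  \left(\frac{\text{no.in } n_g(\tau)}{\text{no.in } \tau}\right)^{\!v},
$$

where the inner sum runs over the nodes of tree $\tau$ that split on $g$,
$IG$ is the node's information gain (base-2 entropy, so a clean balanced
binary split is worth exactly 1 bit), the fraction is the share of the
tree's training samples reaching the node, and $wAcc_\tau$ is the tree's
*balanced accuracy* — the unweighted mean of per-class recalls — measured
on the tree's out-of-bag samples. The exponents default to $u = v = 1$.

Choices the score leaves open, and what this package does:

* **Tree learner.** Top-down binary trees with base-2 entropy impurity,
  grown to purity with a minimum leaf of 2 and no pruning. Split ties break
  toward the lower feature index and lower threshold, so a run is a pure
  function of the seed.
* **$wAcc$ evaluation set.** Each tree's out-of-bag third of the bootstrap;
  classes absent from the out-of-bag set are excluded from the mean. A tree
  with no out-of-bag samples contributes 0.
* **Defaults.** $m = \lceil\sqrt{M}\rceil$, $t = 1000$, $p = 5$; all
  configurable via `mcfs_config()`.
* **Determinism.** Samples are processed in sorted sample-identifier order,
  so the ranking is invariant to row permutations of the input, and equal
  RI scores are ordered by feature identifier.

Two useful invariants follow from the construction and are enforced by the
test suite: RI is additive over any partition of the trees, and the ranking
is invariant to positive rescaling of all intensities (trees split on
thresholds; entropies are unchanged).

## The informative-feature cutoff

The informative set is the head of the RI ranking whose scores exceed a
label-permutation null. The package reruns MCFS on `n_perm` label-shuffled
copies of the data (fresh seeds `seed + 1 … seed + n_perm`, features
untouched) and, per feature, performs a one-sided t-test of the observed RI
against its permutation distribution.

One calibration point matters here. The observed RI is a *single draw*, so
comparing it to the permutation mean with the mean's standard error
$s/\sqrt{n}$ is badly miscalibrated: under the null that statistic has
standard deviation on the order of $\sqrt{n+1}$ rather than 1, and in a
simulated null (effect size 0) roughly a quarter of all peptides came out
"significant". The package therefore uses the prediction-scaled statistic

$$
T \;=\; \frac{\bar{RI}_{perm} - RI_{obs}}{s\,\sqrt{1 + 1/n_{perm}}},
\qquad T \sim t_{n_{perm}-1} \text{ under exchangeability,}
$$

whose p-values are calibrated; they are then Benjamini–Hochberg adjusted
(at $M \approx 10^4$ an unadjusted 5% test would admit hundreds of false
peptides). The informative set is reported as the first $N$ features of
the ranking, with $N$ the number of significant features — the set is a
prefix by construction, matching how informative features head the
ranking's published form.

## Incremental feature selection

IFS turns the ranking into an optimal classifier. Stage 1 evaluates the
prefixes of sizes $10, 20, \dots$ (step configurable) by stratified
10-fold cross-validation, scoring the pooled out-of-fold predictions with
the multi-class MCC; stage 2 re-scans every size within ±10 of the coarse
optimum. Both stages share the fold seed, so the coarse optimum
re-evaluates identically during refinement and the combined curve contains
every size once. Ties on the maximal MCC resolve to the smaller subset
(parsimony). The coarse cap defaults to the informative-set size inside the
pipeline and to the full list in standalone use.

Pooled-prediction scoring (one MCC on all out-of-fold predictions) was
chosen over per-fold averaging because MCC is unstable on small per-fold
confusion matrices, particularly with 10 folds over 40-sample classes.

The two base learners are deliberately standard: a 100-tree random forest
(`randomForest`), and linear SVMs (`e1071`/libsvm, an SMO-family solver)
wrapped in a hand-built one-vs-rest layer — one binary machine per class,
samples assigned to the class with the largest oriented decision value —
because off-the-shelf multi-class SVM in R is one-vs-one. The feature
subset has set semantics (sorted internally), and all seeds are threaded
from the configuration.

## The rule arm

**Johnson reducer.** Rule induction starts from the informative peptides,
first reduced to an attribute subset with similar discerning power.
Features are discretized per-feature by entropy-based recursive binary
splitting with the minimum-description-length stopping rule (Fayyad–Irani);
features with no accepted cut are single-bin and discern nothing. The
greedy reducer then repeatedly picks the feature discerning the most
not-yet-discerned between-class sample pairs until all discernible pairs
are covered, ties breaking on the feature identifier. Greedy set cover is
not guaranteed minimal, but on enumerable toy tables (8 features, brute
force over all $2^8$ subsets) it lands within one attribute of the optimum.

**RIPPER.** Ordered rule induction over the reduct, on the raw continuous
intensities. Classes are processed from rarest to most prevalent
(prevalence ties lexicographic); the most prevalent class becomes the
default and gets no rules. Per class, each rule is grown
condition-by-condition on a stratified 2/3 of the remaining data,
maximizing FOIL information gain over candidate thresholds (midpoints
between sorted distinct covered values, so learned thresholds always sit
strictly between observed values), then pruned on the held-out 1/3 by
maximizing $(p - n)/(p + n)$. Rule addition stops when the total
description length (a per-rule theory cost plus a binomial exception cost)
exceeds the minimum seen by more than 64 bits, or when no positives
remain. Two optimization passes then revisit each rule, choosing by total
description length among the original, a regrown replacement, and a greedy
revision; a final mop-up covers positives freed by the revision. Rules that
cover no new positive of their class are dropped.

Rule evaluation repeats stratified 10-fold cross-validation three times
with fresh fold splits — the reducer and RIPPER are re-run inside every
training fold, so the reported MCC is honest about the whole rule-learning
procedure, not just the final rule set. Per-repeat reports are kept and the
summary is their mean (confusion matrices are summed), so a pooled view is
recoverable. The final, reported rule set is trained once on all samples.

## The synthetic generator

`generate_synthetic()` emulates the study design the pipeline targets:
$K$ classes of $n_k$ samples (default 6 × 40), log-normal baseline
intensities (log2-scale mean 0, sd 0.5 — positive, sub-10 magnitudes like
observed peptide intensities), and for each class a small planted set of
peptides (default 5) whose log2 mean shifts by the effect size (default
1.5) in that class only. Each planted peptide belongs to exactly one class,
keeping recovery metrics unambiguous. Missing entries are placed uniformly
at random; shifts are upward by default with `"down"`/`"mixed"` options,
since real rule sets use both `<=` and `>=` conditions.

What the generator does *not* emulate — and what passing tests therefore do
not show about real arrays: correlated peptides (clones of one epitope),
batch and plate effects, heavy-tailed outliers, intensity-dependent missing
patterns, or class-overlapping signals. Results on real immunosignature
data will be correspondingly noisier, and the informative-set size there is
an empirical outcome, not a parameter.

## Numerical and degenerate-input conventions

* Gorodkin MCC is computed in closed form from the confusion matrix,
  $\bigl(n\,\mathrm{tr}(C) - \sum_k t_k p_k\bigr) / \sqrt{(n^2 - \sum_k
  p_k^2)(n^2 - \sum_k t_k^2)}$; a vanishing variance term (e.g. all samples
  predicted as one class) scores 0. Predicting a class absent from the true
  labels is an error, not a silent class-list extension.
* KNN imputation measures distances between peptide profiles over
  co-observed samples only, rescaling the squared distance by
  total/co-observed so sparsity does not shrink distances; only peptides
  observed at the target sample are candidate neighbours, with graceful
  fallback to fewer neighbours or the feature mean, and an error only when
  a peptide is entirely missing. Observed values are never altered, making
  the operation idempotent.
* Serialized thresholds and intensities use the shortest decimal expansion
  that survives an `as.numeric` round trip, so write→read is the identity;
  three-decimal thresholds from published tables parse unchanged.
* Single-class input to RIPPER yields zero rules with that class as the
  default rather than an error, keeping degenerate cross-validation folds
  total.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full design at 240 × 1,000
(6 classes × 40 samples, 30 planted peptides) with $t = 200$ subsets and 20
permutations — sizes at which every stage's behaviour (recovery, type-I
control, classifier-versus-rule ordering) is already stable — and the MCFS
recovery check at the full $t = 1000$. The whole pipeline is a pure
function of one master seed, which fans out to the stages by fixed offsets
recorded in the run report; rerunning a configuration reproduces every
artifact byte-for-byte.

## Known limitations

* Intensities are analyzed as supplied; no normalization or background
  correction is applied (a `log2` option exists, off by default, since tree
  and rule thresholds are monotone-invariant and published rule thresholds
  are on the natural scale).
* The MCFS inter-feature dependency graph (which features co-operate in
  trees) is out of scope; only the RI ranking is produced.
* The choice between the random-forest and SVM arms is a user decision per
  dataset, not an automated model selection.
* Rule sets use first-match semantics only; no voting or rule weighting.
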