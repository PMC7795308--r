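---
title: "Reconstruction-based fingerprint reweighting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based fingerprint reweighting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbn)
```

## The problem

Ligand-based virtual screening ranks a chemical database by similarity to a
known active reference structure, usually on folded binary 2D fingerprints.
Treating every bit as equally informative is a known weakness: fingerprints
folded to a fixed length contain bits that are structurally stable and
class-informative, bits that are rarely set, and bits that behave like noise.
This package implements a reweighting pipeline: learn a generative model of
the fingerprint population, score each feature by how well the model can
reconstruct it, discard persistent outliers, keep the most re-constructible
features from several complementary descriptors, and search on the fused,
reweighted representation.

## Models

### Restricted Boltzmann machine

The building block is a Bernoulli RBM over visible units $v \in \{0,1\}^V$
and hidden units $h \in \{0,1\}^H$ with energy
$E(v,h) = -a^\top v - b^\top h - v^\top W h$. Absence of intra-layer
connections factorizes both conditionals,
$p(h_j = 1 \mid v) = \sigma(b_j + \sum_i v_i w_{ij})$ and
$p(v_i = 1 \mid h) = \sigma(a_i + \sum_j h_j w_{ij})$, which makes blocked
Gibbs sampling and contrastive divergence (CD-$k$) learning straightforward:

$$\Delta w_{ij} = \varepsilon\,(\langle v_i h_j\rangle_\text{data} -
\langle v_i h_j\rangle_\text{model}),$$

with the model expectation estimated by a $k$-step Gibbs chain started at
each data vector. Two standard variance-reduction choices are fixed here
because they are otherwise unconstrained: the positive phase uses hidden
*probabilities* (mean-field) rather than sampled states, and the negative
chain samples binary states along the way but uses probabilities at its final
step. For models with $V + H \le 20$, `exact_moments()` computes
$\langle v_i h_j\rangle_\text{model}$ by full state enumeration; the test
suite uses it to verify the conditionals, the stationary distribution and the
CD fixed point (a batch drawn from the model's own marginal produces an
expected update of zero), and `rbm_log_likelihood()` to check that updates
with exact negative statistics ascend the data likelihood.

Counts-valued fingerprints are binarized before training (`binarize()`,
threshold 0, strict inequality) because the units are Bernoulli; this is the
minimal consistent treatment of count descriptors.

### Deep belief network and fine-tuning

`dbn_pretrain()` stacks RBMs greedily: each layer trains on the mean-field
hidden activations of the layer below. `dbn_fine_tune()` then unrolls the
stack into an encoder–decoder network (decoder initialized with transposed
encoder weights, then untied) and minimizes the squared reconstruction error
$\tfrac{1}{2N}\sum_i \lVert x_i - y_i \rVert^2$ by mini-batch gradient
descent. Fine-tuning is purely unsupervised — no activity labels enter the
model anywhere — since the objective of the pipeline is a representation, not
a classifier. The analytic gradient is verified against central finite
differences on a 6–4–3 stack to a relative error below $10^{-4}$.

Reconstruction (`dbn_reconstruct()`) is a deterministic mean-field pass:
encode to the deepest layer, decode back, no sampling. This makes the error
matrix reproducible given a model. Per-entry errors are
$E_{ij} = |x_{ij} - y_{ij}|$ and the per-molecule error is the L2 row norm
(an L1 switch exists); the norm in the convergence rule below is configurable
because nothing else pins it down.

## Iterative outlier removal

`iterative_feature_learning()` alternates training and pruning: train a fresh
stack, reconstruct, drop the `outlier_fraction` of current features with the
largest mean column error, repeat. Weights are re-initialized from a
round-derived seed each round rather than warm-started — a deliberate choice
so that the error measured in round $r$ reflects the reduced feature set
alone, not the optimization history. The loop stops when the mean
per-molecule error changes by at most the tolerance `e` between rounds, with
two numerical amendments:

* the statistic is normalized by $\sqrt{M_\text{current}}$, because the raw
  L2 row norm shrinks mechanically as columns are removed and would never
  stabilize;
* a hard `max_rounds` cap (default 10) guarantees termination.

The default tolerance (0.08 at desk scale) sits between the normalized-error
drop caused by removing genuine coin-flip outliers (≈0.05 per batch at the
default generator conditions) and the much smaller drop (≈0.01) from removing
structured features, so the loop stops once the outliers are gone. At that
setting, across seeds, all eight planted outliers are removed and no signal
bits are lost.

Outlier screening uses the *generatively* trained stack (no fine-tuning
inside the loop, though a flag enables it). The reason is structural: the
likelihood gradient of an RBM gains nothing from memorizing a
class-independent fair-coin bit, so such bits keep a mean reconstruction
error near 0.5 and stand out; the squared-error objective of autoencoder
fine-tuning, in contrast, rewards memorizing exactly those high-variance
bits, which would erase the signal the screen relies on. Fine-tuning is
applied *after* removal, on the cleaned matrix, in the full pipeline.

## Error PCA and feature selection

`build_error_pca()` transposes the error matrix ($T = E^\top$, one feature
per row), centers each feature's error profile across molecules
($D = T - \mu$), forms the unnormalized covariance $C = D D^\top$ (the
$1/(N-1)$ factor changes neither eigenvectors nor relative distances and is
omitted), and eigendecomposes it. Feature $i$'s coordinate on component $j$
is its deviation row projected on the $j$-th principal direction, which
equals $\sqrt{\lambda_j}\,u_j[i]$; with the default $k = 3$ the distance to
the origin $\sqrt{x_i^2 + y_i^2 + z_i^2}$ scores each feature.
`select_features()` keeps features with distance at most the threshold
(default 3, a data-scale-dependent secondary filter), sorted ascending with
ties broken by ascending index, truncated to `top_k` (300 per fingerprint at
full scale — the primary selector). Numerical conventions: eigenvector signs
are fixed by making each component's largest-magnitude entry positive, and
tie comparisons use 10 significant digits so bitwise-duplicated columns
respect the index rule.

Two deliberately documented ambiguities:

* the centering direction of $\mu$ (per feature across molecules, the
  standard PCA reading) was chosen over per-molecule centering; both were
  evaluated and behave almost identically on synthetic data;
* similarity searching can run on the original binary bits or on the
  reconstructed continuous values at the selected columns; both are exposed
  and the pipeline defaults to the continuous values, which carry the learned
  weights.

### What the distance does and does not measure

Because the deviation matrix is centered, the PCA distance measures the
*variability* of a feature's reconstruction error, not its level, and the
rank-3 projection retains only variability that is correlated across
features. Two consequences, verified empirically on the synthetic generator
and stated here so that users do not over-read the selection: (i) a feature
whose error is large but constant (a perfectly unpredictable coin-flip bit
reconstructed at 0.5) sits *near* the origin — which is why outlier removal
uses mean column error and must precede selection; (ii) near-constant
background bits are the easiest features to reconstruct and dominate the
lowest distances, so the selected set is *not* strongly enriched in
class-informative bits (measured enrichment ≈1–1.5× random expectation across
seeds and training regimes, not the ≥2× one might hope for). The pipeline's
retrieval quality comes from the signal bits that selection retains alongside
background, not from selecting signal exclusively. This is an honest
limitation of reconstruction-variability selection on sparse fingerprints.

## Similarity search and evaluation

`rank_database()` scores the database against a reference structure with the
binary Tanimoto coefficient $|a \wedge b| / (|a| + |b| - |a \wedge b|)$ or
its continuous generalization
$\sum a_i b_i / (\sum a_i^2 + \sum b_i^2 - \sum a_i b_i)$ (all-zero pairs
score 0 by convention; the two coincide on binary data). Ties are broken by
ascending molecule id, the reference is excluded from its own list (including
it would inflate every recall uniformly; a switch exists), and cutoffs take
`ceiling(fraction × database size)` molecules.

The evaluation protocol (`class_recall()`) samples 10 reference structures
per activity class without replacement (seeded), retrieves the top 1% and 5%,
and averages the per-query recalls, where recall is
$100 \times \text{TP} / (\text{class size} - 1)$ — the query is excluded from
both numerator pool and denominator, consistent with its exclusion from the
ranked list. `build_recall_table()` assembles the classes × methods table
with column means and best-in-class counts (ties credit every tied method);
`recall_gains()` reports differences of column means rounded to two decimals
*before* differencing, matching the precision at which such tables are
conventionally reported. `kendall_w()` treats activity classes as judges and
methods as objects, assigns rank $n$ to the highest recall (mid-ranks on
ties), and computes $W = 12S / (m^2(n^3 - n))$ with the $\chi^2 = m(n-1)W$
approximation on $n-1$ degrees of freedom for the p-value; it is tested to
$10^{-12}$ against an independent transcription of the formulas.

The published per-class recall tables of the three MDDR benchmark subsets
(11 homogeneous+heterogeneous, 10 homogeneous, 10 heterogeneous activity
classes) ship as plain CSV under `inst/extdata/` and load through
`mddr_recall_values()`; they are inputs to the evaluation arithmetic, not
outputs of this package, since the underlying database is licensed.

## The synthetic generator

`synthetic_spec()`/`generate_fingerprints()` emulate the statistical
structure the method exploits, at desk scale: several activity classes of
stated sizes; per class, a disjoint set of signal bits on with probability
0.9 against a 0.05 background (defaults matching realistic folded-fingerprint
bit densities); and outlier features flipped on with probability 0.5
independently of class — maximally non-reconstructible by construction.
Descriptors share molecules and labels but draw independent signal/outlier
positions, so fusion across descriptors adds information. Defaults are
2 classes × 100 molecules, 64 features, 3 descriptors, 8 signal bits per
class, 8 outliers.

What the generator does *not* emulate: real substructure correlation (ring
systems and scaffolds induce correlated bits within and across classes),
heavy-tailed bit frequencies, class imbalance at MDDR scale (classes of
10²–10³ actives in a database of 10⁵), and fingerprint folding collisions.
Passing tests on this generator therefore demonstrate the mechanics and the
recoverable structure — outlier identification, deterministic training,
fusion never hurting retrieval — not screening performance on real chemistry.

## Problem sizes, budgets and determinism

Test- and vignette-scale runs use 64-feature descriptors, 200 molecules,
stacks of 64→48→24 units, 30 CD-1 epochs at learning rate 0.1 (batch 32), and
a few hundred fine-tuning epochs; these sizes were chosen so the full
property suite exercises every stage in about a minute. The full-scale
reference configuration (1024→2000→1800→1300→800→300, 70 epochs, CD with 50
Gibbs steps, batch 128, learning rate 0.05, weights initialized uniformly on
[0, 1)) remains the default of `train_config()`; the uniform-positive
initialization is kept for fidelity, with a small-Gaussian switch (`init =
"gaussian"`) that mixes faster at desk scale.

Every stochastic function takes an explicit seed; `sdbn_run()` derives
per-stage, per-descriptor and per-round seeds from one root seed via a
counter-based hash (kept below $2^{31}$), so a run is reproducible
bit-for-bit and changing one stage's settings does not perturb another's
randomness. A CD chain length of $k$ is exposed in the configuration rather
than hard-coded, since both CD-1 (fast, biased) and long chains (the
full-scale default of 50) are defensible.

## Known limitations

* Selection by PCA distance favours low-variability over class-informative
  features (analysis above); on sparse fingerprints the selected set is
  mostly easy background plus a subset of signal bits.
* At the default synthetic conditions the retrieval task saturates the 1%/5%
  cutoffs (every method retrieves only same-class actives), so recall
  comparisons between methods are ceiling-limited ties; the conditions were
  chosen for recoverability of the planted structure, not for discriminating
  between methods.
* Training is plain R linear algebra: adequate for desk-scale studies and the
  enumeration-verified test suite, not tuned for 10⁵-molecule matrices.
* The $\chi^2$ approximation for Kendall's $W$ is asymptotic in the number of
  judges; with few classes the p-value is indicative only.
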