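---
title: "Methods: influence-relevance voting for ligand-based target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: influence-relevance voting for ligand-based target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irvoter)
```

## The problem

Given a protein target and a set of molecules with measured potencies (EC50,
µM), ligand-based target prediction asks: which untested molecules are likely
active against this target? The package implements a family of scorers that
answer this from chemical similarity alone — no protein structure — together
with the evaluation machinery used to compare them: per-target tenfold
cross-validation, simulated screens against large random-negative pools, AUC
and enrichment metrics, calibration analysis, and paired per-target
significance tests.

## The model

Every molecule is a sparse binary fingerprint: one bit per distinct circular
substructure of radius 0–2 bonds centered on an atom, atoms labeled by element
and heavy-atom degree, bonds by order. Similarity between fingerprints is the
Tanimoto coefficient $|A \cap B| / |A \cup B|$.

The influence-relevance voter (IRV) scores a query molecule $\mathcal{X}$ from
its $k$ nearest training neighbors (default $k = 6$):

$$z(\mathcal{X}) = \sigma\Big(w_z + \sum_{i=1}^{k} R_i V_i\Big), \qquad
  R_i = \tanh(w_y + w_s s_i + w_r r_i),$$

where $s_i$ is the Tanimoto similarity of the $i$-th neighbor, $r_i$ its
1-based rank in the similarity-sorted neighbor list, and $\sigma$ the logistic
function. $R_i \in (-1, 1)$ is the neighbor's *relevance*; $V_i$ is its
*vote*, a learned weight indexed by the neighbor's class. The product
$I_i = R_i V_i$ is the neighbor's *influence*, an additive, signed, directly
inspectable contribution to the prediction — `irv_explain()` exposes it and
`plot_influences()` draws it.

In standard mode the vote table has two entries (inactive $w_0$, active
$w_1$), where a molecule is active iff its EC50 is *strictly* below the chosen
cutoff (1, 5 or 10 µM; a measurement exactly at the cutoff is inactive). The
potency-sensitive variant (PS-IRV) replaces the binary class with the
neighbor's potency bracket — EC50 $< 1$, $[1, 5)$, $[5, 10)$, $\ge 10$ µM,
classes 0–3 — so the votes can distinguish a potent neighbor from a marginal
one. Molecules with no measurement (random negatives) carry potency class 3,
the only bracket available to non-binders. In both modes the training target
is the binary label at the chosen cutoff; only the vote routing differs.

## Training

All weights are fitted jointly by minimizing the cross-entropy (equivalently,
the Kullback–Leibler divergence between empirical labels and predicted
probabilities) over the training molecules, with the neighbor structure fixed
(training molecules are never their own neighbors). Probabilities are clipped
to $[10^{-12}, 1 - 10^{-12}]$ inside the loss so it stays finite; gradients
for every weight are analytic and are verified against central finite
differences in the test suite.

Numerical choices that matter:

* **Optimizer.** The objective is optimized full-batch. The default is Adam
  (step 0.05, 500 epochs): with the near-symmetric small initialization the
  loss surface has a long, shallow plateau — relevances near 0, votes near 0 —
  on which fixed-step gradient descent moves imperceptibly for thousands of
  epochs, while per-parameter adaptive steps cross it reliably. Plain
  fixed-step gradient descent remains available (`optimizer = "gd"`), and its
  monotone-descent property at small learning rates is tested.
* **Step scale.** Gradients are divided by the training-set size (mean loss),
  so the learning rate does not depend on whether 90 or 1090 molecules are in
  the fold.
* **Initialization.** $w_z, w_y, w_s, w_r \sim U(-0.01, 0.01)$ from a seeded
  generator; votes start at $(-0.1, +0.1)$ in standard mode and
  $(+0.1, +0.05, +0.02, -0.1)$ in potency mode, breaking symmetry in the
  informative direction (potent neighbors vote up, non-binders vote down).
* **Early stopping.** Training stops when the mean loss has not improved by
  `tol` ($10^{-8}$) for 100 consecutive epochs; the returned weights are the
  best seen. The patience is deliberately generous: Adam's first tens of
  epochs can wobble without net improvement while the moment estimates warm
  up.
* **Rank feature.** $r_i$ is the raw 1-based rank; $k$ defaults to 6.
* **Regularization.** An optional L2 penalty on all weights is available and
  defaults to 0.
* **Ties.** Neighbor ties are broken by descending similarity then ascending
  molecule id, so results are invariant to the order of the training table.

## Fingerprints

The substructure-to-bit mapping is an explicit, lossless dictionary of
canonical substructure strings (`fp_dictionary()`): no hashing or folding, so
distinct substructures never collide, and the dictionary is persisted inside
serialized models so new molecules are fingerprinted into the same bit space.
The canonical string of an atom's neighborhood is its rooted tree-unfolding to
the given radius with branches sorted lexicographically — a deterministic
canonical form that makes the fingerprint a pure function of the labeled
graph (verified by permutation-invariance and independent-enumerator tests).
Two conventions worth noting: `tanimoto(empty, empty)` is defined as 0, so a
featureless molecule never looks identical to anything; and SMILES input is
canonicalized with OpenBabel before graph extraction, which kekulizes
aromatic rings — bond labels therefore come from the canonical kekulé
assignment, and any two writings of the same molecule map to identical bits.
OpenBabel silently repairs malformed SMILES (for example `C((C` parses as
ethane), so a syntactic validator in front of it enforces the rejection
contract with per-line reasons.

## Activity data

Duplicate (molecule, target) measurements are collapsed to their arithmetic
mean EC50 in µM (a geometric-mean option exists, off by default, since
averaging on the log scale is equally defensible). Targets with fewer than 10
molecules are discarded; a separate optional minimum-actives filter is
provided because the size filter can reasonably be read as counting either all
molecules or only actives — the default counts all molecules. Random-negative
pools are split reproducibly into a training pool (default 1000) and a
disjoint assessment pool (the remainder, nominally 9000).

## Baselines

MeanSim (mean similarity to all known actives) and MaxSim (similarity to the
nearest active, with the arg-max reported for inspection) are untrained;
kNN scores the active fraction among the $k$ nearest neighbors with
denominator $\min(k, n)$ so small training sets still yield proportions. Two
generic learners stand behind the same scorer interface: a random forest
(200 trees, 3 tried attributes) on signed similarity features — the top 10
training similarities, sorted descending, each multiplied by ±1 according to
the training molecule's label, padded with zeros when fewer are available —
and a C-classification SVM on the precomputed Tanimoto kernel (a positive
semidefinite kernel on binary fingerprints; eigenvalue-checked in the tests).
The SVM's cost is selected by an internal stratified 3-fold grid search over
$\{0.1, 1, 10, 100\}$; an epsilon parameter would only apply to
support-vector regression and is not searched. Because decision values from
independently fitted fold models have arbitrary offsets, each model's
decisions are affinely rescaled by its training decision range before fold
outputs are pooled — a monotone map that leaves per-fold AUC untouched and
makes pooled rankings meaningful.

## Evaluation protocols

*Cross-validation.* Each target's molecules are randomly partitioned into 10
folds of near-equal size; each fold is scored by a model trained on the other
nine, and the held-out scores are pooled into one ranked list covering every
molecule exactly once. A plan in which some fold lacks a class is invalid and
the target is skipped with a report — the folds are deliberately *not*
stratified, matching the protocol being emulated.

*Simulated screens.* The fold models are reused, but every fold's held-out
predictions are pooled with the full assessment-negative pool scored by that
fold's model, so each negative appears once per fold. A `negatives_once`
switch instead averages the fold-model scores per negative; per-fold pooling
is the default because fold outputs are pooled everywhere else.
Training-side augmentation adds the training pool to each fold's training set
as potency-class-3 inactives and never touches test sets.

*Metrics.* AUC uses the Mann–Whitney midrank convention (ties count one
half), making it exact under tied scores and invariant under monotone score
transforms. Enrichment at $N\%$ is the *recall* of actives within the top
$\lceil N/100 \cdot n \rceil$ of the ranked list (a precision reading of
"actives found at the top" is arguable; recall is the implemented default).
Reliability curves pool unit-interval scores of targets with AUC > 0.90 into
ten width-0.1 bins and report per-bin active fractions. Paired method
comparisons use a two-sided paired t-test on per-target AUC differences;
identical methods (zero-variance, zero-mean differences) are reported as "no
difference" rather than as an error.

## The synthetic corpus generator

`synthetic_corpus()` emulates the *structure* of a ChEMBL-like benchmark so
every protocol is testable offline: per target, one or more prototype bit sets
("chemical series"); actives that copy a prototype with independent bit flips;
in-assay inactives flipped three times harder with EC50 ≥ 10 µM; and an
optional pool of independent random bit sets serving as random negatives.
An active's potency is tied to its similarity to its own prototype by
$\mathrm{EC50} = 10^{\,1 - 3\,\mathrm{sim}}$ µM times a lognormal noise
$10^{N(0, \sigma)}$, clipped to $[10^{-3}, 10^{3}]$ — higher similarity, more
potent. Defaults: 512 bits, prototype density 0.1, flip probability 0.05,
$\sigma = 0.2$.

Two generator options extend the minimal design, both off by default:

* **Graded flip rates** (`p_flip_max > p_flip`): each active draws its flip
  probability uniformly from $[p_\mathrm{flip}, p_\mathrm{flip,max}]$. With a
  single flip rate the cluster's similarity band is a few hundredths wide and
  $g(\mathrm{sim})$ maps every active into one potency bracket, so cutoff and
  potency structure degenerate; a graded band realizes the "EC50 graded by
  similarity to the prototype" structure and lets the 1/5/10 µM cutoffs split
  the actives non-trivially.
* **Multiple series per target** (`clusters_per_target`): actives split evenly
  over independent prototypes. This reproduces the classical failure mode of
  mean-similarity scoring, which implicitly assumes a single active cluster,
  while leaving nearest-active scoring unaffected.

What the generator does *not* emulate: real chemistry (no valence, rings or
synthesizability — molecules are abstract bit sets), assay noise structure,
inter-target correlations, or matched-pair decoys. Passing tests on these
corpora therefore demonstrate correctness of the algorithms and the claimed
*directional* phenomena under controlled conditions, not performance on real
screening data.

## Reference study conditions

The acceptance script and the end-to-end tests fix four corpus conditions,
chosen once as representative regimes (sizes are the package's own choice to
keep a desk-scale run in minutes):

1. **Separable benchmark** — 10 targets, 50 actives + 50 inactives each, two
   series per target, flip rate 0.05, $\sigma = 0.2$, cutoff 1 µM. All
   learned methods (IRV, PS-IRV, forest, SVM) should exceed 0.95 mean
   cross-validated AUC here, and MeanSim should trail MaxSim because of the
   two-series design.
2. **Potency-graded corpus** — 20 replicate corpora of 5 targets, 80 actives
   (flip rates graded 0.05–0.35, so potency classes 0–2 are all populated)
   + 20 inactives, $\sigma = 0.2$, cutoff 1 µM. Many actives fall between 1
   and 10 µM: they are labeled inactive at the 1 µM cutoff yet are
   structurally informative, which is precisely the information the
   potency-indexed votes can exploit and the binary votes cannot. PS-IRV's
   mean AUC should match or exceed IRV's, with a paired t-test reported.
3. **Simulated screens** — 4 two-series targets plus a 10,000-molecule random
   pool split 1000 (training) / 9000 (assessment). Mean AUC with
   training-side augmentation should exceed mean AUC without it: the
   un-augmented models never see dissimilar molecules during training and
   over-score parts of the random background.
4. **Calibration corpus** — 8 targets, 300 actives with flip rates graded
   0.10–0.30 + 300 inactives, $\sigma = 0.2$, cutoff 1 µM. The graded band
   straddles the cutoff, so true activity probabilities vary smoothly from
   ~0.9 to ~0.1 across the cluster; a well-trained IRV's held-out reliability
   curve should deviate from the diagonal by less than 0.1 in every bin with
   at least 100 predictions. At these bin counts (~100–300) the binomial
   noise floor of a bin fraction is ±0.03–0.05, so the margin on this check
   is genuine but modest.

## Known limitations

* The IRV is instance-based: serialized models embed their training
  fingerprints, so model files grow with the training set.
* Exhaustive similarity search only — appropriate for per-target sets up to a
  few thousand molecules; no approximate nearest-neighbor index.
* The uncertainty-averaged vote extension for conflicting measurements (one
  vote per observed EC50, averaged) is not implemented.
* Unstratified folds mean small or imbalanced targets are sometimes skipped
  as invalid; this mirrors the emulated protocol rather than fixing it.
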