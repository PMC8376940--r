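---
title: "Predicting protein-protein interactions from PSSM profiles: methods and design notes"
author: "ppirof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from PSSM profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `ppirof`, the
assumptions behind them, the parameters that matter, and the design
decisions taken where the method description left choices open. It
states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## The pipeline

Two proteins are judged interacting or not from sequence alone, in four
stages: evolutionary profile, fixed-length descriptor, linear manifold
embedding, ensemble classification.

### From sequence to profile

A protein of length T is represented by its position-specific scoring
matrix (PSSM): a T x 20 integer matrix whose entry (i, j) is the
log-odds score of residue i mutating to amino acid j, estimated by
iterative profile search (PSI-BLAST, e-value cutoff 0.001, 3
iterations against a large reference database such as SwissProt).
Profile search needs an external binary and a multi-gigabyte database,
so the package deliberately stops at the boundary: `psiblast_command()`
constructs the exact invocation and `parse_ascii_pssm()` reads its
ASCII output, but nothing is executed. The ASCII dialect carries 40
numeric columns per residue (20 scores, then 20 weighted percentages,
then two per-position statistics); only the first 20 are kept, because
the profile model is the score matrix. Rows for non-standard residues
(X, B, Z) are taken as PSI-BLAST emits them.

### From profile to descriptor

The embedding and the classifier both need fixed-length inputs, while T
varies per protein. The method description leaves this reduction
unstated, so the package adopts the standard length-invariant summary
used throughout the PSSM-feature literature: squash each score with the
logistic function s(x) = 1/(1 + e^(-x)), then form the normalized
cross-product matrix

F = P'^T P' / T,    P'_ij = s(P_ij),

a 20 x 20 matrix flattened row-major to 400 dimensions
(`pssm_descriptor()`). F[j, k] is the mean over residues of
s(x_ij) s(x_ik), i.e. the co-occurrence of evolutionary preference for
amino acids j and k along the chain. Its useful properties are easy to
state and are asserted by tests: entries lie in (0, 1], F is symmetric,
and duplicating every row of the profile leaves F unchanged (length
invariance). An alternative reading -- applying the embedding to
profile rows rather than to per-protein summaries -- is rejected
because the embedding is a fixed linear map and cannot consume
variable-length inputs; this interpretation is the package's own.

### The OLPP embedding

Descriptors x_1..x_n are embedded by Orthogonal Locality Preserving
Projections. The locality objective min sum_ij ||y_i - y_j||^2 W_ij
asks that samples close in descriptor space stay close after the linear
map y = w^T x. The implemented steps:

1. *PCA pre-projection* (`pca_projection`): center, keep eigenvectors
   of the covariance whose eigenvalues exceed `pca_tol` (default 1e-8)
   times the largest. This removes the null space so the matrices below
   are invertible.
2. *Neighbourhood graph* (`build_knn_graph`): connect i and j when
   either is among the other's `n_neighbors` Euclidean nearest
   neighbours (OR-symmetrization, no self-edges). The alternative
   epsilon-ball rule is not implemented: the nearest-neighbour rule is
   the procedural description, and it needs no data-scale-dependent
   radius.
3. *Heat-kernel weights* (`heat_weights`): W_ij = exp(-||x_i -
   x_j||^2 / t) on edges, zero elsewhere. The bandwidth t has no
   canonical value; the default `"auto"` sets t to the mean squared
   edge distance, so a typical edge weighs e^-1. Any positive t may be
   supplied.
4. *Laplacian* (`degree_laplacian`): D_ii = column sums of W,
   L = D - W. L's rows sum to zero and L is positive semi-definite;
   both are asserted in tests.
5. *Orthogonal basis* (`orthogonal_basis`): o_1 is the
   smallest-eigenvalue eigenvector of (XDX^T)^-1 XLX^T (equivalently
   the smallest generalized eigenvector of XLX^T w = lambda XDX^T w).
   Each subsequent o_k minimizes the same Rayleigh quotient
   o^T XLX^T o / o^T XDX^T o subject to exact orthogonality to
   o_1..o_(k-1).

The embedding is y = W^T (x - mean) with W = W_PCA [o_1..o_d]. It is
fully deterministic — there is no randomness anywhere in the fit.

**Numerical route for step 5.** The constrained minimizer can be
written as the smallest-eigenvalue eigenvector of the deflated operator
{I - (XDX^T)^-1 A B^-1 A^T} (XDX^T)^-1 XLX^T with A = [o_1..o_(k-1)]
and B = A^T (XDX^T)^-1 A. That operator, however, has k-1 exact zero
eigenvalues whose eigenvectors violate the orthogonality constraint
(A^T M = 0 forces range(M) to be orthogonal to A, so only eigenvectors
with nonzero eigenvalue are admissible), and a nonsymmetric
eigensolver must then sort admissible from spurious modes.
`orthogonal_basis()` therefore computes the identical vector in the
orthogonal complement of span(A): with Q an orthonormal basis of that
complement, solve the symmetric-definite problem
(Q^T XLX^T Q) z = lambda (Q^T XDX^T Q) z by Cholesky reduction and set
o_k = Q z. This has no spurious modes, uses symmetric eigensolvers
(about an order of magnitude faster here), and the test suite verifies
both that o_1 matches an independent dense generalized eigensolve and
that o_2 matches the explicit deflated-operator eigenvector and a
brute-force grid minimization over the constraint circle.

Other numerical conventions: a ridge of 1e-8 x trace(XDX^T)/r is added
to XDX^T before inversion (the derivation assumes invertibility
silently); each o_k is unit-normalized (the objective fixes only a
direction); and each o_k is sign-flipped so its largest-magnitude entry
is positive, making fits reproducible across eigensolver
implementations.

Degenerate inputs: constant data fails the PCA step with a
"degenerate data" error; an edgeless graph cannot auto-select t;
`embed_dim` may not exceed the PCA rank, which is itself at most
n - 1 — with n proteins the embedding dimension must stay below n.

### Pair features and the Rotation Forest

A pair (A, B) is represented by concatenating the two embeddings in
pair order (2d dimensions). Concatenation, rather than difference or
product, is the simplest order-preserving choice; nothing downstream
depends on it.

The classifier (`rotation_forest()`) is written from scratch around
`rpart` CART trees (Gini impurity, grown to purity, no pruning — the
tree type is otherwise unspecified in this family of methods, and CART
is the canonical R base learner). For each of the L trees:

* the feature indices are randomly permuted and split into K disjoint
  subsets (sizes differing by at most one when K does not divide n);
* for each subset, a bootstrap sample of ceil(0.75 N) training rows is
  drawn and the subset columns' full PCA coefficient matrix is
  estimated from it (via the covariance eigendecomposition, so the
  block stays square and orthonormal even for rank-deficient
  resamples; a zero-variance subset degrades to an identity block with
  a warning rather than failing);
* the blocks are assembled into an n x n rotation matrix that is
  exactly zero outside the blocks, rows arranged back in original
  feature order;
* the tree trains on the **full** training set rotated by that matrix.
  The "75% bootstrap" resample affects only the PCA estimation — this
  is the classical convention, and the wording of the original
  description is ambiguous on it.

Prediction averages the trees' leaf class-frequency probabilities,
m_j(x) = (1/L) sum_i d_ij(x G_i), and assigns the highest-confidence
class, ties resolving to the lower class index. The random
class-elimination step of the original Rotation Forest formulation is
not implemented, since the method this package follows does not
mention it. All randomness flows from the single `seed` in
`rof_config()`; fits are bit-reproducible.

Reference settings K = 10 and L = 35 are the defaults; `grid_search()`
reproduces the K x L accuracy-surface optimization.

## Evaluation protocol

`confusion()` / `classification_metrics()` implement the four standard
binary measures, with positive class "interacting":

* Acc = (TP + TN) / N,
* Pre = TP / (TP + FP),
* Sen = TP / (TP + FN),
* MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TN+FN)(TN+FP)(TP+FN)).

A zero denominator yields 0 with an explicit `degenerate` flag rather
than NaN. `roc_auc()` computes the AUC as the Mann-Whitney statistic
(ties count one half) and sweeps every unique score as an ROC
threshold, FPR on the X axis, TPR on the Y axis.

`cross_validate()` runs stratified five-fold cross-validation on the
pair list. Stratification keeps the class balance per fold (the
protocol description says only "five parts"; stratified is the safer
reading and is documented as such). Leakage control is strict and is a
deliberate choice where the original protocol is silent: within each
fold the OLPP map is fitted only on descriptors of proteins occurring
in the training pairs; held-out pairs are embedded with that fitted
map. Reported dispersion is the sample (n-1) standard deviation over
folds, matching the usual "mean ± std" convention. ROC scores are the
ensemble's class-1 confidences.

## The synthetic benchmark

Real evaluations in this literature use DIP-derived *Yeast* (11,188
pairs) and *Human* (8,161 pairs) datasets with SwissProt PSI-BLAST
profiles — external downloads the package intentionally avoids.
`synth_pair_dataset()` generates a self-contained substitute with a
controllable class signal:

* sequences: i.i.d. uniform residues, lengths uniform in 50–120 (the
  50-residue floor mirrors the usual fragment filter);
* profiles: integer scores in [-10, 10], each residue's own column
  biased positive (mode ≈ +5) — enough structure to exercise the
  parsers and produce realistically correlated descriptors;
* class signal: a unit latent direction v is drawn inside the span of
  the top five principal modes of the base descriptors; every protein
  carries a binary interface signature z = ±1 and its descriptor is
  shifted by `effect` · sigma · z along v, where sigma is the standard
  deviation of base descriptors projected on v. Pair labels come from
  the noisy score s = `effect` · (+1 if both partners are "+", else
  −1) + N(0, 1): the top `positive_fraction` of scores are labeled
  interacting, giving exact label counts.

Two properties of this construction matter:

* at `effect = 0` the labels are pure pair-level noise. No classifier
  can beat AUC 0.5, *including* one that memorizes proteins it has
  seen in training pairs — a real hazard under pair-level
  cross-validation with shared proteins, and the reason the labels are
  not a deterministic function of protein identity;
* at large `effect` the labels are almost fully determined by the two
  signatures (the N(0, 1) score noise leaves a Bayes ceiling of about
  Phi(effect) per protein readout), and the geometric signature is
  *between-protein* structure along a dominant covariation mode —
  exactly what a locality-preserving embedding retains.

The second point is the result of a design iteration worth recording.
The obvious alternative — perturbing the two endpoint descriptors of
each interacting pair by a shared latent vector — places the class
signal *within* each protein's neighbourhood in descriptor space.
A locality-preserving projection treats within-neighbourhood variation
as noise to be compressed away: in that design the signal direction's
Rayleigh quotient sat far above the retained eigen-band, and the
pipeline stayed at chance accuracy regardless of embedding dimension
or neighbourhood size, even though the raw descriptors separated the
classes almost perfectly. An unsupervised embedding step constrains
where a learnable signal may live; the generator respects that
constraint by making the signal a protein-level property expressed in
the dominant descriptor modes, which is also the biologically sensible
reading (an interface signature a protein either carries or lacks).

What the generator does **not** emulate: homology between proteins,
phylogenetic correlation, realistic amino-acid composition, database
redundancy, or the asymmetric negative sampling of the real datasets.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and recovers a recoverable signal — not that it attains any
particular accuracy on real interactomes.

## Reference problem sizes

The bundled evaluations (test suite and `scripts/acceptance.R`) use
100 proteins, 400 pairs, embedding dimension d = 50, K = 10, L = 35,
five folds. d must stay below the protein count (the PCA rank bound);
50 retains the full between-protein structure of a 100-protein
benchmark while keeping the orthogonal-basis iteration cheap. The
embedding-dimension default in `olpp_config()` is 100, a conventional
choice for datasets with thousands of proteins where the rank bound is
not binding; it is a required, explicit parameter precisely because no
canonical value exists.

## Known limitations

* The embedding dimension d, neighbourhood size and heat bandwidth are
  not self-tuned; only K and L have a built-in grid search.
* `predict.rotation_forest` stores full `rpart` objects; models for
  very large L are correspondingly large. OLPP models serialize to
  portable JSON (`write_olpp_model`); Rotation Forest models use R's
  native serialization.
* The pipeline evaluates pair-level cross-validation with shared
  proteins, as is conventional here; protein-disjoint splits would
  give more conservative estimates on real data.
* Only the unsupervised neighbourhood graph is implemented; the
  supervised variant (edges restricted to same-class samples) is out
  of scope.
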