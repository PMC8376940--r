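# ppirof

Sequence-based prediction of protein–protein interactions (PPIs) with
Orthogonal Locality Preserving Projections and a Rotation Forest
ensemble.

High-throughput interaction screens are expensive and noisy, so
computational prediction of whether two proteins interact — from their
sequences alone — is a standard task in proteomics. `ppirof` implements
a complete, tested pipeline for it:

1. **Evolutionary profiles.** Each protein sequence is represented by
   its position-specific scoring matrix (PSSM), the T × 20 matrix of
   per-residue log-odds substitution scores produced by PSI-BLAST
   (e-value 0.001, 3 iterations; the package builds the command and
   parses the ASCII output — it never runs BLAST itself).
2. **Fixed-length descriptors.** A variable-length profile P is
   summarised as F = P′ᵀP′ / T with P′ = 1/(1+e^(−P)), flattened to a
   400-dimensional vector: a length-invariant summary of inter-residue
   evolutionary covariation.
3. **OLPP embedding.** Descriptors are embedded by Orthogonal Locality
   Preserving Projections: PCA null-space removal, a k-nearest-neighbour
   graph with heat-kernel weights W_ij = exp(−‖x_i−x_j‖²/t), the graph
   Laplacian L = D − W, and d mutually orthogonal directions found by
   successively minimising oᵀXLXᵀo / oᵀXDXᵀo. New samples map linearly:
   y = Wᵀ(x − mean), W = W_PCA · W_OLPP.
4. **Rotation Forest.** A pair (A, B) is the concatenation of the two
   embeddings. L CART trees each train in their own rotated feature
   space: the features are randomly split into K disjoint subsets,
   per-subset PCA coefficients (estimated on a 75% bootstrap resample)
   form a sparse block-diagonal rotation matrix, and the tree sees the
   full training set rotated by it. Prediction averages the trees'
   class probabilities.
5. **Evaluation.** Accuracy, precision, sensitivity, Matthews
   correlation coefficient, ROC/AUC, stratified five-fold
   cross-validation (the embedding is refitted inside each training
   fold — no information leaks from the test fold), and a K × L grid
   search.

A seeded synthetic benchmark generator (sequences, PSSM-like profiles,
labeled pairs with a controllable class-signal strength) makes every
stage testable offline; the DIP-derived *Yeast*/*Human* datasets and a
SwissProt BLAST database are deliberately not required.

## Worked example

```r
library(ppirof)

# a synthetic benchmark: 100 proteins, 400 labeled pairs, strong signal
ds <- synth_pair_dataset(synth_spec(n_proteins = 100, n_pairs = 400,
                                    effect = 2, seed = 42))

report <- cross_validate(ds$pairs, ds$descriptors,
                         olpp = olpp_config(embed_dim = 50),
                         rof  = rof_config(n_subsets = 10, n_trees = 35, seed = 42),
                         k_folds = 5, seed = 42)
print(report)
```

```
5-fold cross-validation (seed 42)
  K = 10 subsets, L = 35 trees, d = 50 embedding dims
  accuracy     0.9725 +/- 0.0105
  precision    0.9902 +/- 0.0218
  sensitivity  0.9550 +/- 0.0209
  mcc          0.9461 +/- 0.0205
  auc          0.9755 +/- 0.0165
```

Each line is the mean ± sample standard deviation over the five folds:
97.25% of held-out pairs are classified correctly, 99.0% of predicted
interactions are real (precision), 95.5% of real interactions are
recovered (sensitivity), and the ranking quality of the class-1
confidence reaches an AUC of 0.976. With `effect = 0` the generator
produces label noise and the same pipeline stays at chance (AUC ≈ 0.5).

The same run is available from the shell via the bundled CLI:

```sh
Rscript inst/cli/ppi.R synth --out-dir bench --n-proteins 100 --n-pairs 400 --effect 2 --seed 42
Rscript inst/cli/ppi.R run --pssm-dir bench/pssm --pairs bench/pairs.tsv \
        --out-dir bench/out --K 10 --L 35 --dim 50 --folds 5 --seed 42
```

which writes `report.json`, per-fold ROC points (`roc.tsv`) and the
descriptor matrix into `bench/out/`.

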