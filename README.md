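# bondgat

Attention-based graph neural networks for predicting ADMET-type molecular
properties (lipophilicity, aqueous solubility, cytochrome P450 inhibition)
directly from SMILES — no computed molecular descriptors.

`bondgat` is aimed at computational chemists and ML practitioners in drug
discovery who want a self-contained, inspectable R implementation of a
*bottom-up* graph attention architecture: the model first analyzes a
molecule's bond-type substructures, then the whole molecular graph.

## The model

A molecule parsed from SMILES becomes a node feature matrix **H** (one-hot
atom features: atomic number, formal charge, hybridization, ring flag,
aromatic flag, chirality; D = 124) and five adjacency matrices — **A**₁ for
the full molecule plus one per bond class (single, double, triple,
aromatic), each with self-loops only on participating atoms.

The network stacks three modules:

1. **Substructure branches.** For each bond class *k*, two multi-head graph
   attention layers on **A**ₖ. One head computes
   Z = HW, e<sub>jl</sub> = LeakyReLU((z<sub>j</sub> ⊕ z<sub>l</sub>)aᵀ),
   λ<sub>jl</sub> = softmax over the neighborhood U(j), and
   h̃<sub>j</sub> = LeakyReLU(Σ<sub>l</sub> λ<sub>jl</sub> z<sub>l</sub>).
   The four branch outputs are fused by a masked sum gated by diag(**A**ₖ).
2. **Whole molecule.** A four-head attention layer on **A**₁ (concatenated,
   width Q = K·F), then gated global attention pooling
   X = Σ<sub>j</sub> σ(h\*<sub>j</sub>W₁+b₁) ⊙ (h\*<sub>j</sub>W₂+b₂).
3. **Head.** Batch normalization and an MLP; linear output for regression,
   sigmoid for classification.

Training objectives address the data's shape: a **density-weighted RMSE**
(w<sub>i</sub> = 1 − α·p′(y<sub>i</sub>), kernel density min–max normalized,
α = 0.55 by default) for skewed continuous targets, and a **log-ratio
class-weighted BCE** (w<sub>c</sub> = ln(N<sub>c*</sub>/N<sub>c</sub> + 1))
for imbalanced labels. Evaluation follows stratified five-fold
cross-validation with a 20% validation carve-out, best-epoch selection
(validation RMSE or AUPRC), and median ± SD reporting; AUPRC is average
precision, whose no-skill baseline equals the positive prevalence.

Two ablation variants are built in: `whole_molecule` (no substructure
branches) and `convolutional` (the whole-molecule attention replaced by a
leaner symmetric-normalized graph convolution).

## Installation and requirements

```sh
R CMD INSTALL .
```

The compiled core needs Rcpp/RcppArmadillo (declared in `DESCRIPTION`).
SMILES parsing is delegated to RDKit through a bundled Python helper, so a
`python` with the `rdkit` package must be on the PATH (override with
`options(bondgat.python = ...)` or `BONDGAT_PYTHON`).

Run the tests with:

```r
testthat::test_dir("tests/testthat", package = "bondgat",
                   load_package = "installed")
```

## A worked example

```r
library(bondgat)

# a synthetic, imbalanced classification corpus (prevalence 0.20):
# positives contain a triple bond or two aromatic rings
d <- generate_synthetic_dataset(400, "classification", seed = 5)

fit <- bondgat(d, task = "classification", epochs = 10, seed = 1)
summary(fit)
#> Bond-substructure graph attention network (complete variant)
#>   task: classification, 158337 parameters, 400 molecules (80 validation)
#>   selected epoch 4/10 with validation AUPRC = 0.9214
#>   training:   AUROC = 0.9382, AUPRC = 0.8480, precision = 0.8831, recall = 0.8500
#>   validation: AUROC = 0.9358, AUPRC = 0.9214, precision = 0.9444, recall = 0.8500
```

The fit selected epoch 4, where validation AUPRC peaked at 0.92 — against a
no-skill baseline equal to the 0.20 prevalence — and the usual methods work:
`predict(fit, c("CC#CC", "CCOCC"))` returns class-1 probabilities,
`coef(fit)` the named weight matrices, `plot(fit)` the training curves.

The full protocol is one call:

```r
cv <- run_cross_validation(d, task = "classification", epochs = 30, seed = 1)
cv            # per-metric median and SD over the 5 test folds
```

Lower-level pieces — `featurize()`, `attention_head()`, `masked_sum()`,
`global_attention_pool()`, `density_weights()`, `class_weights()`,
`split_cv()`, `classification_metrics()` — are exported and documented
individually.

A command-line interface wraps the same functions
(`inst/cli/bondgat synth|stats|featurize|train|crossval|evaluate`); the
four public regression/classification benchmark datasets are reachable via
`load_benchmark()` (network required on first use, cached afterwards).

## Vignette

`vignettes/bondgat-methods.Rmd` documents the model and its assumptions,
the weighting strategies, the evaluation protocol, what the synthetic
corpus does and does not demonstrate, and all numerical choices.
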