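---
title: "Bottom-up bond-substructure graph attention: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up bond-substructure graph attention: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bondgat` predicts molecular properties of the ADMET kind (lipophilicity,
aqueous solubility, cytochrome P450 inhibition) directly from SMILES
strings, with a graph neural network that analyzes a molecule bottom-up:
first its bond-type substructures, then the whole molecular graph. This
vignette is the package's own account of the model, its assumptions, the
tunable parameters, the synthetic data used to exercise it, and the
numerical choices made where the design was genuinely open.

## Molecular graph representation

A molecule is a graph whose nodes are heavy atoms (hydrogens stay
implicit) and whose edges are bonds. Each atom is encoded as the
concatenation of six one-hot blocks — atomic number (1–101), formal charge
(−3…3 plus an "Extreme" slot for |q| > 3), hybridization (S, SP, SP2, SP3,
SP3D, SP3D2, Other), ring membership, aromaticity, and tetrahedral
chirality tag — giving a feature vector of fixed width D = 124. The block
order is part of the model: it is serialized with every fit.

Connectivity is described by *five* N×N adjacency matrices: `A_full` with
every bond, and one matrix per bond class (single, double, triple,
aromatic). All matrices are symmetric and zero-padded to a shared capacity
`n_max` (the dataset's maximum heavy-atom count, stored with the model so
train- and test-time featurization agree).

Two conventions deserve emphasis:

* **Self-loops.** `A_full` has a self-loop on every real atom. A
  substructure matrix, however, has a self-loop on atom *i* only when *i*
  participates in at least one bond of that class. These diagonals are
  exactly the masks read by the fusion layer below; an unconditional
  all-ones diagonal would make the masking vacuous.
* **Aromaticity.** Bond classes are assigned after the parser's standard
  aromaticity perception, so notation does not matter: benzene written in
  Kekulé form still produces six aromatic bonds. Parsing and perception
  are delegated to RDKit (the de-facto standard toolkit, invoked as a
  batched subprocess through a bundled helper script); the package never
  re-implements chemistry perception.

Elements beyond Z = 101 are a hard error rather than a silent bucket — the
vocabulary enumerates elements exhaustively and has no "other element"
slot. Out-of-list charges, hybridizations and chirality tags map to their
designated Extreme/Other slots.

## The network

The architecture has three modules.

**Module 1 — substructure branches.** For each bond class *k*, an
independent branch processes the input features `H` with the class
adjacency `A_k`: a multi-head graph attention layer (heads concatenated),
a second multi-head attention layer, and a head average, yielding an N×F
matrix per branch. A single attention head computes

$$Z = HW,\qquad e_{jl} = \mathrm{LeakyReLU}\big((z_j \oplus z_l)\,a^{\top}\big),\qquad
\lambda_{jl} = \frac{\exp e_{jl}}{\sum_{l' \in U(j)} \exp e_{jl'}},\qquad
\tilde h_j = \mathrm{LeakyReLU}\Big(\sum_{l \in U(j)} \lambda_{jl} z_l\Big),$$

where the neighborhood U(j) is row *j* of the adjacency (including *j*
itself when the diagonal is set). Atoms with an empty neighborhood — padded
rows, and atoms absent from a substructure — map to zero rows. The softmax
is computed only over actual neighbors (excluded pairs are never
exponentiated), so the attention of every real atom is exactly
row-stochastic.

The four branch outputs are fused by a **masked sum**: row *j* of the
result is the sum of the branch rows gated by `diag(A_k)[j]`. An atom in
only the aromatic substructure inherits exactly the aromatic branch's
features; an atom in none maps to zero.

**Module 2 — whole molecule.** The fused features pass through one more
multi-head attention layer on `A_full` (heads concatenated, width
Q = K·F), followed by gated global attention pooling,

$$X = \sum_{j\,\mathrm{real}} \sigma(h^*_j W_1 + b_1) \odot (h^*_j W_2 + b_2) \in \mathbb{R}^P,$$

an order-free readout, so predictions are invariant under atom reindexing
and under padding — properties the test suite checks on the full forward
pass.

**Module 3 — head.** Batch normalization of X, then an MLP with LeakyReLU
hidden layers and a single output unit: linear for regression, sigmoid for
classification (probabilities are therefore strictly inside (0, 1)).

Two ablation variants are built from the same parts: *whole-molecule*
(Module 1 removed; `H` feeds Module 2 directly) and *convolutional*
(Module 2's attention replaced by a symmetric-normalized graph convolution
$\mathrm{LeakyReLU}(\tilde D^{-1/2} A \tilde D^{-1/2} H W)$ of the same
output width, which has D·F parameters against the attention layer's
K·(D·F + 2F) — strictly fewer for any K ≥ 1).

### Defaults, and why

All defaults are exposed in `bondgat_config()` and the fitting functions:

| parameter | default | role |
|---|---|---|
| K | 4 | attention heads per layer (the count the convolution replaces) |
| F | 32 | per-head feature width |
| Q = K·F | 128 | node width entering the pool |
| P | 64 | pooled graph-vector width |
| MLP hidden | 64, 32 | LeakyReLU layers before the output unit |
| LeakyReLU slope | 0.2 | every nonlinearity, including attention logits |
| optimizer | Adam, lr 1e-3, batch 32 | standard schedule |
| epochs | 100 | with best-epoch checkpoint selection (no early stop) |
| α (density weighting) | 0.55 | regression loss, see below |

The head count of 4 in the layer the convolutional variant replaces is a
structural commitment of the architecture; the widths (F, P, hidden
sizes) are stand-in defaults chosen so the complete model has roughly
1.5×10⁵ parameters — large enough to learn the benchmark-scale tasks,
small enough to cross-validate on a single CPU. They are deliberately
config-overridable rather than baked in.

Weights are initialized with variance-scaling (fan-average) uniform draws
seeded from the model seed; biases start at zero and batch-norm at
gamma = 1, beta = 0. Batch normalization uses batch statistics during
training and running statistics (momentum 0.9, epsilon 1e-5) at inference.

A note on layer bookkeeping: descriptions of this architecture sometimes
number the concatenation, averaging and pooling steps inconsistently. The
implementation follows the unambiguous dataflow — branch attention
(concat) → branch attention → head average → masked sum → whole-molecule
attention (concat) → attention pool → batch norm → MLP — and the test
suite pins that composition by reproducing the compiled engine's
predictions from the exported layer functions.

## Training objectives for skewed and imbalanced data

**Regression** uses a weighted RMSE,
$\sqrt{\sum_i w_i (y_i - \hat y_i)^2 / N}$, whose sample weights
down-weight over-represented target values: estimate the target density
p(y) with a Gaussian kernel (Silverman's rule-of-thumb bandwidth — the
standard default, configurable), min–max normalize it to p′ ∈ [0, 1], and
set $w_i = 1 - \alpha\,p'(y_i)$. At α = 0 this is plain RMSE; at the
default α = 0.55 the density mode is weighted 0.45 and the rarest targets
keep weight 1. Weights are a pure function of the training split, computed
once per fold before training — never from validation or test labels, and
never re-estimated per epoch (they depend only on targets).

**Classification** uses a class-weighted binary cross-entropy with
log-ratio weights $w_c = \ln(N_{c^*}/N_c + 1)$, where $N_{c^*}$ is the
majority class count: the majority class always gets ln 2 and the
minority class more, growing with the imbalance. The weight multiplies the
whole per-sample cross-entropy term (the standard weighted-BCE reading).
Probabilities are clipped at 1e-7 on both sides before the logarithms.

## Evaluation protocol and metrics

`run_cross_validation()` implements five-fold cross-validation: the five
test folds partition the data; within each fold, 20% of the remaining
records (drawn per fold, seeded `seed + fold`) form a validation set and
the rest the training set. For classification, both the fold assignment
and the validation carve-out are stratified, keeping prevalence within one
record of the dataset's in every subset. After each epoch the model is
scored on the validation set — RMSE for regression (minimized), AUPRC for
classification (maximized) — and the best epoch's weights are restored at
the end; no patience-based early stopping is applied. Test metrics are
aggregated as median and standard deviation over the five folds.

AUPRC is computed as **average precision**: a step-wise sum of precision
times recall increments over score thresholds, with tied scores handled as
blocks and no linear interpolation (interpolated PR curves overstate the
area). Under this estimator a constant-score classifier attains exactly
the positive prevalence — the no-skill baseline every AUPRC should be read
against. AUROC is the Mann–Whitney rank statistic (midranks, exact under
ties); the tests cross-check it against trapezoidal ROC integration and
against the independent `pROC` implementation. Point precision and recall
are reported at a 0.5 threshold.

One documented leakage exception: the padded capacity `n_max` is computed
dataset-wide (not per training fold) so that all folds share one graph
shape. It is a size, not a statistic of the labels.

## The synthetic corpus: what it does and does not show

`generate_synthetic_dataset()` assembles molecules from a fragment grammar
— alkane/ether/amine chains, at most one vinyl and one ethynyl fragment,
zero to two benzene rings — guaranteeing that all four bond classes occur
and that every emitted SMILES parses. Labels are exact functions of the
structure:

* regression: 0.5·(aromatic atoms) + 1.0·(double bonds) + 1.5·(triple
  bonds) − 0.1·(heavy atoms) + Gaussian noise (sd 0.25, configurable to 0
  for exact recoverability). Ring and triple fragments are rare, so the
  marginal is right-skewed, exercising the density weighting.
* classification: positive iff the molecule contains a triple bond or two
  aromatic rings; 5% of labels are then flipped. The pre-flip prevalence
  is tunable and defaults to 0.20, the imbalance of the most skewed CYP
  inhibition benchmark.

This corpus emulates the *statistical shape* of the benchmark data —
bond-class diversity, a skewed continuous target, an imbalanced binary
target — and provides a signal that a small model can learn in minutes on
one CPU. It does **not** emulate real chemical diversity: molecules are
small (≤ ~20 heavy atoms), contain no charges, stereocenters, fused rings
or heteroaromatics, and the label functions are far simpler than any
ADMET endpoint. Passing the learning-sanity checks therefore demonstrates
that the training machinery works end-to-end (featurization → weighting →
optimization → selection → evaluation), not that the model reaches
literature-level accuracy; reproducing published benchmark numbers
requires downloading the public datasets (`load_benchmark()`) and training
at full scale, which is hours of compute and outside the test suite.

The problem sizes used by `scripts/acceptance.R` — 2000 molecules × 30
epochs for classification, 1000 × 20 for regression, five folds each —
were chosen as the smallest runs at which the cross-validated medians are
stable across seeds.

## Numerical choices and degenerate inputs

* The attention softmax subtracts the per-row maximum before
  exponentiation; excluded (non-neighbor) pairs are never part of the sum,
  yielding exact zeros rather than tiny probabilities.
* Zero-degree rows bypass the graph-convolution normalization and stay
  zero, matching the attention layers' empty-neighborhood convention.
* Constant regression targets make the density (and R²) undefined: the
  weights fall back to all-ones with a warning, and R² is returned as NA.
  Single-class label vectors are a hard, classed error everywhere
  (weights, metrics, stratified splits).
* The training loss's gradient at an exact zero WRMSE is defined as zero
  (the loss is not differentiable there; it cannot occur with noisy data).
* All gradients are analytic, implemented in compiled code, and verified
  against central-difference numerical differentiation for every variant
  and task in the test suite (tolerance 1e-4 on sampled coordinates;
  observed agreement is ~1e-8).
* Determinism: every random choice (corpus generation, splits, weight
  initialization, shuffling) flows from user-supplied integer seeds
  through R's RNG; the compiled engine itself is deterministic. Fitting
  twice with the same seed reproduces the model bit-for-bit.

## Known limitations

* No edge features: bond type enters only through the adjacency
  decomposition, never as a feature vector.
* Single-task, single-output models only; no uncertainty estimates.
* Tetrahedral chirality is encoded as a tag; no 3-D or geometric
  information is used (by design — the approach exists to bypass computed
  descriptors).
* The benchmark loader requires network access (and the Python `tdc`
  client) on first use; offline it fails with guidance to supply a local
  CSV instead. Published benchmark statistics can drift with platform
  releases, so size/prevalence checks are reported as warnings, not
  failures.
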