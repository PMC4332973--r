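---
title: "ELM-MIL: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ELM-MIL: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmmil)
```

## The problem

In multiple instance learning (MIL) the unit of supervision is a *bag* of
feature vectors (*instances*) whose individual labels are unobserved. The
canonical application is drug-activity prediction: a molecule (bag) is
active iff at least one of its conformations (instances) binds the target —
the standard *MIL assumption*. Classification labels are $Y_i \in \{0, 1\}$;
in MIL regression $Y_i$ is a real in $[0, 1]$ determined by the bag's best
instance.

## The model

The learner is a single-hidden-layer feedforward network used the extreme
learning machine (ELM) way: hidden parameters are random and frozen, and
only the linear output layer is estimated. The instance-level network is

$$o(\mathbf{x}) = \sum_{j=1}^{L} \beta_j\, G(\mathbf{a}_j, b_j, \mathbf{x}),$$

with $G$ either the additive sigmoid node
$G(\mathbf{a}, b, \mathbf{x}) = 1/(1 + e^{-(\mathbf{a}\cdot\mathbf{x} + b)})$
or the Gaussian node
$G(\mathbf{a}, b, \mathbf{x}) = \exp(-b\,\lVert\mathbf{x}-\mathbf{a}\rVert^2)$.
Over $N$ inputs the node activations form the $N \times L$ hidden matrix
$\mathbf{H}$, and the output weights solve the ridge problem with regulator
$C$ ($1/C$ is added to the diagonal of the normal equations):

$$\boldsymbol\beta = \mathbf{H}^\top(\mathbf{I}/C + \mathbf{H}\mathbf{H}^\top)^{-1}\mathbf{Y}
\quad (N < L), \qquad
\boldsymbol\beta = (\mathbf{I}/C + \mathbf{H}^\top\mathbf{H})^{-1}\mathbf{H}^\top\mathbf{Y}
\quad (N \ge L).$$

The two branches are algebraically identical (push-through identity); the
shape-dependent choice only picks the smaller system. Both reduce to the
minimal-norm least-squares solution $\mathbf{H}^\dagger\mathbf{Y}$ as
$C \to \infty$. Note the wide-data branch must carry the inverse — the
expression $(\mathbf{I}/C + \mathbf{H}^\top\mathbf{H})\mathbf{H}^\top\mathbf{Y}$
without it is not a least-squares solution and does not approach the
pseudoinverse limit, so this package implements the standard primal ridge
form shown above.

## The two-step MIL fit

Supervision is at bag level, so the bag error is charged to the instance
with the maximum network output:
$E_i = \tfrac12\,(\max_j o_{ij} - Y_i)^2$, summed over bags. `elm_mil()`
trains in one pass:

1. **Random initialization.** Draw the hidden layer
   ($\mathbf{a}_j \sim U[-1,1]^p$, $b_j \sim U[0,1]$, or $U(0,1]$ impact
   factors for Gaussian nodes) *and* a random initial output vector
   $\boldsymbol\beta_0 \sim U[-1,1]^L$ from one seeded stream, so a single
   integer seed reproduces the whole fit.
2. **Win-instance selection.** Score every instance with
   $(\text{layer}, \boldsymbol\beta_0)$ and keep, per bag, the argmax
   instance — the most positive instance of a positive bag, the least
   negative of a negative one. Ties break to the lowest index.
3. **Hidden matrix on the $M$ win-instances**, with the *same* frozen layer.
4. **Ridge solve** of $\boldsymbol\beta$ against the bag labels.

The hidden layer is never retrained; only $\boldsymbol\beta$ changes. At
prediction time the bag score is the maximum instance output under the
fitted $\boldsymbol\beta$ — the natural test-time mirror of the training
rule — and classification thresholds the score at 0.5 with the boundary
counted positive.

Two readings of the bag error coexist in the literature: the maximum of the
squared deviations versus the squared deviation of the maximum output. They
coincide for positive bags and for negative bags with nonnegative outputs
but can differ when an instance output is negative (the output layer is
linear). The operative algorithm here is the argmax-of-output selection;
`bag_error()` reports $\tfrac12(o_{\text{win}} - Y_i)^2$ accordingly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `L` | 100 | hidden nodes; capacity of the random feature expansion |
| `C` | 8 ($2^3$) | ridge regulator; larger fits the selected instances harder |
| `activation` | sigmoid | node family; Gaussian gives RBF-style features |
| `threshold` | 0.5 | decision boundary on the bag score (boundary positive) |
| `scale` | TRUE | per-feature min-max to $[-1,1]$, fitted on training bags |
| `n_reselect` | 0 | extra selection/solve rounds (see below) |

Feature scaling is on by default because drug-activity features are
large-magnitude integers on which sigmoid nodes saturate; scaling parameters
are learned on training bags only and stored in the model, and constant
features map to 0. The weight and bias sampling ranges are configurable
(`weight_range`, `bias_range`): the defaults follow common ELM practice, and
nothing in the algorithm pins a specific distribution, only that the hidden
parameters are random and frozen.

The canonical model-selection protocol is implemented in `grid_search()`:
$C \in \{2^{-3}, \dots, 2^{7}\}$ and
$L \in \{10, 50, 100, \dots, 600\}$ (143 cells) under bag-level $k$-fold
cross-validation repeated with fresh partitions. Folds partition bags, never
instances; stratification balances positive bags across folds within one.
The report keeps per-fold metrics at both granularities (across all folds
and across repeat means), and flags the best cell — while printing a
reminder that quoting a best-of-grid CV score is optimistically biased.

## Synthetic benchmarks: what they emulate, and what they do not

`generate_classification_bags()` emulates a MUSK1-like benchmark:
92 bags of 2–10 instances, half positive. Background instances are standard
spherical Gaussians; *witness* instances are shifted by `class_separation`
(default 3) along each of the `n_relevant` (default 5 of $p$ = 20) relevant
axes, and each positive bag gets `ceiling(witness_rate * N_i)` witnesses
(default rate 0.3). The MIL assumption holds exactly, and the ground truth
records every witness. Defaults were fixed once at a desk scale where
fold-level experiments run in seconds; `p = 166, n_relevant = 80` emulates
the LJ-80.166 regression family's dimensions.

`generate_regression_bags()` draws a hidden linear-logistic target on the
relevant features (weight vector scaled to $\lVert w \rVert = 2$ so instance
responses spread over most of $(0,1)$); the noiseless bag label is the
maximum instance response, plus Gaussian noise (`noise_sd`, default 0.05)
clipped to $[0,1]$. An optional filter discards bags with noiseless labels
within $\delta$ of $1/2$, emulating benchmark variants restricted to labels
away from the midpoint.

What these generators do *not* emulate: correlated instances within a bag
(real conformations of one molecule are highly correlated), heavy-tailed or
integer-valued features, label noise at bag level, and class imbalance
beyond `positive_fraction`. Passing tests on synthetic bags therefore
demonstrates algorithmic correctness and recoverability under the stated
generative model, not performance on any particular real dataset.

## Behaviour at low witness rates — a known limitation

The win-instance is chosen with a *random* $\boldsymbol\beta_0$, so in a
positive bag with few witnesses the selected instance is often a background
instance, which then carries the label 1 into the ridge solve. Background
features thus receive mixed 0/1 targets, and the max over a negative test
bag's instances lands near the 0.5 threshold: positive bags are reliably
caught through their witnesses while negative bags approach coin flips. On
the default synthetic benchmark (witness rate 0.3, separation 3) the
single-pass learner reaches roughly 64% mean CV accuracy — the acceptance
script recomputes this number. Two regimes restore high accuracy and are
kept as property tests:

* **fully witnessed bags** (`witness_rate = 1`): selection always hits a
  witness and single-pass CV accuracy is ≈ 99%;
* **iterated selection** (`n_reselect ≥ 1`): re-selecting with the solved
  $\boldsymbol\beta$ and re-solving identifies true witnesses and pushes the
  hardest negatives toward 0, reaching ≈ 97–99% in two rounds.

Iteration is OFF by default because the canonical algorithm is a single
pass; the option is provided for users who want the EM-style refinement.
For the same structural reason, MIL regression at noise sd 0.05 levels off
at a CV squared loss of ≈ 0.03 (an order above the noise floor
$\sigma^2 = 0.0025$): the selected instance's feature vector is only loosely
coupled to the bag's max response. This matches the squared-loss range this
family of learners reports on the LJ-style regression benchmarks.

## Numerical choices

* Ridge systems are solved by Cholesky factorization of
  $(\mathbf{I}/C + \cdot)$, never by explicit inversion; if rounding pushes
  the matrix off positive definite the code falls back to a generic solve.
  Primal and dual branches agree to ~1e-13 relative on random problems.
* The $N = L$ boundary uses the primal branch (arbitrary but fixed; the
  branches agree anyway).
* Argmax ties break to the lowest instance index — deterministic and stable
  under row order.
* Labels are encoded 0/1 exactly (no ±1 recoding), and the 0.5 decision
  boundary is classified positive.
* Per-(repeat, fold) fit seeds are derived arithmetically from the plan
  seed and stay within 32-bit integer range, so CV runs are reproducible
  end to end from one integer.
* Datasets are regenerated rather than stored: all benchmarks in the tests
  and the acceptance script are built by the generators at run time at the
  92-bag desk scale (larger only where a recovery demonstration needs more
  samples, e.g. 300 single-instance bags for the noiseless regression
  check).

## Interfaces

Bag tables are read and written in the MUSK/C4.5-style CSV dialect (bag
name, optional instance name, feature columns, class column);
`bag_dialect()` accommodates shuffled exports, header/index column naming,
and `{0,1}`, `{-1,1}` or string class encodings. Models serialize to a
single self-describing JSON file. A thin command-line wrapper
(`inst/cli/elmmil.R`) exposes `simulate`, `fit`, `predict`, `cv` and
`gridsearch` over these functions; flags mirror the run-config keys and
every run logs the package version and seed.
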