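---
title: "Completing sparse disconnected PPI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing sparse disconnected PPI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and where the numerically delicate choices
live. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves recompute.

## The problem

Curated protein–protein interaction (PPI) networks are sparse and highly
fragmented: most proteins sit in small components or are isolated, and only
a minority belong to the giant component. Diffusion and random-walk link
predictors score a pair by how probability mass flows between them along
existing edges, so they are structurally unable to score pairs in different
components — the flow is exactly zero. The package addresses the setting
where the *training* network is deliberately or unavoidably a small,
disconnected fraction of the interactome, and the task is to rank all
unobserved pairs, including cross-component ones.

## The model

### Evolution neural network

`train_enn()` fits a five-layer fully connected network with layer sizes
$(m, h_1, h_2, h_3, m)$, sigmoid activation at every layer, and dropout
applied to the three hidden activations during training only. Row $i$ of
the training adjacency matrix is the label for input $i$; the loss is the
mean over rows of the summed per-unit binary cross-entropy, minimised with
Adam. No layer-wise pretraining is used — with all-zero inputs there is
nothing for an unsupervised stage to reconstruct.

Two input conventions are implemented and must be distinguished:

* **`input_mode = "zeros"` (default).** Every row receives the all-zero
  vector, encoding zero prior knowledge of interactions. Since all inputs
  coincide, first-layer weights receive zero gradient (only biases and
  deeper layers train) and the fitted network is a *constant predictor*:
  every row of the evolved matrix EA is identical, and the optimum of the
  cross-entropy for a constant predictor is the vector of label column
  means — i.e. EA's shared row estimates each protein's normalised degree.
  The test suite asserts both the row-degeneracy (max row-pair difference
  below 1e-6) and the convergence to column means (within 0.05 at
  convergence on networks with m ≤ 100).
* **`input_mode = "identity"`.** Row $i$ receives the one-hot indicator of
  protein $i$. This is the smallest row-distinguishing input and yields
  row-distinct outputs, closer to a conventional graph autoencoder. It is
  provided as a documented alternative because the constant-predictor
  degeneracy of the zeros mode is a consequence of taking the zero-input
  description literally.

Under the default zeros mode the downstream transition matrix is
$T_{ij} = \sigma(\bar a_i + \bar a_j + A_{ij})$ with $\bar a$ the column
means: a degree-driven dense background plus the observed edges. That this
degenerate form still carries real signal is exactly what the synthetic
benchmark measures (below).

**Defaults.** Hidden sizes $h_1 = h_3 = \max(16, \lceil m/2\rceil)$,
$h_2 = \max(8, \lceil m/8 \rceil)$ — a mirror-image bottleneck, the middle
layer standing for a smaller "ancient" interactome. Dropout 0.2, Adam step
size $10^{-3}$, at most 500 epochs, full batch for $m \le 1000$ (else 256),
early stop after 20 consecutive epochs improving the loss by less than
$10^{-6}$. All are `enn_config()` fields. Training is deterministic given
the seed: initialisation, dropout masks and batch order all derive from it.

### Transition matrix and diffusion kernel

`build_transition()` computes $T = \sigma(EA^\top + EA + A)$ elementwise.
Both summand groups are symmetric, so $T$ is symmetric; a final averaging
with its transpose removes floating-point asymmetry. The sigmoid argument
lies in $(0, 3)$, so all entries of $T$ fall in $(0.5, 0.953)$: $T$ is
dense *by design*, and that density is what lets diffusion cross component
boundaries. The diagonal is kept as the formula gives it (it cancels from
the Laplacian's action, since $L = D - T$ subtracts it from the row sum).

`regularized_laplacian()` computes $P = (I + \alpha L)^{-1}$, equal to the
series $\sum_k \alpha^k (-L)^k$ whenever $\alpha\,\rho(L) < 1$. The
absolute $\alpha$ is never exposed directly: the user sets
`alpha_fraction` $\in (0,1)$ and $\alpha =$ `alpha_fraction` $/\rho(L)$,
which guarantees the convergence bound for any input; the default fraction
of 0.5 sits in the middle of the admissible range, and the realised
$\alpha$ and $\rho(L)$ are reported in the result's attributes and in the
CLI metadata. $\rho(L)$ comes from Rayleigh-quotient power iteration
(relative tolerance $10^{-8}$, cap 10,000 iterations) started from a fixed
deterministic vector — not the all-ones vector, which is the Laplacian's
null vector — with a dense symmetric eigendecomposition as fallback for
$m \le 2000$. The kernel itself is computed by a dense linear solve, not an
explicit inverse, and symmetrised; for the network sizes this method
targets (up to ~10⁴ proteins) the dense regime is appropriate and no
sparse or approximate solver is provided.

`adj_rl_baseline()` is the identical computation with the raw binary
training adjacency in place of $T$; an edgeless network yields $L = 0$ and
the identity score matrix, the valid degenerate case.

### Kernel fusion (WOLP)

`optimize_weights()` minimises
$\lVert W_0\,G_{tn} + \sum_i W_i K_i - T\rVert^2$ subject to $W \ge 0$,
with the ENN transition matrix as the target. The objective is solved
directly as nonnegative least squares over the vectorised matrices
(Lawson–Hanson). Nonnegativity is imposed because the weights combine
similarity kernels and the equal-weight baseline is nonnegative; no
sum-to-one constraint is imposed because none is implied by the objective.
Topology kernels (Jaccard, shared-neighbours) are always computed from the
*training* network only — held-out edges must never leak into features.
Two conventions the formulas leave open are fixed as: the Jaccard diagonal
is 1 for nodes with at least one neighbour and 0 for isolated nodes; and
min–max normalisation maps a constant kernel to all zeros rather than
dividing by zero. Normalisation is idempotent, and `fuse_kernels()` is
linear in the weights; both are property-tested.

## Golden standard splitting

`split_golden_standard()` keeps exactly
$\lfloor \texttt{ratio\_cap}\cdot|E|\rfloor$ uniformly sampled edges as the
training network over the *full* node set, so the achieved training
fraction is always at or below the cap and the training network is
typically shattered into many components — isolated nodes count as
components of size 1. Uniform sampling at the floor count is the simplest
procedure satisfying the cap; it is a deliberate, documented choice rather
than a claim about how any particular published split was produced. The
same seed reproduces the same split byte-for-byte, and the partition
invariants are exercised over 100 random networks and ratios in the test
suite.

## The synthetic generator

`generate_synthetic_ppi()` grows a network by duplication and divergence:
from a seed triangle, each new node copies a random template, retains each
template edge with probability `retention_prob` (default 0.4) and links
back to the template with probability `attach_prob` (default 0.1). The
defaults were fixed once as values that, at $n = 300$, produce networks
with right-skewed degree distributions, a few hundred edges and many small
fragments — the regime the method is for; the degree skew (max degree
exceeding three times the mean) is property-tested across seeds.

What the generator does **not** emulate: assortativity patterns of real
interactomes, hub-avoidance, experimental ascertainment bias, false
positive edges, or node-level covariates. Passing the synthetic benchmark
therefore shows that the pipeline exploits degree structure and local
topology under extreme sparsity; it does not certify performance on any
real interactome, whose published AUC values additionally depend on an
unstated negative-set convention and unpublished hyperparameters.

## Evaluation

`roc_auc()` takes positives = held-out test edges and candidate negatives =
all unordered non-self pairs outside the golden standard; above
$m \approx 2000$ a seeded negative sample (default 10 negatives per
positive) keeps the cost bounded, and the policy used is recorded in the
result. The AUC is the rank-based Mann–Whitney statistic with half-credit
ties, and the returned curve groups tied scores so that its trapezoidal
area equals the rank AUC exactly (to 1e-9); both facts are tested against a
brute-force all-pairs oracle. `repeat_benchmark()` re-splits with seed
`base_seed + r`, runs every requested method on the same split, and reports
mean ± sample (n−1) standard deviation per method.

`reconnection_curve()` ranks all non-training pairs by score (descending,
ties broken by node-index pair order so runs are reproducible), takes the
top $\lfloor \rho N\rfloor$ as predicted positives, intersects with the
test edges, and counts connected components of the training network after
adding the recovered edges. Recovered sets grow with $\rho$, so the count
is non-increasing, with endpoints at the training network's component
count ($\rho \to 0$) and the component count of the full golden standard
($\rho = 1$).

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is meaningfully exercised:
kernel–series agreement at $m = 8$ over 20 instances, ENN degeneracy at
$m = 30$, weight recovery at $m = 20$ over 10 instances, and the benchmark
on five seeded duplication–divergence networks with $n = 300$ and split
cap 0.125. Every stochastic step — splitting, initialisation, dropout,
negative sampling, the generator — flows from explicit integer seeds, and
all randomised helpers restore the caller's RNG state.

## Known limitations

* The zeros input mode is degenerate by construction (rank-1 EA); the
  identity mode is the provided escape hatch, and which convention best
  matches any given published variant of this architecture is not
  decidable from the architecture description alone.
* Dense $O(m^2)$ memory and $O(m^3)$ solves bound the practical size to a
  few tens of thousands of nodes.
* Whether the elementwise-sigmoid transition matrix is positive
  semi-definite is not guaranteed (and not asserted); only its symmetry
  and the PSD property of its Laplacian are relied upon.
* Sequence, expression and domain kernels are consumed as precomputed
  matrices; the package does not construct them from raw data.
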