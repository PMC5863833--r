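# ennrl

Link prediction for protein–protein interaction (PPI) networks whose
training data are **extremely sparse and disconnected** — the situation that
defeats classical random-walk and diffusion-kernel predictors, which assume
a connected training graph and in practice are restricted to the largest
connected component of a curated interactome.

`ennrl` is aimed at computational biologists who want to complete a partial
PPI network (e.g. a thinned golden standard, or an organism with shallow
interaction coverage) and at methods developers who need reproducible
baselines for disconnected-network link prediction.

## The method

Given a golden standard network *G = (V, E)* with *m = |V|* proteins, a
sparse training network *G<sub>tn</sub>* (a capped random fraction of *E*
over the full node set, typically broken into thousands of components) is
represented by its binary adjacency matrix `trainingAdj`.

1. **Evolution neural network (ENN).** A five-layer fully connected network
   (sizes *m, h₁, h₂, h₃, m*, sigmoid activations, dropout between layers,
   no pretraining) is trained with row *i* of an all-zero matrix as input
   and row *i* of `trainingAdj` as label, under summed per-unit binary
   cross-entropy. The all-zero input encodes zero prior knowledge of
   interactions; the bottleneck layer plays the role of a smaller,
   "ancient" interactome. The row-wise outputs after training form the
   evolved matrix **EA**.
2. **Transition matrix.** `T = sigmoid(EAᵀ + EA + trainingAdj)` — symmetric
   by construction and *dense*, which is what lets subsequent diffusion
   traverse between disconnected components.
3. **Regularized Laplacian kernel.** With `L = D − T` (weighted graph
   Laplacian) and `0 < α < ρ(L)⁻¹`,

   `P = Σₖ αᵏ(−L)ᵏ = (I + αL)⁻¹`

   computed by a dense linear solve; `P[i, j]` scores the interaction
   between proteins *i* and *j*. The package parameterises
   `α = alpha_fraction / ρ(L)` (default fraction 0.5), with `ρ(L)` from
   power iteration.

The baseline **ADJ-RL** applies the same kernel directly to the binary
training adjacency. The package also implements **WOLP** fusion: given
heterogeneous feature kernels *K₁…Kₙ* (neighbourhood Jaccard, degree sums,
or precomputed sequence/expression/domain kernels loaded from file), it
fits nonnegative weights minimising
`‖W₀·G_tn + Σᵢ Wᵢ·Kᵢ − T‖²` against the learned transition matrix
(nonnegative least squares), plus an equal-weight baseline.

Evaluation mirrors the standard protocol: ROC/AUC against held-out edges
(rank-based, half-credit ties, all non-edges or a seeded negative sample),
repeated split-and-evaluate summaries (mean ± sample SD), and
component-reconnection curves counting how many disconnected training
components the top-ranked predictions reconnect.

## Worked example

```r
library(ennrl)

# a duplication-divergence network standing in for a golden standard
net <- generate_synthetic_ppi(300, retention_prob = 0.4,
                              attach_prob = 0.1, seed = 7)
net
#> PPI network: 300 nodes, 317 edges

sp <- split_golden_standard(net, ratio_cap = 0.125, seed = 7)
sp
#> edge split: 39 training / 278 test edges (cap 0.125, seed 7)
component_summary(sp$training)
#> 262 components (1, 1.15, 7)

P <- run_ennrl(sp$training, enn_config(seed = 7), alpha_fraction = 0.5)
P
#> score matrix: 300 x 300, alpha 0.003288 (fraction 0.50), rho(L) 152.1

roc_auc(P, sp)
#> AUC 0.7989 (278 positives, 44533 negatives, policy all)
roc_auc(adj_rl_baseline(to_adjacency(sp$training), 0.5), sp)
#> AUC 0.5104 (278 positives, 44533 negatives, policy all)

reconnection_curve(P, sp, c(0.001, 0.01, 0.05, 0.2, 1))
#> component reconnection (baseline 262 components):
#>    rho components recovered_edges
#>  0.001        259               5
#>  0.010        250              24
#>  0.050        230              83
#>  0.200        184             184
#>  1.000        150             278
```

Reading: from only 39 training edges scattered over 262 components, the
evolution-network kernel ranks the 278 held-out interactions far above
chance (AUC 0.80), while the same diffusion kernel on the raw adjacency is
blind across components (AUC 0.51). The reconnection curve shows the top
predictions progressively stitching the fragmented training network back
together (262 → 150 components, the component count of the full network).

A command-line workflow covering the same stages
(`simulate / split / predict / fuse / evaluate`) is available via
`run_cli()` or the launcher script `inst/cli/ennrl.R`; see
`?read_run_config` for the YAML configuration schema.

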