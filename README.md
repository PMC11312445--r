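# embryomodes

Statistical-physics analysis of embryonic transcriptomes for
invariant-lineage embryos (the motivating system is the early ascidian
embryo). Embryos of such species have a fixed cell number, conserved cell
types and a conserved cell-cell contact map, so single-cell RNA sequencing
of many barcoded embryos measures repeated draws of one high-dimensional
object — the joint expression state of all cells of an embryo. This
package is for researchers who want to go beyond cell typing and ask
whether, and how, expression fluctuations are *coupled across cells* of
the same embryo.

The pipeline:

1. **Robust cell typing** — hierarchical clustering constrained by the
   known embryo structure (a cell type has equal cell counts in every
   complete embryo), on informative genes only, with splits accepted only
   when they reproduce under posterior resampling and beat an
   embryo-shuffled null.
2. **Variance decomposition** — removal of gene means, mother/embryo/type
   means and a fitted developmental-staging direction
   `tau_e * alpha_{t,g}`; residual dimensionality set against a
   column-permutation null; projection onto the retained PCs.
3. **Collective-variation test** — intra- and inter-type covariances
   `C^t_ij = <x_ci x_cj>` and `gamma^tt'_ij = <x_ci x_c'j>` with a
   shuffle test on the standardized deviation
   `Delta = sum(((gamma - gamma_bar)/sigma)^2)`.
4. **Maximum-entropy model** — the least-structured distribution
   consistent with the constrained covariances is a Gaussian
   `p(x) = N(0, J^{-1})` whose interaction matrix

   ```
   J_(pi)(qj) = sum_t M^t_ij I^t_pq + sum_k S^k_ij Psi^k_pq
                + 1/2 sum_k' (U^k'_ij Omega^k'_pq + U^k'_ji Omega^k'_qp)
   ```

   carries within-cell couplings M, symmetric cell-cell couplings S and
   directed couplings U on adjacency matrices; couplings are fit by
   moment matching (PD-safeguarded Newton on the convex dual) and scored
   by `eta = 1 - sum((C - C_pred)^2)/sum(C^2)`.
5. **Sparse network inference** — L1-regularized fits across posterior ×
   bootstrap covariance draws and a lambda-path grid, stability ranking,
   Schulze aggregation, and forward selection to a target eta.
6. **Collective modes** — eigen-decomposition `Sigma = sum_b lambda_b
   phi^b (phi^b)^T` of the model covariance; the leading eigenvectors are
   coordinated embryo-wide patterns of expression variation, judged
   against a Haar-rotation k/D baseline.

A synthetic-embryo generator with complete ground truth (conserved types,
mirror symmetry, mother/embryo/time effects, coupled Gaussian fluctuations
from a known sparse J, measurement noise) stands in for raw data and backs
every test.

## Worked example

Fourteen synthetic 16-cell embryos from a neighbor-coupled ground truth,
tested for collective variation, refit, and decomposed into modes:

```r
library(embryomodes)
graph <- make_topology("mirror16")
graph
#> embryo_graph: 16 cells, 5 types, 18 contact edges

truth <- coupled_model(graph, n_pc = 2)          # neighbor-coupled ground truth
ds <- sample_embryos(truth, n_embryos = 14, seed = 1)

st <- shuffle_test(ds$x, ds$type_of, ds$embryo_of, mode = "across",
                   n_shuffles = 100, seed = 2)
round(c(delta = st$delta_observed, p = st$p_value), 4)
#>    delta        p
#> 111.9698   0.0099
```

The observed covariances deviate from the shuffle ensemble far more than
any of the 100 shuffles (p = 1/101): expression fluctuations are coupled
within embryos. Fitting the neighbor-interaction hypothesis to the
empirical covariances:

```r
cs <- covariance_set(intra_type_cov(ds$x, ds$type_of, ds$embryo_of),
                     inter_type_cov(ds$x, ds$type_of, ds$embryo_of))
fit <- fit_maxent(cs, spec_neighbor(graph), graph, n_pc = 2)
round(fit$report$eta, 3)
#> [1] 0.912
round(fit$model$S$neighbor, 3)
#>        [,1]   [,2]
#> [1,] -0.109  0.059
#> [2,]  0.059 -0.118
```

The fitted neighbor coupling is negative (in J, a negative coupling means
positive correlation between neighbors) and the model explains 91% of the
covariance variance. Its collective modes concentrate variance well above
the rotation baseline:

```r
md <- mode_decomposition(fit$model)
rb <- rotation_baseline(fit$model, md, k = 3, n_rotations = 100, seed = 3)
round(c(top3 = sum(md$variance_fractions[1:3]), baseline = rb$mean), 3)
#>     top3 baseline
#>    0.186    0.094
```

The three leading modes carry 18.6% of the model variance, twice the
k/D = 9.4% that three fixed directions capture in a randomly rotated
model.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch against the installed package —
synthetic world, gene-set filters, cell typing, variance decomposition,
the shuffle test, the three interaction hypotheses, sparse term ranking
with forward selection, and the mode decomposition with its rotation
baseline — printing each stage's summary and writing the JSON report to
`--out`. All randomness derives from `--seed` through named substreams.
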