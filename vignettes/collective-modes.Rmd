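---
title: "Methods: maximum-entropy models of embryonic transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy models of embryonic transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Early embryos of invariant-lineage species (the package's motivating system
is the ascidian) develop through a stereotyped series of divisions: every
individual has the same number of cells, the same cell types, and the same
cell-cell contact map. Single-cell RNA sequencing of many such embryos,
barcoded per embryo, therefore measures repeated draws of one well-defined
high-dimensional object — the joint expression state of all cells of an
embryo. This package treats that object statistically: it identifies the
cell types robustly, strips every known source of variation (gene means,
mother-, embryo- and cell-type-specific means, developmental staging),
tests whether the remaining fluctuations are coupled *between* cells of the
same embryo, fits a maximum-entropy Gaussian model of cell-cell
interactions to the coupled fluctuations, infers a sparse interaction
network, and decomposes the model covariance into collective modes —
coordinated, embryo-wide patterns of expression variation.

Because dissociation destroys position, a sequenced cell carries its embryo
barcode and (after typing) its cell type, but not its exact identity: cells
are known up to permutations within their type. Every downstream method is
built around that partial-identity structure.

# Data model

Three containers move through the pipeline:

* `count_matrix` — cells x genes transcript counts with per-cell metadata
  (embryo, stage, optional mother and type).
* `expression_posterior` — per cell and gene, the posterior mean `X` of log
  expression and its posterior SD `eps`. This is the universal currency:
  every stochastic stage perturbs the data by resampling
  `Normal(X, eps^2)` entrywise, so measurement uncertainty propagates into
  cell typing, covariance estimation and network inference.
* `embryo_graph` — the stereotyped stage structure: cell names, types, the
  symmetric contact adjacency, the sister map and the left-right mirror
  pairing. Matrix orientation is cells x genes everywhere; the flattened
  model state is cell-major, index `(p - 1) n_pc + i` for cell p and
  component i.

A single root seed drives named, hashed substreams
(`substream_seed(root, name)`), so each stage is independently
reproducible. Consecutive raw integers are deliberately avoided as
dataset seeds: consecutively seeded generators can produce weakly
correlated first draws, which inflates the variance of Monte-Carlo
summaries across datasets.

# Normalization stand-in

Expression is the log fraction of a cell's transcripts per gene,
`X_cg = log((a_cg + ps) / sum_g'(a_cg' + ps))` with pseudocount `ps = 1`.
The per-entry uncertainty is a delta-method binomial approximation
`eps_cg = sqrt(1 / (a_cg + ps))`, capped at 3 log units so zero-count
entries do not acquire unbounded variance under resampling. The output is
flagged `emulation_mode`: it is a documented stand-in for a full Bayesian
normalizer, used for synthetic and toy data; native posterior output of an
external normalizer is read directly with `read_posterior()`. Posterior
draws are unbounded Gaussians — no truncation or transformation is applied
before covariance estimation (an open design point resolved in favor of
the simplest faithful choice).

# Gene classes

A gene is *purely zygotic* at stage k when it has fewer than 10 reads in
every cell of the 4-cell baseline, more than 100 reads in some cell at
stage k (both strict inequalities, read literally), and is differentially
expressed across cell types there (two-sided Wilcoxon rank-sum per type
pair, Benjamini-Hochberg adjusted jointly over genes and pairs,
significance at adjusted p < 0.01; BH is the package's choice where only
"adjusted" is specified). A gene is *purely maternal* when it exceeds 500
baseline reads in some cell and is never differentially expressed later.
Known localized maternal factors (e.g. germ-lineage transcripts at the
posterior pole) are removed via an explicit user-supplied exclusion list,
since they are identified biologically rather than by a computation.

# Cell typing

Three principles, combined recursively:

1. **Informative genes.** Trial clusters (k-means, k in 2..4 on all genes)
   are scanned for genes that discriminate them; the score is the largest
   standardized rank-sum statistic |z| over cluster pairs, and the top 20
   genes are kept.
2. **Structural priors.** A cell type has the same number of cells in every
   complete embryo. Clustering is therefore balanced: at each iteration the
   cells of each complete embryo are assigned to cluster slots (`m/k` per
   cluster) by an exact min-cost assignment (Jonker-Volgenant, squared
   distance to centroids); k values that do not divide the per-embryo cell
   count are not candidates. Incomplete embryos are clustered by nearest
   centroid without the constraint.
3. **Robustness.** A split is accepted only if re-clustering perturbed data
   (one posterior resample plus an 80% embryo subsample per replicate,
   50 replicates by default) reproduces it: the consistency score is the
   mean adjusted Rand index against the reference split. Null scores are
   computed identically on data whose cells are randomly reassigned to
   embryos (20 null datasets by default); acceptance requires the score to
   exceed the null 95th percentile *and* an absolute floor
   `min_score = 0.6`.

The floor exists because the quantile rule alone has a designed 5% false
accept rate per tested (node, k), and a typing run tests several. Its
value was calibrated on synthetic data: reference splits that lock onto
the dominant frozen-noise direction of a structureless node reproduce in
up to ~55% of perturbed re-clusterings (informative-gene selection
amplifies the frozen pattern), while true splits at the package's
reference effect size (markers at 4x the noise SD) reproduce at ~100%.
The floor sits just above the measured noise ceiling.

Candidate k values are tried in ascending order and the *smallest*
accepted split wins — a small number of well-separated clusters is sought
before finer sub-clusters, which also prevents a half-real fine split from
outcompeting the true coarse one. Recursion stops when no candidate is
accepted; leaves become cell types, and marker tables map leaves to
canonical identities by mean expression rank (two leaves claiming one
identity is an error; unresolved leaves stay "unassigned"). The procedure
is deliberately resampling-heavy and is not tuned for atlas-scale data.

# Variance decomposition

For maternal-style genes the chain is: center genes, subtract
mother-specific means, subtract embryo-specific means. For zygotic-style
genes: center genes, subtract cell-type means, then remove developmental
staging by the bilinear model `tau_e(c) * alpha_t(c),g` — an embryo's time
offset along a cell-type-specific tangent to the mean trajectory — fit by
alternating least squares. The gauge (the model is invariant under
rescaling and under shifting tau by a constant, the shift being a
type-mean component that the chain has already removed) is fixed *after*
convergence: `sum(tau) = 0`, `||alpha||_F = 1`, sign such that the
largest-magnitude alpha entry is positive. Gauge projection inside the
iteration loop is avoided deliberately: it can increase the objective and
trip the convergence test (relative residual decrease < 1e-10) at a wrong
point. Non-convergence within 500 iterations is an error.

Residual dimensionality is set against a permutation null that shuffles
each gene column independently, preserving marginals while destroying
correlation. The threshold is the *maximum* of the null's largest singular
values over 100 permutations: an i.i.d. matrix has the same distribution
as its own column-permuted null, so a mean-based threshold would be
exceeded by pure noise in half of all datasets; the max corresponds to the
largest singular value of the null model and keeps the false-keep rate at
~1/(n_perm + 1). Retained right singular vectors become the PCs; the
projection is computed on the pooled residual matrix of a stage.

# Covariance statistics and the shuffle test

With `x` the residual projection (cells x PCs), the empirical statistics
are the within-cell covariance per type and the cell-pair covariance per
type pair, with the expectation taken as the average over embryos of
within-embryo averages. Same-type pairs exclude the cell paired with
itself, and all pair sums are normalized by the number of *included* pairs
(`n_t (n_t - 1)` for same-type) — the same convention on the empirical and
the model side, which moment matching requires. Uncertainty comes from
replicates pairing one posterior draw with one bootstrap resample of whole
embryos (resampled embryos relabeled so copies stay distinct).

Collective variation is tested by shuffling: across-mode permutes cells of
the same type between embryos; within-mode permutes cell labels within
each embryo. Over the 100 shuffled covariance vectors plus the observed
one, the componentwise mean and SD define the deviation
`Delta = sum(((gamma - gamma_bar) / sigma)^2)`; the permutation p-value is
`(1 + #[Delta_null >= Delta_obs]) / (n_shuffles + 1)`. All measured
cell-pair components enter Delta, including same-type pairs (a flag
restricts to distinct-type pairs); on the stylized graphs much of the
coupling signal lives in same-type neighbor pairs. A 2000-replicate
rank-uniformity check confirms the test is exactly calibrated on
exchangeable data.

# The maximum-entropy model

The model of one embryo's residual state is `p(x) = Normal(0, J^-1)` over
the flattened (cell, PC) space, with

```
J_(pi)(qj) = sum_t M^t_ij I^t_pq + sum_k S^k_ij Psi^k_pq
             + 1/2 sum_k' (U^k'_ij Omega^k'_pq + U^k'_ji Omega^k'_qp)
```

— within-cell couplings `M^t` per type, symmetric couplings `S^k` on
symmetric adjacencies, directed couplings `U^k'` on directed adjacencies.
This is the least-structured distribution whose constrained covariances
(within-cell per type; adjacency-averaged between cells) take prescribed
values; the couplings are the Lagrange multipliers of those constraints.

Fitting minimizes the convex dual `f(theta) = -log det J + tr(J C_hat)`
(Gaussian maximum likelihood restricted to the linear family; the
stationarity conditions are exactly the moment-matching constraints) by a
damped Newton method with backtracking line search that keeps J positive
definite. Convergence is declared at a relative statistic residual of
1e-6 by default. Infeasible targets — an intra covariance with a
non-positive eigenvalue, or constraints no positive-definite member of the
family can match — raise errors with diagnostics.

Because only cell types are observed, the covariance of a *specific* cell
pair is estimated by its type-level value: the target matrix `C_hat`
carries each type's intra covariance on the diagonal blocks and the
type-pair covariance on all off-diagonal blocks. Left-right averaging of
the constraints is implicit, since mirror-paired cells share a type. This
estimate has a hard information limit: within a type, contact pairs and
non-contact pairs receive the same target, so adjacency structure inside
multi-cell types is invisible — with 2-cell left-right types, within-side
pair targets are diluted exactly 2x (the data cannot distinguish the
left-left from the left-right pairing). Exact targets (e.g.
`constraint_statistics()` of a known model) can be passed directly, and
then moment matching recovers parameters to machine precision — the
self-consistency property of the optimizer, as opposed to the
identifiability ceiling of the data situation.

Predicted type-level covariances aggregate `Sigma = J^-1` with the same
pair conventions as the empirical side. Fit quality is
`eta = 1 - sum((C - C_pred)^2) / sum(C^2)`, over all components by
default; `include_intra = FALSE` scores only the cell-cell covariances,
which is the discriminating comparison between interaction hypotheses
(every model matches the within-cell constraints by construction).
Collective modes are the eigenvectors of `Sigma` (sign: largest-magnitude
entry positive), with variance fractions `lambda_b / sum(lambda)`; the
Haar-rotation baseline shows that k fixed modes capture k/D of a rotated
model's variance on average (exactly k/D for an isotropic model), the
yardstick against which mode concentration is judged.

# Sparse inference

Candidates are the three global hypotheses (embryo-wide, neighbor, sister)
plus one directed term per mirror-symmetrized contact-pair bundle. One
bundle is enumerated per unordered pair orbit: a directed bundle with
general coupling U contributes `(U x Omega + U' x Omega')/2` to J, which
is exactly what the reversed bundle with the transposed coupling
contributes — enumerating both orderings would duplicate the same
J-subspace and leave the L1 objective flat between twins. Directionality
lives in U's asymmetry within a bundle.

The L1 fit minimizes the dual plus `lambda (sum|S| + sum|U|)` (M
unpenalized) by monotone FISTA with backtracking, positive-definite
safeguarding, and a bounded-effort stop (parameter-step tolerance or
objective stagnation); `lambda = 0` delegates to the exact Newton match.
The default grid is anchored at the data's `lambda_max` — the smallest
penalty that zeroes every interaction, from the KKT condition at the
interactions-free fit — descending three decades, so the grid spans the
selection path; fits run down the grid with continuation warm starts,
tracking the minimal-L1 branch through the degenerate small-lambda region.
Per lambda, terms are scored across the covariance draws by
(fraction of draws with coupling norm above 1e-4) x (median norm), and the
per-lambda score ballots are aggregated with the Schulze beatpath method.
Ballots carry scores so that ties (all-zero terms at large lambda) express
no preference — converting ties to an alphabetical order would manufacture
spurious pairwise wins. Forward selection then refits *unregularized*
models with the top m terms until `eta > 0.9` (L1 selects, moment matching
estimates).

# The synthetic world

`make_topology()` builds stylized mirror-symmetric graphs (4, 16 and 32
cells); they are stand-ins, not measured contact maps, and real graphs can
be supplied as JSON. The 16-cell fixture has 5 types with per-embryo sizes
(4, 2, 2, 4, 4), a per-side contact ring and two cross-midline contacts;
`mirror_pair_types()` refines any mirror graph to 2-cell left-right types,
the resolution at which interaction inference is informative (see the
identifiability ceiling above).

Stated defaults, chosen once: neighbor coupling `S = -0.3 I` (moderate
positive neighbor correlation ~0.35, the realism anchor for "clearly
present but not dominant" coupling); planted specific terms of magnitude
0.3 on the off-diagonal PC pair (a directed coupling); measurement noise
`eps = 0.2` (deep-sequencing quality relative to unit biological signal);
14 embryos for paper-scale cohorts and 8 for typing-scale ones (the
magnitudes of real cohorts at the corresponding stages); typing markers at
effect 1.0 against noise SD 0.25 (the 4x reference effect), with the two
2-cell types sharing a marker block so the hierarchy has a coarse split
before a fine one. Counts are log-normal-Poisson around type profiles.

The generator does **not** emulate: real contact geometries, transcript-
level counts behind the PC-space worlds, lineage dynamics across stages,
non-Gaussian expression noise, or incomplete embryos. A green test
therefore establishes that the algorithms do what they claim on data with
exactly the assumed structure — not that real data satisfy the structure.

# Known limitations, and two red checks

Two spec-level checks fail for structural reasons and are kept failing
rather than weakened:

* **Full sparse-recovery conjunction.** On 14-embryo cohorts from the
  default planted model, the neighbor term ranks first in 9/10 seeds and
  ~86% of planted terms land within the top 2n of the aggregated ranking
  (the qualitative claim), but *all* planted terms land there in only
  ~20-30% of seeds, against a stated 80% bar. Noiseless-limit fits show
  why: the left-right identity ambiguity dilutes within-side pair targets
  2x, placing planted specifics at ranks 4-5 before any sampling noise,
  and 14-embryo noise then spreads them to 5-13 while the embryo-wide and
  sister terms legitimately absorb part of the dense indirect covariance.
* **Top-3 mode recovery.** The planted model's 3rd and 4th covariance
  eigenvalues are near-degenerate (2.57 vs 2.39), so the type-level refit
  rotates mode 3 into mode 4 and the top-3 principal angle is 90 degrees
  even with exact type-level statistics; the top-2 subspace recovers to
  ~9 degrees.

Other limitations: each stage is modeled separately (no temporal
dynamics); the Gaussian family cannot express higher-order coupling; the
typing algorithm's resampling cost grows quickly with cells x genes.

Test-scale note: the stochastic test blocks run reduced replicate counts
(e.g. 30 covariance draws instead of 100, 20 consistency resamples instead
of 50); pilot runs at full scale produced the same decisions, and the
reductions are bookkept here rather than silently.
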