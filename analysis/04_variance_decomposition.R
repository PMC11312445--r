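#!/usr/bin/env Rscript
# Removing known variance sources from a zygotic-style expression matrix:
# gene means, cell-type means, then the developmental-staging direction
# (per-embryo time along a type-specific tangent), and selecting the
# residual dimensionality against a column-permutation null.

library(embryomodes)
seed <- 20260917L
out <- "results"
dir.create(out, showWarnings = FALSE)

graph <- make_topology("mirror16")
types <- sort(unique(graph$type_of))
set.seed(substream_seed(seed, "decomp"))
n_emb <- 14
alpha <- matrix(rnorm(length(types) * 25), length(types), 25,
                dimnames = list(types, NULL))
tau <- stats::setNames(rnorm(n_emb), paste0("e", 1:n_emb))
tau <- tau - mean(tau)
emb <- rep(names(tau), each = 16)
ty <- rep(unname(graph$type_of), n_emb)
mu <- matrix(rnorm(length(types) * 25, sd = 2), length(types), 25)

X <- mu[match(ty, types), ] + tau[emb] * alpha[ty, ] +
  matrix(rnorm(n_emb * 16 * 25, sd = 0.1), n_emb * 16, 25)

Y <- center_genes(X)$Y
Z <- subtract_group_means(Y, ty)$Z
tp <- fit_temporal_projection(Z, emb, ty)
cat(sprintf("staging times recovered with |r| = %.4f (ALS, %d iterations)\n",
            abs(cor(tp$tau[names(tau)], tau)), tp$iterations))

sel <- svd_rank_selection(tp$Z_residual, n_perm = 100,
                          seed = substream_seed(seed, "rank"))
cat(sprintf("top singular value %.2f vs null threshold %.2f: keep %d\n",
            sel$d[1], sel$threshold, sel$n_keep))
cat("(the planted signal here is fully explained by means, types and\n")
cat(" staging; the residual sits at the noise floor, so the kept count\n")
cat(" hovers around zero -- fitted-mean subtraction leaves faint structure\n")
cat(" that can put the top singular value marginally above the null)\n")

utils::write.table(data.frame(embryo = names(tp$tau), tau_hat = tp$tau,
                              tau_true = tau[names(tp$tau)]),
                   file.path(out, "staging_times.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote staging_times.tsv\n")
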