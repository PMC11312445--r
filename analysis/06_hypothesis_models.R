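#!/usr/bin/env Rscript
# Comparing single-hypothesis interaction models: all-to-all (embryo-wide),
# sister-only, and spatial-neighbor coupling, each fit by moment matching
# to the empirical type-level covariances of coupled synthetic embryos and
# scored by the fit quality eta (variance of the empirical covariances
# explained by the model-predicted ones).

library(embryomodes)
seed <- 20260917L
out <- "results"
dir.create(out, showWarnings = FALSE)

graph <- make_topology("mirror16")
tab <- do.call(rbind, lapply(c(14, 200), function(ne) {
  ds <- sample_embryos(coupled_model(graph, 2), ne,
                       seed = substream_seed(seed, paste0("hyp", ne)))
  cs <- covariance_set(intra_type_cov(ds$x, ds$type_of, ds$embryo_of),
                       inter_type_cov(ds$x, ds$type_of, ds$embryo_of))
  do.call(rbind, lapply(c("embryo_wide", "neighbor", "sister"),
    function(hyp) {
      spec <- switch(hyp, embryo_wide = spec_embryo_wide(graph),
                     neighbor = spec_neighbor(graph),
                     sister = spec_sister(graph))
      fit <- fit_maxent(cs, spec, graph, 2)
      data.frame(n_embryos = ne, hypothesis = hyp,
                 eta_all = fit$report$eta,
                 eta_inter = fit_quality(cs, fit$report$predicted,
                                         include_intra = FALSE))
    }))
}))
print(tab, row.names = FALSE)
cat("(eta_all includes the within-cell covariances, which every model\n")
cat(" matches by construction; eta_inter scores only the cell-cell\n")
cat(" covariances. At 14 embryos the empirical covariances are noisy and\n")
cat(" all inter scores are low; at 200 embryos the sister model falls\n")
cat(" clearly behind -- it cannot produce covariance between non-sister\n")
cat(" cells -- while embryo-wide and neighbor both explain the data)\n")
utils::write.table(tab, file.path(out, "hypothesis_eta.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote hypothesis_eta.tsv\n")
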