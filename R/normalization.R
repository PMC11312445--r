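#' Log-fraction expression with uncertainty from counts
#'
#' Simplified, self-contained stand-in for an external Bayesian normalizer.
#' Expression is the log fraction of a cell's transcripts given to each gene,
#' `X_cg = log((a_cg + ps) / sum_g'(a_cg' + ps))`, which tracks fold change
#' and stabilizes variance. The per-entry uncertainty is a delta-method
#' binomial approximation `eps_cg = sqrt(1 / (a_cg + ps))`, capped at
#' `eps_cap` so zero-count entries do not get unbounded variance. Output is
#' flagged `emulation_mode`: it is an approximation for synthetic and toy
#' data, not a claim of equivalence to a full Bayesian normalizer, whose
#' native output can be read directly with [read_posterior()].
#'
#' @param cm a [count_matrix()].
#' @param pseudocount positive pseudocount (default 1).
#' @param eps_cap maximum posterior SD in log units (default 3).
#' @return an [expression_posterior()] with attribute `emulation_mode = TRUE`.
#' @export
normalize_log_fraction <- function(cm, pseudocount = 1, eps_cap = 3) {
  abort_if(pseudocount <= 0, "pseudocount must be positive")
  a <- cm$counts
  tot <- rowSums(a)
  if (any(tot == 0))
    stop(sprintf("cell(s) with zero total count: %s",
                 paste(rownames(a)[tot == 0], collapse = ", ")), call. = FALSE)
  ap <- a + pseudocount
  X <- log(ap / rowSums(ap))
  eps <- pmin(sqrt(1 / ap), eps_cap)
  post <- expression_posterior(X, eps, cm$cells, cm$gene_ids)
  attr(post, "emulation_mode") <- TRUE
  post
}

#' Draw one sample from an expression posterior
#'
#' Each entry is drawn independently as `Normal(X_cg, eps_cg^2)`,
#' approximating the per-cell, per-gene Gaussian posterior. Deterministic
#' given `seed`.
#'
#' @param post an [expression_posterior()].
#' @param seed integer seed (optional; uses current RNG state if NULL).
#' @return numeric matrix, same shape and dimnames as `post$X`.
#' @export
sample_posterior <- function(post, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- post$X + post$eps * matrix(stats::rnorm(length(post$X)),
                                     nrow(post$X), ncol(post$X))
  dimnames(draw) <- dimnames(post$X)
  draw
}
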