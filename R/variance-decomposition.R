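#' Center each gene over all cells
#'
#' Subtracts the pooled mean expression of each gene, `X -> Y`.
#'
#' @param X cells x genes matrix.
#' @return list with `Y` (centered matrix) and `gene_means`.
#' @export
center_genes <- function(X) {
  abort_if(nrow(X) < 2, "need at least 2 cells")
  mu <- colMeans(X)
  list(Y = sweep(X, 2, mu), gene_means = mu)
}

#' Subtract per-group per-gene means
#'
#' Removes a known source of variation (mother-, embryo- or cell-type-specific
#' mean expression): within each group of cells the per-gene mean is
#' subtracted, leaving exactly zero group means in the residual.
#'
#' @param Y cells x genes matrix.
#' @param grouping vector of group labels, one per row of `Y`.
#' @return list with `Z` (residual), `group_means` (group x gene matrix).
#' @export
subtract_group_means <- function(Y, grouping) {
  grouping <- as.character(grouping)
  abort_if(length(grouping) != nrow(Y), "one group label per cell required")
  abort_if(anyNA(grouping), "every cell must be grouped")
  sizes <- table(grouping)
  if (any(sizes == 1))
    warning(sprintf("singleton group(s) %s: residual is exactly zero there",
                    paste(names(sizes)[sizes == 1], collapse = ", ")))
  groups <- sort(unique(grouping))
  means <- matrix(0, length(groups), ncol(Y),
                  dimnames = list(groups, colnames(Y)))
  Z <- Y
  for (g in groups) {
    idx <- grouping == g
    means[g, ] <- colMeans(Y[idx, , drop = FALSE])
    Z[idx, ] <- sweep(Y[idx, , drop = FALSE], 2, means[g, ])
  }
  list(Z = Z, group_means = means)
}

#' Fit and remove the developmental-staging direction
#'
#' Embryos differ slightly in developmental time. The temporal component is
#' modeled as a rank-1-per-type bilinear term `tau_e(c) * alpha_t(c),g`
#' (embryo-specific time times a cell-type-specific tangent to the mean
#' trajectory) and fit by alternating least squares, minimizing the residual
#' variance of `Z - tau alpha`. Gauge fixing: `sum_e tau_e = 0`,
#' `||alpha||_F = 1`, sign chosen so the largest-magnitude entry of `alpha`
#' is positive.
#'
#' @param Z residual cells x genes matrix (type means already removed).
#' @param embryo_of,type_of vectors of embryo and type labels per cell.
#' @param max_iter,tol ALS iteration cap (default 500) and relative tolerance
#'   on the residual-variance decrease (default 1e-10).
#' @return list with `tau` (named per embryo), `alpha` (type x gene),
#'   `Z_residual`, `iterations`, `converged`.
#' @export
fit_temporal_projection <- function(Z, embryo_of, type_of, max_iter = 500,
                                    tol = 1e-10) {
  embryo_of <- as.character(embryo_of); type_of <- as.character(type_of)
  embryos <- sort(unique(embryo_of))
  types <- sort(unique(type_of))
  abort_if(length(embryos) < 2, "need at least 2 embryos")
  e_idx <- match(embryo_of, embryos)
  t_idx <- match(type_of, types)

  if (all(Z == 0)) {
    alpha <- matrix(0, length(types), ncol(Z),
                    dimnames = list(types, colnames(Z)))
    tau <- stats::setNames(rep(0, length(embryos)), embryos)
    return(list(tau = tau, alpha = alpha, Z_residual = Z, iterations = 0L,
                converged = TRUE))
  }

  # init tau from the leading left singular vector of the embryo-mean matrix
  Emean <- rowsum(Z, embryo_of) / as.vector(table(embryo_of)[embryos])
  sv <- svd(Emean, nu = 1, nv = 0)
  tau <- sv$u[, 1] * sv$d[1]
  tau <- tau - mean(tau)
  if (all(tau == 0)) tau <- seq_along(embryos) - mean(seq_along(embryos))

  rss <- function(alpha, tau) sum((Z - tau[e_idx] * alpha[t_idx, ])^2)
  prev <- Inf
  alpha <- matrix(0, length(types), ncol(Z),
                  dimnames = list(types, colnames(Z)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # alpha step: per type, regress Z rows on tau
    tc <- tau[e_idx]
    denom_t <- rowsum(tc^2, type_of)[types, 1]
    num <- rowsum(Z * tc, type_of)[types, , drop = FALSE]
    alpha <- num / ifelse(denom_t == 0, 1, denom_t)
    # tau step: per embryo, regress rows on alpha rows of each cell's type
    A <- alpha[t_idx, , drop = FALSE]
    num_e <- rowsum(rowSums(Z * A), embryo_of)[embryos, 1]
    den_e <- rowsum(rowSums(A * A), embryo_of)[embryos, 1]
    tau <- num_e / ifelse(den_e == 0, 1, den_e)
    cur <- rss(alpha, tau)
    if (is.finite(prev) && (prev - cur) < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged)
    stop(sprintf(paste0("temporal projection did not converge in %d ",
                        "iterations (last residual %.6g)"), max_iter, prev),
         call. = FALSE)
  Z_residual <- Z - tau[e_idx] * alpha[t_idx, , drop = FALSE]
  # gauge (applied after the fit; the residual is unaffected): sum tau = 0
  # (the mean-shift tau_bar * alpha is a type-mean component, which the
  # chain has already removed), unit Frobenius alpha, sign by the
  # largest-magnitude alpha entry
  tau <- tau - mean(tau)
  nrm <- sqrt(sum(alpha^2))
  if (nrm > 0) {
    alpha <- alpha / nrm
    tau <- tau * nrm
    s <- sign(alpha[which.max(abs(alpha))])
    alpha <- alpha * s
    tau <- tau * s
  }
  names(tau) <- embryos
  list(tau = tau, alpha = alpha, Z_residual = Z_residual,
       iterations = it, converged = TRUE)
}

#' Select the signal dimensionality against a permutation null
#'
#' Null matrices permute each gene column independently across cells,
#' preserving every gene's marginal distribution while destroying the
#' correlation structure. The number of retained components is the number of
#' singular values of `Z` exceeding the aggregated largest null singular
#' value (`aggregate = "max"` over the permutation draws by default; the
#' threshold line of the null statistical model).
#'
#' @param Z residual cells x genes matrix.
#' @param n_perm number of permutation draws (default 100).
#' @param seed RNG seed.
#' @param aggregate `"max"` (default) or `"mean"` over null largest singular
#'   values.
#' @return list with `d` (singular values), `null_max` (per-draw largest null
#'   singular value), `threshold`, `n_keep`.
#' @export
svd_rank_selection <- function(Z, n_perm = 100, seed = NULL,
                               aggregate = c("max", "mean")) {
  abort_if(length(Z) == 0, "Z is empty")
  aggregate <- match.arg(aggregate)
  if (n_perm < 10) warning("n_perm < 10: unstable null")
  if (!is.null(seed)) set.seed(seed)
  d <- svd(Z, nu = 0, nv = 0)$d
  n <- nrow(Z)
  null_max <- vapply(seq_len(n_perm), function(b) {
    Zp <- apply(Z, 2, function(col) col[sample.int(n)])
    svd(Zp, nu = 0, nv = 0)$d[1]
  }, numeric(1))
  thr <- if (aggregate == "max") max(null_max) else mean(null_max)
  list(d = d, null_max = null_max, threshold = thr,
       n_keep = sum(d > thr))
}

#' Project the residual matrix onto its retained principal components
#'
#' Keeps the top `n_keep` right singular vectors as orthonormal loadings and
#' projects every cell onto them, setting to zero the singular values that
#' were plausibly noise.
#'
#' @param Z residual cells x genes matrix.
#' @param n_keep number of components to retain (>= 1).
#' @return list with `pcs` (genes x n_keep orthonormal loadings) and `x`
#'   (cells x n_keep projected coordinates, `x = Z pcs`).
#' @export
project_pcs <- function(Z, n_keep) {
  abort_if(n_keep < 1, "n_keep must be >= 1")
  sv <- svd(Z)
  r <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_keep > r) {
    warning(sprintf("n_keep = %d exceeds rank %d; capped", n_keep, r))
    n_keep <- r
  }
  pcs <- sv$v[, seq_len(n_keep), drop = FALSE]
  rownames(pcs) <- colnames(Z)
  x <- Z %*% pcs
  list(pcs = pcs, x = x)
}
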