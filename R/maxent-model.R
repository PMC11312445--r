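# Maximum-entropy Gaussian model of the embryonic transcriptome.
#
# The model is p(x) = Normal(0, J^-1) over the flattened (cell, PC) state of
# one embryo, with the interaction matrix J restricted to a linear family:
# within-cell couplings M^t per cell type, symmetric cell-cell couplings S^k
# on symmetric adjacencies Psi^k, and directed couplings U^k on directed
# adjacencies Omega^k. Fitting matches the model covariances of the
# constrained statistics to their empirical values (the couplings are the
# Lagrange multipliers of the constraints); this is solved as the convex dual
# f(theta) = -log det J(theta) + tr(J(theta) %*% LambdaHat), whose gradient
# is (empirical - model) statistic, by a PD-safeguarded Newton method.

#' Constraint specification for the maximum-entropy model
#'
#' Cell-type indicator (within-cell) terms are always present. Symmetric
#' terms constrain the pair-averaged covariance over a symmetric 0/1
#' adjacency; directed terms over a directed 0/1 adjacency (so the coupling
#' between PC i in one cell and PC j in another may differ from its
#' transpose).
#'
#' @param graph an [embryo_graph()].
#' @param sym_terms named list of symmetric 0/1 matrices with zero diagonal.
#' @param dir_terms named list of 0/1 matrices with zero diagonal.
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(graph, sym_terms = list(), dir_terms = list()) {
  n <- length(graph$cell_names)
  chk <- function(m, name, sym) {
    m <- as.matrix(m) * 1
    abort_if(!identical(dim(m), c(n, n)), "term %s: wrong shape", name)
    abort_if(!all(m %in% c(0, 1)), "term %s: entries must be 0/1", name)
    abort_if(any(diag(m) != 0), "term %s: diagonal must be zero", name)
    if (sym) abort_if(!identical(m, t(m)), "term %s must be symmetric", name)
    abort_if(sum(m) == 0, "term %s is empty", name)
    dimnames(m) <- list(graph$cell_names, graph$cell_names)
    m
  }
  abort_if(length(sym_terms) > 0 && is.null(names(sym_terms)),
           "sym_terms must be named")
  abort_if(length(dir_terms) > 0 && is.null(names(dir_terms)),
           "dir_terms must be named")
  abort_if(anyDuplicated(c(names(sym_terms), names(dir_terms))) > 0,
           "duplicated term labels")
  sym_terms <- mapply(chk, sym_terms, names(sym_terms),
                      MoreArgs = list(sym = TRUE), SIMPLIFY = FALSE)
  dir_terms <- mapply(chk, dir_terms, names(dir_terms),
                      MoreArgs = list(sym = FALSE), SIMPLIFY = FALSE)
  structure(list(types = names(graph$n_t), sym_terms = sym_terms,
                 dir_terms = dir_terms, cell_names = graph$cell_names),
            class = "constraint_spec")
}

#' @rdname constraint_spec
#' @details `spec_embryo_wide()`, `spec_neighbor()` and `spec_sister()` build
#'   the three single-hypothesis models: all-to-all coupling, coupling on the
#'   cell-cell contact graph, and coupling between sister cells.
#' @export
spec_embryo_wide <- function(graph) {
  n <- length(graph$cell_names)
  psi <- matrix(1, n, n) - diag(n)
  constraint_spec(graph, sym_terms = list(embryo_wide = psi))
}

#' @rdname constraint_spec
#' @export
spec_neighbor <- function(graph) {
  constraint_spec(graph, sym_terms = list(neighbor = graph$contact))
}

#' @rdname constraint_spec
#' @export
spec_sister <- function(graph) {
  n <- length(graph$cell_names)
  psi <- matrix(0, n, n, dimnames = list(graph$cell_names, graph$cell_names))
  abort_if(is.null(graph$sister) || length(graph$sister) == 0,
           "graph has no sister map")
  for (p in names(graph$sister)) psi[p, graph$sister[[p]]] <- 1
  psi <- 1 * (psi | t(psi))
  constraint_spec(graph, sym_terms = list(sister = psi))
}

# ---- parameter basis -------------------------------------------------------

# One entry per scalar parameter theta_a: the sparse symmetric basis matrix
# A_a (dJ/dtheta_a) as aggregated linear indices + weights into the D x D
# matrix, plus bookkeeping (kind M/S/U, term label, PC indices, penalized).
make_basis <- function(spec, graph, n_pc) {
  cells <- spec$cell_names
  n <- length(cells)
  k <- n_pc
  D <- n * k
  lin <- function(p, i, q, j) ((q - 1) * k + j - 1) * D + (p - 1) * k + i
  params <- list()
  add <- function(kind, term, i, j, idx, wts, penalized) {
    agg <- tapply(wts, idx, sum)
    params[[length(params) + 1]] <<- list(
      kind = kind, term = term, i = i, j = j,
      idx = as.integer(names(agg)), wts = as.numeric(agg),
      penalized = penalized)
  }
  type_cells <- lapply(stats::setNames(spec$types, spec$types), function(t)
    which(graph$type_of == t))
  for (t in spec$types) {
    ps <- type_cells[[t]]
    for (i in seq_len(k)) for (j in i:k) {
      if (i == j) {
        add("M", t, i, j, lin(ps, i, ps, i), rep(1, length(ps)), FALSE)
      } else {
        add("M", t, i, j, c(lin(ps, i, ps, j), lin(ps, j, ps, i)),
            rep(1, 2 * length(ps)), FALSE)
      }
    }
  }
  for (nm in names(spec$sym_terms)) {
    e <- which(spec$sym_terms[[nm]] == 1, arr.ind = TRUE)  # both orders
    for (i in seq_len(k)) for (j in i:k) {
      if (i == j) {
        add("S", nm, i, j, lin(e[, 1], i, e[, 2], i), rep(1, nrow(e)), TRUE)
      } else {
        add("S", nm, i, j,
            c(lin(e[, 1], i, e[, 2], j), lin(e[, 1], j, e[, 2], i)),
            rep(1, 2 * nrow(e)), TRUE)
      }
    }
  }
  for (nm in names(spec$dir_terms)) {
    e <- which(spec$dir_terms[[nm]] == 1, arr.ind = TRUE)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      add("U", nm, i, j,
          c(lin(e[, 1], i, e[, 2], j), lin(e[, 2], j, e[, 1], i)),
          rep(0.5, 2 * nrow(e)), TRUE)
    }
  }
  labels <- vapply(params, function(p)
    sprintf("%s:%s:%d:%d", p$kind, p$term, p$i, p$j), character(1))
  # sparse basis operator P (params x D^2): J = mat(P^T theta),
  # stats tr(A_a W) = P vec(W)
  P <- Matrix::sparseMatrix(
    i = rep(seq_along(params),
            vapply(params, function(p) length(p$idx), integer(1))),
    j = unlist(lapply(params, `[[`, "idx")),
    x = unlist(lapply(params, `[[`, "wts")),
    dims = c(length(params), D * D))
  list(params = params, labels = labels, D = D, n_pc = k,
       penalized = vapply(params, `[[`, logical(1), "penalized"),
       P = P)
}

basis_J <- function(theta, basis) {
  matrix(as.numeric(Matrix::crossprod(basis$P, theta)), basis$D, basis$D)
}

# statistics tr(A_a W) for all parameters, W symmetric
basis_stats <- function(W, basis) {
  as.numeric(basis$P %*% as.numeric(W))
}

# ---- public model assembly -------------------------------------------------

#' Assemble the interaction matrix J from couplings
#'
#' `J_(pi)(qj) = sum_t M^t_ij I^t_pq + sum_k S^k_ij Psi^k_pq
#'  + 1/2 sum_k' (U^k'_ij Omega^k'_pq + U^k'_ji Omega^k'_qp)`,
#' flattened cell-major (index `(p-1) n_pc + i`). Directed terms make the
#' cross-cell coupling between PC i and PC j differ from that between PC j
#' and PC i while J stays symmetric overall.
#'
#' @param M named list (per type) of symmetric PC x PC matrices.
#' @param S named list (per symmetric term) of symmetric PC x PC matrices.
#' @param U named list (per directed term) of PC x PC matrices.
#' @param spec a [constraint_spec()].
#' @param graph an [embryo_graph()].
#' @param n_pc number of retained principal components.
#' @param check_pd error when J is not positive definite (default TRUE).
#' @return symmetric D x D matrix, D = n_cells * n_pc.
#' @export
build_J <- function(M, S = list(), U = list(), spec, graph, n_pc,
                    check_pd = TRUE) {
  n <- length(graph$cell_names)
  J <- matrix(0, n * n_pc, n * n_pc)
  for (t in spec$types) {
    ind <- diag(as.numeric(graph$type_of == t))
    Mt <- as.matrix(M[[t]])
    abort_if(!isTRUE(all.equal(Mt, t(Mt))), "M[[%s]] must be symmetric", t)
    J <- J + kronecker(ind, Mt)
  }
  for (nm in names(spec$sym_terms)) {
    Sk <- as.matrix(S[[nm]])
    abort_if(!isTRUE(all.equal(Sk, t(Sk))), "S[[%s]] must be symmetric", nm)
    J <- J + kronecker(spec$sym_terms[[nm]], Sk)
  }
  for (nm in names(spec$dir_terms)) {
    Om <- spec$dir_terms[[nm]]
    Uk <- as.matrix(U[[nm]])
    J <- J + (kronecker(Om, Uk) + kronecker(t(Om), t(Uk))) / 2
  }
  if (check_pd) {
    ev <- min(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
    abort_if(ev <= 0,
             "J is not positive definite (smallest eigenvalue %.3e)", ev)
  }
  J
}

theta_to_coupling_lists <- function(theta, basis, spec) {
  k <- basis$n_pc
  empty <- function() matrix(0, k, k)
  M <- lapply(stats::setNames(spec$types, spec$types), function(t) empty())
  S <- lapply(spec$sym_terms, function(m) empty())
  U <- lapply(spec$dir_terms, function(m) empty())
  for (a in seq_along(theta)) {
    p <- basis$params[[a]]
    if (p$kind == "M") {
      M[[p$term]][p$i, p$j] <- M[[p$term]][p$j, p$i] <- theta[a]
    } else if (p$kind == "S") {
      S[[p$term]][p$i, p$j] <- S[[p$term]][p$j, p$i] <- theta[a]
    } else {
      U[[p$term]][p$i, p$j] <- theta[a]
    }
  }
  list(M = M, S = S, U = U)
}

new_maxent_model <- function(theta, basis, spec, graph, n_pc) {
  cl <- theta_to_coupling_lists(theta, basis, spec)
  J <- build_J(cl$M, cl$S, cl$U, spec, graph, n_pc, check_pd = FALSE)
  structure(list(spec = spec, M = cl$M, S = cl$S, U = cl$U, graph = graph,
                 n_pc = n_pc, J = J, theta = theta, basis_labels = basis$labels),
            class = "maxent_model")
}

#' Construct a maximum-entropy model from explicit couplings
#' @inheritParams build_J
#' @return object of class `maxent_model`.
#' @export
maxent_model <- function(M, S = list(), U = list(), spec, graph, n_pc) {
  basis <- make_basis(spec, graph, n_pc)
  theta <- numeric(length(basis$params))
  for (a in seq_along(theta)) {
    p <- basis$params[[a]]
    theta[a] <- switch(p$kind,
      M = M[[p$term]][p$i, p$j],
      S = S[[p$term]][p$i, p$j],
      U = U[[p$term]][p$i, p$j])
  }
  m <- new_maxent_model(theta, basis, spec, graph, n_pc)
  ev <- min(eigen(m$J, symmetric = TRUE, only.values = TRUE)$values)
  abort_if(ev <= 0, "J is not positive definite (smallest eigenvalue %.3e)",
           ev)
  m
}

# ---- targets from empirical covariances ------------------------------------

# "Virtual" full moment matrix: diagonal blocks are the intra-type C^t of
# each cell's type, off-diagonal blocks the type-level gamma^tt'. Projecting
# it onto the constraint basis yields the empirical constrained statistics
# (with left-right mirror averaging implied: mirror cells share a type).
lambda_hat_matrix <- function(covset, graph, n_pc) {
  n <- length(graph$cell_names)
  k <- n_pc
  L <- matrix(0, n * k, n * k)
  missing_pairs <- character(0)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      tp <- graph$type_of[[p]]; tq <- graph$type_of[[q]]
      blk <- if (p == q) {
        covset$intra[[tp]]
      } else {
        covset$inter[[paste(tp, tq, sep = "|")]]
      }
      if (is.null(blk)) {
        missing_pairs <- c(missing_pairs, paste(tp, tq, sep = "|"))
        next
      }
      L[(p - 1) * k + seq_len(k), (q - 1) * k + seq_len(k)] <- blk
    }
  }
  if (length(missing_pairs))
    warning(sprintf("missing empirical covariances treated as 0: %s",
                    paste(unique(missing_pairs), collapse = ", ")))
  L
}

# ---- fitting ---------------------------------------------------------------

#' Exact constrained statistics of a model
#'
#' The model-side values of every constrained statistic (the per-type
#' within-cell covariance sums and the adjacency-summed cross-cell
#' covariances), computed exactly from `Sigma = J^-1`. These are the
#' quantities moment matching drives to their empirical targets.
#'
#' @param model a `maxent_model`.
#' @return named numeric vector (names `kind:term:i:j` over the parameter
#'   basis).
#' @export
constraint_statistics <- function(model) {
  basis <- make_basis(model$spec, model$graph, model$n_pc)
  Sigma <- chol2inv(chol(model$J))
  stats::setNames(basis_stats(Sigma, basis), basis$labels)
}

#' Fit the maximum-entropy model by moment matching
#'
#' Minimizes the convex dual `f(theta) = -log det J + sum_a theta_a C_a` by
#' a damped Newton method with backtracking line search that keeps J
#' positive definite; the gradient is (model - empirical) statistic, so at
#' the optimum every constrained statistic of the model equals its target.
#'
#' Targets come from the empirical [covariance_set()]: since only the cell
#' type of a sequenced cell is known (not its identity), the covariance of a
#' specific cell pair is estimated by its type-level value, and each
#' adjacency constraint target is the adjacency sum over those type-level
#' blocks. Left-right mirror averaging is implicit (mirror-paired cells
#' share a type). Alternatively, exact targets (e.g. from
#' [constraint_statistics()] of a known model) can be passed directly via
#' `targets`, bypassing the type-level approximation.
#'
#' @param covset empirical [covariance_set()] (may be NULL when `targets`
#'   is given; then no fit-quality eta is reported).
#' @param spec a [constraint_spec()].
#' @param graph an [embryo_graph()].
#' @param n_pc number of PCs.
#' @param tol relative tolerance on the largest statistic residual
#'   (default 1e-6).
#' @param max_iter Newton iteration cap (default 200).
#' @param targets optional named vector of constraint targets on the
#'   parameter basis (see [constraint_statistics()]).
#' @return list with `model` (a `maxent_model`) and `report` (class
#'   `fit_report`: `eta`, `matched` residuals, `converged`, `iterations`).
#' @export
fit_maxent <- function(covset, spec, graph, n_pc, tol = 1e-6,
                       max_iter = 200, targets = NULL) {
  if (!is.null(covset)) {
    for (t in spec$types) {
      C <- covset$intra[[t]]
      abort_if(is.null(C), "no intra covariance for type %s", t)
      ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      abort_if(ev <= 0,
               "infeasible: intra covariance of type %s not positive definite",
               t)
    }
  }
  basis <- make_basis(spec, graph, n_pc)
  if (is.null(targets)) {
    abort_if(is.null(covset), "need covset or targets")
    L <- lambda_hat_matrix(covset, graph, n_pc)
    e <- basis_stats(L, basis)
  } else {
    abort_if(is.null(names(targets)) || !setequal(names(targets),
                                                  basis$labels),
             "targets must be named over the parameter basis")
    e <- as.numeric(targets[basis$labels])
  }
  scale <- max(abs(e), 1e-10)

  theta <- if (is.null(covset)) init_theta_diag(basis, e)
           else init_theta(basis, covset, spec)
  fit <- newton_dual(theta, basis, e, tol * scale, max_iter)
  if (!fit$converged)
    stop(sprintf(paste0("moment matching did not converge in %d iterations ",
                        "(max residual %.3e, tolerance %.3e); ",
                        "targets may be infeasible"),
                 max_iter, fit$max_resid, tol * scale), call. = FALSE)
  model <- new_maxent_model(fit$theta, basis, spec, graph, n_pc)
  pred <- predict_type_covariances(model)
  eta <- if (is.null(covset)) NA_real_ else fit_quality(covset, pred)
  report <- structure(list(eta = eta, matched = fit$resid,
                           converged = fit$converged,
                           iterations = fit$iterations,
                           predicted = pred),
                      class = "fit_report")
  list(model = model, report = report)
}

# targets-only start: within-cell couplings from the inverse of the mean
# per-cell target block, interactions at zero (J block-diagonal PD)
init_theta_diag <- function(basis, e) {
  theta <- numeric(length(basis$params))
  for (a in seq_along(theta)) {
    p <- basis$params[[a]]
    if (p$kind == "M" && p$i == p$j) theta[a] <- 1
  }
  theta
}

init_theta <- function(basis, covset, spec) {
  theta <- numeric(length(basis$params))
  Minv <- lapply(covset$intra[spec$types], solve)
  for (a in seq_along(theta)) {
    p <- basis$params[[a]]
    if (p$kind == "M") theta[a] <- Minv[[p$term]][p$i, p$j]
  }
  theta
}

# Damped Newton on f(theta) = -logdet J + sum(theta * e);
# grad = e - stats(Sigma); Hessian H_ab = tr(Sigma A_a Sigma A_b).
newton_dual <- function(theta, basis, e, abs_tol, max_iter) {
  f_of <- function(th) {
    J <- basis_J(th, basis)
    ch <- tryCatch(chol(J), error = function(err) NULL)
    if (is.null(ch)) return(list(f = Inf))
    list(f = -2 * sum(log(diag(ch))) + sum(th * e), ch = ch)
  }
  cur <- f_of(theta)
  abort_if(!is.finite(cur$f), "initial J not positive definite")
  resid <- e  # placeholder
  for (it in seq_len(max_iter)) {
    Sigma <- chol2inv(cur$ch)
    s <- basis_stats(Sigma, basis)
    resid <- s - e
    if (max(abs(resid)) < abs_tol)
      return(list(theta = theta, converged = TRUE, iterations = it,
                  resid = resid, max_resid = max(abs(resid))))
    H <- dual_hessian(Sigma, basis)
    grad <- e - s
    step <- tryCatch(
      -solve(H + diag(1e-12 * max(diag(H)), nrow(H)), grad),
      error = function(err) -grad)
    gTd <- sum(grad * step)
    if (gTd > 0) { step <- -grad; gTd <- -sum(grad^2) }
    tfac <- 1
    repeat {
      nxt <- f_of(theta + tfac * step)
      if (is.finite(nxt$f) && nxt$f <= cur$f + 1e-4 * tfac * gTd) break
      tfac <- tfac / 2
      if (tfac < 1e-14)
        return(list(theta = theta, converged = FALSE, iterations = it,
                    resid = resid, max_resid = max(abs(resid))))
    }
    theta <- theta + tfac * step
    cur <- nxt
  }
  list(theta = theta, converged = FALSE, iterations = max_iter,
       resid = resid, max_resid = max(abs(resid)))
}

dual_hessian <- function(Sigma, basis) {
  np <- length(basis$params)
  D <- basis$D
  H <- matrix(0, np, np)
  Ts <- vector("list", np)
  for (a in seq_len(np)) {
    p <- basis$params[[a]]
    # A_a %*% Sigma via sparse rows: entry (r, c, w) adds w * Sigma[c, ]
    r0 <- (p$idx - 1) %% D + 1
    c0 <- (p$idx - 1) %/% D + 1
    AS <- matrix(0, D, D)
    for (m in seq_along(p$idx))
      AS[r0[m], ] <- AS[r0[m], ] + p$wts[m] * Sigma[c0[m], ]
    Ts[[a]] <- Sigma %*% AS
  }
  for (a in seq_len(np)) {
    va <- as.numeric(Ts[[a]])
    for (b in a:np) {
      pb <- basis$params[[b]]
      H[a, b] <- H[b, a] <- sum(pb$wts * va[pb$idx])
    }
  }
  H
}

# ---- prediction, fit quality, modes ----------------------------------------

#' Model-predicted cell-type-level covariances
#'
#' Inverts J and aggregates the full covariance `Sigma = J^-1` to the
#' type level: intra `C~^t_ij` is the mean diagonal block over cells of type
#' t; inter `gamma~^tt'_ij` the mean over distinct cell pairs of the two
#' types. Directly comparable to the empirical [covariance_set()].
#'
#' @param model a `maxent_model`.
#' @return a [covariance_set()].
#' @export
predict_type_covariances <- function(model) {
  graph <- model$graph
  k <- model$n_pc
  Sigma <- tryCatch(chol2inv(chol(model$J)),
                    error = function(err)
                      stop("J is singular or not positive definite",
                           call. = FALSE))
  types <- names(graph$n_t)
  cells_of <- lapply(stats::setNames(types, types), function(t)
    which(graph$type_of == t))
  blk <- function(p, q)
    Sigma[(p - 1) * k + seq_len(k), (q - 1) * k + seq_len(k), drop = FALSE]
  intra <- lapply(cells_of, function(ps) {
    Reduce(`+`, lapply(ps, function(p) blk(p, p))) / length(ps)
  })
  inter <- list()
  nt <- length(types)
  for (a in seq_len(nt)) for (b in a:nt) {
    t1 <- types[a]; t2 <- types[b]
    ps <- cells_of[[t1]]; qs <- cells_of[[t2]]
    acc <- matrix(0, k, k); m <- 0L
    for (p in ps) for (q in qs) {
      if (p == q) next
      acc <- acc + blk(p, q); m <- m + 1L
    }
    if (m == 0L) next
    g <- acc / m
    inter[[paste(t1, t2, sep = "|")]] <- g
    if (t1 != t2) inter[[paste(t2, t1, sep = "|")]] <- t(g)
  }
  covariance_set(intra, inter)
}

#' Fit quality eta between empirical and predicted covariances
#'
#' `eta = 1 - sum_a (C_a - C~_a)^2 / sum_a C_a^2` over the shared covariance
#' components; 1 is a perfect fit, 0 the trivial all-zero prediction.
#'
#' @param empirical,predicted [covariance_set()] objects.
#' @param include_intra include within-cell components (default TRUE).
#' @return scalar eta <= 1.
#' @export
fit_quality <- function(empirical, predicted, include_intra = TRUE) {
  ce <- flatten_covset(empirical, include_intra = include_intra)
  cp <- flatten_covset(predicted, include_intra = include_intra)
  common <- intersect(names(ce), names(cp))
  abort_if(length(common) == 0, "no shared covariance components")
  ce <- ce[common]; cp <- cp[common]
  denom <- sum(ce^2)
  abort_if(denom == 0, "all empirical components are zero: eta undefined")
  1 - sum((ce - cp)^2) / denom
}

#' Collective modes of the model covariance
#'
#' Eigen-decomposition `Sigma = sum_b lambda_b phi^b (phi^b)^T` of the model
#' covariance: the leading eigenvectors are the collective modes of gene
#' expression over (cell, PC) space, with `variance_fractions` their share of
#' the total model variance. Sign convention: largest-magnitude entry of each
#' mode is positive.
#'
#' @param model a `maxent_model` (or a covariance matrix).
#' @return object of class `mode_set`: `eigenvalues` (descending), `modes`
#'   (orthonormal columns), `variance_fractions`.
#' @export
mode_decomposition <- function(model) {
  Sigma <- if (inherits(model, "maxent_model")) chol2inv(chol(model$J))
           else as.matrix(model)
  ee <- eigen(Sigma, symmetric = TRUE)
  modes <- ee$vectors
  for (b in seq_len(ncol(modes))) {
    m <- modes[, b]
    s <- sign(m[which.max(abs(m))])
    if (s < 0) modes[, b] <- -m
  }
  structure(list(eigenvalues = ee$values, modes = modes,
                 variance_fractions = ee$values / sum(ee$values)),
            class = "mode_set")
}

#' Variance explained by fixed modes under random rotations
#'
#' For Haar-random rotations R, the fraction of the rotated model's variance
#' `R Sigma R^T` captured by the fixed top-k unrotated modes. For an
#' isotropic model this is exactly k/D; in general its rotation-average is
#' k/D, the baseline against which the concentration of variance in the
#' leading collective modes is judged.
#'
#' @param model a `maxent_model` (or covariance matrix).
#' @param modes a [mode_decomposition()] result (default: computed from
#'   `model`).
#' @param k number of fixed leading modes.
#' @param n_rotations number of Haar draws (default 100).
#' @param seed RNG seed.
#' @return list with `fractions` (per rotation), `mean`, `sd`.
#' @export
rotation_baseline <- function(model, modes = NULL, k, n_rotations = 100,
                              seed = 1) {
  Sigma <- if (inherits(model, "maxent_model")) chol2inv(chol(model$J))
           else as.matrix(model)
  D <- nrow(Sigma)
  abort_if(k > D, "k exceeds the state-space dimension")
  if (is.null(modes)) modes <- mode_decomposition(Sigma)
  phi <- modes$modes[, seq_len(k), drop = FALSE]
  tot <- sum(diag(Sigma))
  set.seed(seed)
  fr <- vapply(seq_len(n_rotations), function(r) {
    Q <- qr_haar(D)
    RS <- Q %*% Sigma %*% t(Q)
    sum(diag(t(phi) %*% RS %*% phi)) / tot
  }, numeric(1))
  list(fractions = fr, mean = mean(fr), sd = stats::sd(fr))
}

qr_haar <- function(D) {
  qrd <- qr(matrix(stats::rnorm(D * D), D, D))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))), D)
}
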