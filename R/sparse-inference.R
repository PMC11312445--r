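# Sparse inference of the interaction network: L1-regularized moment
# matching across posterior covariance draws and a lambda grid, stability
# ranking of candidate terms, Schulze aggregation of the per-lambda
# rankings, and forward selection of terms up to a target fit quality.

#' Enumerate candidate interaction terms for a graph
#'
#' Candidates are the three global symmetric hypotheses (embryo-wide,
#' neighbor, sister) plus one directed term per mirror-symmetrized contact
#' pair: the pair (p, q) is bundled with its mirror image (p~, q~), so every
#' specific term respects the left-right symmetry of the embryo. One bundle
#' is enumerated per unordered pair orbit: a directed bundle with general
#' coupling U already expresses both directions, because the reversed bundle
#' with the transposed coupling contributes identically to J -- enumerating
#' both orderings would duplicate the same J-subspace and leave the L1
#' objective exactly flat between the twins.
#'
#' @param graph an [embryo_graph()] (with a mirror map; without one the
#'   specific terms are built unsymmetrized, with a warning).
#' @return a [constraint_spec()] with labeled `sym_terms` and `dir_terms`.
#' @export
candidate_terms <- function(graph) {
  n <- length(graph$cell_names)
  sym <- list(embryo_wide = matrix(1, n, n) - diag(n),
              neighbor = graph$contact)
  if (!is.null(graph$sister) && length(graph$sister) > 0)
    sym$sister <- spec_sister(graph)$sym_terms$sister
  has_mirror <- !is.null(graph$mirror)
  if (!has_mirror)
    warning("graph has no mirror map: specific terms built unsymmetrized")
  edges <- which(graph$contact == 1, arr.ind = TRUE)  # all ordered pairs
  dir_terms <- list()
  seen <- character(0)
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]; q <- edges[r, 2]
    # orbit of (p, q) under left-right mirroring and (redundant) reversal
    full <- list(c(p, q), c(q, p))
    if (has_mirror) {
      pm <- match(graph$mirror[[graph$cell_names[p]]], graph$cell_names)
      qm <- match(graph$mirror[[graph$cell_names[q]]], graph$cell_names)
      full <- c(full, list(c(pm, qm), c(qm, pm)))
    }
    canon <- full[[which.min(vapply(full, function(e) e[1] * n + e[2],
                                    numeric(1)))]]
    key <- paste0("pair:", graph$cell_names[canon[1]], ">",
                  graph$cell_names[canon[2]])
    if (key %in% seen) next
    seen <- c(seen, key)
    orbit <- unique(list(canon))
    if (has_mirror) {
      cm <- c(match(graph$mirror[[graph$cell_names[canon[1]]]],
                    graph$cell_names),
              match(graph$mirror[[graph$cell_names[canon[2]]]],
                    graph$cell_names))
      orbit <- unique(list(canon, cm))
    }
    Om <- matrix(0, n, n)
    for (e in orbit) Om[e[1], e[2]] <- 1
    diag(Om) <- 0
    dir_terms[[key]] <- Om
  }
  constraint_spec(graph, sym_terms = sym, dir_terms = dir_terms)
}

# Restrict a constraint spec to a subset of interaction-term labels
# (the per-type M terms are always kept).
spec_subset <- function(spec, labels, graph) {
  constraint_spec(graph,
                  sym_terms = spec$sym_terms[
                    intersect(labels, names(spec$sym_terms))],
                  dir_terms = spec$dir_terms[
                    intersect(labels, names(spec$dir_terms))])
}

#' Default log-spaced regularization grid
#'
#' With `candidates` and `graph` given, the grid is anchored at the data's
#' lambda_max -- the smallest penalty that zeroes every interaction
#' coupling, computed from the KKT condition at the interactions-free
#' moment match (largest dual-gradient magnitude over penalized
#' parameters) -- and descends three decades from just below it, so the
#' grid spans the whole selection path. Without them it falls back to
#' `[1e-3, 10]` times the median magnitude of the empirical covariance
#' components.
#'
#' @param covset empirical [covariance_set()].
#' @param n grid size (default 8).
#' @param candidates optional candidate [constraint_spec()].
#' @param graph,n_pc required with `candidates`.
#' @return ascending numeric vector.
#' @export
default_lambda_grid <- function(covset, n = 8, candidates = NULL,
                                graph = NULL, n_pc = NULL) {
  if (!is.null(candidates)) {
    basis <- make_basis(candidates, graph, n_pc)
    L <- lambda_hat_matrix(covset, graph, n_pc)
    e <- basis_stats(L, basis)
    base <- fit_maxent(covset, constraint_spec(graph), graph, n_pc)
    Sigma0 <- chol2inv(chol(base$model$J))
    # pad the interactions-free J into the candidate basis
    th0 <- numeric(length(basis$params))
    for (a in seq_along(th0)) {
      p <- basis$params[[a]]
      if (p$kind == "M") th0[a] <- base$model$M[[p$term]][p$i, p$j]
    }
    g0 <- e - basis_stats(Sigma0, basis)
    lam_max <- max(abs(g0[basis$penalized]))
    if (!is.finite(lam_max) || lam_max == 0) lam_max <- 1
    return(lam_max * 10^seq(-3, -0.05, length.out = n))
  }
  v <- abs(flatten_covset(covset))
  scale <- stats::median(v[v > 0])
  if (!is.finite(scale) || scale == 0) scale <- 1
  exp(seq(log(1e-3), log(10), length.out = n)) * scale
}

#' L1-regularized moment-matching fit
#'
#' Minimizes the moment-matching dual plus an L1 penalty
#' `lambda * (sum |S| + sum |U|)` on the interaction couplings (within-cell
#' M terms are unpenalized) by FISTA proximal gradient with backtracking,
#' safeguarded to keep J positive definite. With `lambda = 0` the exact
#' Newton moment match is used.
#'
#' @param covset a [covariance_set()] (a single posterior/bootstrap draw or
#'   the point estimate).
#' @param spec candidate [constraint_spec()].
#' @param graph an [embryo_graph()].
#' @param n_pc number of PCs.
#' @param lambda L1 penalty strength.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative tolerance on the parameter step (default 1e-7).
#' @param init optional warm-start parameter vector (e.g. the unpenalized
#'   solution when sweeping a lambda grid).
#' @param strict error on non-convergence (default TRUE); with FALSE a
#'   warning is issued and the final (monotone) iterate returned, which the
#'   stability ranking across many draws tolerates.
#' @return list with `theta`, `labels`, `penalized`, `term_norms` (Frobenius
#'   norm of each interaction term's coupling block), `converged`.
#' @export
fit_regularized <- function(covset, spec, graph, n_pc, lambda,
                            max_iter = 2000, tol = 1e-7, init = NULL,
                            strict = TRUE) {
  basis <- make_basis(spec, graph, n_pc)
  L <- lambda_hat_matrix(covset, graph, n_pc)
  e <- basis_stats(L, basis)
  pen <- basis$penalized

  if (lambda == 0) {
    fit <- newton_dual(init_theta(basis, covset, spec), basis, e,
                       1e-9 * max(abs(e), 1e-10), 500)
    theta <- fit$theta
    conv <- fit$converged
  } else {
    th0 <- if (is.null(init)) init_theta(basis, covset, spec) else init
    res <- fista_l1(th0, basis, e, pen, lambda, max_iter, tol)
    theta <- res$theta
    conv <- res$converged
    if (!conv) {
      msg <- sprintf("regularized fit did not converge (lambda = %.3g)",
                     lambda)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  list(theta = theta, labels = basis$labels, penalized = pen,
       term_norms = term_norms(theta, basis), converged = conv)
}

#' Rank candidate interaction terms from covariance draws
#'
#' The full selection pipeline over uncertainty draws: for every covariance
#' draw an unpenalized moment match provides a warm start, an L1-regularized
#' fit is run at each lambda of the grid, terms are stability-ranked per
#' lambda across draws ([stability_ranking()]), and the per-lambda rankings
#' are aggregated with the Schulze method.
#'
#' @param covset a [covariance_set()] with `draws` (see
#'   [resample_covariances()]).
#' @param candidates candidate [constraint_spec()] (see
#'   [candidate_terms()]).
#' @param graph an [embryo_graph()].
#' @param n_pc number of PCs.
#' @param lambda_grid penalty grid (default [default_lambda_grid()]).
#' @param nonzero_threshold see [stability_ranking()].
#' @return list with `order` (aggregated ranking), `per_lambda` (list of
#'   stability data.frames), `lambda_grid`.
#' @export
rank_interactions <- function(covset, candidates, graph, n_pc,
                              lambda_grid = NULL, nonzero_threshold = 1e-4) {
  abort_if(is.null(covset$draws) || length(covset$draws) < 2,
           "covset must carry at least 2 draws")
  if (is.null(lambda_grid))
    lambda_grid <- default_lambda_grid(covset, candidates = candidates,
                                       graph = graph, n_pc = n_pc)
  lambda_grid <- sort(lambda_grid)
  nl <- length(lambda_grid)
  # descending-lambda continuation per draw: each fit warm-starts from the
  # solution at the next-larger lambda. The candidate family is linearly
  # degenerate (a global term equals a sum of specific-pair terms), so cold
  # or unpenalized starts can leave the solver on a high-L1 branch of the
  # flat valley; continuation from the sparse end tracks the minimal-L1
  # branch that the exact solution selects.
  fits_by_lambda <- replicate(nl, vector("list", length(covset$draws)),
                              simplify = FALSE)
  for (d in seq_along(covset$draws)) {
    cs <- covariance_set(covset$draws[[d]]$intra, covset$draws[[d]]$inter)
    warm <- NULL
    for (li in rev(seq_len(nl))) {
      fit <- fit_regularized(cs, candidates, graph, n_pc, lambda_grid[li],
                             init = warm, strict = FALSE)
      fits_by_lambda[[li]][[d]] <- fit
      warm <- fit$theta
    }
  }
  per_lambda <- lapply(fits_by_lambda, stability_ranking,
                       nonzero_threshold = nonzero_threshold)
  ballots <- lapply(per_lambda, function(tab)
    stats::setNames(tab$score, tab$term))
  order <- schulze_aggregate(ballots)
  list(order = order, per_lambda = per_lambda, lambda_grid = lambda_grid)
}

term_norms <- function(theta, basis) {
  terms <- unique(vapply(basis$params[basis$penalized],
                         `[[`, character(1), "term"))
  vapply(stats::setNames(terms, terms), function(tm) {
    sel <- vapply(basis$params, function(p) p$penalized && p$term == tm,
                  logical(1))
    sqrt(sum(theta[sel]^2))
  }, numeric(1))
}

fista_l1 <- function(theta, basis, e, pen, lambda, max_iter, tol) {
  f_of <- function(th) {
    J <- basis_J(th, basis)
    ch <- tryCatch(chol(J), error = function(err) NULL)
    if (is.null(ch)) return(list(f = Inf))
    list(f = -2 * sum(log(diag(ch))) + sum(th * e), ch = ch)
  }
  grad_of <- function(ch) e - basis_stats(chol2inv(ch), basis)
  soft <- function(v, thr) sign(v) * pmax(abs(v) - thr, 0)
  prox <- function(th, t) {
    th[pen] <- soft(th[pen], t * lambda)
    th
  }
  pen_of <- function(th) lambda * sum(abs(th[pen]))

  # one backtracked proximal step from anchor point z (gradient g at z)
  prox_step <- function(z, fz, step) {
    g <- grad_of(fz$ch)
    repeat {
      cand <- prox(z - step * g, step)
      nf <- f_of(cand)
      dv <- cand - z
      if (is.finite(nf$f) &&
          nf$f <= fz$f + sum(g * dv) + sum(dv^2) / (2 * step)) break
      step <- step / 2
      abort_if(step < 1e-16, "step underflow in regularized fit")
    }
    list(cand = cand, nf = nf, step = step)
  }

  cur <- f_of(theta)
  abort_if(!is.finite(cur$f), "initial J not positive definite")
  y <- theta
  fy <- cur
  Ftheta <- cur$f + pen_of(theta)
  t_mom <- 1
  step <- 1
  stall <- 0L
  for (it in seq_len(max_iter)) {
    ps <- prox_step(y, fy, step)
    Fnew <- ps$nf$f + pen_of(ps$cand)
    if (Fnew > Ftheta) {
      # monotone safeguard: momentum overshot, take a plain descent step
      # from the current iterate (guaranteed not to increase F)
      ft <- f_of(theta)
      ps <- prox_step(theta, ft, ps$step)
      Fnew <- ps$nf$f + pen_of(ps$cand)
      t_mom <- 1
    }
    cand <- ps$cand
    step <- ps$step * 1.25
    dtheta <- max(abs(cand - theta))
    t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- cand + ((t_mom - 1) / t_next) * (cand - theta)
    fy <- f_of(y)
    if (!is.finite(fy$f)) {  # momentum left the PD cone
      y <- cand
      fy <- ps$nf
      t_mom <- 1
    } else {
      t_mom <- t_next
    }
    # converged on a negligible parameter step, or on objective stagnation
    # (the step criterion is step-size dependent and can hover just above
    # tol on ill-conditioned draws)
    stall <- if (abs(Ftheta - Fnew) < 1e-8 * max(1, abs(Fnew))) stall + 1L
             else 0L
    theta <- cand
    Ftheta <- Fnew
    if (dtheta < tol * max(1, max(abs(theta))) || stall >= 10L)
      return(list(theta = theta, converged = TRUE, iterations = it))
  }
  list(theta = theta, converged = FALSE, iterations = max_iter)
}

#' Stability ranking of interaction terms across fits
#'
#' Per candidate term, the score is (fraction of draws in which the term's
#' coupling norm exceeds `nonzero_threshold`) times (median coupling norm);
#' terms are ranked by descending score, ties broken by label.
#'
#' @param fits list of [fit_regularized()] results (one per covariance draw).
#' @param nonzero_threshold magnitude below which a coupling counts as zero
#'   (default 1e-4).
#' @return data.frame with `term`, `score`, `stability`, `median_norm`,
#'   ordered by rank.
#' @export
stability_ranking <- function(fits, nonzero_threshold = 1e-4) {
  abort_if(length(fits) < 2, "need at least 2 draws")
  norms <- do.call(rbind, lapply(fits, `[[`, "term_norms"))
  stab <- colMeans(norms > nonzero_threshold)
  med <- apply(norms, 2, stats::median)
  df <- data.frame(term = colnames(norms), score = stab * med,
                   stability = stab, median_norm = med,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$term), ]
  rownames(df) <- NULL
  df
}

#' Aggregate per-lambda rankings with the Schulze method
#'
#' Computes pairwise preferences over all ballots, strongest beatpaths by
#' Floyd-Warshall, and orders candidates by the number of beatpath wins;
#' remaining ties are broken lexicographically. Deterministic. Each ballot
#' is either a character vector (a total order) or a named numeric score
#' vector; with scores, a ballot expresses a preference between two
#' candidates only where their scores strictly differ, so terms tied at
#' zero do not generate spurious alphabetical preferences.
#'
#' @param rankings list of ballots over the same candidate set.
#' @return character vector: the aggregated total order.
#' @export
schulze_aggregate <- function(rankings) {
  abort_if(length(rankings) == 0, "no rankings to aggregate")
  first <- rankings[[1]]
  cands <- sort(if (is.character(first)) first else names(first))
  abort_if(length(cands) == 0, "empty candidate set")
  for (r in rankings)
    abort_if(!setequal(if (is.character(r)) r else names(r), cands),
             "rankings disagree on the candidate set")
  nc <- length(cands)
  d <- matrix(0, nc, nc, dimnames = list(cands, cands))
  for (r in rankings) {
    if (is.character(r)) {
      pos <- match(cands, r)
      for (a in seq_len(nc)) for (b in seq_len(nc))
        if (pos[a] < pos[b]) d[a, b] <- d[a, b] + 1
    } else {
      sc <- r[cands]
      for (a in seq_len(nc)) for (b in seq_len(nc))
        if (sc[a] > sc[b]) d[a, b] <- d[a, b] + 1
    }
  }
  p <- matrix(0, nc, nc)
  for (a in seq_len(nc)) for (b in seq_len(nc))
    if (a != b && d[a, b] > d[b, a]) p[a, b] <- d[a, b]
  for (k in seq_len(nc)) for (a in seq_len(nc)) if (a != k)
    for (b in seq_len(nc)) if (b != a && b != k)
      p[a, b] <- max(p[a, b], min(p[a, k], p[k, b]))
  wins <- vapply(seq_len(nc), function(a)
    sum(p[a, -a] > p[-a, a]), numeric(1))
  cands[order(-wins, cands)]
}

#' Forward selection of interaction terms to a target fit quality
#'
#' Starting from the most important term of the aggregated ranking, refits
#' the model unregularized with the top m terms for m = 1, 2, ... and
#' returns the smallest model with `eta > eta_target` (L1 is used for
#' selection, plain moment matching for estimation).
#'
#' @param order aggregated term ranking (character vector).
#' @param covset empirical [covariance_set()].
#' @param candidates candidate [constraint_spec()] supplying the term
#'   adjacencies.
#' @param graph an [embryo_graph()].
#' @param n_pc number of PCs.
#' @param eta_target target fit quality (default 0.9).
#' @return list with `model`, `report`, `terms` (selected labels), `etas`
#'   (the eta trajectory), `reached` (logical).
#' @export
forward_select <- function(order, covset, candidates, graph, n_pc,
                           eta_target = 0.9) {
  abort_if(length(order) == 0, "empty term order")
  etas <- numeric(0)
  best <- NULL
  for (m in seq_along(order)) {
    sp <- spec_subset(candidates, order[seq_len(m)], graph)
    fit <- tryCatch(fit_maxent(covset, sp, graph, n_pc),
                    error = function(err) NULL)
    etas[m] <- if (is.null(fit)) NA_real_ else fit$report$eta
    if (!is.null(fit)) best <- fit
    if (!is.null(fit) && fit$report$eta > eta_target) {
      return(list(model = fit$model, report = fit$report,
                  terms = order[seq_len(m)], etas = etas, reached = TRUE))
    }
  }
  warning(sprintf("eta target %.3g not reached with all %d terms",
                  eta_target, length(order)))
  list(model = best$model, report = best$report, terms = order,
       etas = etas, reached = FALSE)
}
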