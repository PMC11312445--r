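# Synthetic embryos with the exact statistical structure the analysis
# assumes -- conserved cell types and contact graph, left-right symmetry,
# mother/embryo/time effects, zero-mean Gaussian collective fluctuations
# from a known sparse interaction matrix, per-entry measurement noise --
# with complete ground truth recorded for every pipeline stage.

#' Stylized mirror-symmetric embryo graphs
#'
#' `toy4`: 4 cells, 2 mirror pairs, 2 types, 3 contacts. `mirror16`: 16
#' cells, 8 mirror pairs, 5 types with per-embryo sizes (4, 2, 2, 4, 4), a
#' per-side contact ring plus two cross-midline contacts. `mirror32`: 32
#' cells, 16 mirror pairs, 8 types of size 4. These are stylized stand-ins
#' for measured contact maps; real graphs can be supplied via the JSON
#' format of [read_embryo_graph()].
#'
#' @param name one of `"toy4"`, `"mirror16"`, `"mirror32"`.
#' @return an [embryo_graph()].
#' @export
make_topology <- function(name) {
  side_graph <- function(base, types_of_base, ring = TRUE, cross = base[1]) {
    cells <- c(paste0(base, "-L"), paste0(base, "-R"))
    nb <- length(base)
    type_of <- stats::setNames(rep(types_of_base, 2), cells)
    mirror <- stats::setNames(c(paste0(base, "-R"), paste0(base, "-L")),
                              cells)
    # sisters: consecutive base cells pair up within a side
    sister <- character(0)
    for (i in seq(1, nb - 1, by = 2)) {
      for (sd in c("-L", "-R")) {
        p <- paste0(base[i], sd); q <- paste0(base[i + 1], sd)
        sister[p] <- q; sister[q] <- p
      }
    }
    contact <- matrix(0, 2 * nb, 2 * nb, dimnames = list(cells, cells))
    add_edge <- function(a, b) {
      contact[a, b] <<- 1; contact[b, a] <<- 1
    }
    if (ring && nb > 2) {
      for (sd in c("-L", "-R")) {
        for (i in seq_len(nb))
          add_edge(paste0(base[i], sd),
                   paste0(base[i %% nb + 1], sd))
      }
    }
    for (cr in cross) add_edge(paste0(cr, "-L"), paste0(cr, "-R"))
    embryo_graph(cells, type_of, contact, sister, mirror)
  }
  switch(name,
    toy4 = {
      cells <- c("A-L", "A-R", "B-L", "B-R")
      type_of <- stats::setNames(c("tA", "tA", "tB", "tB"), cells)
      contact <- matrix(0, 4, 4, dimnames = list(cells, cells))
      contact["A-L", "A-R"] <- contact["A-R", "A-L"] <- 1
      contact["A-L", "B-L"] <- contact["B-L", "A-L"] <- 1
      contact["A-R", "B-R"] <- contact["B-R", "A-R"] <- 1
      sister <- stats::setNames(c("B-L", "B-R", "A-L", "A-R"), cells)
      mirror <- stats::setNames(c("A-R", "A-L", "B-R", "B-L"), cells)
      embryo_graph(cells, type_of, contact, sister, mirror)
    },
    mirror16 = side_graph(
      base = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
      types_of_base = c("t1", "t1", "t2", "t3", "t4", "t4", "t5", "t5"),
      cross = c("a1", "d1")),
    mirror32 = side_graph(
      base = sprintf("x%02d", 1:16),
      types_of_base = rep(sprintf("u%d", 1:8), each = 2),
      cross = c("x01", "x09")),
    stop(sprintf("unknown topology '%s'", name), call. = FALSE))
}

#' Refine a graph's cell types to mirror-pair resolution
#'
#' Returns the same graph with each left-right mirror orbit as its own cell
#' type. This is the "model-level identity" situation: cells are known up to
#' the left-right symmetry only. Cell-identity scrambling within coarse
#' multi-cell types erases most adjacency information (covariances between
#' specific cells are replaced by type averages), so interaction inference
#' is only informative when types resolve most cells -- as in the real
#' embryo, where inferred specific interactions are between left-right
#' partners or sisters of finely resolved types.
#'
#' @param graph an [embryo_graph()] with a mirror map.
#' @return an [embryo_graph()] with per-mirror-pair types.
#' @export
mirror_pair_types <- function(graph) {
  abort_if(is.null(graph$mirror), "graph has no mirror map")
  pair_type <- vapply(graph$cell_names, function(p)
    paste(sort(c(p, graph$mirror[[p]])), collapse = "~"), character(1))
  embryo_graph(graph$cell_names,
               stats::setNames(pair_type, graph$cell_names),
               graph$contact, graph$sister, graph$mirror)
}

#' Reference ground-truth models on a graph
#'
#' `uncoupled_model()`: independent cells (J = identity; no inter-cell
#' terms). `coupled_model()`: within-cell identity couplings plus a neighbor
#' interaction `S = s_neighbor * I` on the contact graph; the default
#' `s_neighbor = -0.3` produces moderate positive neighbor correlations
#' (~0.35), the scale of collective variation the analysis is designed to
#' detect. `planted_sparse_model()` adds `n_specific` directed cell-pair
#' terms (mirror-symmetrized contact-pair bundles, chosen deterministically
#' spread over the candidate list) with an asymmetric PC coupling of
#' magnitude `u_specific`.
#'
#' @param graph an [embryo_graph()].
#' @param n_pc number of PCs.
#' @param s_neighbor neighbor coupling (default -0.3).
#' @param n_specific number of planted specific terms (default 2).
#' @param u_specific magnitude of the specific directed coupling
#'   (default 0.3).
#' @return a `maxent_model`.
#' @export
uncoupled_model <- function(graph, n_pc) {
  spec <- constraint_spec(graph)
  M <- lapply(stats::setNames(names(graph$n_t), names(graph$n_t)),
              function(t) diag(n_pc))
  maxent_model(M, spec = spec, graph = graph, n_pc = n_pc)
}

#' @rdname uncoupled_model
#' @export
coupled_model <- function(graph, n_pc, s_neighbor = -0.3) {
  spec <- spec_neighbor(graph)
  M <- lapply(stats::setNames(names(graph$n_t), names(graph$n_t)),
              function(t) diag(n_pc))
  maxent_model(M, S = list(neighbor = s_neighbor * diag(n_pc)),
               spec = spec, graph = graph, n_pc = n_pc)
}

#' @rdname uncoupled_model
#' @export
planted_sparse_model <- function(graph, n_pc, s_neighbor = -0.3,
                                 n_specific = 2, u_specific = 0.3) {
  cand <- candidate_terms(graph)
  labels <- names(cand$dir_terms)
  abort_if(length(labels) < n_specific, "not enough candidate pairs")
  picks <- labels[round(seq(1, length(labels),
                            length.out = n_specific + 2))[2:(n_specific + 1)]]
  spec <- constraint_spec(graph,
                          sym_terms = list(neighbor = graph$contact),
                          dir_terms = cand$dir_terms[picks])
  M <- lapply(stats::setNames(names(graph$n_t), names(graph$n_t)),
              function(t) diag(n_pc))
  U1 <- matrix(0, n_pc, n_pc)
  if (n_pc >= 2) U1[1, 2] <- u_specific else U1[1, 1] <- u_specific
  maxent_model(M, S = list(neighbor = s_neighbor * diag(n_pc)),
               U = stats::setNames(rep(list(U1), n_specific), picks),
               spec = spec, graph = graph, n_pc = n_pc)
}

#' Sample synthetic embryos from a ground-truth model
#'
#' Each embryo is an independent draw of the flattened (cell, PC) state from
#' `Normal(0, J^-1)`; optional independent Gaussian measurement noise of SD
#' `eps_scale` is added per entry. Within each embryo, cell positions are
#' scrambled within their cell type -- as in the data, only the cell type of
#' each sequenced cell is known, not its exact identity; the true positions
#' are kept in `truth`.
#'
#' @param model a `maxent_model` (the ground truth).
#' @param n_embryos number of embryos.
#' @param eps_scale measurement-noise SD (default 0).
#' @param seed RNG seed.
#' @return list of class `synthetic_dataset`: `posterior` (an
#'   [expression_posterior()] whose "genes" are the PC coordinates),
#'   `x` (observed cells x PC matrix), `type_of`, `embryo_of`, and `truth`
#'   (`x_true` per embryo, `position_of`, the generating `model`).
#' @export
sample_embryos <- function(model, n_embryos, eps_scale = 0, seed = 1) {
  graph <- model$graph
  k <- model$n_pc
  n <- length(graph$cell_names)
  set.seed(seed)
  Sigma <- chol2inv(chol(model$J))
  U <- chol(Sigma)
  types <- graph$type_of
  x_rows <- list(); meta <- list(); truth_x <- list(); pos <- integer(0)
  for (e in seq_len(n_embryos)) {
    z <- as.vector(t(U) %*% stats::rnorm(n * k))
    xe <- t(matrix(z, k, n))  # cells x PC, cell-major flattening
    rownames(xe) <- graph$cell_names
    truth_x[[e]] <- xe
    # scramble positions within type
    perm <- seq_len(n)
    for (t in names(graph$n_t)) {
      sel <- which(types == t)
      perm[sel] <- sel[sample.int(length(sel))]
    }
    x_rows[[e]] <- xe[perm, , drop = FALSE]
    pos <- c(pos, perm)
    meta[[e]] <- data.frame(
      cell_id = sprintf("e%d_c%02d", e, seq_len(n)),
      embryo_id = paste0("e", e), stage = n,
      cell_type = unname(types[perm]), stringsAsFactors = FALSE)
  }
  if (n_embryos == 0) {
    x <- matrix(numeric(0), 0, k)
    cells <- data.frame(cell_id = character(0), embryo_id = character(0),
                        stage = integer(0), cell_type = character(0))
  } else {
    x <- do.call(rbind, x_rows)
    cells <- do.call(rbind, meta)
  }
  noise <- matrix(stats::rnorm(length(x), sd = max(eps_scale, 0)),
                  nrow(x), k)
  if (eps_scale == 0) noise[] <- 0
  X_obs <- x + noise
  colnames(X_obs) <- paste0("PC", seq_len(k))
  post <- expression_posterior(X_obs,
                               matrix(eps_scale, nrow(x), k),
                               cells, paste0("PC", seq_len(k)))
  structure(list(posterior = post, x = X_obs,
                 type_of = stats::setNames(cells$cell_type, cells$cell_id),
                 embryo_of = stats::setNames(cells$embryo_id, cells$cell_id),
                 truth = list(x_true = truth_x, position_of = pos,
                              model = model)),
            class = "synthetic_dataset")
}

#' Add structured mean components to a synthetic dataset
#'
#' Adds the known variance sources of the decomposition model to the latent
#' signal: a cell-type mean `mu_t`, a developmental-staging term
#' `tau_e * alpha_t` (per-embryo time of SD `tau_sd` along a type tangent
#' `alpha`), and maternal-style mother and embryo means (`nu_m` of SD
#' `nu_sd`, `eta_e` of SD `eta_sd`). All drawn components are recorded in
#' `truth`.
#'
#' @param dataset a [sample_embryos()] result.
#' @param mu type x PC matrix of type means (default 0).
#' @param tau_sd SD of the per-embryo time (default 0).
#' @param alpha type x PC tangent matrix (unit Frobenius norm recommended).
#' @param mother_of named map embryo -> mother (default: one mother per
#'   embryo).
#' @param nu_sd,eta_sd SDs of mother and embryo mean effects (default 0).
#' @param seed RNG seed.
#' @return the dataset with updated expression and recorded truth.
#' @export
add_structured_means <- function(dataset, mu = NULL, tau_sd = 0,
                                 alpha = NULL, mother_of = NULL,
                                 nu_sd = 0, eta_sd = 0, seed = 1) {
  set.seed(seed)
  k <- ncol(dataset$x)
  types <- sort(unique(dataset$type_of))
  embryos <- unique(dataset$embryo_of)
  if (is.null(mu))
    mu <- matrix(0, length(types), k, dimnames = list(types, NULL))
  if (is.null(alpha))
    alpha <- matrix(0, length(types), k, dimnames = list(types, NULL))
  if (is.null(mother_of))
    mother_of <- stats::setNames(paste0("m_", embryos), embryos)
  mothers <- unique(mother_of)
  tau <- stats::setNames(stats::rnorm(length(embryos), sd = tau_sd), embryos)
  if (tau_sd > 0) tau <- tau - mean(tau)
  nu <- matrix(stats::rnorm(length(mothers) * k, sd = nu_sd),
               length(mothers), k, dimnames = list(mothers, NULL))
  eta <- matrix(stats::rnorm(length(embryos) * k, sd = eta_sd),
                length(embryos), k, dimnames = list(embryos, NULL))
  t_idx <- match(dataset$type_of, types)
  e_idx <- match(dataset$embryo_of, embryos)
  m_idx <- match(mother_of[dataset$embryo_of], mothers)
  add <- mu[t_idx, , drop = FALSE] +
    tau[e_idx] * alpha[t_idx, , drop = FALSE] +
    nu[m_idx, , drop = FALSE] + eta[e_idx, , drop = FALSE]
  dataset$x <- dataset$x + add
  dataset$posterior$X <- dataset$posterior$X + add
  dataset$truth$mu <- mu
  dataset$truth$tau <- tau
  dataset$truth$alpha <- alpha
  dataset$truth$nu <- nu
  dataset$truth$eta <- eta
  dataset$truth$mother_of <- mother_of
  dataset
}

#' Simulate transcript counts with type-specific expression profiles
#'
#' Per cell, gene rates are the cell type's relative expression profile
#' scaled to the sequencing `depth`, modulated by a mean-one log-normal
#' factor of log-SD `dispersion`; counts are Poisson draws around those
#' rates (a log-normal-Poisson mixture).
#'
#' @param graph an [embryo_graph()].
#' @param type_profiles type x gene matrix of positive relative expression.
#' @param depth expected total reads per cell.
#' @param dispersion log-normal SD of the per-entry rate (default 0).
#' @param n_embryos number of embryos.
#' @param seed RNG seed.
#' @return a [count_matrix()] with populated metadata (stage = cell count;
#'   `cell_type` filled with the true type).
#' @export
simulate_counts <- function(graph, type_profiles, depth, dispersion = 0,
                            n_embryos, seed = 1) {
  abort_if(any(type_profiles <= 0), "profiles must be positive")
  set.seed(seed)
  n <- length(graph$cell_names)
  genes <- colnames(type_profiles)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(type_profiles)))
  rows <- list(); meta <- list()
  r <- 0L
  for (e in seq_len(n_embryos)) {
    for (p in seq_len(n)) {
      r <- r + 1L
      t <- graph$type_of[[p]]
      pr <- type_profiles[t, ] / sum(type_profiles[t, ])
      rate <- depth * pr
      if (dispersion > 0)
        rate <- rate * exp(stats::rnorm(length(rate), sd = dispersion) -
                             dispersion^2 / 2)
      rows[[r]] <- stats::rpois(length(rate), rate)
      meta[[r]] <- data.frame(
        cell_id = sprintf("e%d_%s", e, graph$cell_names[p]),
        embryo_id = paste0("e", e), stage = n,
        cell_type = t, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- genes
  count_matrix(counts, do.call(rbind, meta), genes)
}

#' Marker-gene expression profiles for a graph's cell types
#'
#' Builds a type x gene effect matrix: every type gets `markers_per_type`
#' unique marker genes at height `effect`; optionally, groups of types share
#' an additional set of markers (giving the hierarchy a coarse split before
#' the fine one, as in real differentiation). Background is 0.
#'
#' @param graph an [embryo_graph()].
#' @param effect marker height in log-expression units (default 1).
#' @param markers_per_type unique markers per type (default 3).
#' @param shared_groups optional list of character vectors of type names
#'   that share `markers_per_type` extra markers.
#' @return type x gene matrix.
#' @export
marker_profiles <- function(graph, effect = 1, markers_per_type = 3,
                            shared_groups = NULL) {
  types <- names(graph$n_t)
  n_shared <- length(shared_groups)
  n_genes <- markers_per_type * (length(types) + n_shared)
  prof <- matrix(0, length(types), n_genes,
                 dimnames = list(types, paste0("g", seq_len(n_genes))))
  g <- 0L
  for (t in types) {
    prof[t, g + seq_len(markers_per_type)] <- effect
    g <- g + markers_per_type
  }
  for (grp in shared_groups) {
    prof[grp, g + seq_len(markers_per_type)] <- effect
    g <- g + markers_per_type
  }
  prof
}

#' Simulate an expression posterior with planted cell types
#'
#' Each cell's expression is its type's marker profile plus independent
#' Gaussian noise of SD `noise_sd`; the posterior honestly reports
#' `eps = noise_sd`. The direct input for cell-typing tests with a known
#' marker-effect-to-noise ratio.
#'
#' @param graph an [embryo_graph()].
#' @param profiles type x gene matrix (e.g. [marker_profiles()]).
#' @param noise_sd per-entry noise SD.
#' @param n_embryos number of embryos.
#' @param seed RNG seed.
#' @return an [expression_posterior()] with true types in the metadata.
#' @export
simulate_expression_posterior <- function(graph, profiles, noise_sd,
                                          n_embryos, seed = 1) {
  set.seed(seed)
  n <- length(graph$cell_names)
  genes <- colnames(profiles)
  meta <- list(); rows <- list()
  r <- 0L
  for (e in seq_len(n_embryos)) {
    for (p in seq_len(n)) {
      r <- r + 1L
      t <- graph$type_of[[p]]
      rows[[r]] <- profiles[t, ] + stats::rnorm(ncol(profiles),
                                                sd = noise_sd)
      meta[[r]] <- data.frame(
        cell_id = sprintf("e%d_%s", e, graph$cell_names[p]),
        embryo_id = paste0("e", e), stage = n, cell_type = t,
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- genes
  expression_posterior(X, matrix(noise_sd, nrow(X), ncol(X)),
                       do.call(rbind, meta), genes)
}
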