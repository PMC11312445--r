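# Empirical intra-/inter-type covariance statistics on the retained PCs,
# with posterior-resampling + bootstrap uncertainty, and the shuffle test for
# collective (inter-cell) variation.

cov_prep <- function(type_of, embryo_of) {
  type_of <- as.character(type_of); embryo_of <- as.character(embryo_of)
  embryos <- sort(unique(embryo_of))
  types <- sort(unique(type_of))
  idx <- lapply(embryos, function(e) {
    lapply(stats::setNames(types, types), function(t)
      which(embryo_of == e & type_of == t))
  })
  names(idx) <- embryos
  list(embryos = embryos, types = types, idx = idx)
}

#' Intra-type covariance of the projected expression
#'
#' Per cell type t, the within-cell covariance
#' `C^t_ij = mean over cells of type t of x_ci x_cj`, where the expectation
#' is taken as the average over embryos of the within-embryo cell average.
#' `x` must already be a zero-mean residual.
#'
#' @param x cells x PC matrix of residual expression.
#' @param type_of,embryo_of per-cell labels.
#' @return named list of symmetric PC x PC matrices, one per type.
#' @export
intra_type_cov <- function(x, type_of, embryo_of) {
  prep <- cov_prep(type_of, embryo_of)
  intra_from_perm(x, prep, seq_len(nrow(x)))
}

intra_from_perm <- function(x, prep, perm) {
  k <- ncol(x)
  out <- lapply(stats::setNames(prep$types, prep$types), function(t) {
    acc <- matrix(0, k, k); n_emb <- 0L
    for (e in prep$embryos) {
      ii <- perm[prep$idx[[e]][[t]]]
      if (length(ii) == 0) next
      xe <- x[ii, , drop = FALSE]
      acc <- acc + crossprod(xe) / nrow(xe)
      n_emb <- n_emb + 1L
    }
    abort_if(n_emb == 0L, "type %s has no cells", t)
    acc / n_emb
  })
  out
}

#' Inter-type (cell-cell) covariance of the projected expression
#'
#' For cell types t, t' the average covariance between a cell of type t and a
#' different cell of type t' in the same embryo,
#' `gamma^tt'_ij = < x_ci x_c'j >` averaged over distinct cell pairs within
#' an embryo and then over embryos. Same-type entries (t = t') exclude the
#' c = c' pairs. Satisfies `gamma^tt'_ij = gamma^t't_ji` exactly.
#'
#' @inheritParams intra_type_cov
#' @return named list over ordered type pairs `"t|t'"` of PC x PC matrices;
#'   pairs never co-present in any embryo are `NULL` (flagged missing).
#' @export
inter_type_cov <- function(x, type_of, embryo_of) {
  prep <- cov_prep(type_of, embryo_of)
  inter_from_perm(x, prep, seq_len(nrow(x)))
}

inter_from_perm <- function(x, prep, perm) {
  k <- ncol(x)
  types <- prep$types
  nt <- length(types)
  out <- list()
  for (a in seq_len(nt)) {
    for (b in a:nt) {
      t1 <- types[a]; t2 <- types[b]
      acc <- matrix(0, k, k); n_emb <- 0L
      for (e in prep$embryos) {
        i1 <- perm[prep$idx[[e]][[t1]]]
        i2 <- perm[prep$idx[[e]][[t2]]]
        if (t1 == t2) {
          n1 <- length(i1)
          if (n1 < 2) next
          s <- colSums(x[i1, , drop = FALSE])
          acc <- acc + (outer(s, s) - crossprod(x[i1, , drop = FALSE])) /
            (n1 * (n1 - 1))
        } else {
          if (length(i1) == 0 || length(i2) == 0) next
          s1 <- colSums(x[i1, , drop = FALSE])
          s2 <- colSums(x[i2, , drop = FALSE])
          acc <- acc + outer(s1, s2) / (length(i1) * length(i2))
        }
        n_emb <- n_emb + 1L
      }
      key <- paste(t1, t2, sep = "|")
      if (n_emb == 0L) {
        out[key] <- list(NULL)  # flagged missing
      } else {
        out[[key]] <- acc / n_emb
        if (t1 != t2) out[[paste(t2, t1, sep = "|")]] <- t(acc / n_emb)
      }
    }
  }
  out
}

#' Bundle intra- and inter-type covariances into a covariance set
#' @param intra,inter outputs of [intra_type_cov()] / [inter_type_cov()].
#' @param draws optional list of `list(intra=, inter=)` replicates.
#' @return object of class `covariance_set`.
#' @export
covariance_set <- function(intra, inter, draws = NULL) {
  structure(list(intra = intra, inter = inter, draws = draws),
            class = "covariance_set")
}

#' Flatten a covariance set into a named vector of unique components
#'
#' Intra components are `t:i:j` with i <= j; inter components `t|t':i:j`
#' with t <= t' (all i, j for t < t'; i <= j for the symmetric t = t' case).
#'
#' @param cs a [covariance_set()].
#' @param include_intra include the within-cell `C^t` components
#'   (default TRUE).
#' @return named numeric vector.
#' @export
flatten_covset <- function(cs, include_intra = TRUE) {
  out <- numeric(0)
  if (include_intra) {
    for (t in names(cs$intra)) {
      C <- cs$intra[[t]]
      k <- nrow(C)
      for (i in seq_len(k)) for (j in i:k)
        out[[sprintf("C:%s:%d:%d", t, i, j)]] <- C[i, j]
    }
  }
  seen <- character(0)
  for (key in names(cs$inter)) {
    g <- cs$inter[[key]]
    if (is.null(g)) next
    tt <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (tt[1] > tt[2]) next  # keep t <= t' representative
    k <- nrow(g)
    for (i in seq_len(k)) {
      jj <- if (tt[1] == tt[2]) i:k else seq_len(k)
      for (j in jj)
        out[[sprintf("g:%s:%d:%d", key, i, j)]] <- g[i, j]
    }
    seen <- c(seen, key)
  }
  out
}

#' Covariance estimates with posterior-resampling and bootstrap uncertainty
#'
#' Each replicate pairs one draw from the expression posterior with one
#' bootstrap resample of whole embryos (with replacement; resampled embryos
#' are relabeled so copies stay distinct). The point estimate is the mean
#' over replicates; percentile intervals can be read off the stored draws.
#'
#' @param post an [expression_posterior()] of the residual expression, or a
#'   function `(seed) -> cells x PC matrix` generating one projected draw.
#' @param type_of per-cell type labels (named by cell id or in row order).
#' @param n_draws number of posterior draws (default 100).
#' @param n_boot bootstrap resamples per draw (default 1).
#' @param bootstrap set FALSE to disable embryo resampling.
#' @param seed root seed; substreams are derived per replicate.
#' @param pcs optional genes x PC loading matrix; each posterior draw is
#'   projected onto it (draws of an unprojected posterior).
#' @param embryo_of embryo labels (default: posterior metadata).
#' @return a [covariance_set()] with `draws` populated.
#' @export
resample_covariances <- function(post, type_of, n_draws = 100, n_boot = 1,
                                 bootstrap = TRUE, seed = 1, pcs = NULL,
                                 embryo_of = NULL) {
  if (inherits(post, "expression_posterior") && is.null(embryo_of))
    embryo_of <- post$cells$embryo_id
  embryo_of <- as.character(embryo_of)
  if (!is.null(names(type_of)) && inherits(post, "expression_posterior"))
    type_of <- type_of[post$cells$cell_id]
  type_of <- as.character(type_of)
  embryos <- unique(embryo_of)
  if (bootstrap && length(embryos) < 3)
    warning("fewer than 3 embryos: bootstrap intervals unreliable")
  if (n_draws * n_boot < 2)
    warning("fewer than 2 replicates: no intervals")
  draws <- list()
  r <- 0L
  for (d in seq_len(n_draws)) {
    xd <- if (is.function(post)) {
      post(substream_seed(seed, paste0("resample_draw_", d)))
    } else {
      sample_posterior(post, substream_seed(seed, paste0("resample_draw_", d)))
    }
    if (!is.null(pcs)) xd <- xd %*% pcs
    for (b in seq_len(n_boot)) {
      r <- r + 1L
      if (bootstrap) {
        set.seed(substream_seed(seed, paste0("resample_boot_", d, "_", b)))
        picked <- sample(embryos, length(embryos), replace = TRUE)
        rows <- unlist(lapply(seq_along(picked), function(i)
          which(embryo_of == picked[i])))
        emb_b <- unlist(lapply(seq_along(picked), function(i)
          rep(paste0("b", i), sum(embryo_of == picked[i]))))
        xb <- xd[rows, , drop = FALSE]
        ty_b <- type_of[rows]
      } else {
        xb <- xd; ty_b <- type_of; emb_b <- embryo_of
      }
      draws[[r]] <- list(intra = intra_type_cov(xb, ty_b, emb_b),
                         inter = inter_type_cov(xb, ty_b, emb_b))
    }
  }
  # point estimate: componentwise mean over replicates
  avg_list <- function(field) {
    keys <- names(draws[[1]][[field]])
    out <- stats::setNames(vector("list", length(keys)), keys)
    for (key in keys) {
      mats <- lapply(draws, function(dr) dr[[field]][[key]])
      mats <- mats[!vapply(mats, is.null, logical(1))]
      if (length(mats) == 0) { out[key] <- list(NULL); next }
      out[[key]] <- Reduce(`+`, mats) / length(mats)
    }
    out
  }
  covariance_set(avg_list("intra"), avg_list("inter"), draws = draws)
}

#' Shuffle test for collective variation (the Delta statistic)
#'
#' Compares the observed inter-type covariances against shuffled data.
#' Mode `"across"` permutes cells of the same cell type between embryos
#' (destroying within-embryo coupling while preserving each embryo's per-type
#' cell counts); mode `"within"` permutes cell labels among the cells of each
#' embryo (destroying spatial structure while preserving each embryo's
#' multiset of expression rows). Over the `n_shuffles` shuffled covariance
#' vectors plus the observed one, the componentwise mean `gamma_bar` and SD
#' `sigma` are computed, and each configuration's deviation is
#' `Delta = sum_comp ((gamma - gamma_bar) / sigma)^2`. The permutation
#' p-value is `(1 + #[Delta_null >= Delta_obs]) / (n_shuffles + 1)`.
#'
#' @param x cells x PC residual matrix.
#' @param type_of,embryo_of per-cell labels.
#' @param mode `"across"` or `"within"`.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed RNG seed.
#' @param include_intra_pairs include same-type (t = t') inter-cell
#'   components in Delta (default TRUE: all measured cell-pair covariances
#'   enter the deviation).
#' @return object of class `shuffle_test_result`: `delta_observed`,
#'   `delta_null`, `p_value`, `mode`, `gamma_bar`, `sigma`.
#' @export
shuffle_test <- function(x, type_of, embryo_of, mode = c("across", "within"),
                         n_shuffles = 100, seed = 1,
                         include_intra_pairs = TRUE) {
  mode <- match.arg(mode)
  prep <- cov_prep(type_of, embryo_of)
  n <- nrow(x)
  set.seed(seed)

  components <- function(perm) {
    g <- inter_from_perm(x, prep, perm)
    cs <- covariance_set(NULL, g)
    v <- flatten_covset(cs, include_intra = FALSE)
    if (!include_intra_pairs) {
      keep <- !grepl("^g:([^|]+)\\|\\1:", names(v))
      v <- v[keep]
    }
    v
  }

  type_slots <- lapply(stats::setNames(prep$types, prep$types), function(t)
    which(as.character(type_of) == t))
  embryo_slots <- lapply(stats::setNames(prep$embryos, prep$embryos),
                         function(e) which(as.character(embryo_of) == e))

  make_perm <- function() {
    perm <- seq_len(n)
    if (mode == "across") {
      for (t in prep$types) {
        s <- type_slots[[t]]
        perm[s] <- s[sample.int(length(s))]
      }
    } else {
      for (e in prep$embryos) {
        s <- embryo_slots[[e]]
        perm[s] <- s[sample.int(length(s))]
      }
    }
    perm
  }

  obs <- components(seq_len(n))
  nulls <- matrix(NA_real_, n_shuffles, length(obs),
                  dimnames = list(NULL, names(obs)))
  for (s in seq_len(n_shuffles)) nulls[s, ] <- components(make_perm())

  all_cfg <- rbind(obs, nulls)
  gamma_bar <- colMeans(all_cfg)
  sigma <- apply(all_cfg, 2, stats::sd)
  ok <- sigma > 0
  if (!all(ok))
    warning(sprintf("%d zero-variance component(s) dropped from Delta",
                    sum(!ok)))
  delta_of <- function(v) sum(((v[ok] - gamma_bar[ok]) / sigma[ok])^2)
  delta_obs <- delta_of(obs)
  delta_null <- apply(nulls, 1, delta_of)
  p <- (1 + sum(delta_null >= delta_obs)) / (n_shuffles + 1)
  structure(list(delta_observed = delta_obs, delta_null = delta_null,
                 p_value = p, mode = mode, gamma_bar = gamma_bar,
                 sigma = sigma),
            class = "shuffle_test_result")
}

# Delta for a single covariance vector against given ensemble moments
# (exposed for unit arithmetic checks).
delta_statistic <- function(gamma, gamma_bar, sigma) {
  ok <- sigma > 0
  sum(((gamma[ok] - gamma_bar[ok]) / sigma[ok])^2)
}
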