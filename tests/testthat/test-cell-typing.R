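test_that("informative-gene ranking finds discriminating genes", {
  set.seed(31)
  n <- 24
  trial <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  X[trial == "b", 3] <- X[trial == "b", 3] + 5  # one bimodal gene
  info <- find_informative_genes(X, trial, top_k = 3)
  expect_equal(info$gene[1], "g3")

  # ranking invariant to gene column order
  perm <- c(4, 3, 1, 6, 2, 5)
  info2 <- find_informative_genes(X[, perm], trial, top_k = 3)
  expect_equal(info2$gene[1], "g3")

  # pure noise: scores match the permuted-label distribution (no gene
  # stands out beyond what label permutation produces)
  X0 <- matrix(rnorm(n * 20), n, 20)
  obs <- find_informative_genes(X0, trial, top_k = 20)$score
  null_max <- vapply(1:30, function(i)
    max(find_informative_genes(X0, sample(trial), top_k = 20)$score),
    numeric(1))
  expect_lt(max(obs), quantile(null_max, 0.99) + 1)

  # constant genes cannot be informative
  Xc <- matrix(1, n, 3)
  expect_warning(infc <- find_informative_genes(Xc, trial), "no informative")
  expect_equal(nrow(infc), 0)
})

test_that("balanced clustering enforces per-embryo balance and recovers types", {
  # 2 embryos x 4 cells from two well-separated centers -> ARI = 1, balanced
  set.seed(32)
  centers <- rbind(c(0, 0), c(6, 6))
  truth <- rep(c(1, 2, 1, 2), 2)
  X <- centers[truth, ] + matrix(rnorm(16, sd = 0.3), 8, 2)
  emb <- rep(c("e1", "e2"), each = 4)
  cl <- structured_cluster(X, emb, 2)
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
  tab <- table(cl$cluster, emb)
  expect_true(all(tab == 2))  # 2 cells per cluster in every embryo
  expect_false(cl$low_separation)

  # identical cells: converges, balanced, flagged low-separation
  Xd <- matrix(1, 8, 2)
  cld <- structured_cluster(Xd, emb, 2)
  expect_true(all(table(cld$cluster, emb) == 2))
  expect_true(cld$low_separation)

  # k incompatible with embryo size
  expect_error(structured_cluster(X, emb, 3), "slot allocation")
})

test_that("the assignment solver agrees with the igraph matching oracle", {
  set.seed(33)
  for (i in 1:40) {
    nr <- sample(2:7, 1)
    nc <- nr + sample(0:2, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    a <- embryomodes:::min_cost_assignment(cost)
    b <- embryomodes:::assignment_igraph(cost)
    expect_equal(anyDuplicated(a), 0)
    expect_equal(sum(cost[cbind(seq_len(nr), a)]),
                 sum(cost[cbind(seq_len(nr), b)]), tolerance = 1e-9)
  }
})

test_that("consistency scoring separates real splits from noise", {
  g <- make_topology("toy4")
  # 6 embryos x 4 cells, two planted types at strong separation
  prof <- marker_profiles(g, effect = 1.5, markers_per_type = 3)
  post <- simulate_expression_posterior(g, prof, 0.2, 6, seed = 34)
  emb <- post$cells$embryo_id
  set.seed(35)
  ref <- embryomodes:::cluster_once(post$X, emb, 2, 10)
  cs <- suppressWarnings(consistency_score(post, ref$cluster, 2,
                                           n_resamples = 10, n_null = 8,
                                           seed = 36))
  expect_gt(cs$score, 0.9)
  expect_true(cs$accepted)
  expect_true(all(cs$null_scores <= 1))

  # perfectly separated clusters with eps = 0 and no real perturbation
  # reproduce exactly (score 1 at full subsampling)
  post0 <- simulate_expression_posterior(g, prof, 0, 6, seed = 37)
  post0$eps[] <- 0
  ref0 <- embryomodes:::cluster_once(post0$X, post0$cells$embryo_id, 2, 10)
  cs0 <- suppressWarnings(consistency_score(post0, ref0$cluster, 2,
                                            n_resamples = 5, n_null = 4,
                                            subsample_frac = 1, seed = 38))
  expect_equal(cs0$score, 1)
})

test_that("hierarchical typing is deterministic and names planted types", {
  g <- make_topology("mirror16")
  prof <- marker_profiles(g, effect = 1, markers_per_type = 3,
                          shared_groups = list(c("t2", "t3")))
  post <- simulate_expression_posterior(g, prof, 0.25, 6, seed = 39)
  cfg <- typing_config(n_resamples = 12, n_null = 8, seed = 40)
  a1 <- suppressWarnings(hierarchical_typing(post, cfg))
  a2 <- suppressWarnings(hierarchical_typing(post, cfg))
  expect_identical(a1$type_of, a2$type_of)
  expect_equal(adjusted_rand_index(a1$type_of, post$cells$cell_type), 1)

  # marker-based identity assignment labels each leaf by its own markers
  markers <- data.frame(
    identity = rep(paste0("id_", names(g$n_t)), each = 2),
    gene = as.vector(vapply(seq_along(g$n_t), function(i)
      paste0("g", (i - 1) * 3 + 1:2), character(2))),
    stringsAsFactors = FALSE)
  named <- assign_identities(a1, markers, post)
  expect_equal(sort(unique(named$type_of)), sort(paste0("id_", names(g$n_t))))
  ok <- vapply(seq_len(nrow(post$X)), function(i)
    named$type_of[[i]] == paste0("id_", post$cells$cell_type[i]), logical(1))
  expect_true(all(ok))

  # empty marker table -> everything unassigned
  un <- assign_identities(a1, NULL, post)
  expect_true(all(un$type_of == "unassigned"))
})
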