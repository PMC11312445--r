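test_that("topology fixtures satisfy their structural invariants", {
  g16 <- make_topology("mirror16")
  expect_length(g16$cell_names, 16)
  expect_equal(sort(as.vector(g16$n_t)), c(2, 2, 4, 4, 4))
  expect_symmetric(g16$contact)
  expect_equal(sum(g16$n_t), 16)
  # mirror involutive, 8 pairs
  expect_true(all(vapply(g16$cell_names, function(p)
    g16$mirror[[g16$mirror[[p]]]] == p, logical(1))))
  expect_equal(length(unique(vapply(g16$cell_names, function(p)
    paste(sort(c(p, g16$mirror[[p]])), collapse = "|"), character(1)))), 8)
  # contact map is mirror-symmetric
  for (p in g16$cell_names) for (q in g16$cell_names)
    expect_equal(g16$contact[p, q],
                 g16$contact[g16$mirror[[p]], g16$mirror[[q]]])

  g4 <- make_topology("toy4")
  expect_length(g4$cell_names, 4)
  expect_equal(sum(g4$contact) / 2, 3)

  g32 <- make_topology("mirror32")
  expect_length(g32$cell_names, 32)
  expect_equal(sum(g32$n_t), 32)

  expect_error(make_topology("nope"), "unknown")

  # mirror-pair refinement: one type per mirror orbit
  fine <- mirror_pair_types(g16)
  expect_length(fine$n_t, 8)
  expect_true(all(fine$n_t == 2))
})

test_that("sampled embryos follow the model law with recorded truth", {
  g <- make_topology("toy4")
  m <- coupled_model(g, 2)
  Sigma <- chol2inv(chol(m$J))

  # empirical covariance of the unscrambled truth matches J^-1 within
  # 4 Monte-Carlo standard errors
  n <- 4000
  ds <- sample_embryos(m, n, seed = 41)
  emp <- matrix(0, 8, 8)
  for (e in seq_len(n)) {
    v <- as.vector(t(ds$truth$x_true[[e]]))
    emp <- emp + outer(v, v)
  }
  emp <- emp / n
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n)
  expect_true(all(abs(emp - Sigma) < 4 * se + 1e-12))

  # scrambling stays within type; truth records the permutation
  expect_true(all(ds$type_of ==
                    g$type_of[ds$truth$position_of]))
  # empty dataset
  ds0 <- sample_embryos(m, 0, seed = 1)
  expect_equal(nrow(ds0$x), 0)
  # seed reproducibility
  expect_equal(sample_embryos(m, 3, seed = 7)$x,
               sample_embryos(m, 3, seed = 7)$x)
})

test_that("structured mean components are planted as recorded", {
  g <- make_topology("toy4")
  m <- uncoupled_model(g, 2)
  ds <- sample_embryos(m, 200, seed = 42)

  # no-op when all components vanish
  same <- add_structured_means(ds, seed = 1)
  expect_equal(same$x, ds$x)

  types <- sort(unique(ds$type_of))
  mu <- matrix(c(3, -3, 0, 0), 2, 2, dimnames = list(types, NULL))
  alpha <- matrix(rnorm(4), 2, 2, dimnames = list(types, NULL))
  ds2 <- add_structured_means(ds, mu = mu, tau_sd = 0.5, alpha = alpha,
                              nu_sd = 0.3, eta_sd = 0.2, seed = 43)
  # recorded tau has roughly the requested spread (n = 200 embryos)
  expect_lt(abs(sd(ds2$truth$tau) - 0.5) / 0.5, 0.15)
  # group means of the generated data match the planted components
  tA <- ds2$x[ds2$type_of == "tA", 1]
  shift <- mean(tA) - mean(ds$x[ds$type_of == "tA", 1])
  expect_lt(abs(shift - 3 - mean(ds2$truth$nu[, 1]) -
                  mean(ds2$truth$eta[, 1])), 0.15)
})

test_that("simulated counts track type profiles at the requested depth", {
  g <- make_topology("toy4")
  prof <- rbind(tA = c(8, 1, 1), tB = c(1, 8, 1))
  colnames(prof) <- paste0("g", 1:3)
  cm <- simulate_counts(g, prof, depth = 5e4, dispersion = 0,
                        n_embryos = 4, seed = 44)
  fr <- colSums(cm$counts[cm$cells$cell_type == "tA", ]) /
    sum(cm$counts[cm$cells$cell_type == "tA", ])
  expect_lt(max(abs(fr - prof["tA", ] / sum(prof["tA", ]))), 0.02)

  # depth 0 -> all-zero counts; seeds reproduce
  cm0 <- simulate_counts(g, prof, depth = 0, dispersion = 0,
                         n_embryos = 1, seed = 1)
  expect_true(all(cm0$counts == 0))
  expect_equal(simulate_counts(g, prof, 100, 0.3, 2, seed = 9)$counts,
               simulate_counts(g, prof, 100, 0.3, 2, seed = 9)$counts)
  expect_error(simulate_counts(g, prof * 0, 100, 0, 1, 1), "positive")
})

test_that("marker posteriors plant the advertised effect-to-noise ratio", {
  g <- make_topology("mirror16")
  prof <- marker_profiles(g, effect = 1, markers_per_type = 3,
                          shared_groups = list(c("t2", "t3")))
  expect_equal(dim(prof), c(5L, 18L))
  # shared block expressed in both t2 and t3
  shared_cols <- which(colSums(prof > 0) == 2)
  expect_length(shared_cols, 3)

  post <- simulate_expression_posterior(g, prof, noise_sd = 0.25,
                                        n_embryos = 4, seed = 45)
  expect_equal(nrow(post$X), 64)
  expect_true(all(post$eps == 0.25))
  t1cells <- post$cells$cell_type == "t1"
  expect_lt(abs(mean(post$X[t1cells, 1]) - 1), 0.1)
})
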