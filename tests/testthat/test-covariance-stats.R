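test_that("intra- and inter-type covariances match hand arithmetic", {
  # one embryo, t = {x = 1, x = -1}, t' = {x = 2}:
  # gamma = (1*2 + (-1)*2) / 2 = 0
  x <- matrix(c(1, -1, 2), 3, 1)
  g <- inter_type_cov(x, c("t", "t", "u"), rep("e1", 3))
  expect_equal(g[["t|u"]][1, 1], 0)
  # transpose symmetry holds exactly
  expect_equal(g[["u|t"]], t(g[["t|u"]]))

  # single cell x = (1, 2): C = outer product
  C <- intra_type_cov(matrix(c(1, 2), 1, 2), "t", "e1")
  expect_equal(C$t, matrix(c(1, 2, 2, 4), 2, 2))

  # all-zero expression -> all-zero statistics
  x0 <- matrix(0, 4, 2)
  expect_equal(intra_type_cov(x0, rep("t", 4), rep("e1", 4))$t,
               matrix(0, 2, 2))
  expect_equal(inter_type_cov(x0, rep(c("t", "u"), 2),
                              rep("e1", 4))[["t|u"]], matrix(0, 2, 2))

  # C is an average of outer products: symmetric positive semidefinite
  set.seed(8)
  xr <- matrix(rnorm(40), 20, 2)
  Cr <- intra_type_cov(xr, rep("t", 20), rep(paste0("e", 1:5), each = 4))$t
  expect_symmetric(Cr)
  expect_gte(min(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values), 0)

  # a type pair never co-present in an embryo is flagged missing
  gm <- inter_type_cov(matrix(rnorm(4), 4, 1), c("t", "t", "u", "u"),
                       c("e1", "e1", "e2", "e2"))
  expect_null(gm[["t|u"]])
})

test_that("empirical estimators agree with the model on many samples", {
  # inter/intra estimators applied to draws from a known Gaussian converge
  # to the model-predicted type-level covariances
  g <- make_topology("toy4")
  m <- coupled_model(g, 2)
  ds <- sample_embryos(m, 3000, seed = 21)
  emp_intra <- intra_type_cov(ds$x, ds$type_of, ds$embryo_of)
  emp_inter <- inter_type_cov(ds$x, ds$type_of, ds$embryo_of)
  pred <- predict_type_covariances(m)
  for (t in names(pred$intra))
    expect_lt(max(abs(emp_intra[[t]] - pred$intra[[t]])), 0.15)
  for (k in names(pred$inter))
    expect_lt(max(abs(emp_inter[[k]] - pred$inter[[k]])), 0.15)
})

test_that("resampled covariances are reproducible and honest about noise", {
  g <- make_topology("toy4")
  m <- uncoupled_model(g, 2)
  ds <- sample_embryos(m, 6, eps_scale = 0.3, seed = 3)
  cv1 <- resample_covariances(ds$posterior, ds$type_of, n_draws = 5, seed = 9)
  cv2 <- resample_covariances(ds$posterior, ds$type_of, n_draws = 5, seed = 9)
  expect_equal(cv1$intra, cv2$intra)
  expect_length(cv1$draws, 5)

  # eps = 0 and bootstrap disabled -> every draw identical
  ds0 <- sample_embryos(m, 6, eps_scale = 0, seed = 3)
  cv0 <- suppressWarnings(resample_covariances(
    ds0$posterior, ds0$type_of, n_draws = 3, bootstrap = FALSE, seed = 1))
  expect_equal(cv0$draws[[1]], cv0$draws[[3]])

  # draw-to-draw spread shrinks roughly like 1/sqrt(n_embryos)
  spread <- vapply(c(8, 32), function(ne) {
    dsn <- sample_embryos(m, ne, eps_scale = 0.3, seed = 5)
    cv <- resample_covariances(dsn$posterior, dsn$type_of, n_draws = 25,
                               seed = 7)
    sd(vapply(cv$draws, function(d) d$inter[["tA|tB"]][1, 1], numeric(1)))
  }, numeric(1))
  expect_gt(spread[1] / spread[2], 1.3)  # expect ~2, allow slack
})

test_that("the Delta statistic and shuffle bookkeeping behave as defined", {
  # single component, gamma = 2, gamma_bar = 1, sigma = 0.5 -> Delta = 4
  expect_equal(embryomodes:::delta_statistic(2, 1, 0.5), 4)
  # gamma = gamma_bar componentwise -> Delta = 0
  expect_equal(embryomodes:::delta_statistic(c(1, 2), c(1, 2), c(1, 1)), 0)

  g <- make_topology("mirror16")
  ds <- sample_embryos(coupled_model(g, 2), 8, seed = 13)
  st <- shuffle_test(ds$x, ds$type_of, ds$embryo_of, "across",
                     n_shuffles = 30, seed = 14)
  expect_s3_class(st, "shuffle_test_result")
  expect_gte(st$delta_observed, 0)
  expect_true(st$p_value > 0 && st$p_value <= 1)
  expect_length(st$delta_null, 30)

  # within-mode and across-mode are both deterministic under a seed
  st2 <- shuffle_test(ds$x, ds$type_of, ds$embryo_of, "across",
                      n_shuffles = 30, seed = 14)
  expect_equal(st$delta_null, st2$delta_null)
})

test_that("coupled data are detected, uncoupled data are not (smoke)", {
  g <- make_topology("mirror16")
  dsc <- sample_embryos(coupled_model(g, 2), 14, seed = 2)
  stc <- shuffle_test(dsc$x, dsc$type_of, dsc$embryo_of, "across",
                      n_shuffles = 100, seed = 3)
  expect_lt(stc$p_value, 0.05)
})
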