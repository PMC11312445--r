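test_that("J assembly matches the coupling formula entry by entry", {
  g <- pair_graph()

  # no interactions, identity within-cell couplings -> J = identity
  sp0 <- constraint_spec(g)
  J0 <- build_J(M = list(t = diag(2)), spec = sp0, graph = g, n_pc = 2)
  expect_equal(J0, diag(4))

  # 2 cells, 1 PC, M = 1, symmetric coupling s on the edge
  sp1 <- constraint_spec(g, sym_terms = list(edge = matrix(c(0, 1, 1, 0),
                                                           2, 2)))
  J1 <- build_J(M = list(t = matrix(1)), S = list(edge = matrix(0.5)),
                spec = sp1, graph = g, n_pc = 1)
  expect_equal(J1, matrix(c(1, 0.5, 0.5, 1), 2, 2))

  # directed term: Omega_12 = 1 only, U = [[0, u], [0, 0]] ->
  # J_(1,PC1)(2,PC2) = u/2, J_(1,PC2)(2,PC1) = 0, J symmetric overall
  Om <- matrix(0, 2, 2); Om[1, 2] <- 1
  spd <- constraint_spec(g, dir_terms = list(d = Om))
  U <- matrix(0, 2, 2); U[1, 2] <- 0.4
  Jd <- build_J(M = list(t = diag(2)), U = list(d = U), spec = spd,
                graph = g, n_pc = 2, check_pd = FALSE)
  expect_equal(Jd[1, 4], 0.2)
  expect_equal(Jd[2, 3], 0)
  expect_symmetric(Jd)

  # the sparse basis operator assembles the same J as the kronecker route
  m <- maxent_model(M = list(t = diag(2)), U = list(d = U), spec = spd,
                    graph = g, n_pc = 2)
  basis <- embryomodes:::make_basis(spd, g, 2)
  expect_equal(embryomodes:::basis_J(m$theta, basis), m$J)

  # non-PD J is refused with the offending eigenvalue reported
  expect_error(build_J(M = list(t = matrix(1)),
                       S = list(edge = matrix(2)), spec = sp1, graph = g,
                       n_pc = 1), "positive definite")
})

test_that("predicted type covariances match hand-inverted small models", {
  # 2 cells in distinct types, 1 PC, J = [[1, .5], [.5, 1]]:
  # Sigma = (1/0.75) [[1, -.5], [-.5, 1]] -> gamma = -2/3
  cells <- c("x", "y")
  ct <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(cells, cells))
  g2 <- embryo_graph(cells, c(x = "tx", y = "ty"), ct)
  sp <- constraint_spec(g2, sym_terms = list(edge = ct))
  m <- maxent_model(M = list(tx = matrix(1), ty = matrix(1)),
                    S = list(edge = matrix(0.5)), spec = sp, graph = g2,
                    n_pc = 1)
  pred <- predict_type_covariances(m)
  expect_equal(pred$inter[["tx|ty"]][1, 1], -2 / 3)
  expect_equal(pred$intra$tx[1, 1], 1 / 0.75)

  # J = identity -> intra identity, inter zero
  g4 <- make_topology("toy4")
  m0 <- uncoupled_model(g4, 2)
  p0 <- predict_type_covariances(m0)
  expect_equal(p0$intra$tA, diag(2))
  expect_equal(p0$inter[["tA|tB"]], matrix(0, 2, 2))
})

test_that("moment matching recovers parameters exactly (self-consistency)", {
  # single type, single cell: closed form M = C^-1
  g1 <- embryo_graph("c1", c(c1 = "t"),
                     matrix(0, 1, 1, dimnames = list("c1", "c1")))
  C <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  fit <- fit_maxent(covariance_set(list(t = C), list()),
                    constraint_spec(g1), g1, 2, tol = 1e-12)
  expect_lt(max(abs(fit$model$M$t - solve(C))), 1e-10)
  expect_equal(fit$report$eta, 1)

  # statistics generated from a known model, refit with the same spec:
  # the moment-matching identity
  g <- make_topology("toy4")
  truth <- planted_sparse_model(g, 2, n_specific = 1)
  refit <- fit_maxent(NULL, truth$spec, g, 2, tol = 1e-10,
                      targets = constraint_statistics(truth))
  nz <- abs(truth$theta) > 1e-10
  expect_lt(max(abs(refit$model$theta[nz] - truth$theta[nz]) /
                  abs(truth$theta[nz])), 1e-6)

  # infeasible: an intra target with a negative eigenvalue errors
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(fit_maxent(covariance_set(list(t = bad), list()),
                          constraint_spec(g1), g1, 2), "infeasible")
})

test_that("eta measures explained covariance variance", {
  mk <- function(v) covariance_set(list(t = matrix(v[1])),
                                   list(`t|t` = matrix(v[2])))
  # C~ = C -> 1; C~ = 0 -> 0; C = (1,2), C~ = (1,1) -> 1 - 1/5 = 0.8
  expect_equal(fit_quality(mk(c(1, 2)), mk(c(1, 2))), 1)
  expect_equal(fit_quality(mk(c(1, 2)), mk(c(0, 0))), 0)
  expect_equal(fit_quality(mk(c(1, 2)), mk(c(1, 1))), 0.8)
  # invariant under joint rescaling
  expect_equal(fit_quality(mk(c(2, 4)), mk(c(2, 2))), 0.8)
  # all-zero empirical set is undefined
  expect_error(fit_quality(mk(c(0, 0)), mk(c(1, 1))), "undefined|zero")
})

test_that("mode decomposition and rotation baseline follow the algebra", {
  md <- mode_decomposition(diag(c(3, 1)))
  expect_equal(md$eigenvalues, c(3, 1))
  expect_equal(md$variance_fractions, c(0.75, 0.25))
  expect_equal(abs(md$modes), diag(2))

  g <- make_topology("toy4")
  m <- coupled_model(g, 2)
  md2 <- mode_decomposition(m)
  Sigma <- chol2inv(chol(m$J))
  expect_equal(sum(md2$eigenvalues), sum(diag(Sigma)))
  expect_lt(max(abs(crossprod(md2$modes) - diag(8))), 1e-10)
  # sign convention: largest-magnitude entry positive
  expect_true(all(apply(md2$modes, 2,
                        function(v) v[which.max(abs(v))] > 0)))

  # R = identity recovers the model's own top-k fraction; fractions in [0,1]
  rb <- rotation_baseline(m, md2, k = 3, n_rotations = 10, seed = 1)
  expect_true(all(rb$fractions >= 0 & rb$fractions <= 1))
  phi <- md2$modes[, 1:3]
  own <- sum(diag(t(phi) %*% Sigma %*% phi)) / sum(diag(Sigma))
  expect_equal(own, sum(md2$variance_fractions[1:3]))
})

test_that("sister-only models have exactly block-diagonal covariance", {
  g <- make_topology("mirror16")
  types <- stats::setNames(names(g$n_t), names(g$n_t))
  m <- maxent_model(M = lapply(types, function(t) diag(2)),
                    S = list(sister = -0.3 * diag(2)),
                    spec = spec_sister(g), graph = g, n_pc = 2)
  pred <- predict_type_covariances(m)
  # t1 cells and t4 cells are never sisters: predicted cross-covariance
  # is exactly zero despite the dense-looking inverse
  expect_lt(max(abs(pred$inter[["t1|t4"]])), 1e-12)
})
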