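test_that("candidate enumeration matches hand counting on small graphs", {
  # toy4: 3 contacts; the A-L~B-L edge is the mirror image of A-R~B-R and
  # A-L~A-R maps to itself -> 2 specific bundles; 3 global terms
  g4 <- make_topology("toy4")
  cand <- candidate_terms(g4)
  expect_setequal(names(cand$sym_terms),
                  c("embryo_wide", "neighbor", "sister"))
  expect_length(cand$dir_terms, 2)
  # each bundle maps onto itself under the mirror involution
  for (Om in cand$dir_terms) {
    idx <- which(Om == 1, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      pm <- g4$mirror[[g4$cell_names[idx[r, 1]]]]
      qm <- g4$mirror[[g4$cell_names[idx[r, 2]]]]
      expect_true(Om[pm, qm] == 1 ||
                    any(idx[, 1] == match(qm, g4$cell_names) &
                          idx[, 2] == match(pm, g4$cell_names)))
    }
  }

  # mirror16: 8 within-side + 2 cross-midline unordered bundles
  cand16 <- candidate_terms(make_topology("mirror16"))
  expect_length(cand16$dir_terms, 10)
})

test_that("L1 limits behave: lambda = 0 is the exact match, large lambda kills all", {
  g <- make_topology("toy4")
  truth <- coupled_model(g, 2)
  ds <- sample_embryos(truth, 12, seed = 4)
  cs <- covariance_set(intra_type_cov(ds$x, ds$type_of, ds$embryo_of),
                       inter_type_cov(ds$x, ds$type_of, ds$embryo_of))
  cand <- candidate_terms(g)

  f0 <- fit_regularized(cs, cand, g, 2, lambda = 0)
  fm <- fit_maxent(cs, cand, g, 2, tol = 1e-9)
  expect_lt(max(abs(f0$theta - fm$model$theta)), 1e-6)

  fL <- fit_regularized(cs, cand, g, 2, lambda = 1e3)
  expect_equal(max(fL$term_norms), 0)
})

test_that("the active set shrinks monotonically along the lambda grid", {
  g <- make_topology("toy4")
  ds <- sample_embryos(coupled_model(g, 2), 12, seed = 6)
  cs <- covariance_set(intra_type_cov(ds$x, ds$type_of, ds$embryo_of),
                       inter_type_cov(ds$x, ds$type_of, ds$embryo_of))
  cand <- candidate_terms(g)
  grid <- default_lambda_grid(cs, 5, cand, g, 2)
  warm <- NULL
  nnz <- rev(vapply(rev(seq_along(grid)), function(li) {
    f <- fit_regularized(cs, cand, g, 2, grid[li], init = warm,
                         strict = FALSE)
    warm <<- f$theta
    sum(f$term_norms > 1e-4)
  }, numeric(1)))
  expect_true(all(diff(nnz) <= 0))
})

test_that("stability ranking orders terms by consistent nonzero size", {
  fits <- list(
    list(term_norms = c(big = 1.0, flicker = 0.5, dead = 0)),
    list(term_norms = c(big = 1.2, flicker = 0.5, dead = 0)),
    list(term_norms = c(big = 0.9, flicker = 0, dead = 0)))
  rk <- stability_ranking(fits, nonzero_threshold = 1e-4)
  expect_equal(rk$term, c("big", "flicker", "dead"))
  expect_equal(rk$score[rk$term == "big"], 1.0)   # stability 1 x median 1.0
  expect_equal(rk$score[rk$term == "flicker"], (2 / 3) * 0.5)
  expect_equal(rk$score[rk$term == "dead"], 0)
  expect_error(stability_ranking(fits[1]), "2 draws")
})

test_that("Schulze aggregation reproduces hand-computed beatpaths", {
  # ballots {A>B>C, A>B>C, B>C>A}: A beats B 2-1, B beats C 3-0,
  # A beats C 2-1 -> A > B > C
  out <- schulze_aggregate(list(c("A", "B", "C"), c("A", "B", "C"),
                                c("B", "C", "A")))
  expect_equal(out, c("A", "B", "C"))

  # identical rankings and a single ballot are returned unchanged
  expect_equal(schulze_aggregate(list(c("y", "x", "z"), c("y", "x", "z"))),
               c("y", "x", "z"))
  expect_equal(schulze_aggregate(list(c("q", "p"))), c("q", "p"))

  # score ballots: ties express no preference, so an all-tied ballot
  # cannot override a decisive one
  out2 <- schulze_aggregate(list(c(A = 0, B = 0, C = 0),
                                 c(A = 1, B = 3, C = 2)))
  expect_equal(out2, c("B", "C", "A"))

  expect_error(schulze_aggregate(list()), "no rankings")
  expect_error(schulze_aggregate(list(c("A", "B"), c("A", "C"))),
               "disagree")
})

test_that("forward selection stops at the target fit quality", {
  g <- make_topology("toy4")
  truth <- coupled_model(g, 2, s_neighbor = -0.35)
  ds <- sample_embryos(truth, 60, seed = 8)
  cs <- covariance_set(intra_type_cov(ds$x, ds$type_of, ds$embryo_of),
                       inter_type_cov(ds$x, ds$type_of, ds$embryo_of))
  cand <- candidate_terms(g)
  sel <- forward_select(c("neighbor", "embryo_wide", "sister"), cs, cand,
                        g, 2, eta_target = 0.9)
  expect_true(sel$reached)
  expect_equal(sel$terms, "neighbor")  # first term alone reaches the target
  expect_gt(sel$report$eta, 0.9)
  expect_error(forward_select(character(0), cs, cand, g, 2), "empty")
})
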