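make_expr <- function(X, types, embryo = "e1") {
  cells <- data.frame(cell_id = paste0("c", seq_len(nrow(X))),
                      embryo_id = embryo, stage = nrow(X),
                      cell_type = types, stringsAsFactors = FALSE)
  dimnames(X) <- list(cells$cell_id, paste0("g", seq_len(ncol(X))))
  expression_posterior(X, matrix(0, nrow(X), ncol(X)), cells)
}

test_that("rank-sum DE reproduces the exact enumeration p-value", {
  # groups (1..5) vs (10..14): the most extreme of the choose(10,5) = 252
  # rank assignments, two-sided exact p = 2/252
  X <- cbind(c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14))
  de <- wilcoxon_de(make_expr(X, rep(c("A", "B"), each = 5)))
  expect_equal(de$p, 2 / 252)

  # identical values in both groups -> p = 1, not significant
  X2 <- cbind(rep(2, 8))
  de2 <- suppressWarnings(wilcoxon_de(make_expr(X2, rep(c("A", "B"), 4))))
  expect_equal(de2$p, 1)
  expect_false(de2$significant)

  # BH: adjusted p never below raw p
  set.seed(1)
  X3 <- matrix(rnorm(80), 8, 10)
  de3 <- wilcoxon_de(make_expr(X3, rep(c("A", "B"), each = 4)))
  expect_true(all(de3$p_adj >= de3$p))

  # a type with < 2 cells: each of its pairs is skipped with a warning
  w <- capture_warnings(
    de4 <- wilcoxon_de(make_expr(X3, c(rep("A", 4), rep("B", 3), "C"))))
  expect_true(all(grepl("skipped", w)) && length(w) == 2)
  expect_false(any(de4$type_a == "C" | de4$type_b == "C"))
})

test_that("zygotic and maternal filters follow the read-count rules", {
  cells4 <- data.frame(cell_id = paste0("b", 1:4), embryo_id = "e0",
                       stage = 4L)
  # baseline (4-cell) counts per gene: max 0, 50, 600, 400, 700
  base <- count_matrix(
    matrix(as.integer(c(0, 0, 0, 0,   50, 9, 3, 1,  600, 20, 10, 5,
                        400, 100, 2, 0, 700, 650, 1, 0)), 4, 5,
           dimnames = list(cells4$cell_id, paste0("g", 1:5))), cells4)
  cellsk <- data.frame(cell_id = paste0("k", 1:4), embryo_id = "e1",
                       stage = 16L)
  # stage-k max: 150, 200, 80, 90, 120
  stage <- count_matrix(
    matrix(as.integer(c(150, 5, 0, 0,  200, 8, 1, 0,  80, 70, 2, 1,
                        90, 10, 1, 0,  120, 30, 2, 1)), 4, 5,
           dimnames = list(cellsk$cell_id, paste0("g", 1:5))), cellsk)
  de <- data.frame(gene = paste0("g", 1:5),
                   significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))

  # g1: baseline max 0 < 10, stage 150 > 100, DE -> zygotic
  # g2: baseline max 50 -> excluded regardless of stage counts
  # g3: stage max 80 -> excluded
  expect_identical(classify_zygotic(base, stage, de), "g1")

  # without DE nothing survives
  de0 <- data.frame(gene = paste0("g", 1:5), significant = FALSE)
  expect_identical(classify_zygotic(base, stage, de0), character(0))

  # maternal: baseline max > 500 and never DE at any later stage
  # g3 (600, not DE), g5 (700, DE at one stage -> excluded),
  # g4 (400 -> excluded)
  de_later <- data.frame(gene = "g5", significant = TRUE)
  expect_identical(classify_maternal(base, list(de_later)), "g3")
  # explicit exclusion list removes localized maternal factors
  expect_identical(classify_maternal(base, list(de_later), exclude = "g3"),
                   character(0))
})

test_that("planted maternal/zygotic profiles are recovered exactly", {
  g <- make_topology("toy4")
  # 6 genes: g1 zygotic-like (silent early, high + type-specific later),
  # g2 maternal-like (high early, flat later), rest background
  profiles_base <- rbind(tA = c(1, 800, 2, 2, 2, 2),
                         tB = c(1, 800, 2, 2, 2, 2))
  colnames(profiles_base) <- paste0("g", 1:6)
  base <- simulate_counts(g, profiles_base, depth = 1600, dispersion = 0,
                          n_embryos = 2, seed = 1)
  base$cells$stage <- 4L
  # tB expresses g3 at the level tA expresses g1, so totals balance and
  # the flat maternal gene g2 keeps the same fraction in both types
  profiles_k <- rbind(tA = c(400, 300, 5, 5, 5, 5),
                      tB = c(5, 300, 400, 5, 5, 5))
  colnames(profiles_k) <- paste0("g", 1:6)
  stage <- simulate_counts(g, profiles_k, depth = 1600, dispersion = 0,
                           n_embryos = 4, seed = 2)
  post <- normalize_log_fraction(stage)
  de <- wilcoxon_de(post)
  zyg <- classify_zygotic(base, stage, de)
  mat <- classify_maternal(base, list(de))
  expect_identical(zyg, c("g1", "g3"))
  expect_identical(mat, "g2")
})
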