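# Shared fixtures, built in code.

# minimal 2-cell, 1-type graph (one mirror pair)
pair_graph <- function() {
  cells <- c("p-L", "p-R")
  embryo_graph(cells, stats::setNames(c("t", "t"), cells),
               matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(cells, cells)),
               mirror = stats::setNames(c("p-R", "p-L"), cells))
}

# 8-cell chain graph with 4 mirror pairs and 2 alternating types
chain8_graph <- function() {
  base <- paste0("p", 1:4)
  cells <- c(paste0(base, "-L"), paste0(base, "-R"))
  ct <- matrix(0, 8, 8, dimnames = list(cells, cells))
  for (i in 1:3) for (sd in c("-L", "-R")) {
    a <- paste0("p", i, sd); b <- paste0("p", i + 1, sd)
    ct[a, b] <- ct[b, a] <- 1
  }
  ct["p1-L", "p1-R"] <- ct["p1-R", "p1-L"] <- 1
  type_of <- stats::setNames(rep(c("tA", "tB"), 4), cells)
  mirror <- stats::setNames(c(paste0(base, "-R"), paste0(base, "-L")), cells)
  sister <- stats::setNames(
    c("p2-L", "p1-L", "p4-L", "p3-L", "p2-R", "p1-R", "p4-R", "p3-R"),
    cells)
  embryo_graph(cells, type_of, ct, sister, mirror)
}

# small counts fixture: 3 cells x 2 genes with metadata
tiny_counts <- function() {
  counts <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L), 3, 2,
                   dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      embryo_id = c("e1", "e1", "e2"), stage = 3L,
                      stringsAsFactors = FALSE)
  count_matrix(counts, cells)
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}
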