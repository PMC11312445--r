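#' Derive a named RNG substream seed from a root seed
#'
#' Each stochastic stage of the pipeline draws its randomness from a named
#' substream of a single root seed, so that any stage can be re-run in
#' isolation and reproduce its draws. The substream seed is a deterministic
#' hash of the root seed and the stream name, kept below 2^31 - 1.
#'
#' @param root_seed integer root seed.
#' @param name character stream name, e.g. `"shuffle_test"`.
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(name))
  m <- 2147483563
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((abs(root_seed) %% m * 48271 + h) %% m + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert-Arabie adjusted Rand index; 1 for identical partitions
#' (up to label permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Solve a (rectangular) min-cost assignment of rows to columns of `cost`
# (nrow <= ncol); returns for each row the index of its assigned column.
# Shortest-augmenting-path (Jonker-Volgenant) algorithm with potentials;
# exact, O(n^3). Cross-checked against igraph's weighted bipartite matching
# in the test suite.
min_cost_assignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  stopifnot(nr <= nc)
  if (nr < nc)  # pad with zero-cost dummy rows to square
    cost <- rbind(cost, matrix(0, nc - nr, nc))
  n <- nc
  u <- numeric(n)
  v <- numeric(n + 1)          # column potentials; n + 1 is the dummy column
  p <- integer(n + 1)          # p[j] = row currently assigned to column j
  way <- integer(n + 1)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      nu <- cols[!used[cols]]
      cur <- cost[i0, nu] - u[i0] - v[nu]
      better <- cur < minv[nu]
      minv[nu[better]] <- cur[better]
      way[nu[better]] <- j0
      j1 <- nu[which.min(minv[nu])]
      delta <- minv[j1]
      us <- which(used)
      u[p[us]] <- u[p[us]] + delta
      v[us] <- v[us] - delta
      minv[nu] <- minv[nu] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                   # augment along the found path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assignment <- integer(n)
  assignment[p[cols]] <- cols
  assignment[seq_len(nr)]
}

# reference implementation via igraph maximum-weight bipartite matching
# (used as an independent oracle in the tests)
assignment_igraph <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  stopifnot(nr <= nc)
  w <- max(cost) - cost + 1  # positive weights, min cost <-> max weight
  el <- cbind(rep(seq_len(nr), nc), nr + rep(seq_len(nc), each = nr))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, nc)),
                                    edges = as.vector(t(el)))
  igraph::E(g)$weight <- as.vector(w)
  m <- igraph::max_bipartite_match(g)$matching[seq_len(nr)]
  as.integer(m - nr)
}

# internal: stop unless all TRUE, with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
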