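# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the quantile oracle enumerates interpolating fits,
# the effect oracle enumerates directed paths.

# Exact check-loss minimum by enumerating all p-subsets of rows (a minimiser
# interpolates p observations when X has full column rank). Feasible for
# n <= 12, p <= 3.
brute_force_check_loss <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  for (rows in utils::combn(n, p, simplify = FALSE)) {
    M <- X[rows, , drop = FALSE]
    if (abs(det(M)) < 1e-9) next
    b <- solve(M, y[rows])
    u <- y - X %*% b
    best <- min(best, sum(u * (tau - (u < 0))))
  }
  best
}

# Sum of edge-coefficient products over every directed path from `from` to
# `to` (recursive enumeration), optionally restricted to paths of >= 2 edges.
enumerate_path_effects <- function(edges, from, to, min_edges = 1) {
  walk <- function(node, prod, depth) {
    out <- 0
    nxt <- edges[edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      p2 <- prod * nxt$estimate[i]
      if (nxt$to[i] == to && depth + 1 >= min_edges) out <- out + p2
      out <- out + walk(nxt$to[i], p2, depth + 1)
    }
    out
  }
  # paths ending at `to` only; walk() credits a path when it reaches `to`
  # but keeps extending, which double counts nothing because the graph is
  # acyclic and `to` has its own outgoing edges counted toward other sinks
  walk2 <- function(node, prod, depth) {
    out <- 0
    nxt <- edges[edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      p2 <- prod * nxt$estimate[i]
      if (nxt$to[i] == to) {
        if (depth + 1 >= min_edges) out <- out + p2
      } else {
        out <- out + walk2(nxt$to[i], p2, depth + 1)
      }
    }
    out
  }
  walk2(from, 1, 0)
}

# Random acyclic diagram with standardized-scale edge weights.
random_dag <- function(n_nodes, edge_prob = 0.5) {
  nodes <- paste0("n", seq_len(n_nodes))
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < edge_prob) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  if (length(from) == 0) { from <- nodes[1]; to <- nodes[2] }
  data.frame(from = from, to = to,
             estimate = round(runif(length(from), -0.8, 0.8), 3),
             stringsAsFactors = FALSE)
}

# The published standardized path coefficients of the modified construct
# model (verified against the source tables before freezing).
published_path_coefficients <- function() {
  data.frame(
    from = c("human", "human", "human", "physical", "physical", "social",
             "utilization"),
    to = c("physical", "utilization", "vulnerability", "social",
           "vulnerability", "vulnerability", "vulnerability"),
    estimate = c(0.733, -0.128, 0.415, 0.456, -0.433, -0.195, -0.035),
    stringsAsFactors = FALSE)
}

# Small synthetic config used by I/O and pipeline tests.
small_config <- function(n = 400, seed = 99) {
  synthetic_config(n_households = n, seed = seed)
}
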