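# Independent oracle: recompute both largest-cluster series from scratch at
# every step with igraph's component finder (no union-find, no incremental
# state). Deliberately naive; only for graphs small enough to afford it.
naive_dual_trajectory <- function(graph, sequence) {
  n <- igraph::vcount(graph)
  tm <- length(sequence)
  S_A <- S_I <- integer(tm + 1)
  for (t in 0:tm) {
    idle <- sequence[seq_len(t)]
    act <- setdiff(seq_len(n), idle)
    S_A[t + 1] <- if (length(act)) {
      as.integer(max(
        igraph::components(igraph::induced_subgraph(graph, act))$csize))
    } else 0L
    S_I[t + 1] <- if (length(idle)) {
      as.integer(max(
        igraph::components(igraph::induced_subgraph(graph, idle))$csize))
    } else 0L
  }
  list(S_A = S_A, S_I = S_I)
}

# A random simple graph (possibly disconnected) for property sweeps.
random_test_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.02, 0.5)
  igraph::sample_gnp(n, p)
}

# Invariant suite asserted on every trajectory the tests produce:
# monotonicity, bounds, boundary values, node-set complementarity and the
# edge-count inequality (checked at a handful of times via igraph).
expect_valid_trajectory <- function(traj, graph = NULL) {
  expect_s3_class(traj, "dual_trajectory")
  expect_length(traj$S_A, traj$t_max + 1)
  expect_length(traj$S_I, traj$t_max + 1)
  expect_true(all(diff(traj$S_A) <= 0))          # S_A non-increasing
  expect_true(all(diff(traj$S_I) >= 0))          # S_I non-decreasing
  expect_true(all(traj$S_A <= traj$T - traj$t))  # S_A(t) <= T - t
  expect_true(all(traj$S_I <= traj$t))           # S_I(t) <= t
  expect_identical(traj$S_I[1], 0L)
  if (!is.null(graph)) {
    n <- as.integer(igraph::vcount(graph))
    comp0 <- igraph::components(graph)
    expect_identical(traj$S_A[1], as.integer(max(comp0$csize)))
    if (traj$t_max == n) {
      expect_identical(traj$S_A[n + 1], 0L)
      # at completion the Idle Network is the original network
      expect_identical(traj$S_I[n + 1], traj$S_A[1])
    }
    for (t in unique(c(0L, traj$t_max %/% 2L, traj$t_max))) {
      idle <- traj$sequence[seq_len(t)]
      act <- setdiff(seq_len(n), idle)
      expect_identical(length(idle) + length(act), n)  # complementarity
      e_a <- igraph::ecount(igraph::induced_subgraph(graph, act))
      e_i <- igraph::ecount(igraph::induced_subgraph(graph, idle))
      expect_lte(e_a + e_i, igraph::ecount(graph))
    }
  }
  invisible(traj)
}
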