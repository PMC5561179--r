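test_that("periodic lattice has the prototype size and 4-regular degrees", {
  g <- lattice_graph(100)
  expect_equal(igraph::vcount(g), 10000L)
  expect_equal(igraph::ecount(g), 20000L)  # 4T/2
  expect_true(all(igraph::degree(g) == 4))
  expect_true(igraph::is_connected(g))
  expect_silent(validate_network(g))

  g3 <- lattice_graph(3)
  expect_true(all(igraph::degree(g3) == 4))

  # side = 2 degenerates: wrap-around duplicates collapse to degree 2
  g2 <- lattice_graph(2)
  expect_equal(igraph::vcount(g2), 4L)
  expect_true(all(igraph::degree(g2) == 2))
  expect_silent(validate_network(g2))

  expect_error(lattice_graph(1), "side")
  expect_error(lattice_graph(2.5), "side")
})

test_that("path graph matches the line-network fixture", {
  g <- path_graph(7)
  expect_equal(igraph::vcount(g), 7L)
  expect_equal(igraph::ecount(g), 6L)
  expect_silent(validate_network(g))

  expect_equal(igraph::vcount(path_graph(1)), 1L)
  expect_equal(igraph::ecount(path_graph(1)), 0L)
  expect_identical(sort(igraph::degree(path_graph(3))), c(1, 1, 2))
  expect_error(path_graph(0), "n")
})

test_that("Tokunaga tree sizes match the branch-count recursion", {
  # oracle: N_1 = 1, N_j = 1 + 2 N_{j-1} + sum_k round(a c^(k-1)) N_{j-k}
  tree_size <- function(order, a, c) {
    N <- numeric(order)
    N[1] <- 1
    for (j in seq_len(order)[-1]) {
      side <- sum(vapply(seq_len(j - 1),
                         function(k) round(a * c^(k - 1)) * N[j - k],
                         numeric(1)))
      N[j] <- 1 + 2 * N[j - 1] + side
    }
    N[order]
  }
  expect_equal(igraph::vcount(tokunaga_tree(1)), 1L)
  expect_equal(igraph::vcount(tokunaga_tree(2)), 4L)
  for (om in c(3, 4, 6)) {
    g <- tokunaga_tree(om, 1, 2)
    expect_equal(igraph::vcount(g), tree_size(om, 1, 2))
  }
  g6 <- tokunaga_tree(6, 1, 2)
  expect_equal(igraph::vcount(g6), 912)
  expect_equal(igraph::ecount(g6), 911)  # tree: |E| = T - 1
  expect_true(igraph::is_connected(g6))
  expect_true(igraph::is_acyclic(g6))
  expect_silent(validate_network(g6))

  # deterministic mode ignores the RNG state entirely
  set.seed(1); e1 <- igraph::as_edgelist(tokunaga_tree(5))
  set.seed(99); e2 <- igraph::as_edgelist(tokunaga_tree(5))
  expect_identical(e1, e2)

  # poisson mode is a reproducible random ensemble of trees
  p1 <- tokunaga_tree(5, mode = "poisson", seed = 7)
  p2 <- tokunaga_tree(5, mode = "poisson", seed = 7)
  expect_identical(igraph::as_edgelist(p1), igraph::as_edgelist(p2))
  expect_true(igraph::is_acyclic(p1) && igraph::is_connected(p1))

  expect_error(tokunaga_tree(0), "order")
  expect_error(tokunaga_tree(3, a = -1), "positive")
})

test_that("BA generator obeys the preferential-attachment contract", {
  g <- ba_graph(1000, m0 = 3, m = 2, seed = 1)
  expect_equal(igraph::vcount(g), 1000L)
  expect_equal(igraph::ecount(g), 1997L)  # e0 + m (T - m0)
  expect_true(igraph::is_connected(g))
  expect_silent(validate_network(g))
  # every added node brings m = 2 distinct edges
  expect_true(all(igraph::degree(g)[-(1:3)] >= 2))

  # K4: the fourth node must attach to all three seed nodes
  k4 <- ba_graph(4, m0 = 3, m = 3, seed = 1)
  expect_equal(igraph::ecount(k4), 6L)
  expect_true(all(igraph::degree(k4) == 3))

  # heavier tail than any regular lattice: hubs well above 4 m
  maxdeg <- vapply(1:10, function(s) {
    max(igraph::degree(ba_graph(1000, 3, 2, seed = s)))
  }, numeric(1))
  expect_true(all(maxdeg > 4 * 2))

  set.seed(42); e1 <- igraph::as_edgelist(ba_graph(200, 3, 2))
  set.seed(42); e2 <- igraph::as_edgelist(ba_graph(200, 3, 2))
  expect_identical(e1, e2)

  expect_error(ba_graph(10, m0 = 2, m = 3), "m0")
  expect_error(ba_graph(2, m0 = 3, m = 2), "m0")
})

test_that("surrogate airline generator hits exact counts and stays connected", {
  g <- surrogate_airline(186, 1507, seed = 1)
  expect_equal(igraph::vcount(g), 186L)
  expect_equal(igraph::ecount(g), 1507L)
  expect_true(igraph::is_connected(g))
  expect_silent(validate_network(g))
  # point-to-point style: skewed but not hub-exclusive
  expect_gt(max(igraph::degree(g)), 2 * mean(igraph::degree(g)))

  tree <- surrogate_airline(5, 4, seed = 2)
  expect_equal(igraph::ecount(tree), 4L)
  expect_true(igraph::is_connected(tree))

  full <- surrogate_airline(10, 45, seed = 3)
  expect_true(all(igraph::degree(full) == 9))

  set.seed(8); e1 <- igraph::as_edgelist(surrogate_airline(50, 200))
  set.seed(8); e2 <- igraph::as_edgelist(surrogate_airline(50, 200))
  expect_identical(e1, e2)

  expect_error(surrogate_airline(5, 3), "n_edges")
  expect_error(surrogate_airline(5, 11), "n_edges")
})

test_that("edge-list reader collapses duplicates and maps labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "B,A"), f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_identical(sort(igraph::V(g)$name), c("A", "B"))

  writeLines(c("A,A", "A,B"), f)
  expect_warning(g <- read_network(f), "self-loop")
  expect_equal(igraph::ecount(g), 1L)

  # header auto-detection and tab separation
  writeLines(c("from\tto", "n1\tn2", "n2\tn3"), f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)

  writeLines(c("A,B", "A,B,C"), f)
  expect_error(read_network(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_network(f), "empty")
  expect_error(read_network(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("an airline-scale edge list round-trips through files", {
  g0 <- surrogate_airline(186, 1507, seed = 4)
  igraph::V(g0)$name <- sprintf("AP%03d", seq_len(186))
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g0, f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), 186L)
  expect_equal(igraph::ecount(g), 1507L)

  fg <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g0, fg, format = "graphml")
  g2 <- read_network(fg)
  expect_equal(igraph::vcount(g2), 186L)
  expect_equal(igraph::ecount(g2), 1507L)
})
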