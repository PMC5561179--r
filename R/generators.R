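#' Periodic square lattice (Von Neumann neighbourhood)
#'
#' Builds a `side` x `side` square lattice. With `periodic = TRUE` (the
#' default) opposite boundaries are identified, so for `side >= 3` every node
#' has exactly four neighbours. For `side = 2` the wrap-around duplicates
#' collapse (the graph is simplified), leaving each node with degree 2;
#' strict degree-4 regularity therefore requires `side >= 3`.
#'
#' @param side Integer >= 2, number of nodes along each dimension; the graph
#'   has `side^2` nodes.
#' @param periodic Logical, identify opposite boundaries (torus). Default
#'   `TRUE`.
#' @return An undirected simple [igraph][igraph::igraph-package] graph.
#' @examples
#' g <- lattice_graph(10)
#' all(igraph::degree(g) == 4)
#' @export
lattice_graph <- function(side, periodic = TRUE) {
  if (!is.numeric(side) || length(side) != 1 || is.na(side) || side < 2 ||
      side != round(side)) {
    stop("invalid parameter: `side` must be a single integer >= 2")
  }
  g <- igraph::make_lattice(c(side, side), periodic = periodic)
  igraph::simplify(g)
}

#' Path (line) graph
#'
#' @param n Integer >= 1, number of nodes. Edges connect consecutive nodes
#'   `i -- i+1`.
#' @return An undirected simple igraph graph with `n` nodes and `n - 1`
#'   edges.
#' @examples
#' path_graph(7)
#' @export
path_graph <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != round(n)) {
    stop("invalid parameter: `n` must be a single integer >= 1")
  }
  if (n == 1) return(igraph::make_empty_graph(1, directed = FALSE))
  igraph::make_ring(n, circular = FALSE)
}

#' Tokunaga self-similar tree
#'
#' Generates a self-similar tree in which every Horton-Strahler branch is a
#' node, joined by an edge to its parent branch. The tree is expanded
#' top-down from a single branch of order `order`: each branch of order
#' `i > 1` spawns exactly two principal sub-branches of order `i - 1` plus,
#' for every `k = 1..i-1`, side branches of order `i - k` whose number is
#' `T_k = a * c^(k-1)` (the Tokunaga side-branching law). In
#' `mode = "deterministic"` the side-branch count is `round(T_k)` (exact for
#' the canonical parameters `(a, c) = (1, 2)`); in `mode = "poisson"` it is
#' drawn from a Poisson distribution with mean `T_k`, giving a random tree
#' ensemble.
#'
#' @param order Horton-Strahler order Omega of the root branch, integer
#'   >= 1. `order = 1` gives a single node.
#' @param a,c Positive Tokunaga parameters. Defaults `(1, 2)`.
#' @param mode `"deterministic"` (seed-independent) or `"poisson"`.
#' @param seed Optional integer seed (only relevant for `mode = "poisson"`).
#' @return An undirected tree as an igraph graph; the vertex attribute
#'   `branch_order` records each branch's Horton-Strahler order.
#' @examples
#' g <- tokunaga_tree(6)          # 912 nodes for (a, c) = (1, 2)
#' igraph::vcount(g)
#' @export
tokunaga_tree <- function(order, a = 1, c = 2,
                          mode = c("deterministic", "poisson"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(order) || length(order) != 1 || is.na(order) ||
      order < 1 || order != round(order)) {
    stop("invalid parameter: `order` must be a single integer >= 1")
  }
  if (!is.numeric(a) || a <= 0 || !is.numeric(c) || c <= 0) {
    stop("invalid parameter: `a` and `c` must be positive")
  }
  if (!is.null(seed)) set.seed(seed)

  ords <- as.integer(order)
  edges_from <- integer(0)
  edges_to <- integer(0)
  i <- 1L
  while (i <= length(ords)) {
    oi <- ords[i]
    if (oi > 1L) {
      child_orders <- c(oi - 1L, oi - 1L)  # two principal sub-branches
      for (k in seq_len(oi - 1L)) {
        Tk <- a * c^(k - 1)
        nk <- if (mode == "deterministic") as.integer(round(Tk))
              else stats::rpois(1L, Tk)
        if (nk > 0L) child_orders <- c(child_orders, rep.int(oi - k, nk))
      }
      ids <- length(ords) + seq_along(child_orders)
      edges_from <- c(edges_from, rep.int(i, length(child_orders)))
      edges_to <- c(edges_to, ids)
      ords <- c(ords, child_orders)
    }
    i <- i + 1L
  }
  g <- if (length(ords) == 1L) {
    igraph::make_empty_graph(1, directed = FALSE)
  } else {
    igraph::graph_from_edgelist(cbind(edges_from, edges_to),
                                directed = FALSE)
  }
  igraph::V(g)$branch_order <- ords
  g
}

#' Barabasi-Albert scale-free network
#'
#' Growth with pure degree-proportional preferential attachment. The seed
#' network is the complete graph on `m0` nodes (so every seed node has
#' positive degree); each subsequent node attaches to `m` *distinct*
#' existing nodes chosen with probability proportional to their current
#' degree, degrees held fixed within one insertion step. Growth stops when
#' the graph has `n` nodes in total.
#'
#' @param n Total number of nodes, `n >= m0`.
#' @param m0 Seed-network size, integer >= 1. Default 3 (a triangle).
#' @param m Links added per new node, `1 <= m <= m0`. Default 2.
#' @param seed Optional integer seed.
#' @return An undirected simple igraph graph with `n` nodes and
#'   `choose(m0, 2) + m * (n - m0)` edges.
#' @examples
#' g <- ba_graph(1000, m0 = 3, m = 2, seed = 1)
#' igraph::ecount(g)  # 3 + 2 * 997 = 1997
#' @export
ba_graph <- function(n, m0 = 3, m = 2, seed = NULL) {
  if (!is.numeric(n) || n < 1 || n != round(n) ||
      !is.numeric(m0) || m0 < 1 || m0 != round(m0) ||
      !is.numeric(m) || m < 1 || m != round(m)) {
    stop("invalid parameter: `n`, `m0`, `m` must be positive integers")
  }
  if (m > m0) stop("invalid parameter: `m` must not exceed `m0`")
  if (m0 > n) stop("invalid parameter: `m0` must not exceed `n`")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n); m0 <- as.integer(m0); m <- as.integer(m)
  e0 <- if (m0 >= 2) m0 * (m0 - 1L) %/% 2L else 0L
  n_edges <- e0 + m * (n - m0)
  from <- integer(n_edges); to <- integer(n_edges)
  # multiset of edge endpoints: sampling one uniformly is sampling a node
  # with probability proportional to its degree
  ends <- integer(2L * n_edges)
  ecount <- 0L; nend <- 0L
  if (m0 >= 2) {
    seed_edges <- t(combn(m0, 2L))
    ecount <- nrow(seed_edges)
    from[seq_len(ecount)] <- seed_edges[, 1]
    to[seq_len(ecount)] <- seed_edges[, 2]
    nend <- 2L * ecount
    ends[seq_len(nend)] <- as.integer(t(seed_edges))
  }
  if (n > m0) {
    for (v in (m0 + 1L):n) {
      chosen <- integer(0)
      while (length(chosen) < m) {
        cand <- if (nend > 0L) ends[sample.int(nend, 1L)]
                else sample.int(v - 1L, 1L)  # all-degree-zero fallback
        if (!(cand %in% chosen)) chosen <- c(chosen, cand)
      }
      for (u in chosen) {
        ecount <- ecount + 1L
        from[ecount] <- u; to[ecount] <- v
        ends[nend + 1L] <- u; ends[nend + 2L] <- v
        nend <- nend + 2L
      }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::add_vertices(g, n - igraph::vcount(g))
}

#' Surrogate point-to-point airline network (synthetic)
#'
#' A synthetic stand-in for a point-to-point airline route network: a
#' connected graph with the requested node and edge counts and a skewed but
#' non-hub-exclusive degree distribution (many mid-degree nodes). It is
#' built from a random recursive spanning tree plus extra edges whose
#' endpoints are drawn with probability proportional to `degree + 1`. No
#' real route data is used or bundled.
#'
#' @param n_airports Number of nodes, >= 1.
#' @param n_edges Number of edges, between `n_airports - 1` (spanning tree)
#'   and `choose(n_airports, 2)` (complete graph).
#' @param seed Optional integer seed.
#' @return A connected undirected simple igraph graph.
#' @examples
#' g <- surrogate_airline(186, 1507, seed = 1)
#' c(igraph::vcount(g), igraph::ecount(g))
#' @export
surrogate_airline <- function(n_airports, n_edges, seed = NULL) {
  n <- n_airports
  if (!is.numeric(n) || n < 1 || n != round(n) ||
      !is.numeric(n_edges) || n_edges != round(n_edges)) {
    stop("invalid parameter: counts must be integers")
  }
  max_e <- n * (n - 1) / 2
  if (n_edges > max_e || n_edges < n - 1) {
    stop("invalid parameter: `n_edges` must lie in [n_airports - 1, ",
         "n_airports * (n_airports - 1) / 2]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); n_edges <- as.integer(n_edges)
  if (n == 1L) return(igraph::make_empty_graph(1, directed = FALSE))

  # random recursive tree: node v attaches to a uniform earlier node
  from <- integer(n_edges); to <- integer(n_edges)
  parents <- if (n == 2L) 1L else
    c(1L, vapply(3:n, function(v) sample.int(v - 1L, 1L), integer(1)))
  from[seq_len(n - 1L)] <- parents
  to[seq_len(n - 1L)] <- 2:n
  deg <- tabulate(c(parents, 2:n), nbins = n)
  # membership of unordered pairs, keyed into 1..choose(n, 2)
  pair_key <- function(u, v) {
    lo <- pmin(u, v); hi <- pmax(u, v)
    (lo - 1L) * n - (lo * (lo - 1L)) %/% 2L + (hi - lo)
  }
  present <- logical(max_e)
  present[pair_key(from[seq_len(n - 1L)], to[seq_len(n - 1L)])] <- TRUE
  ecount <- n - 1L
  fails <- 0L
  while (ecount < n_edges) {
    u <- sample.int(n, 1L, prob = deg + 1)
    v <- sample.int(n, 1L, prob = deg + 1)
    k <- if (u != v) pair_key(u, v) else 0L
    if (u != v && !present[k]) {
      ecount <- ecount + 1L
      from[ecount] <- u; to[ecount] <- v
      present[k] <- TRUE
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > 200L) {
        # near-complete graph: draw the remainder uniformly from the
        # missing pairs
        allp <- t(combn(n, 2L))
        open <- which(!present[pair_key(allp[, 1], allp[, 2])])
        take <- sample(open, n_edges - ecount)
        idx <- ecount + seq_along(take)
        from[idx] <- allp[take, 1]; to[idx] <- allp[take, 2]
        ecount <- n_edges
      }
    }
  }
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
}

#' Validate the simple-graph invariants
#'
#' Checks that a graph is undirected, has no self-loops and no duplicate
#' edges. Used by the test-suite on every generator output; exported so
#' user-supplied graphs can be checked before analysis.
#'
#' @param graph An igraph graph.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_network <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("not an igraph graph")
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (any(igraph::which_loop(graph))) stop("graph contains self-loops")
  if (any(igraph::which_multiple(graph))) stop("graph contains duplicate edges")
  invisible(TRUE)
}
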