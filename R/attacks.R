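#' Plan a sequential node-removal attack
#'
#' Generates the ordered removal sequence realised by one of three attack
#' strategies:
#'
#' * `"random_failure"` (`"rf"`): each step removes a node drawn uniformly
#'   from the active nodes.
#' * `"targeted_attack"` (`"ta"`): each step samples an active node with
#'   probability proportional to its degree. With
#'   `ta_degree_mode = "current"` (the default) the weight is the node's
#'   degree within the current Active Network, so weights shrink as
#'   neighbours are removed; with `"initial"` the weight is the degree in
#'   the original graph. If all active weights are zero the draw falls back
#'   to uniform.
#' * `"random_spreading"` (`"rs"`): the first node is removed uniformly at
#'   random; afterwards each step removes a node drawn uniformly from the
#'   active nodes adjacent (in the original graph) to at least one idle
#'   node. On a connected graph the idle set therefore stays connected and
#'   its largest cluster grows linearly, `S_I(t) = t`. If no frontier node
#'   exists (disconnected graph) the process restarts uniformly among
#'   active nodes.
#'
#' @param graph An undirected igraph graph.
#' @param strategy Attack strategy, long or short name.
#' @param horizon Number of removals. `NULL` (default) removes every node; a
#'   fraction in `(0, 1)` removes `floor(horizon * T)` nodes (at least 1);
#'   an integer in `1..T` removes exactly that many.
#' @param seed Optional integer seed; the same `(graph, strategy, seed)`
#'   always yields the same sequence. With `seed = NULL` the current RNG
#'   stream is used.
#' @param ta_degree_mode Degree definition for the targeted attack,
#'   `"current"` or `"initial"`. The `"current"` default is the mode that
#'   reproduces the published prototype-network efficiencies: on a periodic
#'   lattice all initial degrees are equal, so an initial-degree attack is
#'   indistinguishable from random failure, whereas current-degree
#'   weighting is not.
#' @return An integer vector of distinct 1-based node ids, the realised
#'   removal sequence.
#' @seealso [dual_trajectory()], [greedy_fragmentation()]
#' @examples
#' g <- lattice_graph(10)
#' plan_attack(g, "rs", seed = 1)[1:5]
#' @export
plan_attack <- function(graph,
                        strategy = c("random_failure", "targeted_attack",
                                     "random_spreading", "rf", "ta", "rs"),
                        horizon = NULL, seed = NULL,
                        ta_degree_mode = c("current", "initial")) {
  strategy <- match.arg(strategy)
  strategy <- switch(strategy,
                     rf = "random_failure",
                     ta = "targeted_attack",
                     rs = "random_spreading",
                     strategy)
  ta_degree_mode <- match.arg(ta_degree_mode)
  n <- igraph::vcount(graph)
  if (n < 1) stop("graph is empty")
  t_max <- resolve_horizon(horizon, n)
  if (!is.null(seed)) set.seed(seed)
  full <- switch(strategy,
    random_failure = sample.int(n),
    targeted_attack = {
      csr <- graph_csr(graph)
      ta_plan_cpp(csr$ptr, csr$idx, n, ta_degree_mode == "current") + 1L
    },
    random_spreading = {
      csr <- graph_csr(graph)
      rs_plan_cpp(csr$ptr, csr$idx, n) + 1L
    })
  full[seq_len(t_max)]
}

# horizon = NULL: full; fraction in (0,1): floor(f*T), >= 1; integer 1..T.
resolve_horizon <- function(horizon, n) {
  if (is.null(horizon)) return(n)
  if (!is.numeric(horizon) || length(horizon) != 1 || is.na(horizon) ||
      horizon <= 0) {
    stop("invalid horizon: must be NULL, a fraction in (0, 1), ",
         "or an integer in 1..T")
  }
  t_max <- if (horizon < 1) max(1L, as.integer(floor(horizon * n)))
           else as.integer(horizon)
  if (t_max != horizon && horizon >= 1) {
    stop("invalid horizon: non-integer removal count")
  }
  if (t_max > n) stop("invalid horizon: exceeds the number of nodes (", n, ")")
  t_max
}

#' Greedy fragmentation sequence
#'
#' At every step removes the active node whose removal minimises the size of
#' the largest remaining active cluster -- the most efficient destruction of
#' Active-Network connectivity, used for the 7-node line worked example and
#' other small-graph demonstrations. Ties on the largest cluster are broken
#' by the smallest sum of squared component sizes (maximal fragmentation
#' pressure, which is what makes the line-network trajectory reach
#' `S_A = 1` in three steps), then by smallest node id. The search is
#' exhaustive per step (`O(T^2)` component computations), intended for small
#' graphs.
#'
#' @param graph An undirected igraph graph.
#' @param steps Number of removals; default all `T` nodes.
#' @return Integer vector of removed node ids, in order.
#' @examples
#' greedy_fragmentation(path_graph(7))  # 4 2 6 1 3 5 7
#' @export
greedy_fragmentation <- function(graph, steps = NULL) {
  n <- igraph::vcount(graph)
  if (n < 1) stop("graph is empty")
  steps <- resolve_horizon(steps, n)
  active <- rep(TRUE, n)
  out <- integer(steps)
  for (s in seq_len(steps)) {
    cand <- which(active)
    best <- c(Inf, Inf)
    best_u <- cand[1]
    for (u in cand) {
      keep <- setdiff(cand, u)
      cs <- if (length(keep)) {
        igraph::components(igraph::induced_subgraph(graph, keep))$csize
      } else 0
      score <- c(max(cs), sum(cs^2))
      if (score[1] < best[1] ||
          (score[1] == best[1] && score[2] < best[2])) {
        best <- score
        best_u <- u
      }
    }
    out[s] <- best_u
    active[best_u] <- FALSE
  }
  out
}

#' Write / read a removal sequence
#'
#' Serialises a removal sequence to a one-column CSV (column `node`). If the
#' graph has vertex names the original labels are written, enabling replay
#' of externally specified attacks.
#'
#' @param sequence Integer removal sequence (1-based ids).
#' @param path File path.
#' @param graph Optional graph supplying vertex names.
#' @return The path, invisibly.
#' @export
write_removal_sequence <- function(sequence, path, graph = NULL) {
  labels <- sequence
  if (!is.null(graph) && !is.null(igraph::V(graph)$name)) {
    labels <- igraph::V(graph)$name[sequence]
  }
  write.csv(data.frame(node = labels), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_removal_sequence
#' @details `read_removal_sequence()` reads the CSV back; when `graph` is
#'   supplied, labels are mapped to its node ids and validated.
#' @export
read_removal_sequence <- function(path, graph = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!("node" %in% names(df))) stop("expected a `node` column in ", path)
  x <- df$node
  if (is.null(graph)) {
    ids <- suppressWarnings(as.integer(x))
    if (anyNA(ids)) return(x)
    return(ids)
  }
  if (!is.null(igraph::V(graph)$name)) return(as_node_ids(graph, x))
  as_node_ids(graph, suppressWarnings(as.integer(x)))
}
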