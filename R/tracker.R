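#' Joint Active/Idle largest-cluster trajectories
#'
#' Given a graph and a removal sequence, computes for every
#' `t = 0..t_max` the size `S_A(t)` of the largest connected component of
#' the Active Network (the subgraph induced by the not-yet-removed nodes)
#' and the size `S_I(t)` of the largest component of the Idle Network (the
#' subgraph induced by the first `t` removed nodes, with the original
#' edges among them).
#'
#' The computation is incremental: the Idle side adds removed nodes to a
#' union-find forward in time, the Active side re-activates nodes over the
#' reversed sequence, so a full-horizon trajectory on a 10,000-node graph
#' takes milliseconds. `S_A` is non-increasing and `S_I` non-decreasing by
#' construction; at full horizon `S_A(T) = 0` and `S_I(T) = S_A(0)`.
#'
#' @param graph An undirected igraph graph.
#' @param sequence Removal sequence: distinct node ids (or vertex names).
#' @return An object of class `dual_trajectory`: a list with elements `t`
#'   (`0:t_max`), `S_A`, `S_I` (integer vectors of length `t_max + 1`), `T`
#'   (node count), `t_max`, and `sequence` (the validated id sequence).
#' @examples
#' g <- path_graph(7)
#' dual_trajectory(g, greedy_fragmentation(g))
#' @export
dual_trajectory <- function(graph, sequence) {
  ids <- as_node_ids(graph, sequence)
  n <- igraph::vcount(graph)
  csr <- graph_csr(graph)
  res <- dual_traj_cpp(csr$ptr, csr$idx, ids - 1L, n)
  structure(list(t = 0:length(ids),
                 S_A = res$S_A,
                 S_I = res$S_I,
                 T = n,
                 t_max = length(ids),
                 sequence = ids),
            class = "dual_trajectory")
}

#' @export
print.dual_trajectory <- function(x, ...) {
  cat("Dual connectivity trajectory: T =", x$T, ", t_max =", x$t_max, "\n")
  cat("  S_A(0) =", x$S_A[1], "->", "S_A(t_max) =", x$S_A[x$t_max + 1], "\n")
  cat("  S_I(0) =", x$S_I[1], "->", "S_I(t_max) =", x$S_I[x$t_max + 1], "\n")
  invisible(x)
}

#' @export
as.data.frame.dual_trajectory <- function(x, ...) {
  data.frame(t = x$t, S_A = x$S_A, S_I = x$S_I)
}

#' @export
plot.dual_trajectory <- function(x, normalized = TRUE, ...) {
  tt <- if (normalized) x$t / x$T else x$t
  sa <- if (normalized) x$S_A / x$T else x$S_A
  si <- if (normalized) x$S_I / x$T else x$S_I
  plot(tt, sa, type = "s", col = "firebrick", lwd = 2,
       xlab = if (normalized) "t / T" else "t",
       ylab = if (normalized) "S / T" else "largest cluster size",
       ylim = range(0, sa, si), ...)
  graphics::lines(tt, si, type = "s", col = "steelblue", lwd = 2)
  graphics::legend("topright", legend = c("Active network", "Idle network"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

#' Alternative connectivity metrics along an attack
#'
#' Evaluates a connectivity proxy on both the Active and the Idle Network at
#' a set of sampled times. Supported metrics: `"largest_cluster"` (component
#' size), `"n_clusters"` (number of connected components),
#' `"avg_cluster_size"` (arithmetic mean component size, giant component
#' included), `"diameter"` (longest shortest path within the largest
#' component; 0 for empty or single-node networks), `"inv_geodesic"` (mean
#' of `1/d(u, v)` over node pairs with `1/Inf = 0`, i.e. global efficiency;
#' 0 for networks with fewer than two nodes). The all-pairs metrics are
#' quadratic, which is why evaluation is restricted to sampled times
#' (default: up to 51 evenly spaced, including 0 and `t_max`).
#'
#' @param graph An undirected igraph graph.
#' @param sequence Removal sequence (distinct node ids or names).
#' @param metric Metric name, see above.
#' @param sample_times Strictly increasing integer times in `[0, t_max]`;
#'   default evenly spaced.
#' @return An object of class `metric_trajectory`: list with `metric`,
#'   `sample_times`, `values_A`, `values_I`, `T`, `t_max`.
#' @examples
#' g <- path_graph(7)
#' metric_trajectory(g, greedy_fragmentation(g), "n_clusters")
#' @export
metric_trajectory <- function(graph, sequence,
                              metric = c("largest_cluster", "n_clusters",
                                         "avg_cluster_size", "diameter",
                                         "inv_geodesic"),
                              sample_times = NULL) {
  metric <- match.arg(metric)
  ids <- as_node_ids(graph, sequence)
  n <- igraph::vcount(graph)
  tm <- length(ids)
  if (is.null(sample_times)) {
    sample_times <- unique(as.integer(round(
      base::seq(0, tm, length.out = min(51, tm + 1)))))
  }
  sample_times <- as.integer(sample_times)
  if (any(diff(sample_times) <= 0) || any(sample_times < 0) ||
      any(sample_times > tm)) {
    stop("sample_times must be strictly increasing within [0, t_max]")
  }
  vals_A <- vals_I <- numeric(length(sample_times))
  for (i in seq_along(sample_times)) {
    t <- sample_times[i]
    idle <- ids[seq_len(t)]
    act <- setdiff(seq_len(n), idle)
    vals_A[i] <- connectivity_metric(igraph::induced_subgraph(graph, act),
                                     metric)
    vals_I[i] <- connectivity_metric(igraph::induced_subgraph(graph, idle),
                                     metric)
  }
  structure(list(metric = metric, sample_times = sample_times,
                 values_A = vals_A, values_I = vals_I, T = n, t_max = tm),
            class = "metric_trajectory")
}

connectivity_metric <- function(g, metric) {
  nv <- igraph::vcount(g)
  if (nv == 0) return(0)
  comp <- igraph::components(g)
  switch(metric,
    largest_cluster = max(comp$csize),
    n_clusters = comp$no,
    avg_cluster_size = mean(comp$csize),
    diameter = {
      giant <- which(comp$membership == which.max(comp$csize))
      if (length(giant) < 2) 0
      else igraph::diameter(igraph::induced_subgraph(g, giant),
                            unconnected = FALSE)
    },
    inv_geodesic = if (nv < 2) 0 else igraph::global_efficiency(g))
}

#' @export
print.metric_trajectory <- function(x, ...) {
  cat("Metric trajectory (", x$metric, "): T =", x$T,
      ",", length(x$sample_times), "sampled times\n")
  invisible(x)
}

#' @export
as.data.frame.metric_trajectory <- function(x, ...) {
  df <- data.frame(t = x$sample_times, A = x$values_A, I = x$values_I)
  names(df)[2:3] <- paste0(x$metric, c("_A", "_I"))
  df
}
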