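#' Read an undirected network from an edge list or GraphML file
#'
#' Edge lists are two-column CSV/TSV files (delimiter auto-detected from
#' the first line), one undirected edge per row; an optional header row is
#' recognised when its fields are common endpoint names (`from`/`to`,
#' `source`/`target`, `src`/`dst`, `node1`/`node2`). Node labels are
#' arbitrary strings, mapped to contiguous ids in order of first
#' appearance and kept as the `name` vertex attribute. Duplicate and
#' reversed edges collapse to one undirected edge; self-loops are dropped
#' with a warning. GraphML files are read through igraph (nodes and edges
#' only) and coerced to a simple undirected graph.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.graphml` vs delimited text),
#'   `"edgelist"`, or `"graphml"`.
#' @return An undirected simple igraph graph; the original labels are in
#'   `igraph::V(g)$name` (id `i` maps to the `i`-th label).
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "edgelist"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    n_loops <- sum(igraph::which_loop(g))
    if (n_loops > 0) warning("dropped ", n_loops, " self-loop(s)")
    return(igraph::simplify(g))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge-list file: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[1],
         ": expected two ", if (sep == ",") "comma" else "tab",
         "-separated fields")
  }
  a <- trimws(vapply(parts, `[`, character(1), 1))
  b <- trimws(vapply(parts, `[`, character(1), 2))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("parse error in ", path, " at line ",
         which(!nzchar(a) | !nzchar(b))[1], ": empty field")
  }
  header_names <- c("from", "to", "source", "target", "src", "dst",
                    "node1", "node2")
  if (tolower(a[1]) %in% header_names && tolower(b[1]) %in% header_names) {
    a <- a[-1]; b <- b[-1]
    if (length(a) == 0) stop("edge-list file contains only a header: ", path)
  }
  labels <- unique(c(rbind(a, b)))
  loops <- a == b
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)")
    a <- a[!loops]; b <- b[!loops]
  }
  if (length(a) == 0) {
    g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  } else {
    ia <- match(a, labels); ib <- match(b, labels)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    keep <- !duplicated(cbind(lo, hi))
    g <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, length(labels) - igraph::vcount(g))
  }
  igraph::V(g)$name <- labels
  g
}

#' Write a network as a two-column CSV edge list
#'
#' @param graph An undirected igraph graph.
#' @param path Output path.
#' @param header Write a `from,to` header row (default `TRUE`).
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path, header = TRUE) {
  el <- igraph::as_edgelist(graph, names = !is.null(igraph::V(graph)$name))
  df <- data.frame(from = el[, 1], to = el[, 2])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Write a dual trajectory as CSV
#'
#' Columns `t`, `S_A`, `S_I`; with `normalized = TRUE` the additional
#' columns `t_frac` (`t / T`) and `S_A_frac`, `S_I_frac` (`S / T`) are
#' emitted, matching the normalised axes used for trajectory plots.
#'
#' @param traj A [dual_trajectory()] object.
#' @param path Output path.
#' @param normalized Emit normalised columns as well.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path, normalized = FALSE) {
  stopifnot(inherits(traj, "dual_trajectory"))
  df <- as.data.frame(traj)
  if (normalized) {
    df$t_frac <- df$t / traj$T
    df$S_A_frac <- df$S_A / traj$T
    df$S_I_frac <- df$S_I / traj$T
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an efficiency pair as JSON
#'
#' @param E An `efficiency_pair` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_efficiencies_json <- function(E, path) {
  jsonlite::write_json(
    list(E_A = E$E_A, E_I = E$E_I, A_A = E$A_A, A_I = E$A_I,
         A_max = E$A_max, horizon_fraction = E$horizon_fraction,
         T = E$T, t_max = E$t_max),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
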