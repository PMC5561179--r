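#' Monte-Carlo ensemble of attacks
#'
#' Runs `n_runs` independent attack realisations and collects the per-run
#' efficiency pairs. Child seeds are drawn once from `master_seed`
#' (`set.seed(master_seed); sample.int(2^31 - 2, n_runs)`), so runs are
#' independent but the whole ensemble is bit-reproducible. Before each run
#' the RNG is seeded with the run's child seed; a stochastic graph factory
#' then consumes the same stream as the attack, so fresh-graph ensembles are
#' reproducible too.
#'
#' @param graph Either a fixed igraph graph, or a zero-argument function
#'   returning a graph (called once per run, drawing from the current RNG
#'   stream) for ensembles over random networks.
#' @param strategy Attack strategy, see [plan_attack()].
#' @param n_runs Number of realisations, >= 1.
#' @param master_seed Integer master seed.
#' @param horizon Attack horizon, see [plan_attack()].
#' @param ta_degree_mode Targeted-attack degree mode, see [plan_attack()].
#' @param network_id Optional label stored in the result.
#' @return An object of class `attack_ensemble`: list with the run table
#'   (`runs`: seed, `E_A`, `E_I` per run), ensemble means and sample
#'   standard deviations (`mean_E_A`, `sd_E_A`, `mean_E_I`, `sd_E_I`; the
#'   standard deviation is `NA` for `n_runs = 1`), and the configuration.
#' @examples
#' run_ensemble(lattice_graph(10), "rf", n_runs = 5, master_seed = 1)
#' @export
run_ensemble <- function(graph, strategy, n_runs = 100, master_seed = 1,
                         horizon = NULL, ta_degree_mode = "current",
                         network_id = NULL) {
  stopifnot(n_runs >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_runs)
  is_factory <- is.function(graph)
  E_A <- E_I <- numeric(n_runs)
  hf <- NA_real_
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    g <- tryCatch(if (is_factory) graph() else graph,
                  error = function(e) stop("run ", i, ": ",
                                           conditionMessage(e)))
    sq <- tryCatch(
      plan_attack(g, strategy, horizon = horizon,
                  ta_degree_mode = ta_degree_mode),
      error = function(e) stop("run ", i, ": ", conditionMessage(e)))
    p <- attack_efficiencies(dual_trajectory(g, sq))
    E_A[i] <- p$E_A
    E_I[i] <- p$E_I
    hf <- p$horizon_fraction
  }
  structure(list(network_id = network_id %||% "network",
                 strategy = strategy,
                 ta_degree_mode = ta_degree_mode,
                 horizon_fraction = hf,
                 n_runs = n_runs,
                 master_seed = master_seed,
                 runs = data.frame(run = seq_len(n_runs), seed = seeds,
                                   E_A = E_A, E_I = E_I),
                 mean_E_A = mean(E_A),
                 sd_E_A = if (n_runs > 1) sd(E_A) else NA_real_,
                 mean_E_I = mean(E_I),
                 sd_E_I = if (n_runs > 1) sd(E_I) else NA_real_),
            class = "attack_ensemble")
}

#' @export
print.attack_ensemble <- function(x, ...) {
  cat(sprintf(
    "Attack ensemble: %s / %s (%d runs, horizon %.0f%%)\n",
    x$network_id, x$strategy, x$n_runs, 100 * x$horizon_fraction))
  cat(sprintf("  E_A = %.3f +/- %s   E_I = %.3f +/- %s\n",
              x$mean_E_A, fmt_sd(x$sd_E_A),
              x$mean_E_I, fmt_sd(x$sd_E_I)))
  invisible(x)
}

fmt_sd <- function(s) if (is.na(s)) "NA" else sprintf("%.3f", s)

#' Published reference efficiencies for the prototype networks
#'
#' Reference ensemble values (mean +/- standard deviation over 100
#' simulations, full destruction horizon) for the three attack strategies
#' on the three prototype networks: the 10,000-node periodic lattice, the
#' order-6 Tokunaga tree with `(a, c) = (1, 2)`, and the Barabasi-Albert
#' network with `(m0, m) = (3, 2)` and 1,000 nodes. Used by
#' [reproduce_table1()] to report agreement of a fresh simulation with the
#' reference values.
#'
#' @return A data frame with columns `network`, `strategy`, `E_A`,
#'   `sd_E_A`, `E_I`, `sd_E_I`.
#' @export
published_efficiencies <- function() {
  data.frame(
    network = rep(c("lattice", "t_tree", "ba"), each = 3),
    strategy = rep(c("random_failure", "targeted_attack",
                     "random_spreading"), 3),
    E_A = c(0.35, 0.42, 0.02, 0.58, 0.87, 0.76, 0.17, 0.48, 0.19),
    sd_E_A = c(0.01, 0.00, 0.02, 0.10, 0.04, 0.09, 0.02, 0.02, 0.02),
    E_I = c(0.65, 0.58, 1, 0.39, 0.75, 1, 0.83, 0.94, 1),
    sd_E_I = c(0.01, 0.01, 0, 0.10, 0.04, 0, 0.02, 0.01, 0),
    stringsAsFactors = FALSE)
}

#' Reproduce the prototype-network efficiency table
#'
#' Runs the full 3 x 3 ensemble suite -- {periodic lattice, Tokunaga tree,
#' Barabasi-Albert} x {random failure, targeted attack, random spreading}
#' -- at full destruction horizon and reports ensemble mean +/- sample
#' standard deviation of `(E_A, E_I)` per cell, next to the published
#' reference values with absolute differences and z-scores
#' (`(mean - ref) / sd_ref`; `NA` where the reference spread is 0).
#'
#' The lattice and (by default) the Tokunaga tree are fixed graphs attacked
#' with fresh randomness per run; the BA network is regenerated per run.
#' `tree_mode = "poisson"` switches the tree ensemble to a fresh random
#' Tokunaga tree per run.
#'
#' @param n_runs Runs per cell, default 100.
#' @param master_seed Integer master seed; per-cell seeds are derived from
#'   it deterministically.
#' @param lattice_side Lattice side, default 100 (10,000 nodes).
#' @param tree_order,tree_a,tree_c Tokunaga parameters, default order 6,
#'   `(a, c) = (1, 2)`.
#' @param tree_mode `"deterministic"` (one fixed tree) or `"poisson"`
#'   (fresh random tree per run).
#' @param ba_nodes,ba_m0,ba_m Barabasi-Albert parameters, default
#'   `(1000, 3, 2)`.
#' @param ta_degree_mode Targeted-attack degree mode, default `"current"`.
#' @return An object of class `table1_report`: list with `ensembles` (named
#'   list of [run_ensemble()] results, names `<network>.<strategy>`) and
#'   `summary` (one row per cell with means, spreads, reference values and
#'   deviations).
#' @export
reproduce_table1 <- function(n_runs = 100, master_seed = 1,
                             lattice_side = 100,
                             tree_order = 6, tree_a = 1, tree_c = 2,
                             tree_mode = c("deterministic", "poisson"),
                             ba_nodes = 1000, ba_m0 = 3, ba_m = 2,
                             ta_degree_mode = "current") {
  tree_mode <- match.arg(tree_mode)
  networks <- list(
    lattice = lattice_graph(lattice_side),
    t_tree = if (tree_mode == "deterministic") {
      tokunaga_tree(tree_order, tree_a, tree_c)
    } else {
      function() tokunaga_tree(tree_order, tree_a, tree_c, mode = "poisson")
    },
    ba = function() ba_graph(ba_nodes, ba_m0, ba_m))
  strategies <- c("random_failure", "targeted_attack", "random_spreading")

  set.seed(master_seed)
  cell_seeds <- sample.int(2147483646L, length(networks) * length(strategies))
  ensembles <- list()
  rows <- list()
  k <- 0L
  ref <- published_efficiencies()
  for (net in names(networks)) {
    for (strat in strategies) {
      k <- k + 1L
      ens <- run_ensemble(networks[[net]], strat, n_runs = n_runs,
                          master_seed = cell_seeds[k],
                          ta_degree_mode = ta_degree_mode,
                          network_id = net)
      ensembles[[paste(net, strat, sep = ".")]] <- ens
      r <- ref[ref$network == net & ref$strategy == strat, ]
      rows[[k]] <- data.frame(
        network = net, strategy = strat,
        mean_E_A = ens$mean_E_A, sd_E_A = ens$sd_E_A,
        mean_E_I = ens$mean_E_I, sd_E_I = ens$sd_E_I,
        ref_E_A = r$E_A, ref_sd_E_A = r$sd_E_A,
        ref_E_I = r$E_I, ref_sd_E_I = r$sd_E_I,
        delta_E_A = abs(ens$mean_E_A - r$E_A),
        delta_E_I = abs(ens$mean_E_I - r$E_I),
        z_E_A = if (r$sd_E_A > 0) (ens$mean_E_A - r$E_A) / r$sd_E_A
                else NA_real_,
        z_E_I = if (r$sd_E_I > 0) (ens$mean_E_I - r$E_I) / r$sd_E_I
                else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(ensembles = ensembles,
                 summary = do.call(rbind, rows),
                 n_runs = n_runs, master_seed = master_seed,
                 ta_degree_mode = ta_degree_mode, tree_mode = tree_mode),
            class = "table1_report")
}

#' @export
print.table1_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Prototype-network efficiency table (%d runs/cell, seed %d, TA mode %s)\n",
    x$n_runs, x$master_seed, x$ta_degree_mode))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-8s %-17s E_A %.3f+/-%s (ref %.2f)  E_I %.3f+/-%s (ref %.2f)\n",
      s$network[i], s$strategy[i],
      s$mean_E_A[i], fmt_sd(s$sd_E_A[i]), s$ref_E_A[i],
      s$mean_E_I[i], fmt_sd(s$sd_E_I[i]), s$ref_E_I[i]))
  }
  invisible(x)
}

#' Robustness curves and crossover table for a set of strategies
#'
#' From a list of attack ensembles on the same network and horizon, builds
#' one `R_N(alpha)` curve per strategy (from the ensemble-mean
#' efficiencies), all pairwise crossover weights, and the strategy ranking
#' (most to least robust) at `alpha` = 0, 0.5 and 1.
#'
#' @param results Named list of [run_ensemble()] results sharing network
#'   and horizon (names default to each ensemble's strategy).
#' @param alpha_grid Weight grid for the curves.
#' @return An object of class `rn_suite`: list with `curves` (long data
#'   frame `alpha`, `strategy`, `R_N`), `crossovers` (data frame
#'   `strategy_1`, `strategy_2`, `alpha_star`, `status`), and `ranking`
#'   (data frame `alpha`, `ranking`).
#' @export
rn_curve_suite <- function(results, alpha_grid = base::seq(0, 1, by = 0.01)) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- vapply(results, function(r) r$strategy, character(1))
  }
  hf <- vapply(results, function(r) r$horizon_fraction, numeric(1))
  if (length(unique(round(hf, 10))) > 1) {
    stop("mixed horizons: all ensembles must share the same horizon")
  }
  nid <- vapply(results, function(r) r$network_id, character(1))
  if (length(unique(nid)) > 1) {
    stop("mixed networks: all ensembles must be on the same network")
  }
  pairs <- lapply(results, function(r) eff_pair(r$mean_E_A, r$mean_E_I,
                                                r$horizon_fraction))
  curves <- do.call(rbind, lapply(names(pairs), function(nm) {
    data.frame(alpha = alpha_grid, strategy = nm,
               R_N = robustness(pairs[[nm]], alpha_grid),
               stringsAsFactors = FALSE)
  }))
  crossovers <- if (length(pairs) >= 2) {
    cmb <- combn(names(pairs), 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- crossover_alpha(pairs[[cmb[1, j]]], pairs[[cmb[2, j]]])
      data.frame(strategy_1 = cmb[1, j], strategy_2 = cmb[2, j],
                 alpha_star = as.numeric(a),
                 status = attr(a, "status"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(strategy_1 = character(0), strategy_2 = character(0),
               alpha_star = numeric(0), status = character(0))
  }
  ranking <- do.call(rbind, lapply(c(0, 0.5, 1), function(a) {
    rn <- vapply(pairs, robustness, numeric(1), alpha = a)
    data.frame(alpha = a,
               ranking = paste(names(sort(rn, decreasing = TRUE)),
                               collapse = " > "),
               stringsAsFactors = FALSE)
  }))
  structure(list(curves = curves, crossovers = crossovers,
                 ranking = ranking, network_id = nid[[1]],
                 horizon_fraction = hf[[1]]),
            class = "rn_suite")
}

#' @export
print.rn_suite <- function(x, ...) {
  cat(sprintf("Robustness curve suite: %s (horizon %.0f%%)\n",
              x$network_id, 100 * x$horizon_fraction))
  if (nrow(x$crossovers)) {
    cat("Crossovers:\n")
    for (i in seq_len(nrow(x$crossovers))) {
      cat(sprintf("  %s vs %s: alpha* = %s (%s)\n",
                  x$crossovers$strategy_1[i], x$crossovers$strategy_2[i],
                  ifelse(is.na(x$crossovers$alpha_star[i]), "none",
                         sprintf("%.3f", x$crossovers$alpha_star[i])),
                  x$crossovers$status[i]))
    }
  }
  cat("Ranking (most to least robust):\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("  alpha = %.1f: %s\n", x$ranking$alpha[i],
                x$ranking$ranking[i]))
  }
  invisible(x)
}
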