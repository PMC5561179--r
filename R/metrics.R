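#' Attack efficiencies from a dual trajectory
#'
#' The efficiency of destroying the Active Network is the normalised area
#' between the active-node staircase `T - t` and `S_A(t)`,
#' `E_A = A_A / A_max` with `A_A = sum(T - t - S_A(t))` and
#' `A_max = sum(T - t)`, both sums over `t = 0..t_max`. The efficiency of
#' building the Idle Network is the normalised area under `S_I(t)`,
#' `E_I = A_I / A_max` with `A_I = sum(S_I(t))`. At full horizon
#' (`t_max = T`) `A_max = T (T + 1) / 2`, recovering
#' `E_A = 1 - 2 / (T (T + 1)) * sum(S_A)` and
#' `E_I = 2 / (T (T + 1)) * sum(S_I)`; for a partial horizon both numerator
#' and denominator are truncated at `t_max`, which keeps the efficiencies in
#' `[0, 1]` and reduces to the full-horizon formulas when `t_max = T`.
#'
#' `attack_efficiencies()` accepts any horizon. `efficiency_active()` and
#' `efficiency_idle()` are the scalar full-horizon accessors and raise an
#' error on a partial trajectory, pointing to `efficiency_partial()`.
#'
#' @param traj A [dual_trajectory()] object.
#' @return `attack_efficiencies()` and `efficiency_partial()` return an
#'   object of class `efficiency_pair`: a list with `E_A`, `E_I`, the areas
#'   `A_A`, `A_I`, `A_max`, `horizon_fraction` (`t_max / T`), `T`, `t_max`.
#'   The scalar accessors return a single number.
#' @examples
#' g <- path_graph(7)
#' tr <- dual_trajectory(g, greedy_fragmentation(g))
#' efficiency_active(tr)  # 11/28
#' @export
attack_efficiencies <- function(traj) {
  stopifnot(inherits(traj, "dual_trajectory"))
  if (traj$t_max < 1) stop("undefined efficiency: trajectory has t_max = 0")
  tt <- traj$t
  A_max <- sum(traj$T - tt)
  A_A <- A_max - sum(traj$S_A)
  A_I <- sum(traj$S_I)
  structure(list(E_A = A_A / A_max, E_I = A_I / A_max,
                 A_A = A_A, A_I = A_I, A_max = A_max,
                 horizon_fraction = traj$t_max / traj$T,
                 T = traj$T, t_max = traj$t_max),
            class = "efficiency_pair")
}

#' @rdname attack_efficiencies
#' @export
efficiency_active <- function(traj) {
  stopifnot(inherits(traj, "dual_trajectory"))
  if (traj$t_max < traj$T) {
    stop("partial-horizon trajectory: use efficiency_partial()")
  }
  attack_efficiencies(traj)$E_A
}

#' @rdname attack_efficiencies
#' @export
efficiency_idle <- function(traj) {
  stopifnot(inherits(traj, "dual_trajectory"))
  if (traj$t_max < traj$T) {
    stop("partial-horizon trajectory: use efficiency_partial()")
  }
  attack_efficiencies(traj)$E_I
}

#' @rdname attack_efficiencies
#' @export
efficiency_partial <- function(traj) {
  stopifnot(inherits(traj, "dual_trajectory"))
  if (traj$t_max < 1) stop("undefined efficiency: trajectory has t_max = 0")
  attack_efficiencies(traj)
}

#' Construct an efficiency pair from known values
#'
#' Convenience constructor, e.g. for computing crossovers from published or
#' externally obtained mean efficiencies.
#'
#' @param E_A,E_I Efficiencies in `[0, 1]`.
#' @param horizon_fraction Fraction of nodes removed, default 1.
#' @return An `efficiency_pair` object (areas unset).
#' @export
eff_pair <- function(E_A, E_I, horizon_fraction = 1) {
  stopifnot(is.numeric(E_A), is.numeric(E_I))
  structure(list(E_A = E_A, E_I = E_I, A_A = NA_real_, A_I = NA_real_,
                 A_max = NA_real_, horizon_fraction = horizon_fraction,
                 T = NA_integer_, t_max = NA_integer_),
            class = "efficiency_pair")
}

#' @export
print.efficiency_pair <- function(x, ...) {
  cat(sprintf("Attack efficiencies (horizon %.0f%%): E_A = %.4f, E_I = %.4f\n",
              100 * x$horizon_fraction, x$E_A, x$E_I))
  invisible(x)
}

#' Weighted dual-connectivity robustness
#'
#' `R_N(alpha) = alpha (1 - E_A) + (1 - alpha) (1 - E_I)`: the weight
#' `alpha` is given to the (inverse) efficiency of destroying the Active
#' Network and `1 - alpha` to that of building up the Idle Network.
#' `alpha = 1` recovers the conventional robustness used in the
#' attack-tolerance literature; `alpha = 0` scores only the idle side.
#'
#' @param E An `efficiency_pair` (or list with `E_A` and `E_I`).
#' @param alpha Weight(s) in `[0, 1]`; vectorised.
#' @return Numeric robustness value(s).
#' @examples
#' robustness(eff_pair(0.35, 0.65), c(0, 0.5, 1))
#' @export
robustness <- function(E, alpha) {
  if (!is.numeric(alpha) || any(is.na(alpha)) ||
      any(alpha < 0 | alpha > 1)) {
    stop("invalid weight: alpha must lie in [0, 1]")
  }
  alpha * (1 - E$E_A) + (1 - alpha) * (1 - E$E_I)
}

#' @rdname robustness
#' @param alpha_grid Grid of weights, default `seq(0, 1, by = 0.01)`.
#' @return `robustness_curve()` returns a data frame with columns `alpha`
#'   and `R_N`.
#' @export
robustness_curve <- function(E, alpha_grid = base::seq(0, 1, by = 0.01)) {
  data.frame(alpha = alpha_grid, R_N = robustness(E, alpha_grid))
}

#' Crossover weight between two attack strategies
#'
#' Solves `R_N1(alpha*) = R_N2(alpha*)` for the weight at which the two
#' linear robustness curves intersect:
#' `alpha* = (E_I1 - E_I2) / ((E_I1 - E_I2) + (E_A2 - E_A1))`.
#'
#' @param E1,E2 `efficiency_pair` objects (or lists with `E_A`, `E_I`),
#'   typically ensemble means on the same network and horizon.
#' @return The crossover weight in `[0, 1]`, with attribute `status =
#'   "crossover"`; otherwise `NA` with `status` one of `"identical"` (the
#'   curves coincide), `"parallel"` (equal slope, never cross), or
#'   `"outside"` (intersection exists but falls outside `[0, 1]`; the raw
#'   solution is kept in attribute `alpha_raw`).
#' @examples
#' crossover_alpha(eff_pair(0.48, 0.94), eff_pair(0.19, 1))  # ~0.171
#' @export
crossover_alpha <- function(E1, E2) {
  dI <- E1$E_I - E2$E_I
  dA <- E2$E_A - E1$E_A
  if (dI == 0 && dA == 0) return(structure(NA_real_, status = "identical"))
  den <- dI + dA
  if (den == 0) return(structure(NA_real_, status = "parallel"))
  a <- dI / den
  if (a < 0 || a > 1) {
    return(structure(NA_real_, status = "outside", alpha_raw = a))
  }
  structure(a, status = "crossover")
}
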