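test_that("full-horizon efficiencies match closed-form fixture values", {
  g <- path_graph(7)
  tr <- dual_trajectory(g, greedy_fragmentation(g))
  # S_A = (7,3,3,1,1,1,1,0): E_A = 1 - 2*17/56 = 11/28
  expect_equal(efficiency_active(tr), 11 / 28)
  # S_I = (0,1,1,1,2,4,6,7): E_I = 2*22/56 = 11/14 (naive-oracle checked)
  ref <- naive_dual_trajectory(g, greedy_fragmentation(g))
  expect_equal(efficiency_idle(tr), 2 * sum(ref$S_I) / (7 * 8))
  expect_equal(efficiency_idle(tr), 11 / 14)

  p <- attack_efficiencies(tr)
  expect_equal(p$E_A, p$A_A / p$A_max)
  expect_equal(p$E_I, p$A_I / p$A_max)
  expect_equal(p$A_max, 7 * 8 / 2)
})

test_that("complete-graph attacks have zero active efficiency", {
  # removal never fragments a clique: S_A(t) = T - t, so A_A = 0
  g <- igraph::make_full_graph(5)
  tr <- dual_trajectory(g, 1:5)
  expect_equal(efficiency_active(tr), 0)
  expect_equal(efficiency_idle(tr), 1)  # and S_I(t) = t
})

test_that("degenerate sizes behave per the definitions", {
  g1 <- path_graph(1)
  tr1 <- dual_trajectory(g1, 1L)
  expect_equal(efficiency_active(tr1), 0)  # sum S_A = 1 = A_max
  expect_equal(efficiency_idle(tr1), 1)

  # edgeless graph: all clusters are singletons, E_I = 2/(T+1)
  g0 <- igraph::make_empty_graph(6, directed = FALSE)
  tr0 <- dual_trajectory(g0, sample(6))
  expect_equal(efficiency_idle(tr0), 2 / 7)
  expect_error(attack_efficiencies(dual_trajectory(g0, integer(0))),
               "t_max = 0")
})

test_that("random spreading attains exact unit idle efficiency", {
  set.seed(21)
  for (g in list(lattice_graph(12), tokunaga_tree(5), ba_graph(150, 3, 2))) {
    tr <- dual_trajectory(g, plan_attack(g, "rs"))
    expect_identical(efficiency_idle(tr), 1)  # exact, not approximate
  }
})

test_that("partial horizons truncate both numerator and denominator", {
  g <- path_graph(7)
  sq <- greedy_fragmentation(g, steps = 3)
  tr <- dual_trajectory(g, sq)
  p <- efficiency_partial(tr)
  # S_A = (7,3,3,1): A_A = (0+3+2+3), A_max = (7+6+5+4)
  expect_equal(p$E_A, 8 / 22)
  expect_equal(p$A_max, 22)
  expect_equal(p$horizon_fraction, 3 / 7)
  expect_error(efficiency_active(tr), "efficiency_partial")
  expect_error(efficiency_idle(tr), "efficiency_partial")

  # RS under truncation: S_I(t) = t but the normaliser is larger, E_I < 1
  L <- lattice_graph(10)
  trp <- dual_trajectory(L, plan_attack(L, "rs", horizon = 0.1, seed = 2))
  pp <- efficiency_partial(trp)
  expect_lt(pp$E_I, 1)
  expect_equal(pp$E_I, sum(0:10) / sum(100 - 0:10))
})

test_that("efficiencies are invariant under node relabeling", {
  set.seed(9)
  g <- ba_graph(60, 3, 2)
  sq <- plan_attack(g, "ta")
  perm <- sample(60)
  g2 <- igraph::permute(g, perm)
  p1 <- attack_efficiencies(dual_trajectory(g, sq))
  p2 <- attack_efficiencies(dual_trajectory(g2, perm[sq]))
  expect_equal(p1$E_A, p2$E_A)
  expect_equal(p1$E_I, p2$E_I)
})

test_that("robustness is the stated weighted average with valid weights", {
  E <- eff_pair(0.35, 0.65)
  expect_equal(robustness(E, 1), 1 - 0.35)   # conventional AN-only form
  expect_equal(robustness(E, 0), 1 - 0.65)
  expect_equal(robustness(E, 0.5), 0.5)      # complementary pair
  expect_equal(robustness_curve(E, c(0, 1))$R_N, c(0.35, 0.65))
  # linear in alpha with slope E_I - E_A
  a <- base::seq(0, 1, 0.25)
  expect_equal(diff(robustness(E, a)) / diff(a), rep(0.65 - 0.35, 4))
  expect_error(robustness(E, 1.1), "alpha")
  expect_error(robustness(E, -0.1), "alpha")
})

test_that("crossover weights match the reference efficiency pairs", {
  # BA network: TA (0.48, 0.94) vs RS (0.19, 1) -> 0.06/0.35
  a_ba <- crossover_alpha(eff_pair(0.48, 0.94), eff_pair(0.19, 1))
  expect_equal(as.numeric(a_ba), 0.06 / 0.35, tolerance = 1e-12)
  expect_identical(attr(a_ba, "status"), "crossover")
  # Tokunaga tree: TA (0.87, 0.75) vs RS (0.76, 1) -> 0.25/0.36
  a_tt <- crossover_alpha(eff_pair(0.87, 0.75), eff_pair(0.76, 1))
  expect_equal(as.numeric(a_tt), 0.25 / 0.36, tolerance = 1e-12)
  # complementary pairs always cross at exactly 1/2
  expect_equal(as.numeric(crossover_alpha(eff_pair(0.3, 0.7),
                                          eff_pair(0.6, 0.4))), 0.5)

  expect_identical(attr(crossover_alpha(eff_pair(0.4, 0.6),
                                        eff_pair(0.4, 0.6)), "status"),
                   "identical")
  expect_identical(attr(crossover_alpha(eff_pair(0.4, 0.6),
                                        eff_pair(0.5, 0.7)), "status"),
                   "parallel")
  expect_identical(attr(crossover_alpha(eff_pair(0.4, 0.6),
                                        eff_pair(0.45, 0.7)), "status"),
                   "outside")
})

test_that("closed-form crossover agrees with numeric curve intersection", {
  E1 <- eff_pair(0.48, 0.94); E2 <- eff_pair(0.19, 1)
  a_closed <- as.numeric(crossover_alpha(E1, E2))
  a_root <- stats::uniroot(function(a) robustness(E1, a) - robustness(E2, a),
                           c(0, 1), tol = 1e-14)$root
  expect_lt(abs(a_closed - a_root), 1e-9)
})
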