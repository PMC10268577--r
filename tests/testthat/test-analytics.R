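test_that("equilibrium enforcer fractions match hand evaluations", {
  expect_equal(alpha_cooperation(baseline()), 1.5 / 5.3, tolerance = 1e-12)
  expect_equal(alpha_defection(baseline()), 0.6 / 7, tolerance = 1e-12)
  expect_equal(alpha_cooperation(alternative()), 0.9 / 3.4, tolerance = 1e-12)
  expect_equal(alpha_defection(alternative()), 0.6 / 6, tolerance = 1e-12)
  # degenerate limits: no information cost / no conflict loss collapse to tau
  expect_equal(alpha_cooperation(game_params(f = 0)), 0.3)
  expect_equal(alpha_defection(game_params(l = 0)), 0.3)
})

test_that("both equilibrium fractions increase in the tax rate", {
  taus <- seq(0.05, 0.9, by = 0.05)
  aC <- vapply(taus, function(t) alpha_cooperation(game_params(tau = t, v = 0)),
               numeric(1))
  aD <- vapply(taus, function(t) alpha_defection(game_params(tau = t, v = 0)),
               numeric(1))
  expect_true(all(diff(aC) > 0))
  expect_true(all(diff(aD) > 0))
})

test_that("static equilibrium conditions hold at both parameterizations", {
  sb <- check_static_conditions(baseline())
  expect_true(sb$conflict)     # 5 > 2 * max(0.3, 0.1) = 0.6
  expect_true(sb$deterrence)   # 2 > 0.7
  expect_true(sb$both)
  sa <- check_static_conditions(alternative())
  expect_true(sa$conflict)     # 4 > 0.8
  expect_true(sa$deterrence)   # 2 > 1.4
  # the stricter deterrence reading separates the two parameterizations
  expect_true(sb$deterrence_strict)    # 2 > 1 / 0.7
  expect_false(sa$deterrence_strict)   # 2 < 2 / 0.7
  # strictness at the boundary
  expect_false(check_static_conditions(game_params(p = 0.7))$deterrence)
})

test_that("the stochastic-stability criterion matches hand evaluations", {
  sb <- suppressWarnings(stochastic_stability(baseline()))
  expect_equal(sb$lhs, 5 / 0.3 - 1 / 3.5, tolerance = 1e-12)  # ~16.38095
  expect_equal(sb$rhs, 1.06, tolerance = 1e-12)
  expect_equal(sb$verdict, "cooperation")
  sa <- suppressWarnings(stochastic_stability(alternative()))
  expect_equal(sa$lhs, 10 - 1 / 3, tolerance = 1e-12)
  expect_equal(sa$rhs, 1 + 0.4 / 3, tolerance = 1e-12)
  expect_equal(sa$verdict, "cooperation")
  # conflict barely above information cost: defection is selected
  sd <- stochastic_stability(game_params(l = 0.31, f = 0.3, v = 0))
  expect_equal(sd$verdict, "defection")
  expect_equal(stochastic_stability(game_params(f = 0, v = 0))$verdict,
               "cooperation")
  expect_true(suppressWarnings(
    stochastic_stability(baseline()))$assumption_flags[["v_positive"]])
})

test_that("basin classification matches the published inequalities and partitions the space", {
  p <- baseline()  # f / l = 0.06
  grid <- expand.grid(n_CE = 0:15, n_E = 0:15)
  out <- classify_basin(grid, p)
  # every state gets exactly one of the three labels
  expect_true(all(out$basin %in% c("E_C_basin", "E_D_basin", "boundary_band")))
  pick <- function(nce, ne) out$basin[out$n_CE == nce & out$n_E == ne]
  expect_equal(pick(2, 15), "E_C_basin")     # 2 > 0.06 * 14 + 1 = 1.84
  expect_equal(pick(5, 1), "E_D_basin")      # n_E < 2
  expect_equal(pick(0, 15), "E_D_basin")     # no CE at all
  expect_equal(pick(1, 15), "boundary_band") # 0.84 <= ... <= 1
  # direct inequality cross-check on every grid point
  theta <- p$f / p$l
  manual <- with(out, ifelse(n_E < 2, "E_D_basin",
                      ifelse(n_CE > theta * (n_E - 1) + 1, "E_C_basin",
                      ifelse(n_CE < theta * (n_E - 1), "E_D_basin",
                             "boundary_band"))))
  expect_equal(out$basin, manual)
  # population_state interface
  expect_equal(classify_basin(ce2_state(CP = 30, DP = 5, CE = 10, DE = 5), p),
               "E_C_basin")
})

test_that("equilibrium payoffs equalize roles and favour cooperation", {
  ep <- equilibrium_payoffs(baseline())
  expect_equal(ep$producer_coop, 3.5)
  expect_equal(ep$producer_def, 1.4)
  expect_equal(ep$enforcer_coop, ep$producer_coop, tolerance = 1e-12)
  expect_equal(ep$enforcer_def, ep$producer_def, tolerance = 1e-12)
  expect_true(ep$coop_payoff_higher)
  expect_true(ep$alpha_C_higher)
  tt <- tidy(ep)
  expect_equal(nrow(tt), 4L)
})

test_that("cooperation dominates defection across a randomized admissible grid", {
  set.seed(19)
  for (k in 1:100) {
    b <- runif(1, 0.5, 8); c <- runif(1, 0.05, 0.95) * b
    w <- runif(1, 0.5, 5); tau <- runif(1, 0.05, 0.95)
    v <- runif(1, 0, tau * w * 0.9)
    f <- runif(1, 0, 3); l <- f + runif(1, 0.01, 5)  # f < l
    pp <- suppressWarnings(game_params(b = b, c = c, w = w, tau = tau,
                                       v = v, f = f, l = l))
    ep <- equilibrium_payoffs(pp)
    expect_gt(ep$alpha_C, ep$alpha_D)
    expect_gt(ep$producer_coop, ep$producer_def)
    expect_equal(ep$enforcer_coop, ep$producer_coop, tolerance = 1e-9)
  }
})

test_that("parameter scans tabulate the closed-form quantities", {
  sc <- scan_parameters(data.frame(l = c(0.31, 5), f = c(0.3, 0.3)),
                        baseline(v = 0))
  expect_equal(sc$ss_verdict, c("defection", "cooperation"))
  expect_equal(names(sc)[1:2], c("l", "f"))
  expect_true(all(c("alpha_C", "alpha_D", "conflict_ok", "deterrence_ok")
                  %in% names(sc)))
})
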