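test_that("logit probabilities normalize, respect limits, and ignore payoff shifts", {
  expect_equal(logit_probs(c(X = 1, Y = 1), eta = 2), c(X = 0.5, Y = 0.5))
  expect_equal(logit_probs(c(X = 1, Y = 0), eta = 1)[["X"]], exp(1) / (1 + exp(1)))
  expect_equal(unname(logit_probs(c(X = 1, Y = 0), eta = 0)), c(1, 0))
  set.seed(8)
  for (k in 1:20) {
    pay <- stats::setNames(rnorm(sample(2:6, 1), sd = 5), NULL)
    names(pay) <- paste0("s", seq_along(pay))
    eta <- runif(1, 0.01, 10)
    pr <- logit_probs(pay, eta)
    expect_equal(sum(pr), 1)
    expect_equal(logit_probs(pay + 100, eta), pr)      # shift invariance
    expect_true(all(diff(pr[order(pay)]) >= -1e-12))   # monotone in payoffs
  }
  # eta large: approaches uniform; huge payoffs do not overflow
  pr <- logit_probs(c(a = 1e8, b = 0), eta = 1e12)
  expect_lt(abs(pr[["a"]] - 0.5), 1e-3)
  expect_true(all(is.finite(logit_probs(c(a = 1e300, b = -1e300), eta = 1))))
  expect_error(logit_probs(numeric(), 1), "empty menu")
})

test_that("exact best response picks the argmax and breaks ties uniformly", {
  set.seed(2)
  expect_equal(logit_choice(c(A = 3, B = 1), eta = 0), "A")
  picks <- replicate(600, logit_choice(c(A = 1, B = 1), eta = 0))
  expect_lt(abs(mean(picks == "A") - 0.5), 0.07)
})

test_that("revision classes are drawn with the gamma frequencies and fall back when empty", {
  s <- strategy_set("CE2")
  st <- population_state(s, counts = c(CP = 6, CE = 4))
  set.seed(30)
  d <- draw_revision_class(st, c(0, 0, 1))
  expect_equal(d$class, "P")
  expect_setequal(d$menu, c("CP", "DP"))
  d2 <- draw_revision_class(st, c(1, 0, 0))
  expect_equal(d2$class, "PE")
  expect_equal(length(d2$menu), 4L)
  cls <- replicate(20000, draw_revision_class(st, c(0.1, 0.3, 0.6))$class)
  freq <- table(cls)[c("PE", "E", "P")] / 20000
  expect_true(all(abs(freq - c(0.1, 0.3, 0.6)) < 0.015))
  # no enforcers: the enforcer class falls back to the whole population
  st0 <- population_state(s, counts = c(CP = 10))
  d3 <- draw_revision_class(st0, c(0, 1, 0))
  expect_equal(d3$class, "PE")
})

test_that("revise_agent follows payoffs when epsilon = 0 and mutates uniformly when epsilon = 1", {
  p <- baseline(delta = 0, mu = 0, epsilon = 0, eta = 0)
  st <- ce2_state(CP = 8, DP = 2, CE = 4)
  set.seed(3)
  pr <- play_period(st, p)
  dp_agent <- which(st$set$label[st$assign] == "DP")[1]
  # realized CP average 3.5ish beats punished DP average 2.2
  st2 <- revise_agent(st, pr, p, dp_agent, c("CP", "DP"))
  expect_equal(st2$set$label[st2$assign[dp_agent]], "CP")
  # epsilon = 1: uniform over the menu, payoffs ignored
  p1 <- baseline(epsilon = 1)
  set.seed(4)
  picks <- replicate(400, {
    s1 <- revise_agent(st, pr, p1, dp_agent, c("CP", "DP"))
    s1$set$label[s1$assign[dp_agent]]
  })
  expect_lt(abs(mean(picks == "CP") - 0.5), 0.1)
})

test_that("hypothetical payoffs reproduce the closed-form examples", {
  p <- baseline()
  st <- ce2_state(CP = 36, CE = 14)
  expect_equal(hypothetical_payoff("CP", st, p), 3.5)  # (1 - tau)(w + b - c)
  st2 <- ce2_state(CP = 35, DP = 1, CE = 14)
  expect_equal(hypothetical_payoff("DP", st2, p), 0.7 * 6 - 2)  # deterred
  stD <- ce2_state(DP = 46, DE = 4)
  expect_equal(hypothetical_payoff("DE", stD, p),
               p$tau * p$w * 46 / 4 - p$l)
  # unused-candidate contract: the state must contain the candidate
  expect_error(hypothetical_payoff("DE", st, p), "must contain the candidate")
})

test_that("one-period chains average the initial state and identical seeds reproduce runs", {
  p <- baseline()
  s <- strategy_set("CE2")
  st <- population_state(s, counts = c(CP = 30, DP = 6, CE = 10, DE = 4))
  set.seed(10)
  cr <- run_markov_chain(p, init = st, periods = 1L)
  expect_equal(unname(cr$shares), c(30, 6, 10, 4) / 50)
  set.seed(77); a <- run_markov_chain(p, set = s, periods = 500)
  set.seed(77); b <- run_markov_chain(p, set = s, periods = 500)
  expect_identical(a$shares, b$shares)
  expect_identical(a$final$assign, b$final$assign)
})

test_that("with revision mistakes every strategy is eventually adopted (ergodicity)", {
  p <- baseline()  # epsilon = 0.05
  s <- strategy_set("CE2")
  set.seed(14)
  cr <- run_markov_chain(p, set = s, periods = 20000)
  expect_true(all(cr$shares > 0))
  adopted <- tapply(cr$trace$n, cr$trace$label, max)
  expect_true(all(adopted > 0))
})

test_that("cross-run summaries compute SE correctly and shares sum to one", {
  p <- baseline()
  s <- strategy_set("CE2")
  set.seed(1)
  rs <- run_invariant_estimate(p, s, periods = 2000, runs = 3, seeds = c(5, 5, 5))
  expect_equal(max(rs$summary$se), 0)  # identical seeds, identical runs
  expect_equal(rowSums(rs$run_shares), rep(1, 3))
  set.seed(2)
  rs2 <- run_invariant_estimate(p, s, periods = 2000, runs = 3, seeds = c(1, 2, 3))
  sd_hand <- apply(rs2$run_shares, 2, sd) / sqrt(3)
  expect_equal(rs2$summary$se, unname(sd_hand))
  expect_equal(rowSums(rs2$run_shares), rep(1, 3))
})

test_that("the exact best-reply process respects the absorbing sets", {
  p0 <- analytic_params()
  s <- strategy_set("CE2")
  # E_C state (alpha_C * 50 = 14.15, bracket {14}) is absorbing
  stC <- population_state(s, counts = c(CP = 36, CE = 14))
  expect_equal(absorbing_set_label(stC, p0), "E_C")
  set.seed(6)
  r <- run_exact_best_reply(stC, p0, max_cycles = 5)
  expect_equal(r$absorbed, "E_C")
  expect_equal(state_counts(r$state)$n, c(36, 0, 14, 0))
  # fewer than two enforcers: defection takes over
  st1 <- population_state(s, counts = c(CP = 30, DP = 19, CE = 1))
  set.seed(7)
  r1 <- run_exact_best_reply(st1, p0)
  expect_equal(r1$absorbed, "E_D")
})

test_that("the R reference and the compiled engine agree on expected payoffs", {
  set.seed(60)
  for (preset in c("CE2", "CEPE3", "CE16")) {
    s <- strategy_set(preset)
    systems <- attr(s, "systems")
    epar <- enforcegame:::engine_params(baseline())
    estrat <- enforcegame:::engine_strategies(s)
    esys <- enforcegame:::engine_systems(s)
    for (k in 1:30) {
      n <- stats::rpois(nrow(s), 3)
      if (sum(n) < 2) next
      for (i in which(n > 0)) {
        r_val <- enforcegame:::expected_payoff_counts(i, n, s, systems, baseline())
        c_val <- enforcegame:::eg_expected_payoff(epar, estrat, esys, n, i)
        expect_equal(r_val, c_val, tolerance = 1e-12,
                     info = paste(preset, "strategy", s$label[i]))
      }
    }
  }
})
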