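test_that("PD payoffs follow the b/c contract", {
  p <- baseline()
  expect_equal(pd_payoff("C", "C", p), 3)    # b - c
  expect_equal(pd_payoff("C", "D", p), -1)   # cost borne, no benefit
  expect_equal(pd_payoff("D", "C", p), 4)    # free-ride
  expect_equal(pd_payoff("D", "D", p), 0)
  expect_equal(pd_payoff(c("C", "D"), c("D", "D"), p), c(-1, 0))
})

test_that("action mistakes flip with probability mu", {
  expect_equal(realize_action(rep("C", 100), mu = 0), rep("C", 100))
  set.seed(7)
  n <- 1e6
  out <- realize_action(rep(TRUE, n), mu = 0.005)
  flips <- sum(!out)
  expect_lt(abs(flips - n * 0.005), 3 * sqrt(n * 0.005 * 0.995))
  out5 <- realize_action(rep("A", 20000), mu = 0.5)
  expect_lt(abs(mean(out5 == "B") - 0.5), 0.02)
})

test_that("the enforcement step taxes, punishes and charges costs as specified", {
  p <- baseline()
  s <- strategy_set("CE2")
  ce <- s[s$label == "CE", ]
  de <- s[s$label == "DE", ]
  # both clients cooperated: each keeps 0.7 * 5 = 3.5, R = 0.3 * 10, no cost
  out <- enforcement_outcome(c("C", "C"), c(3, 3), ce, p, mu = 0)
  expect_equal(out$client_net, c(3.5, 3.5))
  expect_equal(out$revenue, 3.0)
  expect_equal(out$punish_cost, 0)
  # defector against cooperator: defector taxed then punished
  out2 <- enforcement_outcome(c("D", "C"), c(4, -1), ce, p, mu = 0)
  expect_equal(out2$client_net, c(0.7 * 6 - 2, 0.7 * 1))
  expect_equal(out2$revenue, 0.3 * 7)
  expect_equal(out2$punish_cost, 0.1)
  # DE never punishes
  out3 <- enforcement_outcome(c("D", "D"), c(0, 0), de, p, mu = 0)
  expect_equal(out3$punished, c(FALSE, FALSE))
  expect_equal(out3$punish_cost, 0)
})

test_that("meta-enforcement payoffs reproduce all four cells against a brute-force oracle", {
  # oracle: evaluate the verbal contract directly for each action profile
  oracle <- function(ai, aj, Ri, Rj, psi, l) {
    if (ai == "B" && aj == "B") c(Ri, Rj)
    else if (ai == "A" && aj == "A") c(Ri - l, Rj - l)
    else if (ai == "A") c(Ri + psi * Rj, Rj - psi * Rj - l)
    else c(Ri - psi * Ri - l, Rj + psi * Ri)
  }
  p <- baseline()
  expect_equal(meta_payoffs("B", "B", 3, 2, p), c(3, 2))
  expect_equal(meta_payoffs("A", "B", 3, 2, p), c(4.4, -4.4))
  expect_equal(meta_payoffs("A", "A", 3, 2, p), c(-2, -3))
  set.seed(11)
  for (k in 1:25) {
    Ri <- runif(1, 0, 10); Rj <- runif(1, 0, 10)
    psi <- runif(1); l <- runif(1, 0, 8)
    pk <- game_params(psi = psi, l = l)
    for (ai in c("A", "B")) for (aj in c("A", "B")) {
      expect_equal(meta_payoffs(ai, aj, Ri, Rj, pk),
                   oracle(ai, aj, Ri, Rj, psi, l))
    }
  }
})

test_that("a unilateral attack transfers exactly psi * R_j and destroys exactly l", {
  set.seed(3)
  for (k in 1:10) {
    Ri <- runif(1, 0, 5); Rj <- runif(1, 0, 5)
    p <- game_params(psi = runif(1), l = runif(1, 0, 5))
    mp <- meta_payoffs("A", "B", Ri, Rj, p)
    expect_equal(mp[1] - Ri, p$psi * Rj)             # attacker's gain
    expect_equal(Ri + Rj - sum(mp), p$l)             # only l is destroyed
  }
})

test_that("a played round matches the worked example and conserves revenue", {
  p <- baseline(mu = 0)
  st <- ce2_state(CP = 2, CE = 1)
  led <- standing_ledger(which(st$set$role[st$assign] == "enforcer"),
                         "CE", p$kappa)
  set.seed(5)
  out <- play_round(st, led, p)
  ag <- out$record$agents
  expect_equal(ag$payoff[ag$role == "producer"], c(3.5, 3.5))
  expect_equal(ag$payoff[ag$role == "enforcer"], 3.0 - 0.3)  # R - f, no coplayer
  expect_true(all(out$ledger$scores == 0L))
})

test_that("tax revenue is conserved in every simulated round", {
  p <- baseline()  # action mistakes on
  s <- strategy_set("CE2")
  set.seed(17)
  for (k in 1:10) {
    st <- random_state(s, 20)
    enf <- which(s$role[st$assign] == "enforcer")
    led <- standing_ledger(enf, "CE", p$kappa)
    for (r in 1:5) {
      out <- play_round(st, led, p)
      led <- out$ledger
      pr <- out$record$producers
      if (nrow(pr) == 0 || length(enf) == 0) next
      taxed <- pr[!is.na(pr$enforcer), ]
      expect_equal(sum(out$record$enforcers$revenue),
                   p$tau * sum(taxed$pretax))
    }
  }
})

test_that("an all-cooperative population stays peaceful and in good standing", {
  p <- baseline(mu = 0)
  st <- ce2_state(CP = 10, CE = 4)
  enf <- which(st$set$role[st$assign] == "enforcer")
  led <- standing_ledger(enf, "CE", p$kappa)
  set.seed(1)
  for (r in 1:20) {
    out <- play_round(st, led, p)
    led <- out$ledger
    expect_equal(sum(out$record$enforcers$n_punished), 0L)
    expect_false(any(out$record$enforcers$attacked, na.rm = TRUE))
    expect_true(all(led$scores == 0L))
  }
})

test_that("degenerate rounds (no enforcers, lone producer) never crash", {
  p <- baseline()
  s <- strategy_set("CE2")
  # no enforcers: producers keep untaxed resources
  st <- population_state(s, counts = c(CP = 4))
  out <- play_round(st, standing_ledger(integer(), "CE", p$kappa), p)
  expect_true(all(is.finite(out$record$agents$payoff)))
  # one producer, enforcers only otherwise: producer earns autarky w
  st2 <- population_state(s, counts = c(CP = 1, CE = 3))
  set.seed(2)
  out2 <- play_round(st2, standing_ledger(2:4, "CE", p$kappa), p)
  expect_equal(out2$record$agents$payoff[1], p$w)
})
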