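test_that("parameter validation accepts the published values and rejects domain violations", {
  p <- baseline()
  expect_s3_class(p, "game_params")
  expect_gt(p$tau * p$w, p$v)  # positive tax revenue at baseline
  expect_true(attr(p, "gamma_ordered"))

  bad_cases <- list(
    list(c = 4, b = 4),                 # PD not a dilemma
    list(c = 5, b = 4),
    list(tau = 0),                      # tau outside (0, 1)
    list(tau = 1),
    list(v = 0.7),                      # tau * w = 0.6 <= v
    list(delta = 1),
    list(mu = 0.5),
    list(kappa = 0),
    list(N = 3),
    list(gamma = c(0.5, 0.5, 0.5)),     # not a probability vector
    list(gamma = c(-0.1, 0.5, 0.6))
  )
  for (over in bad_cases) {
    expect_error(do.call(game_params, over), "invalid parameters",
                 info = paste(names(over), unlist(over), collapse = "="))
  }
})

test_that("gamma ordering is a warning flag, not an error", {
  expect_warning(p <- game_params(gamma = c(1 / 3, 1 / 3, 1 / 3)),
                 "gamma_P > gamma_E > gamma_PE")
  expect_false(attr(p, "gamma_ordered"))
  # maximally permissive revisions: still a valid dynamic
  expect_warning(p2 <- game_params(gamma = c(1, 0, 0)))
  expect_false(attr(p2, "gamma_ordered"))
  expect_equal(unname(p2$gamma), c(1, 0, 0))
})

test_that("the two named parameterizations carry the published values", {
  b <- baseline()
  expect_equal(c(b$b, b$c, b$v, b$f, b$l), c(4, 1, 0.1, 0.3, 5))
  a <- alternative()
  expect_equal(c(a$b, a$c, a$v, a$f, a$l), c(3, 2, 0.3, 0.4, 4))
  for (p in list(b, a)) {  # common values
    expect_equal(c(p$delta, p$kappa, p$w, p$tau, p$p, p$psi),
                 c(0.9, 8, 2, 0.3, 2, 0.7))
    expect_equal(c(p$mu, p$eta, p$epsilon), c(0.005, 0.01, 0.05))
    expect_equal(unname(p$gamma), c(0.1, 0.3, 0.6))
    expect_equal(p$N, 50L)
  }
})

test_that("strategy-set presets have the right cardinalities and members", {
  sizes <- c(CE16 = 16L, PE16 = 16L, CE2 = 2L, PE2 = 2L, CEPE3 = 3L)
  for (preset in names(sizes)) {
    s <- strategy_set(preset)
    expect_equal(sum(s$role == "enforcer"), sizes[[preset]], info = preset)
    expect_equal(s$label[s$role == "producer"], c("CP", "DP"), info = preset)
  }
  ce16 <- strategy_set("CE16")
  expect_true("CE:1010" %in% ce16$label)       # antisocial punisher
  expect_setequal(strategy_set("CE2")$label[3:4], c("CE", "DE"))
  expect_setequal(strategy_set("PE2")$label[3:4], c("PE", "DE"))
  expect_setequal(strategy_set("CEPE3")$label[3:5], c("CE", "PE", "DE"))
})

test_that("informed() is false exactly for the four constant-action codes", {
  s <- strategy_set("CE16")
  enf <- s[s$role == "enforcer", ]
  uninformed <- enf$bits[!enf$informed]
  expect_setequal(uninformed, c("0000", "0011", "1100", "1111"))
  expect_equal(sum(enf$informed), 12L)
  # uninformed codes are system-free, so DE is one strategy in every preset
  expect_true(all(is.na(enf$system[!enf$informed])))
})

test_that("strategy literals round-trip through parse_strategy", {
  expect_equal(parse_strategy("CE:0101")$label, "CE")
  expect_equal(parse_strategy("CE")$bits, "0101")
  expect_equal(parse_strategy("PE:0001")$label, "PE")
  expect_equal(parse_strategy("0011")$label, "DE")
  expect_equal(parse_strategy("PE:0011")$label, "DE")  # merged across systems
  expect_equal(parse_strategy("E:1111")$label, "E:1111")
  expect_equal(parse_strategy("CP")$producer_action, "C")
  expect_error(parse_strategy("0101"), "tag it with a system")
  expect_error(parse_strategy("XX:0101"), "cannot parse")
})

test_that("population states keep n_P + n_E = N and counts consistent", {
  s <- strategy_set("CE2")
  st <- population_state(s, counts = c(CP = 30, DP = 6, CE = 10, DE = 4))
  cc <- state_counts(st)
  expect_equal(sum(cc$n), 50)
  expect_equal(sum(cc$n[cc$role == "producer"]) + sum(cc$n[cc$role == "enforcer"]),
               length(st$assign))
  expect_equal(cc$n[cc$label == "CE"], 10)
  expect_error(population_state(s, counts = c(XX = 5)), "unknown strategy")
  set.seed(1)
  for (k in 1:5) {
    r <- random_state(s, 20)
    cr <- state_counts(r)
    expect_equal(sum(cr$n), 20)
  }
})
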