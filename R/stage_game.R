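#' Production-step payoff of the prisoner's dilemma
#'
#' Cooperation bestows `b` on the partner at cost `c`; defection does
#' nothing. The value returned excludes the autarky payoff `w`: a matched
#' producer's pre-tax resources are `w + pd_payoff(...)`.
#'
#' @param own,other Own and partner's realized action, `"C"` or `"D"`
#'   (vectorized).
#' @param params A [game_params()].
#' @return Numeric vector of PD payoffs: `(C,C) -> b - c`, `(C,D) -> -c`,
#'   `(D,C) -> b`, `(D,D) -> 0`.
#' @examples
#' pd_payoff("C", "C", game_params())  # 3 at baseline
#' @export
pd_payoff <- function(own, other, params) {
  params <- as_game_params(params)
  stopifnot(all(own %in% c("C", "D")), all(other %in% c("C", "D")))
  params$b * (other == "C") - params$c * (own == "C")
}

#' Realize an action subject to action mistakes
#'
#' Every binary choice in the stage game goes through the same mistake
#' channel: with probability `1 - mu` the prescribed action is taken, with
#' probability `mu` the other one.
#'
#' @param prescribed Prescribed action(s): a logical vector, or a character
#'   vector over a binary action pair (`"C"`/`"D"` or `"A"`/`"B"`).
#' @param mu Action-mistake probability.
#' @return The realized action(s), same type as `prescribed`.
#' @export
realize_action <- function(prescribed, mu) {
  stopifnot(mu >= 0, mu < 0.5 || mu == 0.5)
  flip <- stats::runif(length(prescribed)) < mu
  if (is.logical(prescribed)) return(xor(prescribed, flip))
  if (is.character(prescribed)) {
    pairs <- list(c("C", "D"), c("A", "B"))
    for (pr in pairs) {
      if (all(prescribed %in% pr)) {
        other <- stats::setNames(rev(pr), pr)
        out <- prescribed
        out[flip] <- other[prescribed[flip]]
        return(out)
      }
    }
  }
  stop("prescribed must be logical, C/D or A/B", call. = FALSE)
}

#' Enforcement-step outcome for one producer pair
#'
#' The enforcer taxes each client a fraction `tau` of the client's pre-tax
#' resources `w + pd` and decides, client by client, whether to punish,
#' applying her `(a_coop, a_def)` bits to each client's realized PD action
#' (each punish decision passes through the mistake channel). Punishment
#' subtracts `p` from the client after taxation and costs the enforcer `v`.
#'
#' @param client_actions Realized PD actions of the two clients
#'   (`"C"`/`"D"`).
#' @param client_pd PD payoffs of the two clients (from [pd_payoff()]).
#' @param enforcer One-row strategy tibble (an enforcer).
#' @param params A [game_params()].
#' @param mu Action-mistake probability (defaults to `params$mu`).
#' @return List: `client_net` (payoff of each client this round),
#'   `punished` (logical), `revenue` (the enforcer's `R` from this pair),
#'   `punish_cost` (`v` times number punished).
#' @examples
#' s <- strategy_set("CE2")
#' ce <- s[s$label == "CE", ]
#' enforcement_outcome(c("C", "C"), c(3, 3), ce, game_params(), mu = 0)
#' @export
enforcement_outcome <- function(client_actions, client_pd, enforcer, params,
                                mu = params$mu) {
  params <- as_game_params(params)
  stopifnot(nrow(enforcer) == 1L, enforcer$role == "enforcer",
            length(client_actions) == length(client_pd))
  pretax <- params$w + client_pd
  prescribed <- ifelse(client_actions == "C",
                       enforcer$a_coop == 1L, enforcer$a_def == 1L)
  punished <- realize_action(prescribed, mu)
  list(
    client_net = (1 - params$tau) * pretax - params$p * punished,
    punished = punished,
    revenue = params$tau * sum(pretax),
    punish_cost = params$v * sum(punished)
  )
}

#' Meta-enforcement-step payoffs
#'
#' Two matched enforcers holding revenues `R_i`, `R_j` each choose attack
#' (`"A"`) or peace (`"B"`). If neither attacks both keep their revenue. A
#' unilateral attacker grabs a fraction `psi` of the victim's revenue and
#' the victim additionally loses `l`. If both attack, each loses `l` and no
#' revenue changes hands.
#'
#' @param action_i,action_j `"A"` or `"B"`.
#' @param R_i,R_j Non-negative revenues.
#' @param params A [game_params()].
#' @return Numeric vector `c(pi_i, pi_j)` of meta-step payoffs.
#' @examples
#' meta_payoffs("A", "B", 3, 2, game_params())  # c(4.4, -4.4) at baseline
#' @export
meta_payoffs <- function(action_i, action_j, R_i, R_j, params) {
  params <- as_game_params(params)
  stopifnot(action_i %in% c("A", "B"), action_j %in% c("A", "B"),
            R_i >= 0, R_j >= 0)
  psi <- params$psi; l <- params$l
  if (action_i == "B" && action_j == "B") return(c(R_i, R_j))
  if (action_i == "A" && action_j == "B")
    return(c(R_i + psi * R_j, (1 - psi) * R_j - l))
  if (action_i == "B" && action_j == "A")
    return(c((1 - psi) * R_i - l, R_j + psi * R_i))
  c(R_i - l, R_j - l)
}

#' Play one round of the stage game
#'
#' Executes the three steps for the whole population: producers are
#' uniformly randomly paired and play the PD (with action mistakes); each
#' producer pair is independently assigned to a uniformly random enforcer,
#' who taxes and possibly punishes; enforcers are uniformly randomly paired
#' for the meta-enforcement step, attacking according to their strategy and
#' the coplayer's standing at round entry (under the attacker's own
#' system). Scores under every active system are then updated from realized
#' conduct. Odd counts: an unmatched producer earns untaxed `w`; an
#' unmatched enforcer skips the meta step and keeps her revenue. Degenerate
#' role classes (no enforcers, fewer than two producers) are handled, never
#' an error.
#'
#' @param state A [population_state()].
#' @param ledger A [standing_ledger()] for the current enforcers (scores at
#'   round entry).
#' @param params A [game_params()].
#' @return List with elements `record` (a `round_record`: per-agent payoffs
#'   and all intermediate quantities, see Details) and `ledger` (scores
#'   after the round).
#'
#' @details The `record` is a list with tibbles `agents` (id, role, label,
#' payoff), `producers` (matching, realized actions, taxation, punishment),
#' `enforcers` (revenue, punish costs, meta matching and payoffs),
#' `compliance` (per enforcer and system: complied, score before/after) and
#' the list `conduct` of [round_conduct()] objects keyed by enforcer id.
#' @export
play_round <- function(state, ledger, params) {
  params <- as_game_params(params)
  set <- state$set
  N <- length(state$assign)
  role <- set$role[state$assign]
  label <- set$label[state$assign]
  prod_ids <- which(role == "producer")
  enf_ids <- which(role == "enforcer")
  nP <- length(prod_ids); nE <- length(enf_ids)
  systems <- colnames(ledger$scores)
  payoff <- numeric(N)

  ## --- step 1: production ---------------------------------------------
  ord <- prod_ids[sample.int(nP)]
  npair <- nP %/% 2L
  p1 <- ord[seq_len(npair) * 2L - 1L]
  p2 <- ord[seq_len(npair) * 2L]
  unmatched_prod <- if (nP %% 2L == 1L) ord[nP] else integer()

  prescribed <- ifelse(set$producer_action[state$assign[c(p1, p2)]] == "C", "C", "D")
  act <- if (npair > 0L) realize_action(prescribed, params$mu) else character()
  a1 <- act[seq_len(npair)]; a2 <- act[npair + seq_len(npair)]
  pd1 <- pd_payoff(a1, a2, params); pd2 <- pd_payoff(a2, a1, params)

  ## --- step 2: enforcement --------------------------------------------
  revenue <- stats::setNames(numeric(nE), as.character(enf_ids))
  punish_cost <- stats::setNames(numeric(nE), as.character(enf_ids))
  n_punished <- stats::setNames(integer(nE), as.character(enf_ids))
  conduct_actions <- stats::setNames(vector("list", nE), as.character(enf_ids))
  conduct_punished <- conduct_actions
  pair_enforcer <- rep(NA_integer_, npair)
  punished1 <- logical(npair); punished2 <- logical(npair)
  net1 <- numeric(npair); net2 <- numeric(npair)

  for (k in seq_len(npair)) {
    if (nE == 0L) {
      # degenerate: no enforcers, producers keep their untaxed resources
      net1[k] <- params$w + pd1[k]; net2[k] <- params$w + pd2[k]
      next
    }
    e <- enf_ids[sample.int(nE, 1L)]
    pair_enforcer[k] <- e
    out <- enforcement_outcome(c(a1[k], a2[k]), c(pd1[k], pd2[k]),
                               set[state$assign[e], ], params)
    key <- as.character(e)
    revenue[key] <- revenue[key] + out$revenue
    punish_cost[key] <- punish_cost[key] + out$punish_cost
    n_punished[key] <- n_punished[key] + sum(out$punished)
    conduct_actions[[key]] <- c(conduct_actions[[key]], c(a1[k], a2[k]))
    conduct_punished[[key]] <- c(conduct_punished[[key]], out$punished)
    net1[k] <- out$client_net[1]; net2[k] <- out$client_net[2]
    punished1[k] <- out$punished[1]; punished2[k] <- out$punished[2]
  }
  payoff[c(p1, p2)] <- c(net1, net2)
  payoff[unmatched_prod] <- params$w  # unmatched producers: untaxed autarky

  ## --- step 3: meta-enforcement ---------------------------------------
  eord <- enf_ids[sample.int(nE)]
  nepair <- nE %/% 2L
  e1 <- eord[seq_len(nepair) * 2L - 1L]
  e2 <- eord[seq_len(nepair) * 2L]
  unmatched_enf <- if (nE %% 2L == 1L) eord[nE] else integer()

  attack <- stats::setNames(rep(NA, nE), as.character(enf_ids))
  meta_pay <- revenue  # unmatched keep their revenue
  coplayer <- stats::setNames(rep(NA_integer_, nE), as.character(enf_ids))
  entry_scores <- ledger$scores  # standings at round ENTRY drive decisions

  prescribe_attack <- function(attacker, victim) {
    srow <- set[state$assign[attacker], ]
    sys <- srow$system
    if (is.na(sys)) sys <- systems[1]  # uninformed: bits equal, any system
    good <- entry_scores[as.character(victim), sys] == 0L
    if (good) srow$a_good == 1L else srow$a_bad == 1L
  }

  for (k in seq_len(nepair)) {
    i <- e1[k]; j <- e2[k]
    ai <- realize_action(prescribe_attack(i, j), params$mu)
    aj <- realize_action(prescribe_attack(j, i), params$mu)
    mp <- meta_payoffs(if (ai) "A" else "B", if (aj) "A" else "B",
                       revenue[[as.character(i)]], revenue[[as.character(j)]],
                       params)
    meta_pay[as.character(i)] <- mp[1]; meta_pay[as.character(j)] <- mp[2]
    attack[as.character(i)] <- ai; attack[as.character(j)] <- aj
    coplayer[as.character(i)] <- j; coplayer[as.character(j)] <- i
  }

  informed <- set$informed[state$assign[enf_ids]]
  payoff[enf_ids] <- meta_pay - punish_cost - params$f * informed

  ## --- scoring ----------------------------------------------------------
  conduct <- stats::setNames(vector("list", nE), as.character(enf_ids))
  comp_rows <- vector("list", 0L)
  new_scores <- entry_scores
  for (e in enf_ids) {
    key <- as.character(e)
    cd <- round_conduct(
      client_actions = if (is.null(conduct_actions[[key]])) character() else conduct_actions[[key]],
      client_punished = if (is.null(conduct_punished[[key]])) logical() else as.logical(conduct_punished[[key]]),
      matched = !is.na(coplayer[[key]]),
      attacked = if (is.na(coplayer[[key]])) NA else as.logical(attack[[key]])
    )
    conduct[[key]] <- cd
    for (sys in systems) {
      cop_standing <- if (is.na(coplayer[[key]])) "good" else {
        if (entry_scores[as.character(coplayer[[key]]), sys] == 0L) "good" else "bad"
      }
      ok <- if (sys == "CE") ce_compliant(cd, cop_standing) else pe_compliant(cd, cop_standing)
      z0 <- entry_scores[key, sys]
      z1 <- update_score(z0, ok, ledger$kappa)
      new_scores[key, sys] <- z1
      comp_rows[[length(comp_rows) + 1L]] <-
        tibble::tibble(enforcer = e, system = sys, complied = ok,
                       z_before = z0, z_after = z1)
    }
  }
  ledger$scores <- new_scores

  record <- structure(list(
    agents = tibble::tibble(id = seq_len(N), role = role, label = label,
                            payoff = payoff),
    producers = tibble::tibble(
      id = c(p1, p2), partner = c(p2, p1),
      action = c(a1, a2), pd = c(pd1, pd2),
      pretax = params$w + c(pd1, pd2),
      enforcer = c(pair_enforcer, pair_enforcer),
      punished = c(punished1, punished2),
      net = c(net1, net2)
    ),
    unmatched_producers = unmatched_prod,
    enforcers = tibble::tibble(
      id = enf_ids, label = label[enf_ids],
      revenue = as.numeric(revenue), punish_cost = as.numeric(punish_cost),
      n_punished = as.integer(n_punished),
      meta_matched = !is.na(coplayer),
      coplayer = as.integer(coplayer), attacked = as.logical(attack),
      meta_payoff = as.numeric(meta_pay),
      payoff = payoff[enf_ids]
    ),
    compliance = if (length(comp_rows)) dplyr::bind_rows(comp_rows) else
      tibble::tibble(enforcer = integer(), system = character(),
                     complied = logical(), z_before = integer(),
                     z_after = integer()),
    conduct = conduct
  ), class = "round_record")

  list(record = record, ledger = ledger)
}
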