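#' Long-run standings under the analytic regime
#'
#' In the regime used for closed-form payoffs (no action mistakes,
#' continuation probability near one, unbounded punishment phase), an
#' enforcer strategy ends the period in bad standing under a system exactly
#' if, starting from the all-good state, it ever violates that system's
#' standard given the population composition — and once bad it stays bad,
#' because the punishment phase never ends. Violations are found by a
#' grow-only iteration over rounds: a strategy violates the CE standard if
#' it would punish a cooperating client / spare a defecting client that the
#' population supplies, or if its (own-system-driven) attack decision
#' against some reachable coplayer disagrees with that coplayer's current
#' standing under the judging system; the PE standard keeps only the attack
#' clause. This reproduces the boundary cases: a lone enforcer, or a
#' never-punishing enforcer with only cooperating clients, stays in good
#' standing.
#'
#' @param enf Tibble of enforcer strategies (rows of a [strategy_set()])
#'   with a column `n` of counts (candidate included).
#' @param n_coop,n_def Numbers of cooperating / defecting producers (0 if
#'   there are no producer pairs).
#' @param systems Active reputation systems.
#' @return Logical matrix `bad` with `nrow(enf)` rows and one column per
#'   system.
#' @keywords internal
long_run_standing <- function(enf, n_coop, n_def, systems) {
  S <- nrow(enf)
  nE <- sum(enf$n)
  bad <- matrix(FALSE, nrow = S, ncol = length(systems),
                dimnames = list(NULL, systems))
  if (S == 0L || nE == 0L) return(bad)
  sys_idx <- match(enf$system, systems)  # NA for uninformed

  attacks <- function(x, y_bad_under_own_sys) {
    # does strategy row x attack a coplayer with the given standing under
    # x's own system? (uninformed: bits equal, standing irrelevant)
    if (y_bad_under_own_sys) enf$a_bad[x] == 1L else enf$a_good[x] == 1L
  }

  repeat {
    changed <- FALSE
    for (si in seq_along(systems)) {
      sys <- systems[si]
      for (x in seq_len(S)) {
        if (bad[x, si] || enf$n[x] == 0L) next
        viol <- FALSE
        if (sys == "CE") {
          if (n_coop > 0 && enf$a_coop[x] == 1L) viol <- TRUE
          if (n_def > 0 && enf$a_def[x] == 0L) viol <- TRUE
        }
        if (!viol && nE >= 2L) {
          own <- sys_idx[x]
          for (y in seq_len(S)) {
            m <- enf$n[y] - (y == x)
            if (m <= 0L) next
            y_bad_judge <- bad[y, si]
            y_bad_own <- if (is.na(own)) FALSE else bad[y, own]
            if (attacks(x, y_bad_own) != y_bad_judge) { viol <- TRUE; break }
          }
        }
        if (viol) { bad[x, si] <- TRUE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  bad
}

#' Expected per-round payoff of a candidate strategy
#'
#' The payoff a revising agent attributes to a strategy that has no current
#' users: the analytic expectation of its per-round payoff against the
#' current population, computed in the regime of the closed-form results
#' (no action mistakes, long periods, unbounded punishment phase).
#' Producers earn `(1 - tau) * (w + E[PD payoff])` minus the expected
#' punishment given the enforcers' punish bits; enforcers earn expected
#' revenue `tau * (w + mean PD payoff) * n_P / n_E` minus variable and
#' information costs plus the expected meta-enforcement payoff under the
#' long-run standing configuration (e.g. all CE good and all DE bad
#' whenever a defecting producer or a CE is present).
#'
#' @param strategy A strategy label (see [parse_strategy()]) or one-row
#'   strategy tibble. Must be present in `state` (the candidate's slot is
#'   already filled with it).
#' @param state A [population_state()] describing the rest of the
#'   population with the revising agent's slot holding `strategy`.
#' @param params A [game_params()].
#' @return Expected per-round payoff (a number).
#' @examples
#' s <- strategy_set("CE2")
#' st <- population_state(s, counts = c(CP = 36, CE = 14))
#' hypothetical_payoff("CP", st, preset_params("baseline"))  # 3.5
#' @export
hypothetical_payoff <- function(strategy, state, params) {
  params <- as_game_params(params)
  set <- state$set
  if (is.character(strategy)) {
    idx <- match(strategy, set$label)
    if (is.na(idx)) stop("strategy ", strategy, " not in the active set", call. = FALSE)
  } else {
    idx <- match(strategy$label, set$label)
    if (is.na(idx)) stop("strategy not in the active set", call. = FALSE)
  }
  counts <- tabulate(state$assign, nbins = nrow(set))
  if (counts[idx] < 1L)
    stop("state must contain the candidate (slot filled by the candidate strategy)",
         call. = FALSE)
  expected_payoff_counts(idx, counts, set, attr(set, "systems"), params)
}

# core arithmetic, shared by hypothetical_payoff and the exact best-reply
# dynamic; counts include the candidate
expected_payoff_counts <- function(idx, counts, set, systems, params) {
  is_prod <- set$role == "producer"
  n_P <- sum(counts[is_prod])
  n_E <- sum(counts[!is_prod])
  n_CP <- sum(counts[is_prod & set$producer_action == "C"], na.rm = TRUE)

  if (is_prod[idx]) {
    if (n_P == 1L) return(params$w)                      # always unmatched
    others_cp <- n_CP - (set$producer_action[idx] == "C")
    pC <- others_cp / (n_P - 1)
    own_C <- set$producer_action[idx] == "C"
    Epd <- pC * params$b - if (own_C) params$c else 0
    if (n_E == 0L) return(params$w + Epd)                # nobody to tax
    bit <- if (own_C) set$a_coop else set$a_def
    p_pun <- sum(counts[!is_prod] * bit[!is_prod]) / n_E
    return((1 - params$tau) * (params$w + Epd) - params$p * p_pun)
  }

  ## enforcer candidate
  enf <- set[!is_prod, c("label", "system", "a_coop", "a_def", "a_good", "a_bad",
                         "informed")]
  enf$n <- counts[!is_prod]
  x <- match(set$label[idx], enf$label)

  have_pairs <- n_P >= 2L
  n_coop <- if (have_pairs) n_CP else 0L
  n_def <- if (have_pairs) n_P - n_CP else 0L

  if (have_pairs) {
    # mean PD payoff of a random producer, exact under uniform pairing
    pd_CP <- if (n_CP > 0) ((n_CP - 1) / (n_P - 1)) * params$b - params$c else 0
    pd_DP <- (n_CP / (n_P - 1)) * params$b
    mean_pd <- (n_CP * pd_CP + (n_P - n_CP) * pd_DP) / n_P
    R <- params$tau * (params$w + mean_pd) * n_P / n_E
    share_C <- n_CP / n_P
    cost_v <- params$v * (n_P / n_E) *
      (enf$a_coop[x] * share_C + enf$a_def[x] * (1 - share_C))
  } else {
    R <- 0; cost_v <- 0
  }

  bad <- long_run_standing(enf, n_coop, n_def, systems)
  own_sys <- match(enf$system[x], systems)  # NA for uninformed

  meta <- R  # unmatched keeps revenue
  if (n_E >= 2L) {
    meta <- 0
    for (y in seq_len(nrow(enf))) {
      m <- enf$n[y] - (y == x)
      if (m <= 0L) next
      y_bad_own <- if (is.na(own_sys)) FALSE else bad[y, own_sys]
      i_att <- if (y_bad_own) enf$a_bad[x] == 1L else enf$a_good[x] == 1L
      y_sys <- match(enf$system[y], systems)
      x_bad_for_y <- if (is.na(y_sys)) FALSE else bad[x, y_sys]
      j_att <- if (x_bad_for_y) enf$a_bad[y] == 1L else enf$a_good[y] == 1L
      cell <- if (!i_att && !j_att) R
      else if (i_att && !j_att) R + params$psi * R
      else if (!i_att && j_att) (1 - params$psi) * R - params$l
      else R - params$l
      meta <- meta + (m / (n_E - 1)) * cell
    }
  }
  meta - cost_v - params$f * enf$informed[x]
}
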