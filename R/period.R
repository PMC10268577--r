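#' Expected number of rounds per period
#'
#' After each round a new round begins with probability `delta`, so the
#' realized round count is geometric with mean `1 / (1 - delta)`. At the
#' baseline `delta = 0.9` the expected length of the repeated game is 10
#' rounds.
#'
#' @param delta Continuation probability, in `[0, 1)`.
#' @return `1 / (1 - delta)`.
#' @examples
#' expected_period_length(0.9)  # 10
#' @export
expected_period_length <- function(delta) {
  if (!is.numeric(delta) || any(delta < 0) || any(delta >= 1))
    stop("delta must lie in [0, 1)", call. = FALSE)
  1 / (1 - delta)
}

#' Play one period (one full repeated game)
#'
#' Starts every enforcer in good standing under every active system, plays
#' a geometric number of rounds (a new round with probability `delta`, no
#' cap by default) and evaluates each agent by her per-round average
#' payoff.
#'
#' @param state A [population_state()].
#' @param params A [game_params()].
#' @param max_rounds Optional safety cap on the number of rounds (testing
#'   aid; `Inf` by default so the geometric stop is untruncated).
#' @return An object of class `"period_result"`: list with `T` (realized
#'   rounds), `agents` (tibble id, role, label, avg_payoff), `strategies`
#'   (the per-strategy table from [strategy_average_payoffs()]) and
#'   `state` (the state that played).
#' @examples
#' s <- strategy_set("CE2")
#' st <- population_state(s, counts = c(CP = 4, CE = 2))
#' pr <- play_period(st, game_params(delta = 0, mu = 0))
#' pr$T  # 1
#' @export
play_period <- function(state, params, max_rounds = Inf) {
  params <- as_game_params(params)
  role <- state$set$role[state$assign]
  enf_ids <- which(role == "enforcer")
  systems <- attr(state$set, "systems")
  ledger <- standing_ledger(enf_ids, systems, params$kappa)

  total <- numeric(length(state$assign))
  t <- 0L
  repeat {
    t <- t + 1L
    out <- play_round(state, ledger, params)
    ledger <- out$ledger
    total <- total + out$record$agents$payoff
    if (t >= max_rounds) break
    if (stats::runif(1) >= params$delta) break
  }

  agents <- tibble::tibble(
    id = seq_along(total), role = role,
    label = state$set$label[state$assign],
    avg_payoff = total / t
  )
  res <- structure(list(T = t, agents = agents, state = state), class = "period_result")
  res$strategies <- strategy_average_payoffs(res)
  res
}

#' Per-strategy realized average payoffs
#'
#' Arithmetic mean of period-average payoffs over the current users of each
#' strategy. A strategy with no users has no observation: its `avg_payoff`
#' is `NA` (never zero) and `n_users` is 0.
#'
#' @param period A `period_result` from [play_period()].
#' @return Tibble with one row per strategy in the active set: `label`,
#'   `role`, `n_users`, `avg_payoff`.
#' @export
strategy_average_payoffs <- function(period) {
  stopifnot(inherits(period, "period_result"))
  set <- period$state$set
  agents <- period$agents
  dplyr::left_join(
    tibble::tibble(label = set$label, role = set$role),
    dplyr::summarise(dplyr::group_by(agents, .data$label),
                     n_users = dplyr::n(),
                     avg_payoff = mean(.data$avg_payoff), .groups = "drop"),
    by = "label"
  ) |>
    dplyr::mutate(n_users = dplyr::coalesce(.data$n_users, 0L))
}

#' @export
print.period_result <- function(x, ...) {
  cat("<period_result> T =", x$T, "rounds\n")
  print(x$strategies)
  invisible(x)
}
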