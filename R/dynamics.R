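#' Logit choice probabilities and sampling
#'
#' A revising agent picks strategy `X` from a menu with probability
#' `exp(pi_X / eta) / sum_Y exp(pi_Y / eta)`. `eta = 0` is the exact best
#' response (argmax, uniform tie-breaking); large `eta` approaches the
#' uniform choice. Probabilities are computed with max-subtraction so large
#' payoffs cannot overflow.
#'
#' @param payoffs Named numeric vector: payoff attributed to each strategy
#'   in the menu.
#' @param eta Logit imprecision (>= 0).
#' @return `logit_probs()`: named probability vector summing to 1.
#'   `logit_choice()`: one sampled strategy name.
#' @examples
#' logit_probs(c(X = 1, Y = 0), eta = 1)  # c(e, 1)/(1 + e)
#' @export
logit_probs <- function(payoffs, eta) {
  if (length(payoffs) == 0L) stop("empty menu", call. = FALSE)
  stopifnot(is.numeric(payoffs), eta >= 0)
  if (eta == 0) {
    best <- payoffs >= max(payoffs) - 0
    pr <- as.numeric(best) / sum(best)
  } else {
    z <- payoffs / eta
    z <- z - max(z)
    pr <- exp(z) / sum(exp(z))
  }
  stats::setNames(pr, names(payoffs))
}

#' @rdname logit_probs
#' @export
logit_choice <- function(payoffs, eta) {
  pr <- logit_probs(payoffs, eta)
  names(pr)[sample.int(length(pr), 1L, prob = pr)]
}

#' Draw a revision class and a revising agent
#'
#' With probability `gamma_P` a producer is drawn (uniformly among current
#' producers) and may choose among producer strategies only; with
#' `gamma_E`, an enforcer choosing among enforcer strategies; with
#' `gamma_PE` an agent from the whole population choosing from the full
#' set. If the drawn class is empty (e.g. no enforcers exist), the draw
#' falls back to the whole-population class so the chain stays ergodic.
#'
#' @param state A [population_state()].
#' @param gamma Numeric triple `(gamma_PE, gamma_E, gamma_P)`.
#' @return List: `class` (`"PE"`, `"E"` or `"P"`, after any fallback),
#'   `agent` (id), `menu` (character vector of strategy labels).
#' @export
draw_revision_class <- function(state, gamma) {
  stopifnot(length(gamma) == 3L, all(gamma >= 0), abs(sum(gamma) - 1) < 1e-8)
  set <- state$set
  role <- set$role[state$assign]
  cls <- c("PE", "E", "P")[sample.int(3L, 1L, prob = gamma)]
  pool <- switch(cls,
    P = which(role == "producer"),
    E = which(role == "enforcer"),
    PE = seq_along(state$assign)
  )
  if (length(pool) == 0L) {           # empty class: whole-population fallback
    cls <- "PE"
    pool <- seq_along(state$assign)
  }
  menu <- switch(cls,
    P = set$label[set$role == "producer"],
    E = set$label[set$role == "enforcer"],
    PE = set$label
  )
  list(class = cls,
       agent = pool[sample.int(length(pool), 1L)],
       menu = menu)
}

#' Revise one agent's strategy
#'
#' With probability `epsilon` the agent adopts a uniformly random strategy
#' from the menu (a revision mistake); otherwise she plays a logit best
#' response to the realized per-strategy average payoffs of the last
#' period. Menu strategies with no users in that period are scored by
#' [hypothetical_payoff()] (their analytic expectation with the agent's
#' slot filled by the candidate).
#'
#' @param state A [population_state()].
#' @param period The last `period_result` (from [play_period()]).
#' @param params A [game_params()].
#' @param agent Id of the revising agent.
#' @param menu Character vector of strategy labels she may choose from.
#' @return The new [population_state()].
#' @export
revise_agent <- function(state, period, params, agent, menu) {
  params <- as_game_params(params)
  set <- state$set
  midx <- match(menu, set$label)
  if (anyNA(midx)) stop("menu contains unknown strategies", call. = FALSE)

  if (stats::runif(1) < params$epsilon) {
    pick <- midx[sample.int(length(midx), 1L)]
  } else {
    realized <- period$strategies
    pay <- vapply(midx, function(i) {
      r <- realized[realized$label == set$label[i], ]
      if (r$n_users > 0L) r$avg_payoff
      else {
        cand <- state
        cand$assign[agent] <- i
        hypothetical_payoff(set$label[i], cand, params)
      }
    }, numeric(1))
    pick <- midx[match(logit_choice(stats::setNames(pay, set$label[midx]),
                                    params$eta), set$label[midx])]
  }
  state$assign[agent] <- pick
  state
}

#' Run the learning Markov chain
#'
#' Alternates one full repeated game ([play_period()]) and one strategy
#' revision per period, recording strategy counts every period; time
#' averages are taken over all periods (no burn-in). The loop runs in
#' compiled code and draws from R's RNG stream, so results are reproducible
#' with `set.seed()`.
#'
#' @param params A [game_params()].
#' @param set A [strategy_set()] (defaults to the set of `init`).
#' @param init Initial [population_state()]; defaults to a [random_state()]
#'   of size `params$N`.
#' @param periods Number of periods (= number of revisions).
#' @param thin Record the full count vector every `thin` periods for the
#'   trace (default records ~1000 points).
#' @return An object of class `"chain_run"`: list with `shares` (named
#'   time-average share of each strategy), `trace` (tibble period, label,
#'   n), `final` (final [population_state()]), `periods`, `mean_T`
#'   (average realized rounds per period).
#' @export
run_markov_chain <- function(params, set = NULL, init = NULL,
                             periods = 1000L, thin = NULL) {
  params <- as_game_params(params)
  if (is.null(init)) {
    if (is.null(set)) stop("supply a strategy set or an initial state", call. = FALSE)
    init <- random_state(set, params$N)
  }
  set <- init$set
  if (is.null(thin)) thin <- max(1L, as.integer(periods %/% 1000L))
  out <- eg_run_chain(engine_params(params), engine_strategies(set),
                      engine_systems(set), state_to_engine(init),
                      as.integer(periods), as.integer(thin))
  labels <- set$label
  shares <- stats::setNames(out$share, labels)
  trace <- tibble::as_tibble(expand.grid(label = labels,
                                         period = out$trace_periods,
                                         stringsAsFactors = FALSE))
  trace <- trace[order(trace$period), c("period", "label")]
  trace$n <- as.integer(t(out$trace))
  structure(list(shares = shares,
                 trace = trace,
                 final = population_state(set, assign = out$final + 1L),
                 periods = periods, mean_T = out$mean_T,
                 set = set, params = params),
            class = "chain_run")
}

#' Estimate the invariant distribution by independent long runs
#'
#' Runs several independent chains, each from an independently drawn random
#' initial condition (every agent's strategy i.i.d. uniform over the active
#' set), and summarizes the per-run time-average shares by their cross-run
#' mean and standard error (sample SD across runs divided by `sqrt(runs)`).
#'
#' @param params A [game_params()].
#' @param set A [strategy_set()].
#' @param periods Periods per run.
#' @param runs Number of independent runs (>= 2 for a standard error).
#' @param seeds Optional integer vector of per-run seeds (length `runs`).
#'   If omitted, seeds are drawn from the current RNG stream.
#' @return An object of class `"run_summary"`: tibble `summary` (columns
#'   `label`, `role`, `system`, `mean_share`, `se`), matrix `run_shares`
#'   (runs x strategies), plus `runs`, `periods`, `seeds`.
#' @export
run_invariant_estimate <- function(params, set, periods = 1e5, runs = 7L,
                                   seeds = NULL) {
  params <- as_game_params(params)
  stopifnot(runs >= 2L)
  if (is.null(seeds)) seeds <- sample.int(.Machine$integer.max - 1L, runs)
  stopifnot(length(seeds) == runs)

  run_shares <- matrix(NA_real_, nrow = runs, ncol = nrow(set),
                       dimnames = list(NULL, set$label))
  for (r in seq_len(runs)) {
    set.seed(seeds[r])
    cr <- run_markov_chain(params, init = random_state(set, params$N),
                           periods = periods)
    run_shares[r, ] <- cr$shares
  }
  mean_share <- colMeans(run_shares)
  se <- apply(run_shares, 2, stats::sd) / sqrt(runs)
  structure(list(
    summary = tibble::tibble(label = set$label, role = set$role,
                             system = set$system,
                             mean_share = as.numeric(mean_share),
                             se = as.numeric(se)),
    run_shares = run_shares,
    runs = runs, periods = periods, seeds = seeds,
    set = set, params = params
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>", x$runs, "runs x", format(x$periods, big.mark = ","),
      "periods; max SE =", signif(max(x$summary$se), 3), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.chain_run <- function(x, ...) {
  cat("<chain_run>", format(x$periods, big.mark = ","),
      "periods; mean rounds/period =", signif(x$mean_T, 4), "\n")
  sh <- sort(x$shares, decreasing = TRUE)
  cat("  time-average shares:",
      paste(sprintf("%s=%.3f", names(sh), sh), collapse = ", "), "\n")
  invisible(x)
}

#' Exact best-reply dynamic
#'
#' The structured revision process behind the analytical results: starting
#' from the initial state, producers revise one by one (in random order,
#' without replacement), then one enforcer revises; the producer sweep and
#' single-enforcer steps alternate until every enforcer has revised, after
#' which one agent drawn from the whole population may switch role; the
#' cycle then repeats. Every revision adopts the strategy maximizing the
#' agent's expected per-round payoff ([hypothetical_payoff()]) against the
#' current population, with uniform tie-breaking. Intended for the
#' two-enforcer-strategy (CE/DE) setting with `mu = 0`, `v = 0`; a warning
#' is issued outside that regime.
#'
#' @param init Initial [population_state()] over a CE2-type set.
#' @param params A [game_params()].
#' @param max_cycles Cap on grand cycles before giving up.
#' @return List of class `"best_reply_run"`: `absorbed` (`"E_C"`, `"E_D"`
#'   or `"none"`), `state` (final state), `cycles`, `trajectory` (tibble
#'   per cycle: n_CP, n_DP, n_CE, n_DE).
#' @export
run_exact_best_reply <- function(init, params, max_cycles = 200L) {
  params <- as_game_params(params)
  if (params$mu != 0 || params$v != 0)
    warning("exact best-reply analysis assumes mu = 0 and v = 0", call. = FALSE)
  set <- init$set
  prod_idx <- which(set$role == "producer")
  enf_idx <- which(set$role == "enforcer")
  state <- init
  systems <- attr(set, "systems")

  epar <- engine_params(params)
  estrat <- engine_strategies(set)
  esys <- engine_systems(set)
  counts <- tabulate(state$assign, nbins = nrow(set))

  # memo: while counts are unchanged, a revising agent with the same current
  # strategy and menu faces the same problem; reuse unique-argmax answers
  # (ties are always re-sampled so random tie-breaking is preserved)
  memo <- new.env(parent = emptyenv())
  memo_counts <- NULL

  best_reply <- function(agent, menu_idx) {
    cur <- state$assign[agent]
    if (!identical(memo_counts, counts)) {
      rm(list = ls(memo), envir = memo)
      memo_counts <<- counts
    }
    key <- paste(cur, paste(menu_idx, collapse = "."))
    pick <- memo[[key]]
    if (is.null(pick)) {
      pay <- vapply(menu_idx, function(i) {
        cc <- counts
        cc[cur] <- cc[cur] - 1L
        cc[i] <- cc[i] + 1L
        eg_expected_payoff(epar, estrat, esys, cc, i)
      }, numeric(1))
      best <- which(pay >= max(pay) - 1e-12)
      pick <- menu_idx[best[sample.int(length(best), 1L)]]
      if (length(best) == 1L) memo[[key]] <- pick
    }
    if (pick != cur) {
      counts[cur] <<- counts[cur] - 1L
      counts[pick] <<- counts[pick] + 1L
    }
    pick
  }

  traj <- vector("list", 0L)
  absorbed <- "none"
  for (cyc in seq_len(max_cycles)) {
    role <- set$role[state$assign]
    producers <- which(role == "producer")
    enforcers <- which(role == "enforcer")
    enf_order <- if (length(enforcers)) sample(enforcers) else integer()
    k <- 0L
    repeat {
      for (a in (if (length(producers)) sample(producers) else integer()))
        state$assign[a] <- best_reply(a, prod_idx)
      k <- k + 1L
      if (k > length(enf_order)) break
      state$assign[enf_order[k]] <- best_reply(enf_order[k], enf_idx)
    }
    a <- sample.int(length(state$assign), 1L)
    state$assign[a] <- best_reply(a, seq_len(nrow(set)))

    cc <- state_counts(state)
    n_CE <- sum(cc$n[cc$label == "CE"]); n_DE <- sum(cc$n[cc$label == "DE"])
    n_CP <- sum(cc$n[cc$label == "CP"]); n_DP <- sum(cc$n[cc$label == "DP"])
    traj[[cyc]] <- tibble::tibble(cycle = cyc, n_CP = n_CP, n_DP = n_DP,
                                  n_CE = n_CE, n_DE = n_DE)
    absorbed <- absorbing_set_label(state, params)
    if (absorbed != "none") break
  }
  list(absorbed = absorbed, state = state,
       cycles = length(traj),
       trajectory = dplyr::bind_rows(traj))
}

#' Absorbing-set membership
#'
#' Tests whether a state lies in the cooperation absorbing set `E_C`
#' (all producers CP, all enforcers CE, and
#' `alpha_C * N - 1 <= n_CE <= alpha_C * N`) or the defection set `E_D`
#' (all DP/DE with the `alpha_D` bracket).
#'
#' @param state A [population_state()].
#' @param params A [game_params()].
#' @return `"E_C"`, `"E_D"` or `"none"`.
#' @export
absorbing_set_label <- function(state, params) {
  params <- as_game_params(params)
  cc <- state_counts(state)
  N <- sum(cc$n)
  n_E <- sum(cc$n[cc$role == "enforcer"])
  n_CE <- sum(cc$n[cc$label == "CE"]); n_DE <- sum(cc$n[cc$label == "DE"])
  n_CP <- sum(cc$n[cc$label == "CP"]); n_DP <- sum(cc$n[cc$label == "DP"])
  aC <- alpha_cooperation(params); aD <- alpha_defection(params)
  if (n_CP + n_CE == N && n_CE == n_E &&
      n_CE >= aC * N - 1 && n_CE <= aC * N) return("E_C")
  if (n_DP + n_DE == N && n_DE == n_E &&
      n_DE >= aD * N - 1 && n_DE <= aD * N) return("E_D")
  "none"
}
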