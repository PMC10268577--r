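#' Equilibrium enforcer fractions
#'
#' In the cooperation equilibrium (all producers cooperate, all enforcers
#' follow CE) the enforcer fraction equalizing producer and enforcer
#' payoffs is `alpha_C = tau * (w + b - c) / (w + b + f - c)`; in the
#' defection equilibrium (all DP / DE) it is `alpha_D = w * tau / (w + l)`.
#'
#' @param params A [game_params()].
#' @return The fraction (a number in (0, 1)).
#' @examples
#' alpha_cooperation(preset_params("baseline"))  # 1.5 / 5.3
#' alpha_defection(preset_params("baseline"))    # 0.6 / 7
#' @export
alpha_cooperation <- function(params) {
  params <- as_game_params(params)
  den <- params$w + params$b + params$f - params$c
  if (den <= 0) stop("w + b + f - c must be positive", call. = FALSE)
  params$tau * (params$w + params$b - params$c) / den
}

#' @rdname alpha_cooperation
#' @export
alpha_defection <- function(params) {
  params <- as_game_params(params)
  den <- params$w + params$l
  if (den <= 0) stop("w + l must be positive", call. = FALSE)
  params$w * params$tau / den
}

#' Static equilibrium conditions
#'
#' For the all-CP/all-CE profile to be a subgame perfect equilibrium of the
#' repeated enforcement game (for high enough `kappa` and `delta`), the
#' conflict loss must dominate enforcement costs, `l > 2 * max(f, v)`, and
#' punishment must deter defection, `p > (1 - tau) * c`. The stricter
#' reading of the deterrence threshold, `p > c / (1 - tau)`, is reported as
#' a separate flag.
#'
#' @param params A [game_params()].
#' @return A list of class `"static_conditions"`: logicals `conflict`,
#'   `deterrence`, `both`, `deterrence_strict`, plus the numeric margins.
#' @export
check_static_conditions <- function(params) {
  params <- as_game_params(params)
  conflict <- params$l > 2 * max(params$f, params$v)
  deterrence <- params$p > (1 - params$tau) * params$c
  strict <- params$p > params$c / (1 - params$tau)
  structure(list(
    conflict = conflict,
    deterrence = deterrence,
    both = conflict && deterrence,
    deterrence_strict = strict,
    conflict_margin = params$l - 2 * max(params$f, params$v),
    deterrence_margin = params$p - (1 - params$tau) * params$c
  ), class = "static_conditions")
}

#' Stochastic-stability criterion
#'
#' With vanishing revision mistakes and a large population, the cooperation
#' equilibrium is stochastically stable if
#' `l/f - 1/(1 + l/w) > 1 + f/(w + b - c)`; if the inequality is reversed
#' the defection equilibrium is. Equality is reported as `"boundary"`. The
#' criterion is derived under `v = 0` (and no action mistakes, exact best
#' response, long periods); the result carries flags when called outside
#' those assumptions (`v > 0`, `f >= l`, or deterrence failing) so users
#' know the verdict need not match noisy simulations exactly.
#'
#' @param params A [game_params()].
#' @return A list of class `"stability_result"`: `verdict` (`"cooperation"`,
#'   `"defection"` or `"boundary"`), `lhs`, `rhs`, and logical
#'   `assumption_flags`.
#' @examples
#' stochastic_stability(preset_params("baseline"))$verdict  # "cooperation"
#' @export
stochastic_stability <- function(params) {
  params <- as_game_params(params)
  rhs <- 1 + params$f / (params$w + params$b - params$c)
  if (params$f == 0) {
    lhs <- Inf
  } else {
    lhs <- params$l / params$f - 1 / (1 + params$l / params$w)
  }
  verdict <- if (lhs > rhs) "cooperation" else if (lhs < rhs) "defection" else "boundary"
  flags <- c(
    v_positive = params$v > 0,
    f_not_below_l = params$f >= params$l,
    deterrence_fails = params$p <= (1 - params$tau) * params$c
  )
  if (any(flags[c("f_not_below_l", "deterrence_fails")]))
    warning("stochastic-stability criterion applied outside its assumptions (",
            paste(names(flags)[flags], collapse = ", "), ")", call. = FALSE)
  structure(list(verdict = verdict, lhs = lhs, rhs = rhs,
                 assumption_flags = flags),
            class = "stability_result")
}

#' Classify a state by basin of attraction
#'
#' Under the exact best-reply dynamic (with deterrent punishment and a
#' large population), a state with `n_CE > (f/l) * (n_E - 1) + 1` converges
#' to the cooperation absorbing set with probability one; a state with
#' `n_CE < (f/l) * (n_E - 1)` or `n_E < 2` converges to the defection set;
#' states in the band `(n_CE - 1)/(n_E - 1) <= f/l <= n_CE/(n_E - 1)` (with
#' `n_E >= 2`) can reach either. The three regions partition the state
#' space.
#'
#' @param x A [population_state()], or a data frame with columns `n_CE` and
#'   `n_E` (classified row-wise).
#' @param params A [game_params()].
#' @return For a state: one of `"E_C_basin"`, `"E_D_basin"`,
#'   `"boundary_band"`. For a data frame: the input as a tibble with a
#'   `basin` column added.
#' @export
classify_basin <- function(x, params) {
  params <- as_game_params(params)
  theta <- params$f / params$l
  lab <- function(n_CE, n_E) {
    dplyr::case_when(
      n_E < 2 ~ "E_D_basin",
      n_CE > theta * (n_E - 1) + 1 ~ "E_C_basin",
      n_CE < theta * (n_E - 1) ~ "E_D_basin",
      .default = "boundary_band"
    )
  }
  if (inherits(x, "population_state")) {
    cc <- state_counts(x)
    n_CE <- sum(cc$n[cc$label == "CE"])
    n_E <- sum(cc$n[cc$role == "enforcer"])
    return(lab(n_CE, n_E))
  }
  stopifnot(is.data.frame(x), all(c("n_CE", "n_E") %in% names(x)))
  dplyr::mutate(tibble::as_tibble(x), basin = lab(.data$n_CE, .data$n_E))
}

#' Equilibrium payoffs and their comparison
#'
#' Per-round payoffs in the two equilibria: producers earn
#' `(1 - tau)(w + b - c)` under cooperation and `(1 - tau) w` under
#' defection; enforcers earn `tau (w + b - c)(1 - alpha)/alpha - f` and
#' `tau w (1 - alpha)/alpha - l` respectively, which equal the producer
#' payoffs exactly at the equilibrium fractions (that equalization is how
#' the fractions are derived). Cooperation dominates: payoffs and the
#' enforcer share are both higher in the cooperation equilibrium.
#'
#' @param params A [game_params()].
#' @return A list of class `"equilibrium_payoffs"`: `producer_coop`,
#'   `enforcer_coop`, `producer_def`, `enforcer_def`, `alpha_C`, `alpha_D`,
#'   and logicals `coop_payoff_higher`, `alpha_C_higher`.
#' @export
equilibrium_payoffs <- function(params) {
  params <- as_game_params(params)
  aC <- alpha_cooperation(params)
  aD <- alpha_defection(params)
  g <- params$w + params$b - params$c
  out <- list(
    producer_coop = (1 - params$tau) * g,
    enforcer_coop = params$tau * g * (1 - aC) / aC - params$f,
    producer_def = (1 - params$tau) * params$w,
    enforcer_def = params$tau * params$w * (1 - aD) / aD - params$l,
    alpha_C = aC, alpha_D = aD
  )
  out$coop_payoff_higher <- out$producer_coop > out$producer_def
  out$alpha_C_higher <- aC > aD
  structure(out, class = "equilibrium_payoffs")
}

#' Scan a parameter grid
#'
#' Evaluates the closed-form quantities over a grid of parameter overrides,
#' for phase-diagram style summaries.
#'
#' @param grid A data frame whose columns are [game_params()] argument
#'   names; each row is a set of overrides.
#' @param params Base parameters the overrides are applied to.
#' @return The grid as a tibble with columns `alpha_C`, `alpha_D`,
#'   `conflict_ok`, `deterrence_ok`, `ss_verdict` added.
#' @examples
#' scan_parameters(data.frame(l = c(0.31, 5)), preset_params("baseline"))
#' @export
scan_parameters <- function(grid, params = game_params()) {
  params <- as_game_params(params)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  res <- purrr::pmap(grid, function(...) {
    over <- list(...)
    pp <- params[setdiff(names(params), names(over))]
    pp <- suppressWarnings(do.call(game_params, c(pp, over)))
    st <- check_static_conditions(pp)
    ss <- suppressWarnings(stochastic_stability(pp))
    tibble::tibble(
      alpha_C = alpha_cooperation(pp), alpha_D = alpha_defection(pp),
      conflict_ok = st$conflict, deterrence_ok = st$deterrence,
      ss_verdict = ss$verdict
    )
  })
  dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
}
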