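#' Validated model parameters for the repeated enforcement game
#'
#' Collects every constant of the model in one validated record: the
#' prisoner's-dilemma benefit/cost (`b`, `c`), the autarky payoff `w`, the
#' tax rate `tau`, punishment loss `p` and its variable cost `v`, the fixed
#' per-round information cost `f`, the conflict loss `l` and grab fraction
#' `psi` of the meta-enforcement step, the continuation probability `delta`,
#' the punishment-phase length `kappa`, the action-mistake probability `mu`,
#' the logit imprecision `eta`, the revision-mistake probability `epsilon`,
#' the revision-class probabilities `gamma` and the population size `N`.
#'
#' Mathematical-domain violations (e.g. `c >= b`, `tau * w <= v`, `gamma`
#' not a probability vector) are errors. The behavioural assumption
#' `gamma_P > gamma_E > gamma_PE` is recorded as a flag
#' (`gamma_ordered`) and produces a warning when violated, not an error,
#' since the dynamic is well defined without it.
#'
#' @param b Benefit of cooperation in the PD (> 0).
#' @param c Cost of cooperation (> 0, `c < b`).
#' @param w Autarky payoff of a producer (> 0).
#' @param tau Tax rate, in (0, 1); must satisfy `tau * w > v`.
#' @param p Loss inflicted on a punished producer (>= 0).
#' @param v Variable cost to the enforcer of punishing one client (>= 0).
#' @param f Fixed per-round cost of being an informed enforcer (>= 0).
#' @param l Loss suffered from being attacked in the meta-enforcement step
#'   (>= 0).
#' @param psi Fraction of the victim's revenue grabbed by a unilateral
#'   attacker, in `[0, 1]`.
#' @param delta Continuation probability of the repeated game, in `[0, 1)`.
#' @param kappa Length of the punishment phase (integer >= 1).
#' @param mu Action-mistake probability, in `[0, 1/2)`.
#' @param eta Logit imprecision (>= 0; 0 means exact best response).
#' @param epsilon Revision-mistake ("mutation") probability, in `[0, 1]`.
#' @param gamma Numeric triple `(gamma_PE, gamma_E, gamma_P)` of
#'   revision-class probabilities: whole-population, enforcer-only,
#'   producer-only. Must be non-negative and sum to 1.
#' @param N Population size (integer >= 4).
#'
#' @return An object of class `"game_params"`: a named list of the validated
#'   values with attributes `gamma_ordered` (logical flag).
#' @examples
#' pars <- game_params()          # baseline parameterization
#' pars$tau * pars$w > pars$v     # positive tax revenue is guaranteed
#' @export
game_params <- function(b = 4, c = 1, w = 2, tau = 0.3, p = 2, v = 0.1,
                        f = 0.3, l = 5, psi = 0.7, delta = 0.9, kappa = 8,
                        mu = 0.005, eta = 0.01, epsilon = 0.05,
                        gamma = c(gamma_PE = 0.1, gamma_E = 0.3, gamma_P = 0.6),
                        N = 50) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg, call. = FALSE)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("invalid parameters: ", nm, " must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  b <- num1(b, "b"); c <- num1(c, "c"); w <- num1(w, "w"); tau <- num1(tau, "tau")
  p <- num1(p, "p"); v <- num1(v, "v"); f <- num1(f, "f"); l <- num1(l, "l")
  psi <- num1(psi, "psi"); delta <- num1(delta, "delta"); mu <- num1(mu, "mu")
  eta <- num1(eta, "eta"); epsilon <- num1(epsilon, "epsilon")
  kappa <- num1(kappa, "kappa"); N <- num1(N, "N")

  chk(b > 0, "b must be > 0")
  chk(c > 0, "c must be > 0")
  chk(c < b, "c < b is required (the PD must be a social dilemma)")
  chk(w > 0, "w must be > 0")
  chk(tau > 0 && tau < 1, "tau must lie in (0, 1)")
  chk(p >= 0, "p must be >= 0")
  chk(v >= 0, "v must be >= 0")
  chk(tau * w > v, sprintf("tau * w = %g must exceed v = %g (positive tax revenue)", tau * w, v))
  chk(f >= 0, "f must be >= 0")
  chk(l >= 0, "l must be >= 0")
  chk(psi >= 0 && psi <= 1, "psi must lie in [0, 1]")
  chk(delta >= 0 && delta < 1, "delta must lie in [0, 1)")
  chk(kappa >= 1 && kappa == round(kappa), "kappa must be an integer >= 1")
  chk(mu >= 0 && mu < 0.5, "mu must lie in [0, 1/2)")
  chk(eta >= 0, "eta must be >= 0")
  chk(epsilon >= 0 && epsilon <= 1, "epsilon must lie in [0, 1]")
  chk(N >= 4 && N == round(N), "N must be an integer >= 4")

  if (!is.numeric(gamma) || length(gamma) != 3L || any(!is.finite(gamma)))
    stop("invalid parameters: gamma must be a numeric triple (gamma_PE, gamma_E, gamma_P)",
         call. = FALSE)
  chk(all(gamma >= 0), "gamma components must be non-negative")
  chk(abs(sum(gamma) - 1) < 1e-8, "gamma components must sum to 1")
  gamma <- as.numeric(gamma)
  names(gamma) <- c("gamma_PE", "gamma_E", "gamma_P")

  gamma_ordered <- gamma[["gamma_P"]] > gamma[["gamma_E"]] &&
    gamma[["gamma_E"]] > gamma[["gamma_PE"]]
  if (!gamma_ordered)
    warning("gamma does not satisfy gamma_P > gamma_E > gamma_PE; ",
            "the dynamic is still well defined", call. = FALSE)

  structure(
    list(b = b, c = c, w = w, tau = tau, p = p, v = v, f = f, l = l,
         psi = psi, delta = delta, kappa = as.integer(kappa), mu = mu,
         eta = eta, epsilon = epsilon, gamma = gamma, N = as.integer(N)),
    gamma_ordered = gamma_ordered,
    class = "game_params"
  )
}

#' Named parameterizations
#'
#' `preset_params("baseline")` and `preset_params("alternative")` return the
#' two published parameterizations. They share
#' `delta = 0.9, kappa = 8, w = 2, tau = 0.3, p = 2, psi = 0.7, mu = 0.005,
#' eta = 0.01, epsilon = 0.05, gamma = (0.1, 0.3, 0.6), N = 50` and differ in
#' `b, c, v, f, l`.
#'
#' @param name `"baseline"` or `"alternative"`.
#' @param ... Overrides passed on to [game_params()].
#' @return A [game_params()] object.
#' @examples
#' preset_params("alternative")$l
#' @export
preset_params <- function(name = c("baseline", "alternative"), ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    baseline    = list(b = 4, c = 1, v = 0.1, f = 0.3, l = 5),
    alternative = list(b = 3, c = 2, v = 0.3, f = 0.4, l = 4)
  )
  base[names(over)] <- over
  do.call(game_params, base)
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params>\n")
  flat <- x[setdiff(names(x), "gamma")]
  cat("  ", paste(sprintf("%s=%g", names(flat), unlist(flat)), collapse = ", "), "\n")
  cat("  gamma (PE, E, P): ", paste(signif(x$gamma, 4), collapse = ", "), "\n", sep = "")
  if (!isTRUE(attr(x, "gamma_ordered")))
    cat("  [note] gamma_P > gamma_E > gamma_PE does not hold\n")
  invisible(x)
}

#' @rdname game_params
#' @param x A `game_params` object.
#' @param ... Unused.
#' @method tidy game_params
#' @export
tidy.game_params <- function(x, ...) {
  tibble::tibble(
    parameter = c("b", "c", "w", "tau", "p", "v", "f", "l", "psi", "delta",
                  "kappa", "mu", "eta", "epsilon",
                  "gamma_PE", "gamma_E", "gamma_P", "N"),
    value = c(x$b, x$c, x$w, x$tau, x$p, x$v, x$f, x$l, x$psi, x$delta,
              x$kappa, x$mu, x$eta, x$epsilon,
              x$gamma[["gamma_PE"]], x$gamma[["gamma_E"]], x$gamma[["gamma_P"]],
              x$N)
  )
}

as_game_params <- function(x) {
  if (inherits(x, "game_params")) return(x)
  if (is.list(x)) return(do.call(game_params, x))
  stop("cannot interpret object as game parameters", call. = FALSE)
}
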