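#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-strategy table of a
#' result, `glance()` a one-row summary.
#'
#' @param x A `run_summary` or `chain_run`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy run_summary
#' @export
tidy.run_summary <- function(x, ...) {
  dplyr::mutate(x$summary, runs = x$runs, periods = x$periods)
}

#' @rdname tidiers
#' @method glance run_summary
#' @export
glance.run_summary <- function(x, ...) {
  s <- x$summary
  enf <- s$mean_share[s$role == "enforcer"]
  tibble::tibble(
    runs = x$runs, periods = x$periods,
    max_se = max(s$se), median_se = stats::median(s$se),
    cp_share = sum(s$mean_share[s$label == "CP"]),
    dp_share = sum(s$mean_share[s$label == "DP"]),
    enforcer_share = sum(enf)
  )
}

#' @rdname tidiers
#' @method tidy chain_run
#' @export
tidy.chain_run <- function(x, ...) {
  tibble::tibble(label = names(x$shares), share = as.numeric(x$shares))
}

#' @rdname tidiers
#' @method glance chain_run
#' @export
glance.chain_run <- function(x, ...) {
  tibble::tibble(periods = x$periods, mean_rounds = x$mean_T,
                 cp_share = as.numeric(x$shares["CP"]),
                 dp_share = as.numeric(x$shares["DP"]))
}

#' @rdname tidiers
#' @method tidy equilibrium_payoffs
#' @export
tidy.equilibrium_payoffs <- function(x, ...) {
  tibble::tibble(
    equilibrium = c("cooperation", "cooperation", "defection", "defection"),
    role = c("producer", "enforcer", "producer", "enforcer"),
    payoff = c(x$producer_coop, x$enforcer_coop,
               x$producer_def, x$enforcer_def),
    alpha = c(x$alpha_C, x$alpha_C, x$alpha_D, x$alpha_D)
  )
}

#' @rdname tidiers
#' @method tidy static_conditions
#' @export
tidy.static_conditions <- function(x, ...) {
  tibble::tibble(
    condition = c("conflict", "deterrence", "deterrence_strict"),
    holds = c(x$conflict, x$deterrence, x$deterrence_strict),
    margin = c(x$conflict_margin, x$deterrence_margin, NA_real_)
  )
}
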