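#' Scenarios: named, validated simulation setups
#'
#' A scenario bundles everything a simulation run needs: parameters, a
#' strategy-set preset, run lengths, number of runs and seeds. The named
#' presets `"baseline"` and `"alternative"` carry the two published
#' parameterizations (see [preset_params()]).
#'
#' @param name Scenario name.
#' @param params A [game_params()].
#' @param preset Strategy-set preset (see [strategy_set()]).
#' @param periods Periods per run.
#' @param runs Number of independent runs.
#' @param seeds Optional integer vector of per-run seeds.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, params, preset = "CE2", periods = 1e5, runs = 7L,
                     seeds = NULL) {
  params <- as_game_params(params)
  preset <- match.arg(preset, c("CE16", "CE2", "PE16", "PE2", "CEPE3"))
  stopifnot(periods >= 1, runs >= 1)
  if (!is.null(seeds)) stopifnot(length(seeds) == runs)
  structure(list(name = name, params = params, preset = preset,
                 periods = as.integer(periods), runs = as.integer(runs),
                 seeds = seeds),
            class = "scenario")
}

#' Load a scenario from a preset name or a config file
#'
#' Accepts the preset names `"baseline"` and `"alternative"`, or a path to
#' a YAML or JSON file with keys `name`, `preset`, `periods`, `runs`,
#' `seeds` and a `params` block whose entries are the [game_params()]
#' argument names (`b, c, w, tau, p, v, f, l, psi, delta, kappa, mu, eta,
#' epsilon, gamma_pe, gamma_e, gamma_p, N`). `overrides` (e.g. from CLI
#' flags) are applied after file values.
#'
#' @param x Preset name or file path.
#' @param overrides Named list of parameter overrides.
#' @return A [scenario()].
#' @examples
#' load_scenario("baseline")$params$b  # 4
#' @export
load_scenario <- function(x, overrides = list()) {
  if (x %in% c("baseline", "alternative")) {
    raw <- list(name = x, preset = "CE2", periods = 1e5, runs = 7,
                params = unclass(preset_params(x)))
    raw$params$gamma <- NULL
    raw$params[c("gamma_pe", "gamma_e", "gamma_p")] <- list(0.1, 0.3, 0.6)
  } else {
    if (!file.exists(x)) stop("no such scenario preset or file: ", x, call. = FALSE)
    raw <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
    if (is.null(raw$params)) stop("config is missing the params block", call. = FALSE)
    known <- c("name", "preset", "periods", "runs", "seeds", "params")
    bad <- setdiff(names(raw), known)
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  if (length(overrides)) raw$params[names(overrides)] <- overrides

  pn <- raw$params
  req <- c("b", "c", "w", "tau", "p", "v", "f", "l", "psi", "delta", "kappa",
           "mu", "eta", "epsilon", "gamma_pe", "gamma_e", "gamma_p", "N")
  missing_keys <- setdiff(tolower(req), tolower(names(pn)))
  if (length(missing_keys))
    stop("config is missing required parameters: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  names(pn) <- tolower(names(pn))
  params <- game_params(
    b = pn$b, c = pn$c, w = pn$w, tau = pn$tau, p = pn$p, v = pn$v,
    f = pn$f, l = pn$l, psi = pn$psi, delta = pn$delta, kappa = pn$kappa,
    mu = pn$mu, eta = pn$eta, epsilon = pn$epsilon,
    gamma = c(gamma_PE = pn$gamma_pe, gamma_E = pn$gamma_e,
              gamma_P = pn$gamma_p),
    N = pn$n
  )
  scenario(name = raw$name %||% "unnamed", params = params,
           preset = raw$preset %||% "CE2",
           periods = raw$periods %||% 1e5, runs = raw$runs %||% 7L,
           seeds = raw$seeds)
}

#' Write a scenario back to YAML
#'
#' Inverse of [load_scenario()]: `load_scenario(write_scenario(sc, path))`
#' reproduces the scenario.
#'
#' @param sc A [scenario()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  p <- sc$params
  out <- list(
    name = sc$name, preset = sc$preset, periods = sc$periods, runs = sc$runs,
    params = list(b = p$b, c = p$c, w = p$w, tau = p$tau, p = p$p, v = p$v,
                  f = p$f, l = p$l, psi = p$psi, delta = p$delta,
                  kappa = p$kappa, mu = p$mu, eta = p$eta,
                  epsilon = p$epsilon,
                  gamma_pe = p$gamma[["gamma_PE"]],
                  gamma_e = p$gamma[["gamma_E"]],
                  gamma_p = p$gamma[["gamma_P"]], N = p$N)
  )
  if (!is.null(sc$seeds)) out$seeds <- sc$seeds
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a scenario
#'
#' Convenience wrapper: builds the strategy set and calls
#' [run_invariant_estimate()].
#'
#' @param sc A [scenario()] (or preset name passed to [load_scenario()]).
#' @param ... Overrides for `periods`, `runs`, `seeds`.
#' @return A `run_summary`.
#' @export
run_scenario <- function(sc, ...) {
  if (is.character(sc)) sc <- load_scenario(sc)
  over <- list(...)
  for (k in names(over)) sc[[k]] <- over[[k]]
  run_invariant_estimate(sc$params, strategy_set(sc$preset),
                         periods = sc$periods, runs = sc$runs,
                         seeds = sc$seeds)
}

#' Write a run summary (or any tabular result) to CSV with metadata
#'
#' Writes the tidy table to `path` and a machine-readable JSON metadata
#' block (`<path>.meta.json`) with the parameters, seeds and package
#' version, so every output is reproducible from its metadata alone.
#' Column order is deterministic and floats are written at full precision.
#'
#' @param x A `run_summary`, `chain_run`, or data frame.
#' @param path Output CSV path.
#' @param format `"csv"` (default) or `"json"` for the table itself.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- if (is.data.frame(x)) tibble::as_tibble(x) else tidy(x)
  meta <- list(package = "enforcegame",
               version = as.character(utils::packageVersion("enforcegame")))
  if (inherits(x, "run_summary")) {
    meta$params <- unclass(x$params)
    meta$seeds <- x$seeds
    meta$runs <- x$runs
    meta$periods <- x$periods
  } else if (inherits(x, "chain_run")) {
    meta$params <- unclass(x$params)
    meta$periods <- x$periods
  }
  if (format == "csv") {
    utils::write.csv(format(as.data.frame(tab), digits = 17,
                            scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
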