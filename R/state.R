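#' Population state
#'
#' Agents have persistent integer identities `1..N`; a state records the
#' strategy each agent currently uses, as a row index into a strategy set.
#' Strategy counts, the number of producers `n_P` and of enforcers `n_E`
#' are derived from the per-agent assignment and always satisfy
#' `n_P + n_E = N`.
#'
#' @param set A [strategy_set()].
#' @param assign Integer vector, one strategy row index per agent; or `NULL`
#'   if `counts` is given.
#' @param counts Named integer vector of per-strategy counts (names are
#'   strategy labels of `set`); expanded to an assignment in label order.
#' @return An object of class `"population_state"`: list with elements
#'   `set` and `assign`.
#' @examples
#' s <- strategy_set("CE2")
#' st <- population_state(s, counts = c(CP = 30, DP = 6, CE = 10, DE = 4))
#' state_counts(st)
#' @export
population_state <- function(set, assign = NULL, counts = NULL) {
  stopifnot(inherits(set, "strategy_set"))
  if (is.null(assign)) {
    if (is.null(counts)) stop("supply either assign or counts", call. = FALSE)
    idx <- match(names(counts), set$label)
    if (anyNA(idx))
      stop("unknown strategy labels: ",
           paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
    assign <- rep(idx, times = as.integer(counts))
  }
  assign <- as.integer(assign)
  if (any(assign < 1L | assign > nrow(set)))
    stop("assignment indices out of range", call. = FALSE)
  structure(list(set = set, assign = assign), class = "population_state")
}

#' Uniform random initial state
#'
#' Each agent's strategy is drawn i.i.d. uniformly over the active strategy
#' set (producer and enforcer strategies alike), the distribution from which
#' chain runs draw their initial conditions.
#'
#' @param set A [strategy_set()].
#' @param N Population size.
#' @return A [population_state()].
#' @export
random_state <- function(set, N) {
  population_state(set, assign = sample.int(nrow(set), N, replace = TRUE))
}

#' Per-strategy counts of a state
#'
#' @param state A [population_state()].
#' @return A tibble with columns `label`, `role`, `system`, `bits`, `n`
#'   (one row per strategy in the set, zero counts included).
#' @export
state_counts <- function(state) {
  stopifnot(inherits(state, "population_state"))
  n <- tabulate(state$assign, nbins = nrow(state$set))
  tibble::tibble(
    label = state$set$label, role = state$set$role,
    system = state$set$system, bits = state$set$bits, n = n
  )
}

n_producers <- function(state) sum(state$set$role[state$assign] == "producer")
n_enforcers <- function(state) sum(state$set$role[state$assign] == "enforcer")

#' @export
print.population_state <- function(x, ...) {
  cc <- state_counts(x)
  cat("<population_state> N =", length(x$assign),
      "(", n_producers(x), "producers,", n_enforcers(x), "enforcers )\n")
  cc <- cc[cc$n > 0L, c("label", "n")]
  cat("  ", paste(sprintf("%s=%d", cc$label, cc$n), collapse = ", "), "\n")
  invisible(x)
}
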