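#' Strategy sets for the repeated enforcement game
#'
#' Producers always use one of two strategies: `CP` (always cooperate) and
#' `DP` (always defect). An enforcer strategy is a string of four binary
#' digits `(a_coop, a_def, a_good, a_bad)`: the action against a client who
#' cooperated / defected (1 = punish) and against a meta-enforcement
#' coplayer in good / bad standing (1 = attack). `0101` is the cooperation
#' enforcer `CE`, `0011` the defection enforcer `DE` (never punishes, always
#' attacks), and `0001` under the parochial standard is `PE`.
#'
#' A strategy whose action depends on neither client behaviour nor coplayer
#' standing (`0000`, `0011`, `1100`, `1111`) is *uninformed*: it never
#' consults any reputation system and pays no information cost `f`. The
#' identity of a conditioning strategy includes the reputation system it
#' consults, so `0101` under the CE system and under the PE system are
#' different strategies; the four uninformed codes are system-free, which in
#' particular makes `DE` a single strategy shared by all presets.
#'
#' @param preset One of `"CE16"`, `"CE2"`, `"PE16"`, `"PE2"`, `"CEPE3"`:
#'   the 16 enforcer strategies under one standard, the two-strategy sets
#'   `{CE, DE}` / `{PE, DE}`, or the mixed set `{CE, PE, DE}`.
#' @return A tibble of class `"strategy_set"` with one row per strategy
#'   (producers first): columns `label`, `role`, `system` (`NA` for
#'   producers and uninformed enforcers), `bits` (4-character code, `NA`
#'   for producers), `a_coop`, `a_def`, `a_good`, `a_bad`, `informed`,
#'   `producer_action`. Attribute `preset` records the preset name and
#'   `systems` the reputation systems that must be tracked.
#' @examples
#' strategy_set("CE2")
#' nrow(dplyr::filter(strategy_set("CE16"), role == "enforcer"))
#' @export
strategy_set <- function(preset = c("CE16", "CE2", "PE16", "PE2", "CEPE3")) {
  preset <- match.arg(preset)
  enf <- switch(preset,
    CE16  = lapply(all_bit_codes(), function(b) enforcer_row(b, "CE")),
    PE16  = lapply(all_bit_codes(), function(b) enforcer_row(b, "PE")),
    CE2   = list(enforcer_row("0101", "CE"), enforcer_row("0011", "CE")),
    PE2   = list(enforcer_row("0001", "PE"), enforcer_row("0011", "PE")),
    CEPE3 = list(enforcer_row("0101", "CE"), enforcer_row("0001", "PE"),
                 enforcer_row("0011", "CE"))
  )
  out <- dplyr::bind_rows(producer_rows(), dplyr::bind_rows(enf))
  systems <- sort(unique(out$system[!is.na(out$system)]))
  if (length(systems) == 0L) systems <- "CE"
  structure(out, preset = preset, systems = systems,
            class = c("strategy_set", class(out)))
}

all_bit_codes <- function() {
  g <- expand.grid(a_bad = 0:1, a_good = 0:1, a_def = 0:1, a_coop = 0:1)
  paste0(g$a_coop, g$a_def, g$a_good, g$a_bad)
}

producer_rows <- function() {
  tibble::tibble(
    label = c("CP", "DP"), role = "producer", system = NA_character_,
    bits = NA_character_,
    a_coop = NA_integer_, a_def = NA_integer_,
    a_good = NA_integer_, a_bad = NA_integer_,
    informed = FALSE, producer_action = c("C", "D")
  )
}

enforcer_row <- function(bits, system) {
  stopifnot(grepl("^[01]{4}$", bits))
  bv <- as.integer(strsplit(bits, "")[[1]])
  inf <- bv[1] != bv[2] || bv[3] != bv[4]
  if (!inf) system <- NA_character_  # uninformed codes are system-free
  label <- strategy_alias(bits, system, inf)
  tibble::tibble(
    label = label, role = "enforcer", system = system, bits = bits,
    a_coop = bv[1], a_def = bv[2], a_good = bv[3], a_bad = bv[4],
    informed = inf, producer_action = NA_character_
  )
}

strategy_alias <- function(bits, system, informed) {
  if (bits == "0011") return("DE")
  if (informed && bits == "0101" && identical(system, "CE")) return("CE")
  if (informed && bits == "0001" && identical(system, "PE")) return("PE")
  if (!informed) return(paste0("E:", bits))
  paste0(system, ":", bits)
}

#' Parse a strategy literal
#'
#' Accepts the aliases `"CP"`, `"DP"`, `"CE"`, `"DE"`, `"PE"` and the
#' general forms `"CE:0101"`, `"PE:0001"` (conditioning enforcer strategies
#' tagged with the reputation system they consult) and `"E:0000"` /
#' bare `"0011"` for uninformed codes. `"CE:0011"` and `"PE:0011"` both
#' normalize to the single system-free `DE`.
#'
#' @param x A strategy literal.
#' @return A one-row strategy tibble as in [strategy_set()].
#' @examples
#' parse_strategy("CE:0101")$label
#' parse_strategy("PE:0011")$label   # "DE"
#' @export
parse_strategy <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(trimws(x))
  if (x == "CP") return(producer_rows()[1, ])
  if (x == "DP") return(producer_rows()[2, ])
  if (x == "CE") return(enforcer_row("0101", "CE"))
  if (x == "PE") return(enforcer_row("0001", "PE"))
  if (x == "DE") return(enforcer_row("0011", NA_character_))
  if (grepl("^[01]{4}$", x)) {
    row <- enforcer_row(x, NA_character_)
    if (row$informed)
      stop("strategy code ", x, " conditions on information; ",
           "tag it with a system, e.g. \"CE:", x, "\"", call. = FALSE)
    return(row)
  }
  m <- regmatches(x, regexec("^(CE|PE|E):([01]{4})$", x))[[1]]
  if (length(m) == 3L) {
    sys <- if (m[2] == "E") NA_character_ else m[2]
    row <- enforcer_row(m[3], sys)
    if (row$informed && is.na(row$system))
      stop("strategy code ", m[3], " conditions on information; ",
           "tag it with CE: or PE:", call. = FALSE)
    return(row)
  }
  stop("cannot parse strategy literal: ", x, call. = FALSE)
}

#' Is a strategy informed?
#'
#' An enforcer strategy is informed iff it conditions on something:
#' `a_coop != a_def` or `a_good != a_bad`. Informed enforcers pay the fixed
#' cost `f` every round; uninformed ones do not. Producers are never
#' informed.
#'
#' @param strategies A strategy tibble ([strategy_set()] or rows of one).
#' @return Logical vector.
#' @export
is_informed <- function(strategies) {
  stopifnot(is.data.frame(strategies))
  strategies$informed
}
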