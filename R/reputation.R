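#' Standing scores and the reputation automaton
#'
#' Each enforcer `i` carries a score `z_i` in `{0, 1, ..., kappa}` under
#' every reputation system in play. `z = 0` means good standing; `z = k > 0`
#' means bad standing for the next `k` rounds (including the current one).
#' All enforcers start each period in good standing. The automaton:
#' a compliant round leaves `z = 0` at 0 and decrements `z = k > 0` to
#' `k - 1`; any violation resets the score to `kappa`, whatever it was.
#'
#' `standing_ledger()` creates the per-period score table; `update_score()`
#' is the (vectorized) transition map.
#'
#' @param enforcer_ids Integer agent identities of the current enforcers.
#' @param systems Character vector of active reputation systems
#'   (subset of `c("CE", "PE")`).
#' @param kappa Punishment-phase length.
#' @return `standing_ledger()`: an object of class `"standing_ledger"`
#'   wrapping an integer matrix (rows = enforcers, columns = systems) of
#'   zeros.
#' @examples
#' led <- standing_ledger(c(3L, 7L), "CE", kappa = 8)
#' update_score(0L, complied = FALSE, kappa = 8)  # -> 8
#' @export
standing_ledger <- function(enforcer_ids, systems, kappa) {
  m <- matrix(0L, nrow = length(enforcer_ids), ncol = length(systems),
              dimnames = list(as.character(enforcer_ids), systems))
  structure(list(scores = m, kappa = as.integer(kappa)),
            class = "standing_ledger")
}

#' @rdname standing_ledger
#' @param z Current score(s), integers in `{0, ..., kappa}`.
#' @param complied Logical: did the enforcer comply with the standard this
#'   round?
#' @return `update_score()`: the new score(s).
#' @export
update_score <- function(z, complied, kappa) {
  z <- as.integer(z)
  if (any(z < 0L | z > kappa))
    stop("score out of range [0, kappa]", call. = FALSE)
  ifelse(complied, pmax(z - 1L, 0L), as.integer(kappa))
}

#' Query good/bad standing
#'
#' @param ledger A [standing_ledger()].
#' @param enforcer_id Agent identity.
#' @param system Reputation system name.
#' @return `TRUE` if the enforcer's score under `system` is 0 (good
#'   standing).
#' @export
in_good_standing <- function(ledger, enforcer_id, system) {
  ledger$scores[as.character(enforcer_id), system] == 0L
}

#' Tidy snapshot of a standing ledger
#'
#' @param x A [standing_ledger()].
#' @param ... Unused.
#' @return Tibble with columns `enforcer`, `system`, `score`, `standing`.
#' @method tidy standing_ledger
#' @export
tidy.standing_ledger <- function(x, ...) {
  m <- x$scores
  tibble::tibble(
    enforcer = rep(as.integer(rownames(m)), times = ncol(m)),
    system = rep(colnames(m), each = nrow(m)),
    score = as.integer(m),
    standing = ifelse(as.integer(m) == 0L, "good", "bad")
  )
}

#' One enforcer's conduct in one round
#'
#' The evidence on which compliance is judged: what each of her clients did
#' in the PD and whether she punished them, plus whether she attacked her
#' meta-enforcement coplayer (if she was matched). Actions recorded are the
#' *realized* ones, after action mistakes — scores are updated according to
#' actual actions taken.
#'
#' @param client_actions Character vector of realized client PD actions
#'   (`"C"`/`"D"`); may be empty.
#' @param client_punished Logical vector, same length.
#' @param matched Was the enforcer matched in the meta-enforcement step?
#' @param attacked If matched, did she (actually) attack?
#' @return A list of class `"round_conduct"`.
#' @export
round_conduct <- function(client_actions = character(), client_punished = logical(),
                          matched = FALSE, attacked = NA) {
  stopifnot(length(client_actions) == length(client_punished),
            all(client_actions %in% c("C", "D")))
  if (matched && is.na(attacked))
    stop("attacked must be TRUE/FALSE when matched", call. = FALSE)
  structure(list(client_actions = client_actions,
                 client_punished = client_punished,
                 matched = isTRUE(matched),
                 attacked = attacked),
            class = "round_conduct")
}

#' Compliance with the CE and PE standards
#'
#' The cooperation-enforcer (CE) standard requires punishing every act of
#' defection and no act of cooperation among one's clients, and attacking
#' the meta-enforcement coplayer if and only if that coplayer entered the
#' round in bad standing. The parochial-enforcer (PE) standard ignores the
#' treatment of producers and keeps only the attack clause. Clauses with no
#' evidence (no clients; unmatched in the meta step) are vacuously
#' satisfied. Coplayer standing is the standing at round entry under the
#' judging system.
#'
#' @param conduct A [round_conduct()].
#' @param coplayer_standing `"good"` or `"bad"`: the coplayer's standing at
#'   round entry under the judging system (ignored if unmatched).
#' @return `TRUE` iff the conduct complies with the standard.
#' @examples
#' ok <- round_conduct(c("D", "C"), c(TRUE, FALSE))
#' ce_compliant(ok, "good")  # TRUE: defector punished, cooperator spared
#' @export
ce_compliant <- function(conduct, coplayer_standing = c("good", "bad")) {
  stopifnot(inherits(conduct, "round_conduct"))
  punished_right <- all(conduct$client_punished == (conduct$client_actions == "D"))
  punished_right && attack_clause(conduct, coplayer_standing)
}

#' @rdname ce_compliant
#' @export
pe_compliant <- function(conduct, coplayer_standing = c("good", "bad")) {
  stopifnot(inherits(conduct, "round_conduct"))
  attack_clause(conduct, coplayer_standing)
}

attack_clause <- function(conduct, coplayer_standing) {
  if (!conduct$matched) return(TRUE)
  coplayer_standing <- match.arg(coplayer_standing, c("good", "bad"))
  identical(conduct$attacked, coplayer_standing == "bad")
}
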