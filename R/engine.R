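# converters feeding the compiled chain engine

engine_params <- function(params) {
  list(b = params$b, c = params$c, w = params$w, tau = params$tau,
       p = params$p, v = params$v, f = params$f, l = params$l,
       psi = params$psi, delta = params$delta, mu = params$mu,
       eta = params$eta, epsilon = params$epsilon,
       gPE = params$gamma[["gamma_PE"]], gE = params$gamma[["gamma_E"]],
       gP = params$gamma[["gamma_P"]],
       kappa = params$kappa, N = params$N)
}

engine_strategies <- function(set) {
  systems <- attr(set, "systems")
  m <- cbind(
    role = as.integer(set$role == "enforcer"),
    prodC = ifelse(set$role == "producer",
                   as.integer(set$producer_action == "C"), -1L),
    a_coop = ifelse(is.na(set$a_coop), 0L, set$a_coop),
    a_def = ifelse(is.na(set$a_def), 0L, set$a_def),
    a_good = ifelse(is.na(set$a_good), 0L, set$a_good),
    a_bad = ifelse(is.na(set$a_bad), 0L, set$a_bad),
    informed = as.integer(set$informed),
    sys = ifelse(is.na(set$system), -1L, match(set$system, systems) - 1L)
  )
  storage.mode(m) <- "integer"
  m
}

engine_systems <- function(set) {
  as.integer(attr(set, "systems") == "CE")
}

state_to_engine <- function(state) as.integer(state$assign - 1L)
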