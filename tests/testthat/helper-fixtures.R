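# shared fixtures: the two published parameterizations and the analytic
# regime (no action mistakes, no variable cost, exact best response)
baseline <- function(...) preset_params("baseline", ...)
alternative <- function(...) preset_params("alternative", ...)
analytic_params <- function(name = "baseline", ...) {
  preset_params(name, mu = 0, v = 0, epsilon = 0, eta = 0, ...)
}

ce2_state <- function(CP = 0, DP = 0, CE = 0, DE = 0) {
  population_state(strategy_set("CE2"),
                   counts = c(CP = CP, DP = DP, CE = CE, DE = DE))
}
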