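---
title: "Guarding the guards: the repeated enforcement game and its learning dynamic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guarding the guards: the repeated enforcement game and its learning dynamic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enforcegame)
```

## The model

`enforcegame` simulates a population in which cooperation among ordinary
*producers* is sustained not by reciprocity among the producers themselves
but by specialized *enforcers* — and in which the enforcers are in turn
policed by one another through a reputation system. The question the model
answers is the classic "who guards the guards?": under what conditions does
an evolutionary process select enforcers who actually provide enforcement
services, rather than enforcers who simply extort?

Time is divided into periods. Within a period the population plays a
repeated game: after every round a new round begins with probability
$\delta$, so the number of rounds is geometric with mean $1/(1-\delta)$
(10 rounds at the default $\delta = 0.9$). Each round has three steps:

1. **Production.** Producers are uniformly randomly paired and play a
   prisoner's dilemma: cooperation confers a benefit $b$ on the partner at
   cost $c < b$; defection does nothing. Every producer also has an
   autarky payoff $w$, so a matched producer ends the step holding
   $w + \text{PD payoff}$.
2. **Enforcement.** Each producer pair is independently assigned to a
   uniformly random enforcer, who coercively taxes each client a fraction
   $\tau$ of the client's holdings and may punish any client, inflicting a
   loss $p$ at a cost $v$ per punished client.
3. **Meta-enforcement.** Enforcers are uniformly randomly paired. Each may
   attack the other over the tax revenue $R$ collected in step 2: a
   unilateral attacker grabs a fraction $\psi$ of the victim's revenue and
   the victim additionally loses $l$; under mutual attack both lose $l$ and
   nothing is transferred.

Enforcers who condition their behaviour — on what their clients did, or on
the standing of the coplayer they meet in step 3 — are *informed* and pay a
fixed per-round cost $f$ for the requisite information channels. Every
binary choice in the game is executed with an action-mistake probability
$\mu$ of flipping.

### Reputation

Each enforcer carries a score $z \in \{0, 1, \dots, \kappa\}$ under every
active reputation system: $z = 0$ is good standing, $z > 0$ bad standing
for the next $z$ rounds. Compliance is judged once per enforcer per round.
Under the *cooperation-enforcer* (CE) standard an enforcer complies if she
punished exactly the defecting clients and attacked her step-3 coplayer if
and only if that coplayer entered the round in bad standing. The
*parochial-enforcer* (PE) standard keeps only the attack clause and ignores
how producers are treated. A compliant round leaves $z = 0$ in place and
decrements $z > 0$; any violation resets $z$ to $\kappa$. All enforcers
start every period in good standing; standings do not persist across
periods, because each period is a self-contained repeated game.

Strategies are four bits $(a_{\text{coop}}, a_{\text{def}}, a_{\text{good}},
a_{\text{bad}})$ — punish a cooperator / a defector, attack a good- / a
bad-standing coplayer — giving $2^4 = 16$ enforcer strategies per standard.
`0101` under CE is the CE strategy (always comply), `0011` is the
always-attacking, never-punishing defection enforcer DE, and `0001` under
PE is the PE strategy. Producers are `CP` (always cooperate) or `DP`
(always defect).

### Learning

Between consecutive periods exactly one agent revises. With probability
$\gamma_P$ a producer revises among producer strategies, with $\gamma_E$ an
enforcer among enforcer strategies, and with $\gamma_{P,E}$ an agent drawn
from the whole population chooses from the full set (this is the only
channel through which the producer/enforcer split changes). With
probability $\varepsilon$ the revision is a mistake — a uniform draw from
the menu — and otherwise a logit best response with imprecision $\eta$ to
the realized per-strategy average payoffs of the period just played. The
resulting Markov chain is ergodic for $\varepsilon > 0$, and its invariant
distribution is estimated by time averages of strategy shares.

## Closed-form results

In the analytic regime ($\mu = v = 0$, $\eta = 0$, $\delta \to 1$,
$\kappa \to \infty$, CE/DE enforcers only) the unperturbed dynamic has two
absorbing sets. In the cooperation equilibrium all producers cooperate and
all enforcers follow CE, with enforcer fraction
$\alpha^C = \tau(w+b-c)/(w+b+f-c)$; in the defection equilibrium all defect
and all enforcers are DE, with $\alpha^D = w\tau/(w+l)$. Both fractions
come from payoff equalization across roles, which is why
`equilibrium_payoffs()` reports producer and enforcer payoffs that agree to
machine precision at these fractions. The basin boundary is governed by the
ratio $f/l$: a state converges to cooperation whenever
$n_{CE} > (f/l)(n_E - 1) + 1$, to defection whenever
$n_{CE} < (f/l)(n_E - 1)$ or $n_E < 2$, and can reach either limit from the
band in between (`classify_basin()`; checked against
`run_exact_best_reply()` in the test suite). With rare revision mistakes
the cooperation equilibrium is stochastically stable iff
$l/f - 1/(1 + l/w) > 1 + f/(w+b-c)$ (`stochastic_stability()`).

The static existence conditions are $l > 2\max\{f, v\}$ (conflict among
enforcers must be costly relative to enforcement costs) and deterrent
punishment. The deterrence threshold appears in two algebraic forms in the
model's sources, $p > (1-\tau)c$ and the stricter $p > c/(1-\tau)$;
`check_static_conditions()` adopts the former — the form under which all of
the dynamic analysis is derived — and reports the stricter reading as a
separate flag. The distinction matters: the alternative parameterization
($c = 2$, $\tau = 0.3$, $p = 2$) satisfies only the weaker form.

## Parameters

The two shipped parameterizations (`preset_params()`, also available as
scenario presets):

| symbol | meaning | baseline | alternative |
|---|---|---|---|
| $b$, $c$ | PD benefit / cost | 4, 1 | 3, 2 |
| $v$, $f$ | variable / fixed enforcement cost | 0.1, 0.3 | 0.3, 0.4 |
| $l$ | loss from being attacked | 5 | 4 |
| $w$, $\tau$, $p$, $\psi$ | autarky, tax, punishment, grab | 2, 0.3, 2, 0.7 | same |
| $\delta$, $\kappa$ | continuation, punishment phase | 0.9, 8 | same |
| $\mu$, $\eta$, $\varepsilon$ | action / logit / revision noise | 0.005, 0.01, 0.05 | same |
| $(\gamma_{P,E}, \gamma_E, \gamma_P)$ | revision classes | (0.1, 0.3, 0.6) | same |
| $N$ | population size | 50 | same |

Validation is strict for mathematical domain violations ($c \ge b$,
$\tau w \le v$, $\gamma$ not a probability vector, ...) and warning-only
for the behavioural ordering $\gamma_P > \gamma_E > \gamma_{P,E}$, which
the model relaxes when studying permissive revision regimes.

## Design choices in genuinely open corners

Several details are under-determined by the model statement; the package
fixes them once, as follows.

* **Tax base.** Pre-tax resources are $w + \text{PD payoff}$, i.e. the
  autarky payoff is taxed too. This is the only base consistent with the
  assumption $\tau w > v$ ("positive tax revenue") and it reproduces
  $\alpha^C$ and $\alpha^D$ exactly when payoffs are equalized.
* **The fixed cost $f$ is charged per round** to every informed enforcer;
  per-round charging is what makes the cooperation-equilibrium payoff
  equalization yield $\alpha^C = \tau(w+b-c)/(w+b+f-c)$ exactly.
* **Odd counts.** An unmatched producer earns untaxed $w$; an unmatched
  enforcer skips the meta step and keeps her revenue; missing steps are
  vacuously compliant. The sources do not print their convention, so this
  one is the package's own and is deliberately minimal.
* **Strategy identity.** A conditioning strategy is identified by
  (system, bits); the four constant-action codes consult nothing and are
  system-free, so DE is one strategy in every preset and the mixed
  CE/PE set has exactly three enforcer strategies.
* **Coexisting systems.** When CE and PE standings are both active, every
  enforcer is scored under both standards simultaneously, each standard
  judging by its own books; a strategy consults only its own system's
  standing when deciding attacks. The sources do not describe
  cross-system bookkeeping; this symmetric convention is the minimal one.
* **Unused strategies in the logit.** Realized average payoffs are
  undefined for strategies with no users, so the menu is completed with
  `hypothetical_payoff()`: the analytic expectation of the candidate's
  per-round payoff against the current population, computed in the
  long-run regime (all CE-compliant enforcers in good standing, all
  violators in permanent bad standing). "Current payoffs" is read as the
  whole previous period's realized per-round averages, matching how
  payoffs are defined.
* **Long-run standings** for those expectations come from a grow-only
  fixed point: starting from all-good, a strategy is marked bad under a
  system as soon as any reachable interaction would make it violate that
  system's standard, and stays bad (the analytic regime has an unbounded
  punishment phase). This reproduces the boundary cases — a lone enforcer
  stays good; DE stays good only when it can meet neither a defecting
  client nor another enforcer.
* **Ties at $\eta = 0$** are broken uniformly. Equality cases of all the
  closed-form inequalities return explicit `"boundary"` labels.
* **The stochastic-stability criterion is evaluated exactly as derived**
  (in particular with $v$ absent); calling it at $v > 0$ sets a flag on
  the result rather than silently pretending the criterion covers $v$.

## Numerics and reproducibility

The chain engine is compiled (Rcpp). It mirrors the R-level
`play_round()`/`play_period()`/`revise_agent()` reference implementation,
which the test suite cross-checks against it on deterministic
configurations and on the analytic payoff formulas. Randomness inside the
engine comes from a xoshiro256++ generator seeded from R's RNG stream, so
`set.seed()` makes every run reproducible; logit weights are computed with
max-subtraction so extreme payoffs cannot overflow. A million-period run
at $N = 50$ takes a few seconds on one core.

`run_invariant_estimate()` follows the estimation protocol of the model's
numerical analysis: independent chains from independently drawn uniform
initial conditions, time averages over *all* periods (no burn-in), and
cross-run standard errors (sample SD across runs over $\sqrt{\text{runs}}$).
The package's own acceptance checks use seven runs of $10^6$ periods for
the 16-strategy baseline — the full published scale — plus $10^5$-period
two-strategy runs for the qualitative orderings; at those sizes the
largest cross-run SE is well under 0.01.

## What the simulations do and do not show

The generator *is* the model: stylized producers and enforcers, uniform
random matching, public error-free standings, and one strategy revision
per period. Passing tests therefore show that the implementation
reproduces the model's analytic structure (equilibrium fractions, basins,
stability selection) and its qualitative simulation findings (cooperation
with CE enforcers at the baseline, defection under the alternative
parameterization, PE failing to support producer cooperation, CE winning
the direct CE-vs-PE contest). They say nothing about real enforcement
institutions beyond what the model's assumptions license: no partner
choice, no counter-punishment by producers, no private or noisy
reputation, no enforcer organizations larger than one.

## A worked example

```{r example, eval = FALSE}
library(enforcegame)

params <- preset_params("baseline")
alpha_cooperation(params)                     # 0.2830189
suppressWarnings(stochastic_stability(params))$verdict   # "cooperation"

set.seed(1)
run <- run_markov_chain(params, set = strategy_set("CE2"), periods = 1e5)
run$shares
#        CP        DP        CE        DE
# 0.6339372 0.1163740 0.1970700 0.0526188
autoplot(run)
```

The time-average shares put the cooperating producer and the cooperation
enforcer far ahead of their defecting counterparts, and the realized
enforcer share (`CE + DE` $\approx 0.25$) sits near the analytic
cooperation-equilibrium fraction $\alpha^C \approx 0.28$.
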