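---
title: "Evolutionary stability of social norms under noisy indirect reciprocity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary stability of social norms under noisy indirect reciprocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socnorm)
library(dplyr)
```

## The model

socnorm analyzes indirect reciprocity in an infinite, well-mixed population
with *public, binary* reputations. Each round a random donor meets a random
recipient and plays a donation game: cooperation (C) costs the donor `c` and
delivers `b > c` to the recipient; defection (D) yields zero for both. A
*social norm* is a pair:

* an **action rule** `S(X, Y)`: the action a donor with reputation `X ∈ {G, B}`
  takes toward a recipient with reputation `Y`. Action rules are
  deterministic — a stochastic action rule cannot be evolutionarily stable,
  because except at ties one action is the strictly better response in each
  context;
* an **assessment rule** `R(X, Y, A)`: the probability that the donor is
  assigned a good reputation after taking action `A` in context `(X, Y)`.
  Assessment rules may be stochastic (entries anywhere in `[0, 1]`).

Both rules are *third order*: they may condition on the donor's reputation,
the recipient's reputation, and the action. Everyone observes the same
public reputation for each player, so a rare mutant can deviate only in its
action rule — the assessment machinery is shared.

Three noise sources enter ([`error_model()`]):

| rate | meaning | range |
|------|---------|-------|
| `mu` | an assigned reputation is flipped | `[0, 0.5)` |
| `mu_e` | an intended cooperation is executed as defection | `[0, 1)` |
| `eps_dc` | an executed defection is observed as cooperation | `[0, 1)` |

They are folded into the *effective* assessment rule in a fixed order
(`effective_assessment()`): the assessment error first
(`R → (1−mu) R + mu (1−R)`, every entry), then the perception error (the D
column is mixed toward the C column), then the implementation error (the C
column is mixed toward the perception-adjusted D column; defections are
implemented as intended, so the D column is untouched by `mu_e`). With only
`mu` active, every effective entry lies in `[mu, 1−mu]`, and the reputation
dynamics are ergodic whenever `mu > 0`. The package accepts `mu = 0` but
flags the result as non-ergodic; vanishing-error analyses should use the
symbolic CESS classification instead of `mu = 0` numerics. Mirror-image
perception errors (C seen as D) are not modeled, and `mu_e`/`eps_dc` apply
only between C and D: the punishment action, when present, is implemented
and perceived as prescribed and is subject to the assessment error only.
Punishment analyses therefore default to `mu` as the sole error source.

## Reputation dynamics

With everyone following the same norm, the good fraction `h(t)` obeys a
quadratic drift built from the prescribed effective assessments
`RS(X,Y) = R_eff(X, Y, S(X,Y))`. Setting the drift to zero gives
`c2 h² + c1 h + c0 = 0`; `stationary_state()` returns the coefficients and
the root

```
h* = (−c1 − sqrt(c1² − 4 c2 c0)) / (2 c2),    or   −c0/c1 when c2 = 0.
```

For `mu > 0` this root is unique in `[0, 1]` and dynamically stable; the
companion root lies outside the unit interval.

```{r}
stationary_state(norm_catalog("L7"), error_model(mu = 0.1))
```

**Numerical choices.** `|c2| < 1e−12` switches to the linear branch — below
that scale the quadratic formula only adds cancellation error. The root is
verified against the drift (`|drift(h*)| ≤ 1e−10`; a violation raises an
error rather than a warning). Exactly degenerate dynamics (`c2 = c1 = 0`,
possible only at `mu = 0`) are reported as an error: there is no isolated
fixed point to return.

## The value of a good reputation

The central quantity is `Δv`, the long-run difference in cumulative payoff
between a player currently labeled good and one labeled bad. In closed form
(`delta_v()`) it is the per-round payoff asymmetry — extra benefits received
and extra costs paid by a good player, averaged over the stationary
population — divided by `1 − ρ`, where
`ρ = h* RS(Δ,G) + (1−h*) RS(Δ,B)` measures how persistent the current label
is ("sticky" norms have larger `ρ` and hence larger `Δv`). Under
always-defect, payoffs decouple from reputations entirely and `Δv = 0`; for
any second-order norm with a discriminating action rule, `Δv = b` exactly,
at any error rates.

**Units convention.** `Δv` is reported in intended-cooperation units: `b`
and `c` enter the numerator unrescaled while the assessment table carries
all three errors. The fully-rescaled alternative (replacing `b, c` by
`(1−mu_e) b, (1−mu_e) c` everywhere) multiplies `Δv` and every stability
margin by the same positive factor `1 − mu_e` and flips no verdict; the
convention used here keeps the familiar closed forms (such as `Δv = b` for
Stern Judging) exact at all error rates, and is applied consistently in the
margins below, which compare against the plain instantaneous costs.

## Exact stability conditions

A norm is a strict ESS exactly when its prescribed action is the unique
best response in all four contexts. `ess_report()` evaluates, for every
context and alternative action `A'`,

```
margin = [R_eff(X,Y,S) − R_eff(X,Y,A')] · Δv − (ζ_S − ζ_A')
```

with instantaneous costs `ζ_C = c`, `ζ_D = 0`, `ζ_P = alpha`. All margins
positive ⇒ strict ESS; any margin within the tolerance (`1e−9`, absolute —
payoffs are of order `b`) of zero ⇒ knife-edge, reported as such rather
than forced into a verdict, since at ties neutral drift is possible. With
punishment, an action is the best response only if it beats *both*
alternatives.

Two consequences worth knowing:

* **Always-defect is always a strict ESS**: `Δv = 0`, so each cooperation
  margin is exactly `c > 0`.
* **Simple Standing (L3) and Stern Judging (L6) share one condition**:
  `b/c > 1 / ((1−2mu)(1−mu_e)(1−eps_dc))` (`l3_l6_threshold()`), even
  though L6 punishes deviations harder (see `payoff_gap_table()`). Among
  the leading eight, L6's `Δv` never exceeds those of L4, L7, L8 — Staying
  (L7) has the widest stable region.

## Cooperative ESS in the vanishing-error limit

A CESS is an ESS whose cooperation rate tends to one as errors vanish.
`classify_cess()` evaluates the exact limit conditions symbolically at the
intended assessment values (not by small-`mu` numerics — the limit
conditions are known exactly, and small-`mu` evaluation is used as an
independent test instead). The population must settle in the all-good
state (`R(G,G,S(G,G)) = 1`, `R(G,B,S(G,B)) + R(B,G,S(B,G)) > 1`,
`S(G,G) = C`), and the remaining margins split into two branches by how a
bad donor redeems itself toward a good recipient: through cooperation
(branch alive for `b > c`) or through justified defection (`b > 2c`). The
`(B,B)` assessment is unconstrained, but given it, the action `S(B,B)` is
uniquely forced — except at measure-zero parameter points where the forcing
condition is an equality, which are classified as knife-edge, not CESS (all
CESS inequalities are strict; `b = c` and `b = 2c` are therefore not CESS).

Since the two labels are interchangeable, `classify_cess()` also tests the
G/B-mirrored norm. The exhaustive scan `enumerate_deterministic_cess()`
counts the canonical labeling only — otherwise every family would appear
twice, once mirrored:

```{r}
nrow(enumerate_deterministic_cess(game_params(1.5, 1)))  # the leading eight
count(enumerate_deterministic_cess(game_params(3, 1)), branch)
```

`cess_branch_threshold()` locates the critical ratio by bisection over the
enumeration (it is not hard-coded): the defect branch switches on at
`b/c = 2.000000`.

With punishment (`cess_with_punishment()`), the admissible action rules
fall into six classes by `(S(G,B), S(B,G))` — a good donor must not
cooperate with a bad recipient, giving `2 × 3` pairs — each with a closed
form for `Δv` whose denominator is always the assessment of the redeeming
action, `R(B, G, S(B,G))`.

## Equalizer norms

A norm satisfying `[R_eff(X,Y,C) − R_eff(X,Y,D)] Δv = c` in *all four*
contexts makes cooperation and defection payoff-equivalent everywhere: any
mutant action rule earns exactly the resident payoff. Such equalizers are
Nash equilibria but never strict (neutral invasion is free). For
second-order discriminating norms, `Δv = b`, so equalization pins the
intended C-versus-D assessment gap at `c / ((1 − 2mu) b)` in both recipient
contexts — the assessment error shrinks intended gaps by `1 − 2mu`, so the
intended gap must be inflated by exactly that factor for the effective gap
to come out at `c/b`. `make_second_order_equalizer()` constructs the family
from two free base levels; bases `(1, 1)` give Generous Scoring and
`(1, gap)` the cautious variant that keeps bad recipients' images low.

```{r}
pe <- game_params(1, 0.1); ee <- error_model(mu = 0.01)
equalizer_check(norm_catalog("GSCO", pe, ee), pe, ee)$equalizer
equalizer_demo() %>% select(resident, mutant, gap)
```

## The oracles

Every analytic result has an independently-coded cross-check:

* `finite_horizon_gap()` iterates the one-step value recursion from a zero
  gap; it converges geometrically with ratio `(1 + ρ)/2` and its limit must
  equal the closed-form `Δv` (the package tests demand `1e−9` agreement on
  a 200-norm random panel).
* `brute_force_strict_nash()` enumerates all 15 (or 80, with punishment)
  deviating deterministic action rules and computes invasion payoffs
  directly. The mutant payoff model is the one forced by public assessment:
  the mutant's reputation evolves only on its donor rounds under the shared
  effective assessment, giving the linear fixed point
  `h_m = g_B / (1 − g_G + g_B)` with
  `g_X = h* R_eff(X,G,S'(X,G)) + (1−h*) R_eff(X,B,S'(X,B))`; residents
  react to the mutant only through its current public label. Per-round
  payoffs put the player in the donor and recipient role with probability
  1/2 each; cooperation benefits and costs carry the factor `1 − mu_e`
  (perception errors touch assessments only, not payoffs). Norms with any
  margin or payoff gap inside the knife-edge band (`1e−6`) are excluded
  from equivalence testing.
* `simulate_population()` runs the finite-population process itself
  (Rcpp), drawing donor/recipient pairs, implementing and perceiving
  actions with explicit `mu_e`/`eps_dc` events, and redrawing the donor's
  public label from the `mu`-effective assessment. It reports time-averaged
  good fraction and cooperation rate with batch-means standard errors
  (100 batches, first 10% of rounds discarded as burn-in).

## What the random-norm generator emulates

`sample_random_norm()` draws action entries uniformly over the action set
and assessment entries uniformly on `[0, 1]` (or `{0, 1}` for deterministic
norms). The test panels pair such norms with assessment errors drawn
uniformly from `mu ∈ [0.01, 0.3]` — safely inside the ergodic regime and
spanning mild to severe noise — and games with `b ∈ (1, 2)`,
`c ∈ (0.1, 0.9)`. This exercises the full stochastic norm space uniformly;
it does not emulate empirically observed norm distributions (real
populations concentrate near a few focal norms), nor private or noisy
*disagreeing* assessments, so passing tests certify the mathematics of the
public-assessment model, not behavioral realism.

Default problem sizes: the deterministic enumeration is exhaustive (4096
candidates, seconds); property panels use 200 random norms; region scans
use a 50×50 grid; simulations use 500 players and 10⁶ rounds, which puts
3 standard errors of the good fraction at about ±0.003 — tight enough to
detect any systematic disagreement with the analytic fixed point.

## Known limitations

* Binary, public reputations only; private-assessment disagreement and
  richer reputation scales are out of scope.
* Monomorphic residents versus a single rare mutant: no polymorphic
  coexistence, no replicator or Moran dynamics, no finite-population
  evolutionary process beyond the validation simulator.
* Knife-edge parameter combinations are reported, never resolved: at exact
  ties the model genuinely does not determine a best response.
* The symmetric perception error (C seen as D) and error models for the
  punishment action are not formalized here; punishment results are exact
  for assessment noise only.
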