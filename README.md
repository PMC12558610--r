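# socnorm

Exact evolutionary-stability analysis of social norms for indirect
reciprocity with public, binary reputations and noise.

## The problem

In indirect reciprocity, people help others to build a reputation that
earns them help later. Whether that works depends on the *social norm* in
force: an **action rule** `S(X, Y)` saying how a donor with reputation
`X ∈ {G, B}` treats a recipient with reputation `Y`, and an **assessment
rule** `R(X, Y, A)` giving the probability the donor is judged good after
taking action `A`. socnorm is for researchers in evolutionary game theory
who want *exact* answers about such norms — possibly stochastic, possibly
noisy, possibly with costly punishment — rather than simulation estimates:

- the stationary fraction of good players, from the quadratic drift
  `ḣ = h²RS(G,G) + h(1−h)[RS(G,B)+RS(B,G)] + (1−h)²RS(B,B) − h`;
- the long-term value of a good reputation,

  `Δv = ( b χ̄_C(h*,Δ) − c χ̄_C(Δ,h*) ) / ( 1 − h* RS(Δ,G) − (1−h*) RS(Δ,B) )`;

- strict-ESS verdicts from the best-response margins
  `[R̃(X,Y,S) − R̃(X,Y,A')] Δv − (ζ_S − ζ_{A'})` in every context;
- the complete deterministic cooperative-ESS catalog (the leading eight for
  `b > c`, the secondary sixteen for `b > 2c`), by exhaustive enumeration;
- *equalizer* norms that pin every mutant's payoff to the residents';
- three error types: assessment noise `μ`, implementation noise `μ_e`,
  perception noise `ε_DC`.

Every analytic verdict has an independently-coded oracle in the package:
a finite-horizon value recursion for `Δv`, brute-force invasion payoffs
over all deviating action rules, and an Rcpp finite-population simulator.

## A worked example

Is Stern Judging (L6) evolutionarily stable in a game with benefit 1 and
cost 0.8 when 5% of reputation assignments are erroneous?

```r
library(socnorm)

norm_catalog("L6")
#> <social_norm> "L6"
#>    S R(C) R(D)
#> GG C    1    0
#> GB D    0    1
#> BG C    1    0
#> BB D    0    1

ess_report(norm_catalog("L6"), game_params(1, 0.8), error_model(mu = 0.05))
#> <ess_report> [L6] strict ESS (delta_v = 1, h* = 0.95, min margin 0.1 in GG)
#> # A tibble: 4 × 5
#>   context prescribed alternative assessment_gain margin
#>   <chr>   <chr>      <chr>                 <dbl>  <dbl>
#> 1 GG      C          D                       0.9 0.1000
#> 2 GB      D          C                       0.9 1.7
#> 3 BG      C          D                       0.9 0.1000
#> 4 BB      D          C                       0.9 1.7
```

At `μ = 0.05`, 95% of the population is good in the stationary state
(`h* = 0.95`), and a good reputation is worth exactly one benefit unit
(`Δv = b = 1`, as for every second-order discriminating norm). The binding
margin is cooperation with good recipients: the assessment gain `0.9 = 1−2μ`
times `Δv` exceeds the cost 0.8 by `0.1`, so every deviation loses — a
strict ESS. The closed-form boundary agrees:

```r
l3_l6_threshold(error_model(mu = 0.05))   # critical b/c ratio
#> [1] 1.111111                             # b/c = 1.25 exceeds it
```

and so does the brute-force invasion oracle over all 15 deviating action
rules:

```r
glance(brute_force_strict_nash(norm_catalog("L6"), game_params(1, 0.8),
                               error_model(mu = 0.05)))
#> # A tibble: 1 × 4
#>   verdict n_mutants min_gap mean_gap
#>   <chr>       <int>   <dbl>    <dbl>
#> 1 strict         15 0.00223    0.048
```

Doubling the benefit-cost ratio unlocks the second family of cooperative
norms:

```r
dplyr::count(enumerate_deterministic_cess(game_params(3, 1)),
             branch, condition)
#> # A tibble: 2 × 3
#>   branch condition     n
#>   <chr>  <chr>     <int>
#> 1 coop   b>c           8
#> 2 defect b>2c         16
```

Scans, payoff-gap panels and equalizer demonstrations return tibbles with
`autoplot()` methods (`ess_region_scan()`, `payoff_gap_table()`,
`equalizer_demo()`); fitted/report objects have broom-style `tidy()` and
`glance()` methods. A thin command-line driver with the same capabilities
ships in `inst/cli/socnorm`. The methods vignette
(`vignettes/social-norm-stability.Rmd`) documents the model, conventions,
and numerical choices.

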