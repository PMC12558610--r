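# Independent brute-force verification layer.
#
# Nothing here reuses the closed-form solutions of the stability module:
# the value gap is obtained by iterating the finite-horizon payoff
# recursion, ESS verdicts by enumerating every deviating action rule and
# computing resident and mutant payoffs directly, and the stationary
# reputation frequencies by Monte Carlo simulation of a finite population.

#' Finite-horizon reputation value recursion
#'
#' Iterates the one-step recursion for the difference in cumulative payoff
#' between a currently-good and a currently-bad player over horizons
#' T = 1, 2, ...: each round contributes the per-round payoff asymmetry with
#' probability 1/2, and with the complementary weight the player carries its
#' (possibly re-assessed) reputation into the remaining horizon. The gap
#' converges geometrically with ratio `(1 + rho) / 2`, where `rho` is the
#' reputation persistence; its limit is the reputation value gap that
#' [delta_v()] computes in closed form.
#'
#' @param norm A [social_norm()].
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @param horizon If given, iterate exactly this many rounds and skip the
#'   convergence check.
#' @param tol Convergence tolerance on successive gaps.
#' @param max_iter Iteration cap; non-convergence (possible only at
#'   `mu = 0`) raises an error.
#' @param state Optional precomputed [stationary_state()].
#' @return A list with `gap` (the converged or horizon-T value), `gap_trace`
#'   (first 10 horizons), `iterations`, `converged`, and `rho`.
#' @export
finite_horizon_gap <- function(norm, params, err = error_model(),
                               horizon = NULL, tol = 1e-12, max_iter = 1e6,
                               state = NULL) {
  stopifnot(inherits(norm, "social_norm"), inherits(params, "game_params"))
  actions <- norm_actions(norm)
  state <- state %||% stationary_state(norm, err)
  h <- state$h_star
  rs <- state$rs
  s <- as.character(norm$action)
  names(s) <- CONTEXTS
  chi <- function(a, ctx) as.numeric(s[[ctx]] == a)
  per_round <- params$b * (h * (chi("C", "GG") - chi("C", "GB")) +
                             (1 - h) * (chi("C", "BG") - chi("C", "BB"))) -
    params$c * (h * (chi("C", "GG") - chi("C", "BG")) +
                  (1 - h) * (chi("C", "GB") - chi("C", "BB")))
  if ("P" %in% actions) {
    per_round <- per_round -
      params$beta * (h * (chi("P", "GG") - chi("P", "GB")) +
                       (1 - h) * (chi("P", "BG") - chi("P", "BB"))) -
      params$alpha * (h * (chi("P", "GG") - chi("P", "BG")) +
                        (1 - h) * (chi("P", "GB") - chi("P", "BB")))
  }
  rho <- h * (rs[["GG"]] - rs[["BG"]]) + (1 - h) * (rs[["GB"]] - rs[["BB"]])
  gap <- 0
  trace <- numeric(0)
  n_iter <- if (is.null(horizon)) max_iter else horizon
  converged <- FALSE
  iterations <- 0
  while (iterations < n_iter) {
    new_gap <- (per_round + gap * (1 + rho)) / 2
    iterations <- iterations + 1
    if (iterations <= 10) trace[iterations] <- new_gap
    if (is.null(horizon) && abs(new_gap - gap) < tol) {
      gap <- new_gap
      converged <- TRUE
      break
    }
    gap <- new_gap
  }
  if (is.null(horizon) && !converged) {
    stop("finite-horizon recursion failed to converge within ", max_iter,
         " iterations (degenerate mu = 0 dynamics)", call. = FALSE)
  }
  list(gap = gap, gap_trace = trace, iterations = iterations,
       converged = converged || !is.null(horizon), rho = rho)
}

#' Stationary reputation of a rare mutant
#'
#' A rare mutant shares the resident assessment rule (reputations are
#' public and externally updated) but follows its own action rule. Its
#' reputation changes only when it acts as a donor, meeting good residents
#' with probability `h*`. Writing `g_X` for the probability that an
#' X-reputation mutant donor is assessed good, the stationary good
#' probability solves the linear fixed point
#' `h_m = h_m g_G + (1 - h_m) g_B`, i.e. `h_m = g_B / (1 - g_G + g_B)`.
#'
#' @param resident The resident [social_norm()].
#' @param mutant_actions An [action_rule()] over the resident's action set.
#' @param err An [error_model()].
#' @param state Optional precomputed resident [stationary_state()].
#' @return The mutant's stationary good-reputation probability.
#' @export
mutant_stationary_reputation <- function(resident, mutant_actions,
                                         err = error_model(), state = NULL) {
  stopifnot(inherits(resident, "social_norm"),
            inherits(mutant_actions, "action_rule"))
  state <- state %||% stationary_state(resident, err)
  h <- state$h_star
  r_eff <- effective_assessment(resident, err)
  sm <- as.character(mutant_actions)
  names(sm) <- CONTEXTS
  g <- function(x) { # x: mutant's own reputation, "G" or "B"
    h * r_eff[[paste0(x, "G.", sm[[paste0(x, "G")]])]] +
      (1 - h) * r_eff[[paste0(x, "B.", sm[[paste0(x, "B")]])]]
  }
  gG <- g("G"); gB <- g("B")
  denom <- 1 - gG + gB
  if (abs(denom) < 1e-14) {
    stop("mutant reputation chain degenerate (possible only at mu = 0)",
         call. = FALSE)
  }
  gB / denom
}

payoff_against <- function(donor_rule, donor_h, recipient_h, params, err,
                           actions) {
  # expected per-round flows when a donor with reputation ~ donor_h and rule
  # donor_rule meets a recipient with reputation ~ recipient_h
  s <- as.character(donor_rule)
  names(s) <- CONTEXTS
  p_ctx <- c(GG = donor_h * recipient_h, GB = donor_h * (1 - recipient_h),
             BG = (1 - donor_h) * recipient_h,
             BB = (1 - donor_h) * (1 - recipient_h))
  p_act <- vapply(actions, function(a) sum(p_ctx[s == a]), numeric(1))
  eff <- effective_game_params(params, err)
  list(benefit_given = eff$b * p_act[["C"]],
       cost_paid = eff$c * p_act[["C"]] +
         (if ("P" %in% actions) params$alpha * p_act[["P"]] else 0),
       harm_given = if ("P" %in% actions) params$beta * p_act[["P"]] else 0)
}

#' Invasion payoffs of a mutant action rule
#'
#' Expected per-round payoffs of residents and of a vanishingly rare mutant
#' (a mutant never meets another mutant). Each round a player is donor or
#' recipient with probability 1/2. Benefits and costs of cooperation carry
#' the implementation-error factor `1 - mu_e` (an intended cooperation is
#' executed with that probability); punishment is executed as intended.
#'
#' @inheritParams mutant_stationary_reputation
#' @param params A [game_params()].
#' @return A one-row tibble with `h_mut`, `pi_res`, `pi_mut`, and
#'   `gap = pi_res - pi_mut`.
#' @export
invasion_payoffs <- function(resident, mutant_actions, params,
                             err = error_model(), state = NULL) {
  actions <- norm_actions(resident)
  if (!identical(attr(mutant_actions, "actions"), actions)) {
    stop("mutant action rule must use the resident's action set",
         call. = FALSE)
  }
  if ("P" %in% actions && is.null(params$alpha)) {
    stop("punishment action present: game parameters need alpha and beta",
         call. = FALSE)
  }
  state <- state %||% stationary_state(resident, err)
  h <- state$h_star
  h_m <- mutant_stationary_reputation(resident, mutant_actions, err,
                                      state = state)
  # resident donors facing the focal player's reputation distribution
  res_to_res <- payoff_against(resident$action, h, h, params, err, actions)
  res_to_mut <- payoff_against(resident$action, h, h_m, params, err, actions)
  mut_to_res <- payoff_against(mutant_actions, h_m, h, params, err, actions)
  pi_res <- (res_to_res$benefit_given - res_to_res$harm_given -
               res_to_res$cost_paid) / 2
  pi_mut <- (res_to_mut$benefit_given - res_to_mut$harm_given -
               mut_to_res$cost_paid) / 2
  tibble::tibble(h_mut = h_m, pi_res = pi_res, pi_mut = pi_mut,
                 gap = pi_res - pi_mut)
}

#' All deterministic action rules
#'
#' @param actions Active action set.
#' @param exclude Optional [action_rule()] to drop (e.g. the resident's).
#' @return A list of `action_rule` objects (16 for `{C, D}`, 81 for
#'   `{C, D, P}`; one fewer with `exclude`).
#' @export
enumerate_action_rules <- function(actions = c("C", "D"), exclude = NULL) {
  grid <- expand.grid(rep(list(actions), 4), stringsAsFactors = FALSE)
  rules <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.character(grid[i, ])
    action_rule(s[1], s[2], s[3], s[4], actions = actions)
  })
  if (!is.null(exclude)) {
    keep <- !vapply(rules, function(r) {
      all(as.character(r) == as.character(exclude))
    }, logical(1))
    rules <- rules[keep]
  }
  rules
}

rule_label <- function(rule) paste(as.character(rule), collapse = "")

#' Brute-force strict-Nash verdict
#'
#' Enumerates every deterministic action rule other than the resident's (15
#' in the two-action game, 80 with punishment), computes each mutant's
#' invasion payoff, and declares the resident a strict Nash equilibrium iff
#' every payoff gap is positive. Gaps within `tol` of zero give a
#' knife-edge verdict. This is the independent check of the analytic ESS
#' margins of [ess_report()].
#'
#' @param resident The resident [social_norm()].
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @param tol Gap tolerance for strictness.
#' @return A `strict_nash` object with `verdict` (`"strict"`,
#'   `"not strict"`, `"knife-edge"`), the per-mutant `gaps` tibble, and
#'   `n_mutants`.
#' @export
brute_force_strict_nash <- function(resident, params, err = error_model(),
                                    tol = 1e-9) {
  state <- stationary_state(resident, err)
  mutants <- enumerate_action_rules(norm_actions(resident),
                                    exclude = resident$action)
  gaps <- purrr::map_dfr(mutants, function(m) {
    dplyr::mutate(invasion_payoffs(resident, m, params, err, state = state),
                  mutant = rule_label(m), .before = 1)
  })
  verdict <- if (any(abs(gaps$gap) <= tol)) "knife-edge"
             else if (all(gaps$gap > tol)) "strict"
             else "not strict"
  structure(list(verdict = verdict, gaps = gaps, n_mutants = nrow(gaps),
                 tol = tol, norm_name = resident$name),
            class = "strict_nash")
}

#' @export
print.strict_nash <- function(x, ...) {
  cat(sprintf("<strict_nash>%s %s over %d mutants (min gap %.3g)\n",
              if (!is.null(x$norm_name)) paste0(" [", x$norm_name, "]") else "",
              x$verdict, x$n_mutants, min(x$gaps$gap)))
  invisible(x)
}

#' @export
tidy.strict_nash <- function(x, ...) x$gaps

#' @export
glance.strict_nash <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, n_mutants = x$n_mutants,
                 min_gap = min(x$gaps$gap), mean_gap = mean(x$gaps$gap))
}

#' Finite-population Monte Carlo simulation
#'
#' Simulates the reputation process in a finite population: each round a
#' random donor meets a random recipient, acts according to the norm
#' (intended cooperation failing with probability `mu_e`), the executed
#' action is perceived (an executed defection reads as cooperation with
#' probability `eps_dc`), and the donor's public reputation is redrawn from
#' the mu-effective assessment of the perceived action. Reports the
#' time-averaged good fraction and realized cooperation rate with
#' batch-means standard errors; the first `burn_in` fraction of rounds is
#' discarded.
#'
#' @param norm A [social_norm()].
#' @param err An [error_model()] with `mu > 0`.
#' @param n_players Population size (>= 2).
#' @param n_rounds Number of donation games simulated.
#' @param seed Optional integer seed (applied locally).
#' @param burn_in Fraction of rounds discarded before averaging.
#' @param n_batches Number of batches for the standard errors.
#' @return A one-row tibble: `good_fraction`, `good_se`, `coop_rate`,
#'   `coop_se`, `n_players`, `n_rounds`.
#' @export
simulate_population <- function(norm, err = error_model(mu = 0.01),
                                n_players = 500, n_rounds = 1e6,
                                seed = NULL, burn_in = 0.1, n_batches = 100) {
  stopifnot(inherits(norm, "social_norm"), n_players >= 2)
  if (err$mu <= 0) {
    stop("simulation requires mu > 0 for ergodic reputation dynamics",
         call. = FALSE)
  }
  actions <- norm_actions(norm)
  # mu folded analytically; mu_e and eps_dc are simulated event-by-event
  r_mu <- effective_assessment(norm, error_model(mu = err$mu))
  r_mat <- matrix(as.numeric(r_mu), nrow = 4, byrow = TRUE,
                  dimnames = list(CONTEXTS, actions))
  act_idx <- match(as.character(norm$action), actions) - 1L
  run <- function() {
    mc_population_cpp(act_idx, r_mat, err$mu_e, err$eps_dc,
                      as.integer(n_players), as.numeric(n_rounds),
                      as.numeric(floor(n_rounds * burn_in)),
                      as.integer(n_batches))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(good_fraction = res$good_fraction, good_se = res$good_se,
                 coop_rate = res$coop_rate, coop_se = res$coop_se,
                 n_players = n_players, n_rounds = n_rounds)
}
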