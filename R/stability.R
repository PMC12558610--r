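# The reputation value gap and exact evolutionary-stability conditions.
#
# The central quantity is delta_v, the long-run payoff advantage of holding
# a good rather than a bad reputation. A norm is a strict ESS exactly when,
# in every context, the prescribed action beats each alternative: the change
# in assessment times delta_v must outweigh the change in instantaneous cost.
#
# Units convention: delta_v is reported in intended-cooperation units (the
# benefit b and cost c enter unrescaled, while the assessment table carries
# all three error types). Margins therefore compare against the plain
# instantaneous costs (c for C, 0 for D, alpha for P). Rescaling both b, c
# and the cost side by (1 - mu_e) multiplies every margin by the same
# positive factor and changes no verdict; the convention used here keeps the
# familiar closed forms (e.g. delta_v = b for second-order discriminators at
# any error rates) exact.

chi_indicator <- function(norm, a) {
  s <- as.character(norm$action)
  stats::setNames(as.numeric(s == a), CONTEXTS)
}

instant_cost <- function(params, actions) {
  z <- c(C = params$c, D = 0,
         P = if ("P" %in% actions) params$alpha else NA_real_)
  z[actions]
}

#' Long-term value of a good reputation
#'
#' Computes `delta_v`, the limit of the difference in cumulative expected
#' payoff between a currently-good and a currently-bad player, in closed
#' form: the per-round payoff asymmetries (extra benefit received, extra
#' cost paid, and with punishment the extra harm received and punishment
#' cost paid), divided by `1 - rho`, where
#' `rho = h* RS(delta, G) + (1 - h*) RS(delta, B)` measures how persistent
#' the initial reputation is under the norm.
#'
#' @param norm A [social_norm()].
#' @param params A [game_params()] (with `alpha`, `beta` when the action
#'   set includes P).
#' @param err An [error_model()].
#' @param state Optional precomputed [stationary_state()].
#' @return A `rep_value_gap` object with fields `delta_v`, `rho`, the four
#'   numerator terms, and `h_star`.
#' @examples
#' delta_v(norm_catalog("L7"), game_params(1, 0.8), error_model(mu = 0.1))
#' @export
delta_v <- function(norm, params, err = error_model(), state = NULL) {
  stopifnot(inherits(norm, "social_norm"), inherits(params, "game_params"))
  actions <- norm_actions(norm)
  if ("P" %in% actions && is.null(params$alpha)) {
    stop("punishment action present: game parameters need alpha and beta",
         call. = FALSE)
  }
  state <- state %||% stationary_state(norm, err)
  h <- state$h_star
  rs <- state$rs
  chiC <- chi_indicator(norm, "C")
  # donor-side and recipient-side averaged asymmetries
  bar_row <- function(chi) { # chi_bar(h*, delta): recipient contrast
    h * (chi[["GG"]] - chi[["GB"]]) + (1 - h) * (chi[["BG"]] - chi[["BB"]])
  }
  bar_col <- function(chi) { # chi_bar(delta, h*): donor contrast
    h * (chi[["GG"]] - chi[["BG"]]) + (1 - h) * (chi[["GB"]] - chi[["BB"]])
  }
  num_benefit <- params$b * bar_row(chiC)
  num_cost <- params$c * bar_col(chiC)
  num_pun_recv <- 0
  num_pun_paid <- 0
  if ("P" %in% actions) {
    chiP <- chi_indicator(norm, "P")
    num_pun_recv <- params$beta * bar_row(chiP)
    num_pun_paid <- params$alpha * bar_col(chiP)
  }
  rho <- h * (rs[["GG"]] - rs[["BG"]]) + (1 - h) * (rs[["GB"]] - rs[["BB"]])
  if (1 - rho < 1e-14) {
    stop("reputation persistence rho >= 1: delta_v diverges ",
         "(possible only at mu = 0)", call. = FALSE)
  }
  dv <- (num_benefit - num_cost - num_pun_recv - num_pun_paid) / (1 - rho)
  structure(list(delta_v = dv, rho = rho, h_star = h,
                 numerator_benefit = num_benefit,
                 numerator_cost = num_cost,
                 numerator_punish_received = num_pun_recv,
                 numerator_punish_paid = num_pun_paid,
                 state = state),
            class = "rep_value_gap")
}

#' @export
print.rep_value_gap <- function(x, ...) {
  cat(sprintf("<rep_value_gap> delta_v = %.6g (rho = %.6g, h* = %.6g)\n",
              x$delta_v, x$rho, x$h_star))
  invisible(x)
}

#' @export
tidy.rep_value_gap <- function(x, ...) {
  tibble::tibble(
    term = c("benefit", "cost", "punish_received", "punish_paid"),
    value = c(x$numerator_benefit, x$numerator_cost,
              x$numerator_punish_received, x$numerator_punish_paid))
}

#' @export
glance.rep_value_gap <- function(x, ...) {
  tibble::tibble(delta_v = x$delta_v, rho = x$rho, h_star = x$h_star)
}

#' Closed-form delta_v for the leading eight
#'
#' Redundant cross-check of [delta_v()]: evaluates the per-norm closed forms
#' of the reputation value gap for L1-L8 under all three error types, e.g.
#' `b` for L3 and L6, `b / (1 - (1 - h*) (1 - 2 mu))` for L7.
#'
#' @param name One of `"L1"` ... `"L8"`.
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @param state Optional precomputed [stationary_state()] of that norm.
#' @return The closed-form `delta_v` (a number).
#' @export
leading_eight_delta_v <- function(name, params, err = error_model(),
                                  state = NULL) {
  if (!name %in% paste0("L", 1:8)) {
    stop("`name` must be one of L1..L8", call. = FALSE)
  }
  state <- state %||% stationary_state(norm_catalog(name), err)
  h <- state$h_star
  b <- params$b; cc <- params$c
  mu <- err$mu; mue <- err$mu_e; eps <- err$eps_dc
  k <- (1 - h) * (1 - 2 * mu)
  switch(name,
    L1 = (b * h + cc * (1 - h)) / (1 - k * mue * (1 - eps)),
    L2 = (b * h + cc * (1 - h)) / (1 - k * (mue - eps - mue * eps)),
    L3 = b,
    L4 = b / (1 - k * eps),
    L5 = b / (1 + k * eps),
    L6 = b,
    L7 = b / (1 - k),
    L8 = b / (1 - k * (1 - eps)))
}

#' Exact ESS evaluation of a norm
#'
#' For every context and every alternative action `A'` to the prescribed
#' action `S`, computes the best-response margin
#' `[R_eff(X,Y,S) - R_eff(X,Y,A')] delta_v - (zeta_S - zeta_A')`,
#' where `zeta` is the instantaneous cost of an action (`c` for C, 0 for D,
#' `alpha` for P). The norm is a strict ESS iff every margin is positive;
#' margins within `tol` of zero are knife-edge cases, which are reported
#' rather than classified (at such points two actions tie and neutral drift
#' is possible).
#'
#' @param norm A [social_norm()].
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @param tol Strictness tolerance for the margins (absolute; payoffs are
#'   of order `b`).
#' @param state Optional precomputed [stationary_state()].
#' @return An `ess_report` with fields `verdict` (`"strict ESS"`,
#'   `"not ESS"` or `"knife-edge"`), `margins` (a tibble with one row per
#'   context/alternative), `binding_context`, `delta_v` and `h_star`.
#' @examples
#' ess_report(norm_catalog("L6"), game_params(1, 0.8), error_model(mu = 0.05))
#' @export
ess_report <- function(norm, params, err = error_model(), tol = 1e-9,
                       state = NULL) {
  actions <- norm_actions(norm)
  state <- state %||% stationary_state(norm, err)
  dv <- delta_v(norm, params, err, state = state)
  r_eff <- effective_assessment(norm, err)
  zeta <- instant_cost(params, actions)
  s <- as.character(norm$action)
  names(s) <- CONTEXTS
  rows <- purrr::map_dfr(CONTEXTS, function(ctx) {
    prescribed <- s[[ctx]]
    alts <- setdiff(actions, prescribed)
    purrr::map_dfr(alts, function(a) {
      dR <- r_eff[[paste(ctx, prescribed, sep = ".")]] -
        r_eff[[paste(ctx, a, sep = ".")]]
      tibble::tibble(
        context = ctx, prescribed = prescribed, alternative = a,
        assessment_gain = dR,
        margin = dR * dv$delta_v - (zeta[[prescribed]] - zeta[[a]]))
    })
  })
  verdict <- if (any(abs(rows$margin) <= tol)) "knife-edge"
             else if (all(rows$margin > tol)) "strict ESS"
             else "not ESS"
  structure(list(verdict = verdict, margins = rows,
                 binding_context = rows$context[which.min(rows$margin)],
                 delta_v = dv$delta_v, h_star = state$h_star,
                 tol = tol, norm_name = norm$name),
            class = "ess_report")
}

#' @export
print.ess_report <- function(x, ...) {
  cat(sprintf("<ess_report>%s %s (delta_v = %.6g, h* = %.6g, min margin %.3g in %s)\n",
              if (!is.null(x$norm_name)) paste0(" [", x$norm_name, "]") else "",
              x$verdict, x$delta_v, x$h_star, min(x$margins$margin),
              x$binding_context))
  print(x$margins)
  invisible(x)
}

#' @rdname ess_report
#' @return For `is_ess()`: `TRUE` iff the verdict is `"strict ESS"`, with
#'   the verdict string as attribute `verdict`.
#' @export
is_ess <- function(norm, params, err = error_model(), tol = 1e-9,
                   state = NULL) {
  rep <- ess_report(norm, params, err, tol = tol, state = state)
  structure(rep$verdict == "strict ESS", verdict = rep$verdict)
}

#' @export
tidy.ess_report <- function(x, ...) x$margins

#' @export
glance.ess_report <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, delta_v = x$delta_v,
                 h_star = x$h_star, min_margin = min(x$margins$margin),
                 binding_context = x$binding_context)
}

#' Critical benefit-cost ratio for Simple Standing and Stern Judging
#'
#' L3 and L6 share the ESS condition
#' `b / c > 1 / ((1 - 2 mu) (1 - mu_e) (1 - eps_dc))`; this returns the
#' right-hand side. As any error rate approaches its upper bound the
#' threshold diverges and cooperation becomes impossible to stabilize.
#'
#' @param err An [error_model()].
#' @return The critical `b/c` ratio.
#' @export
l3_l6_threshold <- function(err = error_model()) {
  f <- (1 - 2 * err$mu) * (1 - err$mu_e) * (1 - err$eps_dc)
  if (f <= 0) {
    stop("threshold diverges: (1-2mu)(1-mu_e)(1-eps_dc) <= 0", call. = FALSE)
  }
  1 / f
}

#' Equalizer check
#'
#' A norm is an equalizer when `[R_eff(X,Y,C) - R_eff(X,Y,D)] delta_v = c`
#' holds in all four contexts: cooperation and defection then yield
#' identical expected payoffs everywhere, so every mutant action rule earns
#' exactly the resident payoff. Equalizers are Nash equilibria but not ESS
#' (they admit neutral invasion).
#'
#' @param norm A [social_norm()] over the two-action set.
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @param tol Residual tolerance.
#' @return A list with `equalizer` (logical), `residuals` (tibble, one row
#'   per context) and `delta_v`.
#' @export
equalizer_check <- function(norm, params, err = error_model(), tol = 1e-9) {
  if (!identical(norm_actions(norm), c("C", "D"))) {
    stop("equalizer analysis is defined for the {C, D} action set",
         call. = FALSE)
  }
  dv <- delta_v(norm, params, err)
  r_eff <- effective_assessment(norm, err)
  residuals <- purrr::map_dfr(CONTEXTS, function(ctx) {
    dR <- r_eff[[paste0(ctx, ".C")]] - r_eff[[paste0(ctx, ".D")]]
    tibble::tibble(context = ctx,
                   residual = dR * dv$delta_v - params$c)
  })
  list(equalizer = all(abs(residuals$residual) <= tol),
       residuals = residuals, delta_v = dv$delta_v)
}

#' Construct a second-order equalizer norm
#'
#' Builds a discriminating second-order norm (cooperate with good
#' recipients, defect against bad ones) whose C-versus-D assessment gap in
#' both recipient contexts equals `c / ((1 - 2 mu) b)` (see
#' [equalizer_gap()]), so that [equalizer_check()] passes exactly. The two
#' free base levels set `R(*, G, C)` and `R(*, B, C)`; the corresponding D
#' entries sit one gap below. Base levels `(1, 1)` give Generous Scoring;
#' `(1, gap)` gives Cautious Scoring.
#'
#' @param params A [game_params()].
#' @param err An [error_model()] (only `mu` enters).
#' @param base_good,base_bad Assessment after cooperation with a good / bad
#'   recipient; both defaults 1.
#' @return A `social_norm` that is an equalizer.
#' @examples
#' eq <- make_second_order_equalizer(game_params(1, 0.1), error_model(0.01))
#' equalizer_check(eq, game_params(1, 0.1), error_model(0.01))$equalizer
#' @export
make_second_order_equalizer <- function(params, err = error_model(),
                                        base_good = 1, base_bad = 1) {
  gap <- equalizer_gap(params, err)
  rc <- c(base_good, base_bad, base_good, base_bad)
  rd <- rc - gap
  if (any(rc > 1) || any(rd < 0)) {
    stop("base levels infeasible: entries must keep both R(C) <= 1 and ",
         "R(C) - gap >= 0 with gap = ", format(gap), call. = FALSE)
  }
  social_norm(action_rule("C", "D", "C", "D"),
              assessment_from_vectors(RC = rc, RD = rd),
              name = "second-order equalizer")
}
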