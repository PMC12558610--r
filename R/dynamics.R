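# Stationary reputation dynamics of a homogeneous resident population.
#
# In a large well-mixed population where everyone follows the same norm, the
# fraction h(t) of players currently labeled good follows a quadratic drift:
# each interaction replaces the donor's label with a good one at the rate
# prescribed by the effective assessment of the action the donor takes.

#' Prescribed effective assessment per context
#'
#' The probability `RS(X, Y)` that a donor is assigned a good reputation in
#' context `(X, Y)` when everyone follows the norm: the effective assessment
#' evaluated at the prescribed action, `RS(X,Y) = R_eff(X, Y, S(X,Y))`.
#'
#' @param norm A [social_norm()].
#' @param err An [error_model()].
#' @return A named numeric vector over the four contexts, of class
#'   `prescribed_assessment`.
#' @examples
#' prescribed_assessment(norm_catalog("L6"), error_model(mu = 0.1))
#' @export
prescribed_assessment <- function(norm, err = error_model()) {
  stopifnot(inherits(norm, "social_norm"))
  r_eff <- effective_assessment(norm, err)
  keys <- paste(CONTEXTS, as.character(norm$action), sep = ".")
  structure(stats::setNames(as.numeric(r_eff)[match(keys, names(r_eff))],
                            CONTEXTS),
            class = "prescribed_assessment")
}

#' Drift of the good fraction
#'
#' The instantaneous rate of change of the fraction `h` of good players:
#' donors are drawn at rate one, meet good recipients with probability `h`,
#' and are re-assessed according to `rs`.
#'
#' @param h Fraction(s) of good players, in `[0, 1]`; vectorized.
#' @param rs A [prescribed_assessment()] (or any numeric vector named by
#'   context).
#' @return The drift, same length as `h`.
#' @export
reputation_drift <- function(h, rs) {
  h^2 * rs[["GG"]] + h * (1 - h) * (rs[["GB"]] + rs[["BG"]]) +
    (1 - h)^2 * rs[["BB"]] - h
}

#' Stationary state of the reputation dynamics
#'
#' Solves for the stationary fraction `h*` of good players. Setting the
#' drift to zero gives the quadratic `c2 h^2 + c1 h + c0 = 0` with
#' `c2 = RS(GG) - RS(GB) - RS(BG) + RS(BB)`,
#' `c1 = RS(GB) + RS(BG) - 2 RS(BB) - 1`, `c0 = RS(BB)`;
#' the root in `[0, 1]` is `(-c1 - sqrt(c1^2 - 4 c2 c0)) / (2 c2)`, or
#' `-c0 / c1` when `|c2|` is numerically zero (below 1e-12). For `mu > 0`
#' this root is unique in the unit interval and dynamically stable; the
#' residual drift at the root is verified to be below 1e-10.
#'
#' @param norm A [social_norm()].
#' @param err An [error_model()]. With `mu = 0` the result carries
#'   `ergodic = FALSE`: the dynamics may then depend on initial conditions
#'   and vanishing-error analyses should use [classify_cess()] instead.
#' @return A `stationary_state` object with fields `h_star`, `c2`, `c1`,
#'   `c0`, `rs`, `p_rates` (stationary action rates), and `ergodic`.
#' @examples
#' stationary_state(norm_catalog("L7"), error_model(mu = 0.1))$h_star
#' @export
stationary_state <- function(norm, err = error_model()) {
  rs <- prescribed_assessment(norm, err)
  c2 <- rs[["GG"]] - rs[["GB"]] - rs[["BG"]] + rs[["BB"]]
  c1 <- rs[["GB"]] + rs[["BG"]] - 2 * rs[["BB"]] - 1
  c0 <- rs[["BB"]]
  if (abs(c2) < 1e-12) {
    if (abs(c1) < 1e-12) {
      stop("degenerate reputation dynamics: drift vanishes identically ",
           "(possible only at mu = 0)", call. = FALSE)
    }
    h <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    h <- (-c1 - sqrt(disc)) / (2 * c2)
  }
  if (is.nan(h) || h < -1e-12 || h > 1 + 1e-12) {
    stop("no stationary good fraction in [0, 1] (degenerate mu = 0 case)",
         call. = FALSE)
  }
  h <- min(max(h, 0), 1)
  resid <- reputation_drift(h, rs)
  if (abs(resid) > 1e-10) {
    stop(sprintf("stationary root failed verification: |drift(h*)| = %g",
                 abs(resid)), call. = FALSE)
  }
  state <- structure(
    list(h_star = h, c2 = c2, c1 = c1, c0 = c0, rs = rs,
         ergodic = err$mu > 0, norm_name = norm$name),
    class = "stationary_state")
  state$p_rates <- action_rates(norm, state, err)
  state
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("<stationary_state>%s h* = %.6f%s\n",
              if (!is.null(x$norm_name)) paste0(" [", x$norm_name, "]") else "",
              x$h_star, if (!x$ergodic) " (non-ergodic: mu = 0)" else ""))
  print(x$p_rates)
  invisible(x)
}

#' Stationary action rates
#'
#' The probability that a random donor takes each action against a random
#' recipient once reputations have equilibrated: the indicator of each
#' action, averaged over contexts weighted by `h*`. The `realized` column
#' additionally accounts for the implementation error, under which an
#' intended cooperation is executed as defection with probability `mu_e`.
#'
#' @param norm A [social_norm()].
#' @param state A [stationary_state()] for this norm (computed if `NULL`).
#' @param err An [error_model()].
#' @return A tibble with columns `action`, `intended`, `realized`.
#' @export
action_rates <- function(norm, state = NULL, err = error_model()) {
  state <- state %||% stationary_state(norm, err)
  h <- state$h_star
  w <- c(GG = h^2, GB = h * (1 - h), BG = (1 - h) * h, BB = (1 - h)^2)
  actions <- norm_actions(norm)
  s <- as.character(norm$action)
  intended <- vapply(actions, function(a) sum(w[s == a]), numeric(1))
  realized <- intended
  if ("C" %in% actions) {
    shifted <- realized[["C"]] * err$mu_e
    realized[["C"]] <- realized[["C"]] - shifted
    realized[["D"]] <- realized[["D"]] + shifted
  }
  tibble::tibble(action = actions, intended = unname(intended),
                 realized = unname(realized))
}

#' Is a norm self-cooperative?
#'
#' A norm is self-cooperative when, in the limit of vanishing errors, a
#' homogeneous population playing it cooperates with probability one. With
#' the good label taken at face value this requires the all-good state to be
#' a stable fixed point reached with cooperation:
#' `R(G,G,S(G,G)) = 1`, `R(G,B,S(G,B)) + R(B,G,S(B,G)) > 1`, and
#' `S(G,G) = C`. Because the two labels are interchangeable, the mirrored
#' condition (everyone labeled bad, with `B` playing the role of the
#' cooperative label) is checked symmetrically.
#'
#' @param norm A [social_norm()], interpreted at its intended (error-free)
#'   assessment values.
#' @return `TRUE` or `FALSE`, with attribute `branch` (`"good"`, `"bad"`,
#'   or `NA`) indicating which labeling supports full cooperation.
#' @export
is_self_cooperative <- function(norm) {
  check <- function(nrm) {
    r <- as.numeric(nrm$assessment)
    names(r) <- names(nrm$assessment)
    s <- as.character(nrm$action)
    names(s) <- CONTEXTS
    rs <- function(ctx) r[[paste(ctx, s[[ctx]], sep = ".")]]
    rs("GG") == 1 && (rs("GB") + rs("BG")) > 1 && s[["GG"]] == "C"
  }
  if (check(norm)) {
    return(structure(TRUE, branch = "good"))
  }
  if (check(relabel_norm(norm))) {
    return(structure(TRUE, branch = "bad"))
  }
  structure(FALSE, branch = NA_character_)
}

#' @export
tidy.stationary_state <- function(x, ...) {
  dplyr::mutate(x$p_rates, h_star = x$h_star, .before = 1)
}

#' @export
glance.stationary_state <- function(x, ...) {
  tibble::tibble(h_star = x$h_star, c2 = x$c2, c1 = x$c1, c0 = x$c0,
                 ergodic = x$ergodic)
}
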