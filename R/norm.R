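# Core representation of social norms for indirect reciprocity with public,
# binary reputations. A context (X, Y) pairs the donor's reputation X with the
# recipient's reputation Y; G is encoded as 1 and B as 0 throughout the
# package, and contexts are always ordered GG, GB, BG, BB (donor first).

CONTEXTS <- c("GG", "GB", "BG", "BB")

#' Reputation contexts
#'
#' The four donor/recipient reputation contexts, in the canonical order used
#' everywhere in the package: `"GG"`, `"GB"`, `"BG"`, `"BB"` (donor
#' reputation first, `G` = good, `B` = bad).
#'
#' @return A character vector of length four.
#' @export
contexts <- function() CONTEXTS

assess_keys <- function(actions) {
  as.vector(t(outer(CONTEXTS, actions, paste, sep = ".")))
}

#' Create an action rule
#'
#' An action rule prescribes the donor's action in each of the four
#' reputation contexts. Action rules are deterministic: stochastic action
#' rules cannot be evolutionarily stable in this setting, because for any
#' context one action is the unique best response except at knife-edge
#' parameter combinations.
#'
#' @param GG,GB,BG,BB Actions (`"C"`, `"D"`, or `"P"`) prescribed in each
#'   context, donor reputation first.
#' @param actions The active action set, either `c("C", "D")` or
#'   `c("C", "D", "P")`. Defaults to the smallest set containing the
#'   prescribed actions (at least `c("C", "D")`).
#' @return An `action_rule` object: a named character vector over the four
#'   contexts with the active action set as an attribute.
#' @examples
#' action_rule("C", "D", "C", "D") # the discriminator (DISC) rule
#' @export
action_rule <- function(GG, GB, BG, BB, actions = NULL) {
  s <- c(GG = GG, GB = GB, BG = BG, BB = BB)
  if (is.null(actions)) {
    actions <- if ("P" %in% s) c("C", "D", "P") else c("C", "D")
  }
  actions <- match.arg(actions, c("C", "D", "P"), several.ok = TRUE)
  if (!all(s %in% actions)) {
    stop("action rule uses actions outside the active action set {",
         paste(actions, collapse = ", "), "}", call. = FALSE)
  }
  structure(s, actions = actions, class = "action_rule")
}

#' @export
print.action_rule <- function(x, ...) {
  cat("<action_rule> over {", paste(attr(x, "actions"), collapse = ","),
      "}\n", sep = "")
  print(stats::setNames(as.character(x), names(x)))
  invisible(x)
}

#' Create an assessment rule
#'
#' An assessment rule gives, for every context and every action in the active
#' action set, the probability that the donor is assigned a good reputation
#' after taking that action. Entries in (0, 1) make the rule stochastic;
#' a rule with all entries in {0, 1} is deterministic.
#'
#' @param ... Named probabilities keyed `"<context>.<action>"`, e.g.
#'   `GG.C = 1, GG.D = 0, ...`, or a single named numeric vector. All
#'   `4 * length(actions)` entries must be supplied.
#' @param actions The active action set.
#' @return An `assessment_rule` object: a named numeric vector.
#' @export
assessment_rule <- function(..., actions = c("C", "D")) {
  vals <- c(...)
  keys <- assess_keys(actions)
  if (!setequal(names(vals), keys)) {
    missing <- setdiff(keys, names(vals))
    extra <- setdiff(names(vals), keys)
    stop("assessment rule must have exactly the entries ",
         paste(keys, collapse = ", "),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  vals <- vals[keys]
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("assessment probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(vals, actions = actions, class = "assessment_rule")
}

#' Build an assessment rule from per-context vectors
#'
#' Convenience constructor mirroring how deterministic norms are usually
#' tabulated: one probability vector per action, each over the four contexts
#' in canonical order.
#'
#' @param RC,RD,RP Numeric vectors of length 4 (contexts GG, GB, BG, BB)
#'   giving the probability of a good assessment after C, D and (optionally)
#'   P. Omit `RP` for the two-action game.
#' @return An `assessment_rule`.
#' @export
assessment_from_vectors <- function(RC, RD, RP = NULL) {
  actions <- if (is.null(RP)) c("C", "D") else c("C", "D", "P")
  cols <- list(C = RC, D = RD, P = RP)[actions]
  vals <- unlist(lapply(seq_along(CONTEXTS), function(i) {
    stats::setNames(vapply(cols, `[`, numeric(1), i),
                    paste(CONTEXTS[i], actions, sep = "."))
  }))
  assessment_rule(vals, actions = actions)
}

#' @export
print.assessment_rule <- function(x, ...) {
  acts <- attr(x, "actions")
  cat("<assessment_rule> over {", paste(acts, collapse = ","), "}\n", sep = "")
  m <- matrix(as.numeric(x), nrow = 4, byrow = TRUE,
              dimnames = list(CONTEXTS, acts))
  print(m)
  invisible(x)
}

#' Create a social norm
#'
#' A social norm couples a deterministic action rule with a (possibly
#' stochastic) assessment rule over the same action set.
#'
#' @param action An [action_rule()].
#' @param assessment An [assessment_rule()].
#' @param name Optional label.
#' @return A `social_norm` object.
#' @examples
#' stern <- norm_catalog("L6")
#' social_norm(stern$action, stern$assessment, name = "my copy of L6")
#' @export
social_norm <- function(action, assessment, name = NULL) {
  stopifnot(inherits(action, "action_rule"), inherits(assessment, "assessment_rule"))
  if (!identical(attr(action, "actions"), attr(assessment, "actions"))) {
    stop("action rule and assessment rule must share the same action set",
         call. = FALSE)
  }
  structure(list(action = action, assessment = assessment, name = name),
            class = "social_norm")
}

#' @export
print.social_norm <- function(x, ...) {
  cat("<social_norm>", if (!is.null(x$name)) paste0(" \"", x$name, "\""), "\n", sep = "")
  acts <- attr(x$action, "actions")
  m <- matrix(as.numeric(x$assessment), nrow = 4, byrow = TRUE,
              dimnames = list(CONTEXTS, paste0("R(", acts, ")")))
  df <- data.frame(S = as.character(x$action), m, check.names = FALSE)
  print(df)
  invisible(x)
}

norm_actions <- function(norm) attr(norm$action, "actions")

#' Deterministic norm from tabulated prescriptions
#'
#' @param S Character vector of length 4: prescribed actions per context.
#' @param RC,RD,RP Assessments after C, D, P per context (length 4 each);
#'   omit `RP` for the two-action game.
#' @param name Optional label.
#' @return A `social_norm`.
#' @export
deterministic_norm <- function(S, RC, RD, RP = NULL, name = NULL) {
  ar <- action_rule(S[1], S[2], S[3], S[4],
                    actions = if (is.null(RP)) c("C", "D") else c("C", "D", "P"))
  social_norm(ar, assessment_from_vectors(RC, RD, RP), name = name)
}

#' Error model: assessment, implementation and perception errors
#'
#' Three independent noise sources act on the reputation process:
#' * `mu`, the assessment error: an assigned reputation is flipped with this
#'   probability, so intended assessments `R` become
#'   `(1 - mu) R + mu (1 - R)`. Ergodicity of the reputation dynamics
#'   requires `mu > 0`; `mu = 0` is accepted but downstream results carry a
#'   non-ergodic flag.
#' * `mu_e`, the implementation error: an intended cooperation fails and is
#'   executed as defection with this probability. Defections are always
#'   implemented as intended.
#' * `eps_dc`, the perception error: an executed defection is observed (and
#'   assessed) as cooperation with this probability.
#'
#' Implementation and perception errors are defined between C and D only;
#' the punishment action P is assessed as prescribed, subject only to `mu`.
#'
#' @param mu Assessment error rate, in `[0, 0.5)`.
#' @param mu_e Implementation error rate, in `[0, 1)`.
#' @param eps_dc Perception (D-seen-as-C) error rate, in `[0, 1)`.
#' @return An `error_model` object.
#' @export
error_model <- function(mu = 0, mu_e = 0, eps_dc = 0) {
  chk <- function(x, nm, hi) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x >= hi) {
      stop(sprintf("error rate `%s` must lie in [0, %s); got %s", nm, hi,
                   format(x)), call. = FALSE)
    }
  }
  chk(mu, "mu", 0.5)
  chk(mu_e, "mu_e", 1)
  chk(eps_dc, "eps_dc", 1)
  structure(list(mu = mu, mu_e = mu_e, eps_dc = eps_dc), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> mu = %g, mu_e = %g, eps_dc = %g%s\n",
              x$mu, x$mu_e, x$eps_dc,
              if (x$mu == 0) " (non-ergodic: mu = 0)" else ""))
  invisible(x)
}

#' Donation-game parameters
#'
#' @param b Benefit of cooperation to the recipient. The donation game is a
#'   social dilemma when `b > c`; the machinery accepts any positive pair,
#'   which is useful for locating critical benefit-cost ratios.
#' @param c Cost of cooperation to the donor, `c > 0`.
#' @param alpha Punisher's own cost per punishment (required when the action
#'   set includes P).
#' @param beta Harm inflicted on a punished recipient.
#' @return A `game_params` object.
#' @export
game_params <- function(b, c, alpha = NULL, beta = NULL) {
  if (!is.numeric(b) || !is.numeric(c) || b <= 0 || c <= 0) {
    stop("need b > 0 and c > 0", call. = FALSE)
  }
  if (xor(is.null(alpha), is.null(beta))) {
    stop("supply both `alpha` and `beta`, or neither", call. = FALSE)
  }
  if (!is.null(alpha) && (alpha <= 0 || beta <= 0)) {
    stop("punishment parameters alpha and beta must be positive", call. = FALSE)
  }
  structure(list(b = b, c = c, alpha = alpha, beta = beta),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("<game_params> b = %g, c = %g", x$b, x$c))
  if (!is.null(x$alpha)) cat(sprintf(", alpha = %g, beta = %g", x$alpha, x$beta))
  cat("\n")
  invisible(x)
}

#' Effective assessment rule under errors
#'
#' Folds the three error types into the intended assessment rule, in the
#' fixed order: assessment error first (`R -> (1-mu) R + mu (1-R)`, every
#' entry), then perception error (the D column is mixed toward the C column:
#' an executed defection is assessed as a cooperation with probability
#' `eps_dc`), then implementation error (the C column is mixed toward the
#' perception-adjusted D column: an intended cooperation is executed, and
#' hence assessed, as a defection with probability `mu_e`; the D column is
#' unchanged). Entries for the punishment action P, when present, are subject
#' to the assessment error only.
#'
#' With only `mu` active every effective entry lies in `[mu, 1 - mu]`.
#'
#' @param R An [assessment_rule()] or a [social_norm()] (whose assessment
#'   rule is used).
#' @param err An [error_model()].
#' @return The effective `assessment_rule`.
#' @examples
#' r <- norm_catalog("L6")$assessment
#' effective_assessment(r, error_model(mu = 0.1))
#' @export
effective_assessment <- function(R, err = error_model()) {
  if (inherits(R, "social_norm")) R <- R$assessment
  stopifnot(inherits(R, "assessment_rule"), inherits(err, "error_model"))
  actions <- attr(R, "actions")
  v <- as.numeric(R)
  names(v) <- names(R)
  # assessment error, all entries
  v <- (1 - err$mu) * v + err$mu * (1 - v)
  kc <- paste(CONTEXTS, "C", sep = ".")
  kd <- paste(CONTEXTS, "D", sep = ".")
  # perception error: executed D assessed as C with prob eps_dc
  v[kd] <- (1 - err$eps_dc) * v[kd] + err$eps_dc * v[kc]
  # implementation error: intended C executed as D with prob mu_e
  v[kc] <- (1 - err$mu_e) * v[kc] + err$mu_e * v[kd]
  structure(v, actions = actions, class = "assessment_rule", effective = TRUE)
}

#' Effective benefit and cost under implementation errors
#'
#' An intended cooperation is executed with probability `1 - mu_e`, so the
#' expected benefit and cost per intended cooperation are scaled accordingly.
#' Punishment parameters are unchanged: P is implemented as intended.
#'
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @return A `game_params` with `b` and `c` rescaled by `1 - mu_e`.
#' @export
effective_game_params <- function(params, err = error_model()) {
  stopifnot(inherits(params, "game_params"), inherits(err, "error_model"))
  game_params(b = (1 - err$mu_e) * params$b, c = (1 - err$mu_e) * params$c,
              alpha = params$alpha, beta = params$beta)
}

#' Swap the reputation labels of a norm
#'
#' Relabeling exchanges the roles of G and B: contexts are mirrored and every
#' assessment probability `p` (of being assigned the *good* label) becomes
#' `1 - p`. The stationary good fraction of the relabeled norm is one minus
#' that of the original.
#'
#' @param norm A [social_norm()].
#' @return The relabeled `social_norm`.
#' @export
relabel_norm <- function(norm) {
  stopifnot(inherits(norm, "social_norm"))
  actions <- norm_actions(norm)
  flip <- c(GG = "BB", GB = "BG", BG = "GB", BB = "GG")
  s <- as.character(norm$action)[match(flip[CONTEXTS], CONTEXTS)]
  ar <- action_rule(s[1], s[2], s[3], s[4], actions = actions)
  r_old <- stats::setNames(as.numeric(norm$assessment),
                           names(norm$assessment))
  v <- numeric(0)
  for (ctx in CONTEXTS) {
    for (a in actions) {
      v[paste(ctx, a, sep = ".")] <- 1 - r_old[[paste(flip[ctx], a, sep = ".")]]
    }
  }
  social_norm(ar, assessment_rule(v, actions = actions),
              name = if (!is.null(norm$name)) paste0(norm$name, " (relabeled)"))
}
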