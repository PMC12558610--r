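# Built-in catalog of named norms and action rules, plus a seeded random
# norm generator and JSON serialization.

leading_eight_defs <- function() {
  # Prescriptions per context (GG, GB, BG, BB): action, R after C, R after D.
  list(
    L1 = list(S = c("C", "D", "C", "C"), RC = c(1, 1, 1, 1), RD = c(0, 1, 0, 0),
              alias = "Standing"),
    L2 = list(S = c("C", "D", "C", "C"), RC = c(1, 0, 1, 1), RD = c(0, 1, 0, 0),
              alias = "Consistent Standing"),
    L3 = list(S = c("C", "D", "C", "D"), RC = c(1, 1, 1, 1), RD = c(0, 1, 0, 1),
              alias = "Simple Standing"),
    L4 = list(S = c("C", "D", "C", "D"), RC = c(1, 1, 1, 0), RD = c(0, 1, 0, 1),
              alias = NULL),
    L5 = list(S = c("C", "D", "C", "D"), RC = c(1, 0, 1, 1), RD = c(0, 1, 0, 1),
              alias = NULL),
    L6 = list(S = c("C", "D", "C", "D"), RC = c(1, 0, 1, 0), RD = c(0, 1, 0, 1),
              alias = "Stern Judging"),
    L7 = list(S = c("C", "D", "C", "D"), RC = c(1, 1, 1, 0), RD = c(0, 1, 0, 0),
              alias = "Staying"),
    L8 = list(S = c("C", "D", "C", "D"), RC = c(1, 0, 1, 0), RD = c(0, 1, 0, 0),
              alias = "Judging")
  )
}

#' The leading eight, as a tibble
#'
#' One row per norm, with the prescribed action and the assessments after C
#' and D for each of the four contexts.
#'
#' @return A tibble with 8 rows and columns `name`, `alias`, then
#'   `S_GG, RC_GG, RD_GG, ..., RD_BB`.
#' @export
leading_eight <- function() {
  specs <- leading_eight_defs()
  purrr::map_dfr(names(specs), function(nm) {
    sp <- specs[[nm]]
    row <- tibble::tibble(name = nm, alias = sp$alias %||% NA_character_)
    for (i in seq_along(CONTEXTS)) {
      row[[paste0("S_", CONTEXTS[i])]] <- sp$S[i]
      row[[paste0("RC_", CONTEXTS[i])]] <- sp$RC[i]
      row[[paste0("RD_", CONTEXTS[i])]] <- sp$RD[i]
    }
    row
  })
}

catalog_action_rules <- function() {
  list(
    ALLC  = c("C", "C", "C", "C"),
    ALLD  = c("D", "D", "D", "D"),
    DISC  = c("C", "D", "C", "D"),
    ADISC = c("D", "C", "D", "C")
  )
}

#' Names available in the norm catalog
#' @return Character vector of names accepted by [norm_catalog()].
#' @export
catalog_names <- function() {
  c(names(leading_eight_defs()), "GSCO", "CautiousScoring",
    names(catalog_action_rules()))
}

#' The equalizer assessment gap
#'
#' The C-versus-D gap, in intended assessment units, that makes a
#' second-order discriminating norm an equalizer: `c / ((1 - 2 mu) b)`.
#' After the assessment error flips each assignment with probability `mu`,
#' the effective gap is `c / b`, which multiplied by the reputation value
#' `delta_v = b` of such norms makes cooperation and defection exactly
#' payoff-equivalent.
#'
#' @param params A [game_params()].
#' @param err An [error_model()] (only `mu` matters).
#' @return The gap, a number in (0, 1] when feasible.
#' @export
equalizer_gap <- function(params, err = error_model()) {
  gap <- params$c / ((1 - 2 * err$mu) * params$b)
  if (gap > 1) {
    stop("equalizer gap c / ((1 - 2 mu) b) exceeds 1: no feasible ",
         "assessment rule at these parameters", call. = FALSE)
  }
  gap
}

#' Retrieve a named norm from the catalog
#'
#' Available names (see [catalog_names()]):
#' * `L1`–`L8` (aliases accepted: "Standing", "Consistent Standing",
#'   "Simple Standing", "Stern Judging", "Staying", "Judging"): the leading
#'   eight, tabulated cell-for-cell.
#' * `GSCO` (Generous Scoring): the first-order equalizer with
#'   `R(*,*,C) = 1` and `R(*,*,D) = 1 - c/((1 - 2 mu) b)`; requires
#'   `params` and `err`.
#' * `CautiousScoring`: the second-order equalizer with
#'   `R(*,G,C) = 1`, `R(*,G,D) = 1 - c/((1-2mu) b)`,
#'   `R(*,B,C) = c/((1-2mu) b)`, `R(*,B,D) = 0`; requires `params` and
#'   `err`.
#' * `ALLC`, `ALLD`, `DISC`, `ADISC`: action rules (always cooperate, always
#'   defect, discriminator, anti-discriminator) paired with the supplied
#'   `assessment` rule (default: Stern Judging's).
#'
#' @param name A catalog name.
#' @param params A [game_params()] (needed for the equalizer norms).
#' @param err An [error_model()] (needed for the equalizer norms).
#' @param assessment Assessment rule to pair with the pure action rules
#'   `ALLC`/`ALLD`/`DISC`/`ADISC`.
#' @return A `social_norm`.
#' @examples
#' norm_catalog("L6")
#' norm_catalog("GSCO", game_params(1, 0.1), error_model(mu = 0.01))
#' @export
norm_catalog <- function(name, params = NULL, err = NULL, assessment = NULL) {
  specs <- leading_eight_defs()
  aliases <- purrr::map_chr(specs, ~ .x$alias %||% NA_character_)
  if (name %in% aliases) name <- names(aliases)[match(name, aliases)]
  if (name %in% names(specs)) {
    sp <- specs[[name]]
    return(deterministic_norm(sp$S, sp$RC, sp$RD, name = name))
  }
  if (name %in% c("GSCO", "CautiousScoring")) {
    if (is.null(params)) {
      stop("`", name, "` needs game parameters (b, c) and an error model",
           call. = FALSE)
    }
    err <- err %||% error_model()
    gap <- equalizer_gap(params, err)
    disc <- action_rule("C", "D", "C", "D")
    assess <- if (name == "GSCO") {
      assessment_from_vectors(RC = rep(1, 4), RD = rep(1 - gap, 4))
    } else {
      # cautious variant: bad recipients get low assessments throughout
      assessment_from_vectors(RC = c(1, gap, 1, gap), RD = c(1 - gap, 0, 1 - gap, 0))
    }
    return(social_norm(disc, assess, name = name))
  }
  ars <- catalog_action_rules()
  if (name %in% names(ars)) {
    assessment <- assessment %||% norm_catalog("L6")$assessment
    s <- ars[[name]]
    return(social_norm(action_rule(s[1], s[2], s[3], s[4]), assessment,
                       name = name))
  }
  stop("unknown norm `", name, "`; available: ",
       paste(catalog_names(), collapse = ", "), call. = FALSE)
}

#' Sample a random norm
#'
#' Draws a reproducible random norm: each action entry uniform over the
#' action set, each assessment entry uniform on `[0, 1]` (stochastic) or
#' uniform on `{0, 1}` (deterministic).
#'
#' @param seed Optional integer; when given, the draw is made under this
#'   seed without disturbing the caller's RNG state.
#' @param deterministic If `TRUE`, assessment entries are 0/1 coin flips.
#' @param actions Active action set.
#' @return A `social_norm`.
#' @examples
#' identical(sample_random_norm(seed = 1), sample_random_norm(seed = 1))
#' @export
sample_random_norm <- function(seed = NULL, deterministic = FALSE,
                               actions = c("C", "D")) {
  draw <- function() {
    s <- sample(actions, 4, replace = TRUE)
    n_entries <- 4 * length(actions)
    vals <- if (deterministic) sample(c(0, 1), n_entries, replace = TRUE)
            else stats::runif(n_entries)
    names(vals) <- assess_keys(actions)
    social_norm(action_rule(s[1], s[2], s[3], s[4], actions = actions),
                assessment_rule(vals, actions = actions))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Write a norm to JSON
#'
#' The schema has fields `name`, `actions`, `action_rule` (an object keyed
#' `"GG"`, `"GB"`, `"BG"`, `"BB"`) and `assessment_rule` (an object keyed
#' `"GG.C"`, `"GG.D"`, ...). Probabilities are written at full precision so
#' a write/read round trip reproduces the norm exactly.
#'
#' @param norm A [social_norm()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_norm_json <- function(norm, path) {
  stopifnot(inherits(norm, "social_norm"))
  obj <- list(
    name = norm$name,
    actions = attr(norm$action, "actions"),
    action_rule = as.list(stats::setNames(as.character(norm$action),
                                          names(norm$action))),
    assessment_rule = as.list(stats::setNames(as.numeric(norm$assessment),
                                              names(norm$assessment)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a norm from JSON
#'
#' Strictly validates the schema written by [write_norm_json()].
#'
#' @param path Input file path.
#' @return A `social_norm`.
#' @export
read_norm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  needed <- c("actions", "action_rule", "assessment_rule")
  if (!all(needed %in% names(obj))) {
    stop("norm file must contain fields: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  actions <- unlist(obj$actions)
  if (!all(actions %in% c("C", "D", "P"))) {
    stop("invalid action set in norm file: ", paste(actions, collapse = ","),
         call. = FALSE)
  }
  ar_list <- obj$action_rule
  if (!setequal(names(ar_list), CONTEXTS)) {
    stop("action_rule must be keyed GG, GB, BG, BB", call. = FALSE)
  }
  s <- vapply(CONTEXTS, function(k) as.character(ar_list[[k]]), character(1))
  vals <- vapply(obj$assessment_rule, function(x) {
    if (!is.numeric(x)) stop("assessment probabilities must be numbers",
                             call. = FALSE)
    as.numeric(x)
  }, numeric(1))
  social_norm(action_rule(s[1], s[2], s[3], s[4], actions = actions),
              assessment_rule(vals, actions = actions),
              name = if (!is.null(obj$name)) as.character(obj$name))
}
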