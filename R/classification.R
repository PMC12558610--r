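# Cooperative ESS (CESS) in the limit of vanishing errors.
#
# A CESS is a norm that is both self-cooperative (cooperation rate -> 1 as
# errors vanish) and an ESS. In that limit the population settles in the
# all-good state, delta_v takes a simple closed form, and the ESS margins
# reduce to a short list of strict inequalities on the intended assessment
# entries. Two branches exist, split by the action S(B,G) a bad donor takes
# toward a good recipient: redeeming through cooperation (stable for b > c)
# or through defection (stable for b > 2c).

intended_R <- function(norm) {
  r <- as.numeric(norm$assessment)
  names(r) <- names(norm$assessment)
  r
}

cess_conditions_canonical <- function(norm, params, tol = 0) {
  r <- intended_R(norm)
  s <- as.character(norm$action)
  names(s) <- CONTEXTS
  b <- params$b; cc <- params$c
  ids <- character(0); lhss <- numeric(0); cmps <- character(0)
  rhss <- numeric(0); oks <- logical(0)
  add <- function(id, lhs, rhs, type) {
    ok <- switch(type,
                 ">" = lhs > rhs + tol,
                 "<" = lhs < rhs - tol,
                 "=" = abs(lhs - rhs) <= tol)
    ids[[length(ids) + 1]] <<- id
    lhss[[length(lhss) + 1]] <<- lhs
    cmps[[length(cmps) + 1]] <<- type
    rhss[[length(rhss) + 1]] <<- rhs
    oks[[length(oks) + 1]] <<- ok
    ok
  }
  # structural prerequisites of full cooperation around the all-good state
  ok <- add("S(G,G)=C", as.numeric(s[["GG"]] == "C"), 1, "=")
  ok <- add("S(G,B)=D", as.numeric(s[["GB"]] == "D"), 1, "=") && ok
  ok <- add("R(G,G,C)=1", r[["GG.C"]], 1, "=") && ok
  branch <- if (s[["BG"]] == "C") "coop" else "defect"
  if (branch == "coop") {
    rbg <- r[["BG.C"]]
    gain <- b # net payoff contrast b - c [1 - chiC(B,G)] with chiC(B,G) = 1
    ok <- add("R(G,B,D)+R(B,G,C)>1", r[["GB.D"]] + rbg, 1, ">") && ok
  } else {
    rbg <- r[["BG.D"]]
    gain <- b - cc
    ok <- add("R(G,B,D)+R(B,G,D)>1", r[["GB.D"]] + rbg, 1, ">") && ok
  }
  ok <- add("(G,G) margin", (r[["GG.C"]] - r[["GG.D"]]) * gain, cc * rbg, ">") && ok
  ok <- add("(G,B) margin", (r[["GB.C"]] - r[["GB.D"]]) * gain, cc * rbg, "<") && ok
  if (branch == "coop") {
    ok <- add("(B,G) margin", (r[["BG.C"]] - r[["BG.D"]]) * gain, cc * rbg, ">") && ok
  } else {
    ok <- add("(B,G) margin", (r[["BG.C"]] - r[["BG.D"]]) * gain, cc * rbg, "<") && ok
  }
  bb_lhs <- (r[["BB.C"]] - r[["BB.D"]]) * gain
  bb_rhs <- cc * rbg
  required_SBB <- if (bb_lhs > bb_rhs) "C"
                  else if (bb_lhs < bb_rhs) "D"
                  else NA_character_ # knife-edge: no action strictly forced
  ok <- add("S(B,B) forced",
            as.numeric(!is.na(required_SBB) && s[["BB"]] == required_SBB),
            1, "=") && ok
  list(pass = ok, branch = branch, required_SBB = required_SBB,
       knife_edge = is.na(required_SBB),
       conditions = tibble::tibble(id = ids, lhs = lhss, cmp = cmps,
                                   rhs = rhss, satisfied = oks))
}

#' Classify a norm as a cooperative ESS in the vanishing-error limit
#'
#' Evaluates the exact necessary-and-sufficient CESS conditions at the
#' intended (error-free) assessment values, with strict inequalities. The
#' conditions are checked in the canonical labeling (the all-good state
#' carries cooperation) and, because the two reputation labels are
#' interchangeable, also on the G/B-relabeled norm.
#'
#' @param norm A [social_norm()] over `{C, D}`.
#' @param params A [game_params()] with `b > c`.
#' @param check_relabeled Also test the relabeled (all-bad-state) branch.
#' @return A `cess_verdict` object with fields `cess` (logical), `branch`
#'   (`"coop"`, `"defect"`, or `NA`), `labeling` (`"canonical"`,
#'   `"relabeled"`, or `NA`), `required_SBB`, `knife_edge`, and the tibble
#'   `conditions`.
#' @examples
#' classify_cess(norm_catalog("L1"), game_params(1.5, 1))
#' @export
classify_cess <- function(norm, params, check_relabeled = TRUE) {
  stopifnot(inherits(norm, "social_norm"))
  if (!identical(norm_actions(norm), c("C", "D"))) {
    stop("classify_cess covers the {C, D} game; see cess_with_punishment()",
         call. = FALSE)
  }
  res <- cess_conditions_canonical(norm, params)
  labeling <- if (res$pass) "canonical" else NA_character_
  if (!res$pass && check_relabeled) {
    res2 <- cess_conditions_canonical(relabel_norm(norm), params)
    if (res2$pass) {
      res <- res2
      labeling <- "relabeled"
    }
  }
  structure(list(cess = res$pass, branch = if (res$pass) res$branch else NA_character_,
                 labeling = labeling, required_SBB = res$required_SBB,
                 knife_edge = res$knife_edge, conditions = res$conditions,
                 norm_name = norm$name),
            class = "cess_verdict")
}

#' @export
print.cess_verdict <- function(x, ...) {
  cat(sprintf("<cess_verdict>%s %s%s\n",
              if (!is.null(x$norm_name)) paste0(" [", x$norm_name, "]") else "",
              if (x$cess) paste0("CESS (", x$branch, " branch, ", x$labeling,
                                 " labeling, S(B,B) forced to ", x$required_SBB, ")")
              else "not a CESS",
              if (x$knife_edge) " [knife-edge S(B,B)]" else ""))
  invisible(x)
}

#' @export
tidy.cess_verdict <- function(x, ...) x$conditions

#' @export
glance.cess_verdict <- function(x, ...) {
  tibble::tibble(cess = x$cess, branch = x$branch, labeling = x$labeling,
                 required_SBB = x$required_SBB, knife_edge = x$knife_edge)
}

all_deterministic_norms <- function(actions = c("C", "D")) {
  n_act <- length(actions)
  act_grid <- expand.grid(rep(list(actions), 4), stringsAsFactors = FALSE)
  assess_grid <- expand.grid(rep(list(c(0, 1)), 4 * n_act))
  list(actions = act_grid, assessments = assess_grid)
}

#' Enumerate all deterministic cooperative ESS
#'
#' Exhaustively scans the 4096 deterministic third-order norms of the
#' two-action game (16 action rules times 256 assessment rules) and keeps
#' those classified as CESS under the canonical labeling. (Each CESS has a
#' mirror image under exchanging the reputation labels; counting one
#' labeling avoids listing every norm twice.) For `b/c` between 1 and 2 the
#' result is the leading-eight family; for `b/c > 2` the defect branch adds
#' the secondary sixteen.
#'
#' @param params A [game_params()] with `b > c`.
#' @return A tibble with one row per CESS: the four action entries, the
#'   eight assessment entries, `branch`, `required_SBB` and the stability
#'   condition label (`"b>c"` or `"b>2c"`).
#' @examples
#' nrow(enumerate_deterministic_cess(game_params(1.5, 1))) # 8
#' @export
enumerate_deterministic_cess <- function(params) {
  grids <- all_deterministic_norms()
  keys <- assess_keys(c("C", "D"))
  out <- vector("list", 256)
  k <- 0
  for (ai in seq_len(nrow(grids$actions))) {
    s <- as.character(grids$actions[ai, ])
    # both CESS branches require S = (C, D, *, forced); skip the rest early
    if (s[1] != "C" || s[2] != "D") next
    ar <- action_rule(s[1], s[2], s[3], s[4])
    for (ri in seq_len(nrow(grids$assessments))) {
      vals <- stats::setNames(as.numeric(grids$assessments[ri, ]), keys)
      norm <- social_norm(ar, assessment_rule(vals, actions = c("C", "D")))
      v <- classify_cess(norm, params, check_relabeled = FALSE)
      if (v$cess) {
        k <- k + 1
        row <- tibble::tibble(branch = v$branch,
                              required_SBB = v$required_SBB,
                              condition = if (v$branch == "coop") "b>c" else "b>2c")
        for (i in seq_along(CONTEXTS)) row[[paste0("S_", CONTEXTS[i])]] <- s[i]
        for (key in keys) {
          row[[sub("\\.", "_R", paste0("R_", key))]] <- vals[[key]]
        }
        out[[k]] <- row
      }
    }
  }
  if (k == 0) {
    return(tibble::tibble(branch = character(), required_SBB = character(),
                          condition = character()))
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  dplyr::arrange(res, dplyr::desc(.data$branch), dplyr::across(dplyr::starts_with("R_")))
}

#' Critical benefit-cost ratio of a CESS branch
#'
#' Finds, by bisection over the deterministic enumeration, the infimum of
#' `b/c` above which the branch contains at least one deterministic CESS.
#' The defect branch (bad donors redeem themselves without paying the
#' cooperation cost) switches on at `b/c = 2`; the cooperation branch at
#' `b/c = 1`.
#'
#' @param branch `"defect"` or `"coop"`.
#' @param lower,upper Bracketing ratios; the branch must be empty at
#'   `lower` and non-empty at `upper`.
#' @param tol Bisection tolerance on the ratio.
#' @return The threshold ratio.
#' @export
cess_branch_threshold <- function(branch = c("defect", "coop"),
                                  lower = 1, upper = 4, tol = 1e-6) {
  branch <- match.arg(branch)
  nonempty <- function(ratio) {
    enum <- enumerate_deterministic_cess(game_params(ratio, 1))
    any(enum$branch == branch)
  }
  if (nonempty(lower)) return(lower)
  if (!nonempty(upper)) {
    stop("branch still empty at b/c = ", upper, call. = FALSE)
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nonempty(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# ---- punishment ------------------------------------------------------------

#' The six CESS classes with costly punishment
#'
#' With the action set `{C, D, P}`, a cooperative ESS must prescribe
#' `S(G,G) = C` and `S(G,B)` in `{D, P}`, while `S(B,G)` may be any of
#' `{C, D, P}`; the six admissible pairs define the classes, each with its
#' own closed form for the reputation value gap, always with denominator
#' `R(B, G, S(B,G))`.
#'
#' @return A tibble with columns `A_GB`, `A_BG`, `numerator` (formula
#'   string) and `delta_v_form` (full formula string).
#' @export
enumerate_punishment_classes <- function() {
  grid <- expand.grid(A_GB = c("D", "P"), A_BG = c("C", "D", "P"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$A_GB, grid$A_BG), ]
  num <- mapply(function(agb, abg) {
    terms <- c("b",
               if (abg != "C") "- c",
               if (abg == "P") "+ alpha",
               if (agb == "P") "+ beta")
    paste(terms, collapse = " ")
  }, grid$A_GB, grid$A_BG)
  tibble::tibble(A_GB = grid$A_GB, A_BG = grid$A_BG, numerator = unname(num),
                 delta_v_form = paste0("(", num, ") / R(B,G,", grid$A_BG, ")"))
}

#' Closed-form delta_v for a punishment CESS class
#'
#' @param A_GB Action of a good donor toward a bad recipient (`"D"` or
#'   `"P"`).
#' @param A_BG Action of a bad donor toward a good recipient.
#' @param params A [game_params()] with `alpha`, `beta`.
#' @param R_BG Intended assessment `R(B, G, A_BG)` of the redeeming action;
#'   must be positive.
#' @return The reputation value gap in the vanishing-error limit.
#' @export
punishment_delta_v <- function(A_GB, A_BG, params, R_BG) {
  if (!A_GB %in% c("D", "P")) stop("A_GB must be D or P", call. = FALSE)
  if (!A_BG %in% c("C", "D", "P")) stop("A_BG must be C, D or P", call. = FALSE)
  if (R_BG <= 0) stop("R(B,G,A_BG) must be positive", call. = FALSE)
  num <- params$b +
    (if (A_BG != "C") -params$c else 0) +
    (if (A_BG == "P") params$alpha else 0) +
    (if (A_GB == "P") params$beta else 0)
  num / R_BG
}

#' CESS classification with a costly-punishment action
#'
#' Vanishing-error CESS conditions for the three-action game: the action
#' rule must have `S(G,G) = C` and `S(G,B)` in `{D, P}`; the assessment rule
#' must give `R(G,G,C) = 1` and `R(G,B,S(G,B)) + R(B,G,S(B,G)) > 1`; and in
#' each context the prescribed action must strictly beat both alternatives,
#' with the reputation value gap given by the class closed form (see
#' [enumerate_punishment_classes()]) and instantaneous costs `c`, `0`,
#' `alpha` for C, D, P.
#'
#' @param norm A [social_norm()] over `{C, D, P}`.
#' @param params A [game_params()] with `alpha` and `beta`.
#' @param tol Strictness tolerance; conditions within `tol` of equality are
#'   knife-edge.
#' @return A `cess_verdict` (with `branch` of the form `"punish (A_GB, A_BG)"`).
#' @export
cess_with_punishment <- function(norm, params, tol = 0) {
  if (!identical(norm_actions(norm), c("C", "D", "P"))) {
    stop("cess_with_punishment needs the {C, D, P} action set", call. = FALSE)
  }
  if (is.null(params$alpha)) {
    stop("game parameters must include alpha and beta", call. = FALSE)
  }
  r <- intended_R(norm)
  s <- as.character(norm$action)
  names(s) <- CONTEXTS
  conds <- list()
  add <- function(id, ok, lhs = NA_real_, rhs = NA_real_) {
    conds[[length(conds) + 1]] <<- tibble::tibble(
      id = id, lhs = lhs, cmp = NA_character_, rhs = rhs, satisfied = ok)
    ok
  }
  ok <- add("S(G,G)=C", s[["GG"]] == "C")
  ok <- add("S(G,B) in {D,P}", s[["GB"]] %in% c("D", "P")) && ok
  fail <- function() {
    structure(list(cess = FALSE, branch = NA_character_,
                   labeling = NA_character_, required_SBB = NA_character_,
                   knife_edge = FALSE, conditions = dplyr::bind_rows(conds),
                   norm_name = norm$name),
              class = "cess_verdict")
  }
  if (!ok) return(fail())
  a_gb <- s[["GB"]]; a_bg <- s[["BG"]]
  ok <- add("R(G,G,C)=1", r[["GG.C"]] == 1, r[["GG.C"]], 1) && ok
  sum_r <- r[[paste0("GB.", a_gb)]] + r[[paste0("BG.", a_bg)]]
  ok <- add("R(G,B,A_GB)+R(B,G,A_BG)>1", sum_r > 1 + tol, sum_r, 1) && ok
  rbg <- r[[paste0("BG.", a_bg)]]
  if (rbg <= 0) return(fail())
  dv <- punishment_delta_v(a_gb, a_bg, params, rbg)
  zeta <- c(C = params$c, D = 0, P = params$alpha)
  knife <- FALSE
  for (ctx in CONTEXTS) {
    prescribed <- s[[ctx]]
    for (a in setdiff(c("C", "D", "P"), prescribed)) {
      lhs <- (r[[paste0(ctx, ".", prescribed)]] - r[[paste0(ctx, ".", a)]]) * dv
      rhs <- zeta[[prescribed]] - zeta[[a]]
      if (abs(lhs - rhs) <= tol) knife <- TRUE
      ok <- add(sprintf("(%s,%s) %s beats %s", substr(ctx, 1, 1),
                        substr(ctx, 2, 2), prescribed, a),
                lhs > rhs + tol, lhs, rhs) && ok
    }
  }
  structure(list(cess = ok, knife_edge = knife,
                 branch = if (ok) sprintf("punish (%s,%s)", a_gb, a_bg)
                          else NA_character_,
                 labeling = if (ok) "canonical" else NA_character_,
                 required_SBB = if (ok) s[["BB"]] else NA_character_,
                 conditions = dplyr::bind_rows(conds),
                 delta_v = dv, norm_name = norm$name),
            class = "cess_verdict")
}
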