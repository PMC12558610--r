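# Grid scans, payoff-gap panels, equalizer demonstrations and CESS exports:
# the tabular reporting layer over the analytic and oracle machinery. All
# functions return tibbles; autoplot() methods give quick-look figures.

#' ESS region scan over error rates
#'
#' Evaluates the analytic ESS verdict of one or more norms on a grid over
#' two error rates (the third held fixed), optionally cross-checking each
#' cell with the brute-force invasion oracle.
#'
#' @param norms A [social_norm()], a catalog name, or a list of either.
#' @param params A [game_params()].
#' @param vary Which two rates vary: subset of `c("mu", "mu_e", "eps_dc")`.
#' @param n Grid resolution per axis (>= 2).
#' @param mu,mu_e,eps_dc Fixed values for the non-varying rates.
#' @param max_mu,max_rate Upper grid limits for `mu` and for
#'   `mu_e`/`eps_dc`; kept strictly inside the valid ranges.
#' @param oracle If `TRUE`, add the brute-force strict-Nash verdict per cell
#'   (slower).
#' @return A tibble of class `ess_region_scan`: one row per (norm, cell)
#'   with the three rates, `ess`, `verdict`, `min_margin`, and the
#'   second-order boundary value
#'   `boundary = (1-2mu)(1-mu_e)(1-eps_dc) - c/b` (zero on the analytic
#'   L3/L6 ESS frontier).
#' @examples
#' sc <- ess_region_scan("L6", game_params(1, 0.8), n = 5)
#' dplyr::count(sc, ess)
#' @export
ess_region_scan <- function(norms, params, vary = c("mu", "eps_dc"), n = 50,
                            mu = 0, mu_e = 0, eps_dc = 0,
                            max_mu = 0.49, max_rate = 0.99, oracle = FALSE) {
  if (n < 2) stop("grid resolution must be at least 2", call. = FALSE)
  vary <- match.arg(vary, c("mu", "mu_e", "eps_dc"), several.ok = TRUE)
  if (!is.list(norms) || inherits(norms, "social_norm")) norms <- list(norms)
  norms <- lapply(norms, function(x) {
    if (is.character(x)) norm_catalog(x, params) else x
  })
  axis <- function(rate) {
    if (!rate %in% vary) {
      return(switch(rate, mu = mu, mu_e = mu_e, eps_dc = eps_dc))
    }
    seq(0, if (rate == "mu") max_mu else max_rate, length.out = n)
  }
  grid <- tidyr::expand_grid(mu = axis("mu"), mu_e = axis("mu_e"),
                             eps_dc = axis("eps_dc"))
  res <- purrr::map_dfr(norms, function(nrm) {
    label <- nrm$name %||% "norm"
    purrr::pmap_dfr(grid, function(mu, mu_e, eps_dc) {
      err <- error_model(mu = mu, mu_e = mu_e, eps_dc = eps_dc)
      rep <- ess_report(nrm, params, err)
      row <- tibble::tibble(
        norm = label, mu = mu, mu_e = mu_e, eps_dc = eps_dc,
        ess = rep$verdict == "strict ESS", verdict = rep$verdict,
        min_margin = min(rep$margins$margin),
        boundary = (1 - 2 * mu) * (1 - mu_e) * (1 - eps_dc) -
          params$c / params$b)
      if (oracle) {
        row$oracle_strict <-
          brute_force_strict_nash(nrm, params, err)$verdict == "strict"
      }
      row
    })
  })
  class(res) <- c("ess_region_scan", class(res))
  attr(res, "vary") <- vary
  res
}

#' @export
autoplot.ess_region_scan <- function(object, ...) {
  vary <- attr(object, "vary")[1:2]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[vary[1]]],
                                       y = .data[[vary[2]]],
                                       fill = .data$ess)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~norm) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#3366bb",
                                          `FALSE` = "#cc4444"),
                               name = "strict ESS") +
    ggplot2::labs(x = vary[1], y = vary[2])
}

#' Resident-vs-mutant payoff gaps
#'
#' For each resident norm, computes the invasion payoff gap against every
#' deviating deterministic action rule (15 in the two-action game).
#'
#' @param residents A norm, catalog name, or list of either.
#' @param params A [game_params()].
#' @param err An [error_model()].
#' @return A tibble of class `payoff_gap_table`: one row per
#'   (resident, mutant) with `pi_res`, `pi_mut`, `gap`, plus the per-resident
#'   unweighted `mean_gap`.
#' @examples
#' pg <- payoff_gap_table(c("L3", "L6"), game_params(1, 0.2),
#'                        error_model(0.1, 0.1, 0.1))
#' dplyr::distinct(pg, resident, mean_gap)
#' @export
payoff_gap_table <- function(residents, params, err = error_model()) {
  if (!is.list(residents) || inherits(residents, "social_norm")) {
    residents <- as.list(residents)
  }
  residents <- lapply(residents, function(x) {
    if (is.character(x)) norm_catalog(x, params, err) else x
  })
  res <- purrr::map_dfr(residents, function(nrm) {
    bf <- brute_force_strict_nash(nrm, params, err)
    dplyr::mutate(bf$gaps, resident = nrm$name %||% "norm", .before = 1)
  })
  res <- dplyr::mutate(dplyr::group_by(res, .data$resident),
                       mean_gap = mean(.data$gap))
  res <- dplyr::ungroup(res)
  class(res) <- c("payoff_gap_table", class(res))
  res
}

#' @export
autoplot.payoff_gap_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mutant, y = .data$gap,
                                       fill = .data$resident)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mutant action rule (S over GG, GB, BG, BB)",
                  y = "resident payoff - mutant payoff") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Equalizer demonstration
#'
#' Shows that Generous Scoring and Cautious Scoring impose the resident
#' payoff on every mutant: for each resident, the invasion payoffs of the
#' ALLC, ALLD and ADISC deviations (and, with `all_mutants = TRUE`, of all
#' 15 deviating rules).
#'
#' @param params A [game_params()]; defaults to `b = 1`, `c = 0.1`.
#' @param err An [error_model()]; defaults to `mu = 0.01`.
#' @param all_mutants Use all 15 deviating action rules instead of the three
#'   named ones.
#' @return A tibble: one row per (resident, mutant) with payoffs and gap.
#' @export
equalizer_demo <- function(params = game_params(1, 0.1),
                           err = error_model(mu = 0.01),
                           all_mutants = FALSE) {
  residents <- list(norm_catalog("GSCO", params, err),
                    norm_catalog("CautiousScoring", params, err))
  purrr::map_dfr(residents, function(nrm) {
    state <- stationary_state(nrm, err)
    mutants <- if (all_mutants) {
      enumerate_action_rules(exclude = nrm$action)
    } else {
      ars <- catalog_action_rules()[c("ALLC", "ALLD", "ADISC")]
      lapply(ars, function(s) action_rule(s[1], s[2], s[3], s[4]))
    }
    labels <- if (all_mutants) vapply(mutants, rule_label, character(1))
              else names(mutants)
    purrr::map2_dfr(mutants, labels, function(m, lab) {
      dplyr::mutate(invasion_payoffs(nrm, m, params, err, state = state),
                    resident = nrm$name, mutant = lab, .before = 1)
    })
  })
}

#' Export a CESS enumeration to CSV
#'
#' @param tbl The tibble from [enumerate_deterministic_cess()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_cess_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
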