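test_that("the reputation value gap has its known closed-form special cases", {
  # unconditional defection severs payoff from reputation entirely
  for (assess in list(norm_catalog("L6")$assessment,
                      sample_random_norm(seed = 15)$assessment)) {
    alld <- social_norm(action_rule("D", "D", "D", "D"), assess)
    for (err in list(error_model(0.1), error_model(0.3, 0.2, 0.1))) {
      expect_identical(delta_v(alld, game_params(1, 0.5), err)$delta_v, 0)
    }
  }

  # second-order discriminating norms: the gap is exactly the benefit b
  gsco <- norm_catalog("GSCO", game_params(1, 0.1), error_model(mu = 0.01))
  expect_equal(delta_v(gsco, game_params(1, 0.1),
                       error_model(mu = 0.01))$delta_v, 1)
  expect_equal(delta_v(norm_catalog("L6"), game_params(2.5, 1),
                       error_model(0.2, 0.1, 0.3))$delta_v, 2.5)

  # Staying at mu = 0.1: persistence inflates the gap above b
  dv7 <- delta_v(norm_catalog("L7"), game_params(1, 0.8), error_model(0.1))
  expect_equal(dv7$delta_v, 1 / (1 - (1 - dv7$h_star) * 0.8),
               tolerance = 1e-12)
  expect_equal(dv7$delta_v, 1.0961178, tolerance = 1e-6)
})

test_that("generic and leading-eight closed-form gaps agree on an error grid", {
  p <- game_params(1, 0.8)
  grid <- expand.grid(mu = c(0, 0.1, 0.2, 0.3, 0.45),
                      mu_e = c(0, 0.1, 0.3, 0.6, 0.9),
                      eps_dc = c(0, 0.1, 0.3, 0.6, 0.9))
  for (nm in paste0("L", 1:8)) {
    nrm <- norm_catalog(nm)
    for (i in seq_len(nrow(grid))) {
      err <- error_model(grid$mu[i], grid$mu_e[i], grid$eps_dc[i])
      st <- stationary_state(nrm, err)
      expect_equal(delta_v(nrm, p, err, state = st)$delta_v,
                   leading_eight_delta_v(nm, p, err, state = st),
                   tolerance = 1e-12)
    }
  }
})

test_that("Stern Judging's gap never exceeds those of L4, L7 and L8", {
  p <- game_params(1, 0.8)
  grid <- expand.grid(mu = c(0.05, 0.2, 0.4), mu_e = c(0, 0.3, 0.7),
                      eps_dc = c(0, 0.3, 0.7))
  for (i in seq_len(nrow(grid))) {
    err <- error_model(grid$mu[i], grid$mu_e[i], grid$eps_dc[i])
    dv6 <- delta_v(norm_catalog("L6"), p, err)$delta_v
    for (nm in c("L4", "L7", "L8")) {
      expect_lte(dv6, delta_v(norm_catalog(nm), p, err)$delta_v + 1e-12)
    }
    # and L5's gap never exceeds b
    expect_lte(delta_v(norm_catalog("L5"), p, err)$delta_v, p$b + 1e-12)
  }
})

test_that("ESS margins reproduce the exact stability conditions", {
  # always-defect is strict: nothing to gain, cooperation costs c
  rep_alld <- ess_report(norm_catalog("ALLD"), game_params(1, 0.5),
                         error_model(0.1))
  expect_equal(rep_alld$verdict, "strict ESS")
  expect_equal(rep_alld$margins$margin, rep(0.5, 4))

  # Stern Judging: stable iff b/c > 1/((1-2mu)(1-mu_e)(1-eps_dc))
  p <- game_params(1, 0.8)
  expect_equal(ess_report(norm_catalog("L6"), p,
                          error_model(0.05, 0.05, 0.05))$verdict, "strict ESS")
  expect_equal(ess_report(norm_catalog("L6"), p,
                          error_model(0.1, 0.1, 0.1))$verdict, "not ESS")
  expect_equal(l3_l6_threshold(error_model()), 1)
  expect_equal(l3_l6_threshold(error_model(0.1)), 1.25)
  expect_equal(l3_l6_threshold(error_model(0.05, 0.05, 0.05)),
               1 / (0.9 * 0.95 * 0.95))
  # the threshold diverges as any rate approaches its upper bound
  expect_gt(l3_l6_threshold(error_model(mu = 0.4999)), 5000)

  # the verdict flips exactly where the threshold predicts
  for (mu in c(0.02, 0.06, 0.09)) {
    err <- error_model(mu)
    strict <- p$b / p$c > l3_l6_threshold(err)
    for (nm in c("L3", "L6")) {
      expect_equal(is_ess(norm_catalog(nm), p, err), strict,
                   ignore_attr = TRUE)
    }
  }

  # an equalizer sits on the knife edge by construction
  pe <- game_params(1, 0.1); ee <- error_model(0.01)
  expect_equal(ess_report(norm_catalog("GSCO", pe, ee), pe, ee)$verdict,
               "knife-edge")
})

test_that("margins are tidy and glance-able", {
  rep <- ess_report(norm_catalog("L6"), game_params(1, 0.8), error_model(0.05))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4) # one alternative per context in the {C,D} game
  expect_named(td, c("context", "prescribed", "alternative",
                     "assessment_gain", "margin"))
  gl <- glance(rep)
  expect_equal(gl$verdict, "strict ESS")
  expect_equal(gl$min_margin, min(td$margin))
})

test_that("equalizer norms satisfy the fixed-payoff identity, others do not", {
  pe <- game_params(1, 0.1); ee <- error_model(mu = 0.01)
  gsco <- norm_catalog("GSCO", pe, ee)
  expect_true(equalizer_check(gsco, pe, ee)$equalizer)
  cs <- norm_catalog("CautiousScoring", pe, ee)
  expect_true(equalizer_check(cs, pe, ee)$equalizer)

  # Stern Judging is strictly stable there, hence not an equalizer
  chk6 <- equalizer_check(norm_catalog("L6"), pe, ee)
  expect_false(chk6$equalizer)
  expect_gt(min(abs(chk6$residuals$residual)), 1e-3)

  # perturbing the defector assessment breaks the identity
  pert <- gsco$assessment
  pert[paste(contexts(), "D", sep = ".")] <-
    pert[paste(contexts(), "D", sep = ".")] - 0.05
  perturbed <- social_norm(gsco$action,
                           assessment_rule(unclass(pert), actions = c("C", "D")))
  expect_false(equalizer_check(perturbed, pe, ee)$equalizer)
})

test_that("constructed second-order equalizers pass their own check", {
  pe <- game_params(1, 0.1); ee <- error_model(mu = 0.01)
  gap <- equalizer_gap(pe, ee)
  expect_equal(gap, 0.1 / 0.98)

  eq1 <- make_second_order_equalizer(pe, ee) # base levels (1, 1): GSCO
  expect_norms_equal(social_norm(eq1$action, eq1$assessment),
                     social_norm(norm_catalog("GSCO", pe, ee)$action,
                                 norm_catalog("GSCO", pe, ee)$assessment))
  eq2 <- make_second_order_equalizer(pe, ee, base_bad = gap) # Cautious Scoring
  expect_norms_equal(social_norm(eq2$action, eq2$assessment),
                     social_norm(norm_catalog("CautiousScoring", pe, ee)$action,
                                 norm_catalog("CautiousScoring", pe, ee)$assessment))
  for (bases in list(c(1, 1), c(0.9, 0.8), c(1, gap))) {
    eq <- make_second_order_equalizer(pe, ee, bases[1], bases[2])
    expect_true(equalizer_check(eq, pe, ee)$equalizer)
  }

  # infeasible gap: cost too high relative to (1 - 2 mu) b
  expect_error(make_second_order_equalizer(game_params(1, 0.99),
                                           error_model(mu = 0.4)),
               "no feasible")
  expect_error(make_second_order_equalizer(pe, ee, base_good = 0.05),
               "infeasible")
})
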