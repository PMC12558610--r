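test_that("effective assessment folds each error type in the fixed order", {
  r <- assessment_from_vectors(RC = rep(1, 4), RD = rep(0, 4))

  # assessment error alone flips each assignment with probability mu
  e1 <- effective_assessment(r, error_model(mu = 0.1))
  expect_equal(unname(e1[["GG.C"]]), 0.9)
  expect_equal(unname(e1[["GG.D"]]), 0.1)

  # perception error mixes the D column toward the C column
  e2 <- effective_assessment(r, error_model(eps_dc = 0.2))
  expect_equal(unname(e2[["GG.D"]]), 0.2)
  expect_equal(unname(e2[["GG.C"]]), 1)

  # implementation error mixes the C column toward the adjusted D column
  e3 <- effective_assessment(r, error_model(mu_e = 0.25))
  expect_equal(unname(e3[["GG.C"]]), 0.75)
  expect_equal(unname(e3[["GG.D"]]), 0)

  # all rates zero: identity
  e0 <- effective_assessment(r, error_model())
  expect_equal(as.numeric(e0), as.numeric(r))
})

test_that("composed errors reproduce the leading-eight persistence factors", {
  # closed forms for RS(G,B) - RS(B,B) under the prescribed actions
  expected <- list(
    L1 = function(mu, me, ep) me * (1 - ep) * (1 - 2 * mu),
    L2 = function(mu, me, ep) (me - ep - me * ep) * (1 - 2 * mu),
    L3 = function(mu, me, ep) 0,
    L4 = function(mu, me, ep) ep * (1 - 2 * mu),
    L5 = function(mu, me, ep) -ep * (1 - 2 * mu),
    L6 = function(mu, me, ep) 0,
    L7 = function(mu, me, ep) 1 - 2 * mu,
    L8 = function(mu, me, ep) (1 - ep) * (1 - 2 * mu)
  )
  grid <- expand.grid(mu = c(0, 0.1, 0.3), me = c(0, 0.2, 0.5),
                      ep = c(0, 0.3, 0.6))
  for (nm in names(expected)) {
    norm <- norm_catalog(nm)
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      rs <- prescribed_assessment(norm, error_model(g$mu, g$me, g$ep))
      expect_equal(unname(rs[["GB"]] - rs[["BB"]]),
                   expected[[nm]](g$mu, g$me, g$ep), tolerance = 1e-14)
      # donor-side persistence vanishes for all eight
      expect_equal(unname(rs[["GG"]] - rs[["BG"]]), 0, tolerance = 1e-14)
    }
  }
  # spot value: mu = 0.1, mu_e = 0.2, eps_dc = 0.3 gives 0.112 for L1
  rs <- prescribed_assessment(norm_catalog("L1"), error_model(0.1, 0.2, 0.3))
  expect_equal(unname(rs[["GB"]] - rs[["BB"]]), 0.112)
})

test_that("with only mu active every effective entry lies in [mu, 1 - mu]", {
  for (fix in random_norm_panel(25, seed = 11)) {
    mu <- fix$err$mu
    eff <- effective_assessment(fix$norm, error_model(mu = mu))
    expect_true(all(as.numeric(eff) >= mu - 1e-15))
    expect_true(all(as.numeric(eff) <= 1 - mu + 1e-15))
  }
})

test_that("error model rejects out-of-range rates by name", {
  expect_error(error_model(mu = 0.5), "mu")
  expect_error(error_model(mu_e = 1), "mu_e")
  expect_error(error_model(eps_dc = -0.1), "eps_dc")
  expect_silent(error_model(0.49, 0.99, 0.99))
})

test_that("effective game parameters rescale by the implementation rate", {
  expect_equal(unlist(effective_game_params(game_params(1, 0.8),
                                            error_model())[c("b", "c")]),
               c(b = 1, c = 0.8))
  expect_equal(unlist(effective_game_params(game_params(1, 0.8),
                                            error_model(mu_e = 0.5))[c("b", "c")]),
               c(b = 0.5, c = 0.4))
  eff <- effective_game_params(game_params(3, 1, alpha = 0.5, beta = 2),
                               error_model(mu_e = 0.1))
  expect_equal(c(eff$b, eff$c, eff$alpha, eff$beta), c(2.7, 0.9, 0.5, 2))
})

test_that("the catalog reproduces the tabulated norms", {
  l6 <- norm_catalog("L6")
  expect_equal(as.character(l6$action), c("C", "D", "C", "D"))
  expect_equal(
    unname(as.numeric(l6$assessment)),
    c(1, 0, 0, 1, 1, 0, 0, 1)) # (GG.C, GG.D, GB.C, GB.D, BG.C, BG.D, BB.C, BB.D)
  expect_equal(as.character(norm_catalog("Stern Judging")$action),
               as.character(l6$action))

  # every leading-eight norm agrees with the tabulated tibble
  tab <- leading_eight()
  for (i in seq_len(nrow(tab))) {
    nrm <- norm_catalog(tab$name[i])
    for (ctx in contexts()) {
      expect_identical(as.character(nrm$action)[[match(ctx, contexts())]],
                       tab[[paste0("S_", ctx)]][i])
      expect_identical(unname(nrm$assessment[[paste0(ctx, ".C")]]),
                       tab[[paste0("RC_", ctx)]][i])
      expect_identical(unname(nrm$assessment[[paste0(ctx, ".D")]]),
                       tab[[paste0("RD_", ctx)]][i])
    }
  }

  # generous scoring: defectors keep a good image except a c/((1-2mu) b) gap
  g <- norm_catalog("GSCO", game_params(1, 0.1), error_model(mu = 0.01))
  expect_equal(unname(g$assessment[["GG.C"]]), 1)
  expect_equal(unname(g$assessment[["GG.D"]]), 1 - 0.1 / 0.98)
  expect_equal(length(unique(as.numeric(g$assessment)[c(2, 4, 6, 8)])), 1)

  expect_equal(as.character(norm_catalog("ALLD")$action), rep("D", 4))
  expect_error(norm_catalog("nope"), "available")
})

test_that("random norm sampling is seed-reproducible and in range", {
  expect_norms_equal(sample_random_norm(seed = 5), sample_random_norm(seed = 5))
  det <- sample_random_norm(seed = 9, deterministic = TRUE)
  expect_true(all(as.numeric(det$assessment) %in% c(0, 1)))
  withr::with_seed(123, {
    for (i in 1:50) {
      nrm <- sample_random_norm(actions = c("C", "D", "P"))
      expect_true(all(as.numeric(nrm$assessment) >= 0 &
                        as.numeric(nrm$assessment) <= 1))
      expect_length(nrm$assessment, 12)
      expect_true(all(as.character(nrm$action) %in% c("C", "D", "P")))
    }
  })
})

test_that("norm JSON serialization round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  for (nrm in list(sample_random_norm(seed = 3),
                   sample_random_norm(seed = 4, actions = c("C", "D", "P")),
                   norm_catalog("L4"))) {
    write_norm_json(nrm, path)
    back <- read_norm_json(path)
    expect_norms_equal(nrm, back)
  }
  # strict schema: a malformed file is rejected
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(actions = c("C", "D")), bad, auto_unbox = TRUE)
  expect_error(read_norm_json(bad), "must contain")
})

test_that("rule constructors validate their inputs", {
  expect_error(action_rule("C", "D", "C", "Q"), "action set")
  expect_error(assessment_rule(GG.C = 1.2, GG.D = 0, GB.C = 0, GB.D = 0,
                               BG.C = 0, BG.D = 0, BB.C = 0, BB.D = 0),
               "\\[0, 1\\]")
  expect_error(assessment_from_vectors(RC = rep(1, 4), RD = rep(0, 3)))
  expect_error(game_params(1, -1), "c > 0")
  expect_error(game_params(1, 0.5, alpha = 1), "both")
})

test_that("relabeling mirrors contexts and inverts assessments", {
  nrm <- sample_random_norm(seed = 77)
  rel <- relabel_norm(nrm)
  expect_equal(unname(as.character(rel$action)),
               unname(as.character(nrm$action)[c(4, 3, 2, 1)]))
  expect_equal(unname(rel$assessment[["GG.C"]]),
               1 - unname(nrm$assessment[["BB.C"]]))
  expect_norms_equal(relabel_norm(rel), nrm)
})
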