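# Shared fixtures: seeded panels of random norms and small reference
# calculations used as independent oracles.

# A reproducible panel of random stochastic norms with error models, for
# property-style tests.
random_norm_panel <- function(n, seed = 20260924, mu_range = c(0.01, 0.3),
                              deterministic = FALSE) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(norm = sample_random_norm(deterministic = deterministic),
           err = error_model(mu = stats::runif(1, mu_range[1], mu_range[2])),
           params = game_params(b = 1 + stats::runif(1),
                                c = stats::runif(1, 0.1, 0.9)))
    })
  })
}

# Independent root of the drift equation, by bisection on the drift itself
# (never via the quadratic formula the package uses).
bisect_h_star <- function(rs, tol = 1e-12) {
  f <- function(h) reputation_drift(h, rs)
  lo <- 0; hi <- 1
  if (f(0) < 0) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Forward Euler iteration of the drift, an independent convergence oracle.
iterate_h <- function(rs, h0, step = 0.1, n = 20000) {
  h <- h0
  for (i in seq_len(n)) h <- h + step * reputation_drift(h, rs)
  h
}

expect_norms_equal <- function(a, b) {
  expect_equal(as.character(a$action), as.character(b$action))
  expect_equal(as.numeric(a$assessment), as.numeric(b$assessment))
  expect_equal(names(a$assessment), names(b$assessment))
}
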