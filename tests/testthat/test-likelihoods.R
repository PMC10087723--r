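test_that("plain likelihood matches direct density evaluation", {
  one <- study_data(0, 1, scale = "raw")
  expect_equal(loglik_plain(one, 0, 0), log(dnorm(0)), tolerance = 1e-12)

  d2 <- study_data(c(0.2, 0.4), c(0.1, 0.2), scale = "raw")
  expect_equal(loglik_plain(d2, 0.3, 0.05),
               sum(dnorm(c(0.2, 0.4), 0.3, sqrt(c(0.1, 0.2)^2 + 0.05^2),
                         log = TRUE)),
               tolerance = 1e-12)
  # tau = 0 reduces to the fixed-effect formula
  expect_equal(loglik_plain(d2, 0.1, 0),
               sum(dnorm(c(0.2, 0.4), 0.1, c(0.1, 0.2), log = TRUE)))
})

test_that("interval probabilities are correct and sum to one", {
  wf1 <- weight_fn("one", 0.05)
  expect_equal(interval_probs(0, 0, 1, wf1), c(0.05, 0.95), tolerance = 1e-10)
  wf2 <- weight_fn("two", 0.05)
  expect_equal(interval_probs(0, 0, 1, wf2), c(0.05, 0.95), tolerance = 1e-10)
  # shifted mean: recomputed from the normal CDF at the shifted threshold
  expect_equal(interval_probs(1, 0, 1, wf1),
               c(1 - pnorm(qnorm(0.95) - 1), pnorm(qnorm(0.95) - 1)),
               tolerance = 1e-10)
  # negative direction mirrors
  expect_equal(interval_probs(-1, 0, 1, wf1, direction = "negative"),
               interval_probs(1, 0, 1, wf1), tolerance = 1e-12)

  set.seed(4)
  for (wf in default_weight_functions()) {
    for (i in 1:5) {
      p <- interval_probs(rnorm(1), abs(rnorm(1, 0, 0.3)), runif(1, 0.05, 2), wf)
      expect_equal(sum(p), 1, tolerance = 1e-10)
      expect_true(all(p >= 0))
    }
  }
})

test_that("selection likelihood matches the weighted-density formula", {
  one <- study_data(0, 1, scale = "raw")
  wf <- weight_fn("two", 0.05)
  # hand evaluation: log(0.5 * dnorm(0) / (1*0.05 + 0.5*0.95))
  expect_equal(loglik_selection(one, 0, 0, c(1, 0.5), wf),
               log(0.5 * dnorm(0) / 0.525), tolerance = 1e-10)
  expect_equal(log(0.3799450), loglik_selection(one, 0, 0, c(1, 0.5), wf),
               tolerance = 1e-6)

  # all weights one: reduces exactly to the plain likelihood
  dat <- tiny_data()
  for (wf in default_weight_functions()) {
    expect_equal(loglik_selection(dat, 0.1, 0.05, rep(1, wf$J), wf),
                 loglik_plain(dat, 0.1, 0.05), tolerance = 1e-12)
  }

  # zero weight on an observed interval: impossible datum
  wf2s <- weight_fn("two", 0.05)
  expect_identical(loglik_selection(one, 0, 0, c(1, 0), wf2s), -Inf)

  # continuity as omega -> 1
  wf3 <- weight_fn("one", c(0.025, 0.05))
  near1 <- loglik_selection(dat, 0.1, 0.05, c(1, 1 - 1e-8, 1 - 1e-8), wf3)
  expect_equal(near1, loglik_plain(dat, 0.1, 0.05), tolerance = 1e-6)
})

test_that("selection density is properly normalised over y", {
  set.seed(8)
  wf <- weight_fn("one", c(0.05, 0.50))
  mu <- 0.2; tau <- 0.1; omega <- c(1, 0.4, 0.15); se <- 0.5
  f <- function(y) vapply(y, function(yy)
    exp(loglik_selection(study_data(yy, se, scale = "raw"), mu, tau, omega, wf)), 0)
  total <- integrate(f, -6, 6, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("likelihoods are invariant to study ordering", {
  dat <- tiny_data()
  perm <- study_data(dat$y[5:1], dat$se[5:1], scale = "raw")
  wf <- weight_fn("one", c(0.025, 0.05))
  expect_equal(loglik_plain(dat, 0.2, 0.1), loglik_plain(perm, 0.2, 0.1))
  expect_equal(loglik_selection(dat, 0.2, 0.1, c(1, 0.5, 0.2), wf),
               loglik_selection(perm, 0.2, 0.1, c(1, 0.5, 0.2), wf))
  expect_equal(loglik_regression(dat, 0.1, 0.05, 0.5, "pet"),
               loglik_regression(perm, 0.1, 0.05, 0.5, "pet"))
})

test_that("PET/PEESE regression likelihoods are correct", {
  dat <- tiny_data()
  expect_equal(loglik_regression(dat, 0.1, 0.05, 0, "pet"),
               loglik_plain(dat, 0.1, 0.05), tolerance = 1e-12)
  # mean matches datum exactly: density is dnorm(0, sd = 0.1) scaled
  one <- study_data(0.3, 0.1, scale = "raw")
  expect_equal(loglik_regression(one, 0.1, 0, 2, "pet"),
               log(dnorm(0.3, 0.3, 0.1)), tolerance = 1e-12)
  expect_equal(log(3.989423), loglik_regression(one, 0.1, 0, 2, "pet"),
               tolerance = 1e-6)
  # se = 1 makes PET and PEESE coincide
  u <- study_data(0.25, 1, scale = "raw")
  expect_equal(loglik_regression(u, 0.1, 0.2, 0.7, "pet"),
               loglik_regression(u, 0.1, 0.2, 0.7, "peese"))
})

test_that("log_prior evaluates the component densities", {
  ens <- raw_ensemble()
  m36 <- ens[[36]]  # mu ~ N(0,1), tau ~ IG(1, 0.15), PEESE slope
  expect_equal(log_prior(list(mu = 0), m36), log(1 / sqrt(2 * pi)),
               tolerance = 1e-10)
  expect_equal(log_prior(list(tau = 0.15), m36), log((1 / 0.15) * exp(-1)),
               tolerance = 1e-10)
  expect_identical(log_prior(list(b = -0.1), m36), -Inf)
  # half-Cauchy integrates the truncation renormalisation (x2)
  m_pet <- Filter(function(m) m$bias$type == "pet", ens)[[1]]
  expect_equal(log_prior(list(b = 0.5), m_pet),
               log(2 * dcauchy(0.5, 0, 1)), tolerance = 1e-10)
  # flat Dirichlet over the simplex
  m_sel <- Filter(function(m) m$bias$type == "selection" && m$bias$wf$J == 3, ens)[[1]]
  expect_equal(log_prior(list(eta = c(0.2, 0.3, 0.5)), m_sel), lgamma(3))
  expect_identical(log_prior(list(eta = c(0.5, 0.1)), m_sel), -Inf)
})
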