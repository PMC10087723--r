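test_that("conjugate posterior is recovered by the sampler", {
  # single study y = 0.2, se = 0.1, mu ~ N(0, 1), fixed effect:
  # posterior is N(mu_hat, v), v = (1 + 1/0.01)^-1, mu_hat = v * 0.2/0.01
  dat <- study_data(0.2, 0.1, scale = "raw")
  spec <- Filter(function(m) m$effect$family != "point" &&
                   m$tau$family == "point" && m$bias$type == "none",
                 raw_ensemble())[[1]]
  v <- 1 / (1 + 1 / 0.01)
  mu_hat <- v * (0.2 / 0.01)
  set.seed(2)
  draws <- sample_posterior(spec, dat, fast_settings())
  mu <- draws$theta[, "mu"]
  mcse <- sd(mu) / sqrt(effective_sample_size(list(mu)))
  expect_lt(abs(mean(mu) - mu_hat), 3 * mcse + 1e-6)
  expect_equal(var(mu), v, tolerance = 0.15)
  expect_true(all(draws$diagnostics$rhat < 1.05))
})

test_that("parameter-free models return exact marginal likelihoods", {
  dat <- study_data(c(0, 0), c(1, 1), scale = "raw")
  spec <- raw_ensemble()[[1]]
  expect_identical(n_free_params(spec), 0L)
  set.seed(1)
  dr <- sample_posterior(spec, dat, fast_settings())
  expect_identical(nrow(dr$theta), 0L)
  expect_true(dr$converged)
  ml <- log_marginal_likelihood(spec, dat, dr, fast_settings())
  expect_equal(ml$logml, 2 * log(dnorm(0)), tolerance = 1e-12)
  expect_equal(ml$logml, -1.8378771, tolerance = 1e-6)
  expect_identical(ml$se, 0)
  expect_equal(as.numeric(quadrature_oracle(spec, dat)), 2 * log(dnorm(0)),
               tolerance = 1e-12)
})

test_that("bridge and quadrature agree with the conjugate closed form", {
  dat <- tiny_data()
  spec <- Filter(function(m) m$effect$family != "point" &&
                   m$tau$family == "point" && m$bias$type == "none",
                 raw_ensemble())[[1]]
  K <- nrow(dat)
  V <- diag(dat$se^2) + matrix(1, K, K)  # prior sd 1 on mu
  closed <- -0.5 * (K * log(2 * pi) + as.numeric(determinant(V)$modulus) +
                      sum(dat$y * solve(V, dat$y)))
  fm <- fit_model(spec, dat, oracle_settings(seed = 3))
  expect_lt(abs(fm$log_marglik - closed), 0.01)
  qo <- quadrature_oracle(spec, dat)
  expect_lt(abs(as.numeric(qo) - closed), 1e-5)
})

test_that("same seed gives identical draws and marginal likelihoods", {
  dat <- tiny_data()
  spec <- Filter(function(m) m$bias$type == "pet" &&
                   m$effect$family != "point", raw_ensemble())[[1]]
  f1 <- fit_model(spec, dat, fast_settings(seed = 123))
  f2 <- fit_model(spec, dat, fast_settings(seed = 123))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$log_marglik, f2$log_marglik)
  f3 <- fit_model(spec, dat, fast_settings(seed = 124))
  expect_false(identical(f1$theta, f3$theta))
})

test_that("quadrature oracle rejects high-dimensional models", {
  dat <- tiny_data()
  spec <- Filter(function(m) m$bias$type == "selection" && m$bias$wf$J == 4 &&
                   m$effect$family != "point" && m$tau$family != "point",
                 raw_ensemble())[[1]]
  expect_identical(n_free_params(spec), 5L)
  expect_error(quadrature_oracle(spec, dat), "unsupported-dimension")
})

test_that("selection model with fixed weights matches reduced-dimension quadrature", {
  # a 2-free-parameter selection model (mu, tau; eta fixed by J = 2 with a
  # point mass is not representable, so use the J = 2 model with only the
  # single eta coordinate free and mu, tau at their null point masses)
  dat <- tiny_data()
  spec <- Filter(function(m) m$bias$type == "selection" && m$bias$wf$J == 2 &&
                   m$effect$family == "point" && m$tau$family == "point",
                 raw_ensemble())[[1]]
  expect_identical(n_free_params(spec), 1L)
  qo <- quadrature_oracle(spec, dat)
  # independent 1-D integration over omega_2 on the natural scale:
  # eta ~ Dirichlet(1,1) => omega_2 = eta_2 ~ Uniform(0,1)
  wf <- spec$bias$wf
  f <- function(w2) vapply(w2, function(w)
    exp(loglik_selection(dat, 0, 0, c(1, w), wf)), 0)
  direct <- log(integrate(f, 0, 1, rel.tol = 1e-10)$value)
  expect_equal(as.numeric(qo), direct, tolerance = 1e-4)
})

test_that("random-effects posterior mean approaches DL as the prior widens", {
  set.seed(5)
  cfg <- sim_config(true_mu = 0.3, true_tau = 0.15, K = 25, n_range = c(40, 120))
  dat <- simulate_meta_analysis(cfg)
  dl <- dersimonian_laird(dat)
  spec <- Filter(function(m) m$effect$family != "point" &&
                   m$tau$family != "point" && m$bias$type == "none",
                 build_ensemble(
                   effect_prior = prior_spec("normal", mean = 0, sd = 10,
                                             declared_scale = "analysis"),
                   tau_prior = prior_spec("invgamma", shape = 1, scale = 0.15,
                                          declared_scale = "analysis"),
                   weight_fns = NULL, pet_prior = NULL, peese_prior = NULL))[[1]]
  fm <- fit_model(spec, dat, fast_settings(seed = 6), analysis = "direct")
  expect_equal(mean(fm$theta[, "mu"]), dl$mu, tolerance = 0.05)
})
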