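# printed posterior model probabilities of the 36-model worked example
# (used as fixed inputs to the aggregation arithmetic)
.example_post <- c(0.000, 0.000, 0.000, 0.012, 0.034, 0.001, 0.004, 0.281, 0.254,
                   0.000, 0.000, 0.000, 0.014, 0.020, 0.006, 0.010, 0.021, 0.017,
                   0.051, 0.007, 0.031, 0.030, 0.035, 0.018, 0.022, 0.047, 0.046,
                   0.007, 0.001, 0.003, 0.005, 0.005, 0.003, 0.004, 0.004, 0.004)

test_that("posterior model probabilities follow Bayes' rule", {
  expect_equal(posterior_model_probs(c(-3, -3, -3), c(0.2, 0.5, 0.3)),
               c(0.2, 0.5, 0.3))
  # log-marglik difference of ln 3 at equal priors gives odds 3:1
  expect_equal(posterior_model_probs(c(log(3), 0), c(0.5, 0.5)), c(0.75, 0.25))
  # invariant to adding a constant to all log margliks
  lm <- c(-5, -2, -9)
  pri <- c(0.25, 0.5, 0.25)
  expect_equal(posterior_model_probs(lm, pri),
               posterior_model_probs(lm + 1234.5, pri), tolerance = 1e-12)
  expect_error(posterior_model_probs(c(-Inf, -Inf), c(0.5, 0.5)),
               "degenerate-ensemble")
  expect_error(posterior_model_probs(c(0, 0), c(0.7, 0.7)), "invalid-input")
})

test_that("inclusion Bayes factors reproduce the printed ensemble numbers", {
  pri <- build_ensemble()
  pri <- vapply(pri, `[[`, 0, "prior_prob")
  post <- .example_post
  # effect inclusion: models 19-36 vs 1-18 (printed value 0.479; 0.477
  # after 3-decimal rounding of the table column)
  expect_equal(inclusion_bf(pri, post, 19:36), 0.477, tolerance = 0.01)
  # selection vs PET-PEESE restricted comparison (printed 0.397)
  sel <- c(2:7, 11:16, 20:25, 29:34)
  pp <- c(8, 9, 17, 18, 26, 27, 35, 36)
  keep <- c(sel, pp)
  bf <- inclusion_bf(pri[keep] / sum(pri[keep]), post[keep] / sum(post[keep]),
                     seq_along(sel))
  expect_equal(bf, 0.397, tolerance = 0.015)

  # posterior = prior gives BF 1; complement inverts exactly
  expect_equal(inclusion_bf(pri, pri, 19:36), 1)
  expect_equal(inclusion_bf(pri, post, 19:36) * inclusion_bf(pri, post, 1:18),
               1, tolerance = 1e-12)
  expect_error(inclusion_bf(pri, post, integer(0)), "invalid-subset")
  expect_error(inclusion_bf(pri, post, 1:36), "invalid-subset")
})

test_that("evidence categories use inclusive 1/10 and 10 boundaries", {
  expect_identical(evidence_category(1), "undecided")
  expect_identical(evidence_category(10), "evidence_presence")
  expect_identical(evidence_category(0.1), "evidence_absence")
  expect_identical(evidence_category(0.05), "evidence_absence")
  expect_identical(evidence_category(c(0.5, 30)),
                   c("undecided", "evidence_presence"))
  expect_error(evidence_category(-1), "invalid-input")
  expect_identical(unname(decisions_from_bf(c(0.01, 1, 100))),
                   c("null", "undecided", "effect"))
})

test_that("mixture summaries handle spike, slab, and their combination", {
  # pure spike
  mix <- structure(list(parameter = "mu", spike_weight = 1, spike_value = 0,
                        draws = numeric(0), weights = numeric(0)),
                   class = "bma_mixture")
  s <- mixture_summary(mix)
  expect_equal(s$mean, 0)
  expect_equal(s$ci, c(0, 0))

  # spike 0.6 + tight slab at 0.1 with weight 0.4: mean 0.04
  mix2 <- structure(list(parameter = "mu", spike_weight = 0.6, spike_value = 0,
                         draws = rep(0.1, 4000),
                         weights = rep(0.4 / 4000, 4000)),
                    class = "bma_mixture")
  expect_equal(mixture_summary(mix2)$mean, 0.04, tolerance = 1e-10)

  # 50/50 spike + Uniform(1, 2) slab: lower CI bound is the spike
  set.seed(1)
  u <- runif(20000, 1, 2)
  mix3 <- structure(list(parameter = "mu", spike_weight = 0.5, spike_value = 0,
                         draws = u, weights = rep(0.5 / 20000, 20000)),
                    class = "bma_mixture")
  s3 <- mixture_summary(mix3)
  expect_equal(s3$ci[1], 0)
  expect_equal(s3$ci[2], 1.95, tolerance = 0.01)
  expect_equal(s3$mean, 0.75, tolerance = 0.01)
})

test_that("a single-model ensemble reproduces that model's posterior", {
  dat <- tiny_data()
  spec <- Filter(function(m) m$effect$family != "point" &&
                   m$tau$family == "point" && m$bias$type == "none",
                 raw_ensemble())[[1]]
  fm <- fit_model(spec, dat, fast_settings(seed = 9))
  mix <- model_averaged_posterior(list(fm), 1, "mu")
  expect_equal(mix$spike_weight, 0)
  s <- mixture_summary(mix)
  expect_equal(s$mean, mean(fm$theta[, "mu"]), tolerance = 1e-10)
  expect_equal(s$ci, unname(quantile(fm$theta[, "mu"], c(0.025, 0.975),
                                     type = 1)),
               tolerance = 1e-3)
})

test_that("aggregation invariants hold on a small fitted ensemble", {
  dat <- tiny_data()
  ens <- raw_ensemble(weight_fns = list(weight_fn("one", 0.05)))
  fits <- lapply(ens, fit_model, data = dat, settings = fast_settings(seed = 31))
  fit <- aggregate_ensemble(fits, ens, analysis = "direct")
  expect_equal(sum(fit$posterior_probs), 1, tolerance = 1e-10)
  expect_true(all(fit$per_model_bf > 0))
  # model-averaged mean lies in the convex hull of per-model means
  means <- vapply(seq_along(fits), function(i) {
    if (ens[[i]]$effect$family == "point") 0 else mean(fits[[i]]$theta[, "mu"])
  }, 0)
  expect_gte(fit$mu$mean, min(means) - 1e-9)
  expect_lte(fit$mu$mean, max(means) + 1e-9)
  # averaged weight function is 1 at the origin-side interval and monotone
  awf <- averaged_weight_function(fit, p_grid = c(0.01, 0.2, 0.8))
  expect_true(all(awf$mean <= 1 + 1e-9))
  expect_true(all(diff(awf$mean) <= 1e-9))
})

test_that("zero bias mass reduces to spike-and-slab meta-analysis", {
  dat <- tiny_data()
  plain <- build_ensemble(
    effect_prior = prior_spec("normal", mean = 0, sd = 1, declared_scale = "analysis"),
    tau_prior = prior_spec("invgamma", shape = 1, scale = 0.15, declared_scale = "analysis"),
    weight_fns = NULL, pet_prior = NULL, peese_prior = NULL)
  fits <- lapply(plain, fit_model, data = dat, settings = fast_settings(seed = 17))
  fit <- aggregate_ensemble(fits, plain, analysis = "direct")
  # manual two-by-two spike/slab aggregation from the same margliks
  lm <- vapply(fits, `[[`, 0, "log_marglik")
  post <- posterior_model_probs(lm, rep(0.25, 4))
  bf10 <- (sum(post[3:4]) / sum(post[1:2])) / 1
  expect_equal(fit$bf_effect, bf10, tolerance = 1e-10)
  expect_true(is.na(fit$bf_bias))
})
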