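test_that("the six default weight functions are as specified", {
  wfs <- default_weight_functions()
  expect_length(wfs, 6)
  sided <- vapply(wfs, `[[`, "", "sidedness")
  expect_identical(sum(sided == "two"), 2L)
  expect_identical(sum(sided == "one"), 4L)
  expect_identical(wfs[[1]]$cutoffs, 0.05)
  expect_identical(wfs[[2]]$cutoffs, c(0.05, 0.10))
  expect_identical(wfs[[4]]$cutoffs, c(0.025, 0.05))
  expect_identical(wfs[[6]]$cutoffs, c(0.025, 0.05, 0.50))
  expect_identical(wfs[[6]]$J, 4L)
  expect_identical(wfs[[1]]$J, 2L)
  expect_error(weight_fn("one", c(0.05, 0.05)), "strictly increasing")
  expect_error(weight_fn("one", c(0, 0.05)), "invalid-input")
})

test_that("default ensemble has 36 models with the Table-1 prior masses", {
  ens <- build_ensemble()
  expect_length(ens, 36)
  type <- vapply(ens, function(m) m$bias$type, "")
  expect_identical(sum(type == "none"), 4L)
  expect_identical(sum(type == "selection"), 24L)
  expect_identical(sum(type %in% c("pet", "peese")), 8L)
  pri <- vapply(ens, `[[`, 0, "prior_prob")
  expect_equal(unique(pri[type == "none"]), 0.125)
  expect_equal(unique(pri[type == "selection"]), 0.25 / 24)
  expect_equal(unique(pri[type %in% c("pet", "peese")]), 0.03125)
  expect_equal(sum(pri), 1, tolerance = 1e-12)
  expect_identical(vapply(ens, `[[`, 0L, "id"), 1:36)

  # ordering: null-effect block first, then by heterogeneity, bias order
  # none, two-sided, one-sided, PET, PEESE within each block of 9
  expect_true(all(vapply(ens[1:18], function(m) m$effect$family == "point", TRUE)))
  expect_true(all(vapply(ens[19:36], function(m) m$effect$family == "normal", TRUE)))
  expect_identical(type[1:9],
                   c("none", rep("selection", 6), "pet", "peese"))
  expect_true(all(vapply(ens[1:9], function(m) m$tau$family == "point", TRUE)))
  expect_true(all(vapply(ens[10:18], function(m) m$tau$family == "invgamma", TRUE)))
})

test_that("reduced ensembles count and weight models correctly", {
  sel <- build_ensemble(pet_prior = NULL, peese_prior = NULL)
  expect_length(sel, 28)  # 6*4 + 4
  pri <- vapply(sel, `[[`, 0, "prior_prob")
  type <- vapply(sel, function(m) m$bias$type, "")
  expect_equal(sum(pri), 1, tolerance = 1e-12)
  expect_equal(sum(pri[type == "none"]), 0.5)       # bias-adjusted keep 0.5
  expect_equal(unique(pri[type == "selection"]), 0.5 / 24)

  pp <- build_ensemble(weight_fns = NULL)
  expect_length(pp, 12)
  expect_equal(sum(vapply(pp, `[[`, 0, "prior_prob")), 1, tolerance = 1e-12)

  plain <- build_ensemble(weight_fns = NULL, pet_prior = NULL, peese_prior = NULL)
  expect_length(plain, 4)
  expect_equal(unique(vapply(plain, `[[`, 0, "prior_prob")), 0.25)
})

test_that("cum_dirichlet_weights produces monotone weights with omega_1 = 1", {
  expect_equal(cum_dirichlet_weights(c(0.3, 0.7)), c(1.0, 0.7))
  expect_equal(cum_dirichlet_weights(c(0.2, 0.3, 0.5)), c(1.0, 0.8, 0.5))
  expect_error(cum_dirichlet_weights(c(0.2, 0.2)), "invalid-input")
  expect_error(cum_dirichlet_weights(c(-0.1, 1.1)), "invalid-input")

  set.seed(11)
  for (J in 2:4) {
    g <- matrix(stats::rgamma(200 * J, 1), 200, J)
    eta <- g / rowSums(g)
    om <- t(apply(eta, 1, cum_dirichlet_weights))
    expect_equal(om[, 1], rep(1, 200))
    expect_true(all(om >= -1e-12 & om <= 1 + 1e-12))
    expect_true(all(apply(om, 1, function(w) all(diff(w) <= 1e-12))))
  }
})

test_that("omega_2 under Dirichlet(1,1) is uniform (Monte-Carlo KS)", {
  set.seed(99)
  g <- matrix(stats::rgamma(2e5, 1), 1e5, 2)
  eta <- g / rowSums(g)
  omega2 <- eta[, 2]  # cumulative weight of the least significant interval
  ks <- suppressWarnings(stats::ks.test(omega2, "punif"))
  expect_gt(ks$p.value, 1e-4)
})
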