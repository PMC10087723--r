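# Shared fixtures: all synthetic data are built in code at test time.

# fast but adequate sampler settings for unit tests
fast_settings <- function(seed = 1, ...) {
  mcmc_settings(chains = 2, iterations = 1500, burnin = 500, seed = seed, ...)
}

# settings strong enough for marginal-likelihood comparisons
oracle_settings <- function(seed = 1) {
  mcmc_settings(chains = 4, iterations = 8000, burnin = 2000, seed = seed,
                max_bridge_draws = 8000)
}

# a small fixed study set on a generic scale
tiny_data <- function() {
  study_data(y = c(0.2, 0.4, -0.1, 0.3, 0.15),
             se = c(0.1, 0.2, 0.15, 0.12, 0.3), scale = "raw")
}

# default ensemble with priors declared directly on the analysis scale,
# so no d-to-z machinery is involved
raw_ensemble <- function(...) {
  build_ensemble(
    effect_prior = prior_spec("normal", mean = 0, sd = 1, declared_scale = "analysis"),
    tau_prior = prior_spec("invgamma", shape = 1, scale = 0.15, declared_scale = "analysis"),
    pet_prior = prior_spec("cauchy_plus", scale = 1, declared_scale = "analysis"),
    peese_prior = prior_spec("cauchy_plus", scale = 5, declared_scale = "analysis"),
    ...)
}

bem_data <- function() {
  read_studies(system.file("extdata", "bem2011_reconstructed.csv", package = "bmapb"),
               scale = "cohens_d")
}

# reallocate prior mass over a subset of fitted models (selection-only or
# PET-PEESE-only views of a fitted 36-model ensemble, avoiding a refit)
subensemble_summary <- function(fit, types) {
  ens <- fit$ensemble
  idx <- which(vapply(ens, function(m) m$bias$type %in% c("none", types), TRUE))
  n_sel <- sum(vapply(ens[idx], function(m) m$bias$type == "selection", TRUE))
  n_reg <- sum(vapply(ens[idx], function(m) m$bias$type %in% c("pet", "peese"), TRUE))
  # class masses 0.5 (no bias) / 0.5 (bias-adjusted), uniform within class
  pri <- vapply(ens[idx], function(m) {
    if (m$bias$type == "none") 0.5 / 4 else 0.5 / (n_sel + n_reg)
  }, 0)
  post <- posterior_model_probs(fit$log_margliks[idx], pri)
  eff <- which(vapply(ens[idx], function(m) m$effect$family != "point", TRUE))
  het <- which(vapply(ens[idx], function(m) m$tau$family != "point", TRUE))
  mix <- model_averaged_posterior(fit$models[idx], post, "mu")
  s <- mixture_summary(mix, transform = function(z) 2 * sinh(z))
  list(bf10 = inclusion_bf(pri, post, eff),
       bf_rf = inclusion_bf(pri, post, het),
       mu = s$mean, ci = s$ci)
}
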