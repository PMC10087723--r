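#' Posterior model probabilities
#'
#' Bayes' rule on the model level: `p_i` proportional to
#' `prior_i * exp(log_marglik_i)`, evaluated through log-sum-exp.
#'
#' @param log_margliks Vector of log marginal likelihoods.
#' @param prior_probs Prior model probabilities (summing to 1).
#' @return Posterior probabilities summing to 1.
#' @export
posterior_model_probs <- function(log_margliks, prior_probs) {
  stopifnot(length(log_margliks) == length(prior_probs))
  if (any(prior_probs < 0) || abs(sum(prior_probs) - 1) > 1e-8)
    stop("invalid-input: prior probabilities must sum to 1", call. = FALSE)
  lw <- log(prior_probs) + log_margliks
  if (!any(is.finite(lw)))
    stop("degenerate-ensemble: all model weights are zero", call. = FALSE)
  mx <- max(lw[is.finite(lw)])
  w <- exp(lw - mx)
  w / sum(w)
}

#' Inclusion Bayes factor
#'
#' Change from prior to posterior odds for a set of models against its
#' complement within the ensemble.
#'
#' @param prior_probs,posterior_probs Aligned probability vectors.
#' @param subset Indices of the models whose inclusion is assessed.
#' @return Scalar Bayes factor.
#' @export
inclusion_bf <- function(prior_probs, posterior_probs, subset) {
  n <- length(prior_probs)
  subset <- unique(as.integer(subset))
  if (length(subset) == 0 || length(subset) >= n ||
      any(subset < 1) || any(subset > n))
    stop("invalid-subset: need a non-empty proper subset of models", call. = FALSE)
  post_in <- sum(posterior_probs[subset])
  post_out <- sum(posterior_probs[-subset])
  prior_in <- sum(prior_probs[subset])
  prior_out <- sum(prior_probs[-subset])
  (post_in / post_out) / (prior_in / prior_out)
}

#' Categorise a Bayes factor
#'
#' Three-way evidence call with an explicit undecided band: `BF <= lower`
#' is evidence of absence, `BF >= upper` evidence of presence (boundaries
#' inclusive), anything in between undecided.
#'
#' @param bf Bayes factor(s), positive.
#' @param lower,upper Band limits (defaults 1/10 and 10).
#' @return Character vector in
#'   `{"evidence_absence", "undecided", "evidence_presence"}`.
#' @export
evidence_category <- function(bf, lower = 1 / 10, upper = 10) {
  if (any(!is.finite(bf) & !is.infinite(bf)) || any(bf <= 0, na.rm = TRUE))
    stop("invalid-input: Bayes factors must be positive", call. = FALSE)
  ifelse(bf <= lower, "evidence_absence",
         ifelse(bf >= upper, "evidence_presence", "undecided"))
}

# weighted type-1 (inverse CDF) quantile
.wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], 0)
}

#' Model-averaged posterior mixture
#'
#' Combines per-model posteriors into the spike-and-slab mixture of the
#' ensemble: models whose prior pins the parameter (point mass) contribute
#' a spike, the rest contribute their posterior draws weighted by posterior
#' model probability.
#'
#' @param fitted List of `fitted_model` objects.
#' @param posterior_probs Aligned posterior model probabilities.
#' @param parameter `"mu"` or `"tau"`.
#' @return An object of class `bma_mixture` supporting [mixture_summary()].
#' @export
model_averaged_posterior <- function(fitted, posterior_probs,
                                     parameter = c("mu", "tau")) {
  parameter <- match.arg(parameter)
  stopifnot(length(fitted) == length(posterior_probs))
  spike_weight <- 0
  draws <- numeric(0)
  weights <- numeric(0)
  for (i in seq_along(fitted)) {
    f <- fitted[[i]]
    is_point <- switch(parameter,
                       mu = f$spec$effect$family == "point",
                       tau = f$spec$tau$family == "point")
    if (is_point) {
      spike_weight <- spike_weight + posterior_probs[i]
    } else {
      x <- f$theta[, parameter]
      draws <- c(draws, x)
      weights <- c(weights, rep(posterior_probs[i] / length(x), length(x)))
    }
  }
  structure(list(parameter = parameter, spike_weight = spike_weight,
                 spike_value = 0, draws = draws, weights = weights),
            class = "bma_mixture")
}

#' Summarise a model-averaged mixture
#'
#' Mean and central credible interval of a spike-and-slab mixture; the
#' interval quantiles include the spike, so an endpoint can be exactly the
#' spike value.
#'
#' @param mix A `bma_mixture`.
#' @param level Credible level (default 0.95).
#' @param transform Optional monotone map applied to the draws (and spike)
#'   before summarising, e.g. the Fisher z to Cohen's d back-transform.
#' @return List with `mean`, `ci` (length-2), `spike_weight`.
#' @export
mixture_summary <- function(mix, level = 0.95, transform = identity) {
  a <- (1 - level) / 2
  sv <- transform(mix$spike_value)
  if (length(mix$draws) == 0) {
    return(list(mean = sv, ci = c(sv, sv), spike_weight = mix$spike_weight))
  }
  x <- c(sv, transform(mix$draws))
  w <- c(mix$spike_weight, mix$weights)
  list(mean = sum(w * x) / sum(w),
       ci = .wquantile(x, w, c(a, 1 - a)),
       spike_weight = mix$spike_weight)
}

#' @export
print.bma_mixture <- function(x, ...) {
  s <- mixture_summary(x)
  cat(sprintf("model-averaged posterior of %s: spike weight %.3f, mean %.4f, 95%% CI [%.4f, %.4f]\n",
              x$parameter, x$spike_weight, s$mean, s$ci[1], s$ci[2]))
  invisible(x)
}

#' Model-averaged weight function
#'
#' Posterior mean (and credible band) of the publication probability
#' omega(p) over a grid of p-values, averaged over the whole ensemble.
#' Models without a selection component (no-bias, PET, PEESE) enter with
#' the constant weight function omega = 1.
#'
#' @param fit An `ensemble_fit` from [fit_ensemble()].
#' @param p_grid Grid of p-values.
#' @param level Credible level of the band.
#' @return Data frame with columns `p`, `mean`, `lower`, `upper`.
#' @export
averaged_weight_function <- function(fit, p_grid = seq(0.001, 0.999, length.out = 199),
                                     level = 0.95) {
  probs <- fit$posterior_probs
  a <- (1 - level) / 2
  out <- matrix(0, length(p_grid), 3)
  for (g in seq_along(p_grid)) {
    p <- p_grid[g]
    vals <- numeric(0)
    wts <- numeric(0)
    const_w <- 0
    for (i in seq_along(fit$models)) {
      f <- fit$models[[i]]
      if (f$spec$bias$type == "selection") {
        wf <- f$spec$bias$wf
        j <- 1L + sum(p > wf$cutoffs)
        om <- if (j == 1L) rep(1, nrow(f$theta)) else f$theta[, paste0("omega", j)]
        vals <- c(vals, om)
        wts <- c(wts, rep(probs[i] / length(om), length(om)))
      } else {
        const_w <- const_w + probs[i]
      }
    }
    vals <- c(1, vals)
    wts <- c(const_w, wts)
    out[g, ] <- c(sum(vals * wts) / sum(wts), .wquantile(vals, wts, c(a, 1 - a)))
  }
  data.frame(p = p_grid, mean = out[, 1], lower = out[, 2], upper = out[, 3])
}

#' Fit the full model-averaged ensemble
#'
#' End-to-end Bayesian model-averaged meta-analysis: transforms the data
#' onto the analysis scale (Cohen's d input is fitted on the Fisher z scale
#' unless `transform = FALSE`), fits every ensemble member by adaptive
#' Metropolis + bridge sampling, and aggregates posterior model
#' probabilities, inclusion Bayes factors and model-averaged estimates.
#' Models that fail to converge are excluded with their prior mass
#' renormalised over the remaining models (with a warning).
#'
#' @param data A [study_data()] object.
#' @param ensemble A [build_ensemble()] result.
#' @param settings An [mcmc_settings()].
#' @param transform Fit Cohen's d input on the Fisher z scale (default).
#' @param verbose Print per-model progress.
#' @return An object of class `ensemble_fit`.
#' @export
fit_ensemble <- function(data, ensemble = build_ensemble(),
                         settings = mcmc_settings(), transform = TRUE,
                         verbose = FALSE) {
  prep <- .to_analysis_scale(data, transform)
  adata <- prep$data
  fits <- vector("list", length(ensemble))
  for (i in seq_along(ensemble)) {
    if (verbose)
      message(sprintf("fitting model %d/%d ...", i, length(ensemble)))
    fits[[i]] <- fit_model(ensemble[[i]], adata, settings, prep$analysis)
  }
  aggregate_ensemble(fits, ensemble, analysis = prep$analysis, data = data)
}

#' Aggregate fitted ensemble members
#'
#' @param fits List of `fitted_model` objects aligned with `ensemble`.
#' @param ensemble The `bma_ensemble` that produced them.
#' @param analysis `"direct"` or `"d_to_z"` (controls the reporting
#'   back-transform).
#' @param data Optional original [study_data()] (stored for reporting).
#' @return An `ensemble_fit` object.
#' @export
aggregate_ensemble <- function(fits, ensemble, analysis = "direct", data = NULL) {
  conv <- vapply(fits, `[[`, TRUE, "converged")
  prior_probs <- vapply(ensemble, `[[`, 0, "prior_prob")
  if (!all(conv)) {
    warning(sprintf("excluding %d unconverged model(s): %s",
                    sum(!conv), paste(which(!conv), collapse = ", ")),
            call. = FALSE)
    fits <- fits[conv]
    ensemble <- structure(ensemble[conv], class = "bma_ensemble")
    prior_probs <- prior_probs[conv] / sum(prior_probs[conv])
  }
  logml <- vapply(fits, `[[`, 0, "log_marglik")
  post <- posterior_model_probs(logml, prior_probs)

  safe_bf <- function(what) {
    idx <- .component_index(ensemble, what)
    if (length(idx) == 0 || length(idx) == length(fits)) return(NA_real_)
    inclusion_bf(prior_probs, post, idx)
  }
  bf_effect <- safe_bf("effect")
  bf_het <- safe_bf("heterogeneity")
  bf_bias <- safe_bf("bias")
  sel_idx <- .component_index(ensemble, "selection")
  pp_idx <- .component_index(ensemble, "petpeese")
  bf_sel_vs_pp <- if (length(sel_idx) && length(pp_idx)) {
    keep <- c(sel_idx, pp_idx)
    inclusion_bf(prior_probs[keep] / sum(prior_probs[keep]),
                 post[keep] / sum(post[keep]),
                 match(sel_idx, keep))
  } else NA_real_
  per_model_bf <- vapply(seq_along(fits), function(i)
    inclusion_bf(prior_probs, post, i), 0)

  mix_mu <- model_averaged_posterior(fits, post, "mu")
  mix_tau <- model_averaged_posterior(fits, post, "tau")
  mu_analysis <- mixture_summary(mix_mu)
  tau_analysis <- mixture_summary(mix_tau)
  if (identical(analysis, "d_to_z")) {
    mu_d <- mixture_summary(mix_mu, transform = function(z) 2 * sinh(z))
    tau_d <- mixture_summary(mix_tau, transform = function(z) 2 * z)
  } else {
    mu_d <- mu_analysis
    tau_d <- tau_analysis
  }

  structure(list(models = fits, ensemble = ensemble,
                 prior_probs = prior_probs, posterior_probs = post,
                 log_margliks = logml,
                 bf_effect = bf_effect, bf_heterogeneity = bf_het,
                 bf_bias = bf_bias, bf_selection_vs_petpeese = bf_sel_vs_pp,
                 per_model_bf = per_model_bf,
                 mix_mu = mix_mu, mix_tau = mix_tau,
                 mu = mu_d, tau = tau_d,
                 mu_analysis = mu_analysis, tau_analysis = tau_analysis,
                 analysis = analysis, data = data),
            class = "ensemble_fit")
}

#' Per-model summary table of an ensemble fit
#'
#' @param fit An `ensemble_fit`.
#' @return Data frame with one row per model (priors, probabilities,
#'   marginal likelihoods, diagnostics).
#' @export
ensemble_table <- function(fit) {
  rows <- lapply(seq_along(fit$models), function(i) {
    f <- fit$models[[i]]
    s <- f$spec
    data.frame(
      id = s$id,
      effect = if (s$effect$family == "point") "mu = 0" else format(s$effect),
      heterogeneity = if (s$tau$family == "point") "tau = 0" else format(s$tau),
      bias = switch(s$bias$type,
                    none = "none",
                    selection = format(s$bias$wf),
                    pet = "PET", peese = "PEESE"),
      prior_prob = fit$prior_probs[i],
      posterior_prob = fit$posterior_probs[i],
      log_marglik = f$log_marglik,
      log_marglik_se = f$log_marglik_se,
      max_rhat = if (nrow(f$diagnostics)) max(f$diagnostics$rhat) else NA_real_,
      min_ess = if (nrow(f$diagnostics)) min(f$diagnostics$ess) else NA_real_,
      inclusion_bf = fit$per_model_bf[i],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ensemble_fit <- function(x, digits = 3, ...) {
  scale_lab <- if (identical(x$analysis, "d_to_z")) "Cohen's d" else "analysis"
  cat(sprintf("Model-averaged meta-analysis (%d models)\n", length(x$models)))
  cat(sprintf("  BF_10 (effect):          %.3f\n", x$bf_effect))
  cat(sprintf("  BF_rf (heterogeneity):   %.3f\n", x$bf_heterogeneity))
  cat(sprintf("  BF_pb (publication bias):%.3f\n", x$bf_bias))
  if (!is.na(x$bf_selection_vs_petpeese))
    cat(sprintf("  BF selection vs PET-PEESE: %.3f\n", x$bf_selection_vs_petpeese))
  cat(sprintf("  mu  (%s scale): mean %.3f, 95%% CI [%.3f, %.3f]\n",
              scale_lab, x$mu$mean, x$mu$ci[1], x$mu$ci[2]))
  cat(sprintf("  tau (%s scale): mean %.3f, 95%% CI [%.3f, %.3f]\n",
              scale_lab, x$tau$mean, x$tau$ci[1], x$tau$ci[2]))
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  print(object)
  cat("\nPer-model table:\n")
  tab <- ensemble_table(object)
  tab$prior_prob <- round(tab$prior_prob, 3)
  tab$posterior_prob <- round(tab$posterior_prob, 3)
  tab$log_marglik <- round(tab$log_marglik, 2)
  print(tab[, c("id", "effect", "heterogeneity", "bias",
                "prior_prob", "posterior_prob", "log_marglik")],
        row.names = FALSE)
  invisible(object)
}
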