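#' Step weight function over p-value intervals
#'
#' A publication-probability step function: the p axis is partitioned at the
#' given cutoffs into `J = length(cutoffs) + 1` intervals, ordered from most
#' significant (interval 1, smallest p-values) to least significant.  The
#' weight vector omega gives the relative publication probability of each
#' interval with `omega[1] = 1` fixed as the reference.
#'
#' @param sidedness `"one"` or `"two"`.
#' @param cutoffs Strictly increasing p-value cutoffs in (0, 1).
#' @return An object of class `weight_fn`.
#' @examples
#' weight_fn("one", c(0.025, 0.05, 0.50))
#' @export
weight_fn <- function(sidedness = c("two", "one"), cutoffs) {
  sidedness <- match.arg(sidedness)
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1 || any(cutoffs <= 0) || any(cutoffs >= 1))
    stop("invalid-input: cutoffs must lie in (0, 1)", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("invalid-input: cutoffs must be strictly increasing", call. = FALSE)
  structure(list(sidedness = sidedness, cutoffs = cutoffs,
                 J = length(cutoffs) + 1L),
            class = "weight_fn")
}

#' @export
format.weight_fn <- function(x, ...) {
  sprintf("%s-sided(%s)", x$sidedness, paste(rev(x$cutoffs), collapse = ", "))
}

#' @export
print.weight_fn <- function(x, ...) {
  cat(format(x), sprintf("[J = %d intervals]\n", x$J))
  invisible(x)
}

#' The six default weight functions
#'
#' Two two-sided selection processes (significance; significance or marginal
#' significance) and four one-sided processes for positive effects that add
#' cutoffs at 0.025 (one-sided significance of a two-sided test) and 0.50
#' (expected effect direction).
#'
#' @return List of six [weight_fn()] objects.
#' @export
default_weight_functions <- function() {
  list(weight_fn("two", 0.05),
       weight_fn("two", c(0.05, 0.10)),
       weight_fn("one", 0.05),
       weight_fn("one", c(0.025, 0.05)),
       weight_fn("one", c(0.05, 0.50)),
       weight_fn("one", c(0.025, 0.05, 0.50)))
}

#' Cumulative Dirichlet weights
#'
#' Maps an interval mass vector eta (a point on the simplex) to the monotone
#' weight vector omega via reverse cumulative sums: `omega[j] = sum(eta[j:J])`.
#' With interval 1 the most significant, `omega[1] = 1` and omega is
#' non-increasing -- publication probability never increases as p grows.
#'
#' @param eta Non-negative vector summing to 1.
#' @return Weight vector omega of the same length.
#' @examples
#' cum_dirichlet_weights(c(0.2, 0.3, 0.5))
#' @export
cum_dirichlet_weights <- function(eta) {
  if (any(eta < 0) || abs(sum(eta) - 1) > 1e-10)
    stop("invalid-input: eta must be a probability simplex vector", call. = FALSE)
  rev(cumsum(rev(eta)))
}

# Internal constructor for one ensemble member.
.model_spec <- function(id, effect, tau, bias, prior_prob) {
  structure(list(id = id, effect = effect, tau = tau, bias = bias,
                 prior_prob = prior_prob),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  eff <- if (x$effect$family == "point") "mu = 0" else
    paste0("mu ~ ", format(x$effect))
  tau <- if (x$tau$family == "point") "tau = 0" else
    paste0("tau ~ ", format(x$tau))
  bias <- switch(x$bias$type,
    none = "none",
    selection = paste0("omega[", format(x$bias$wf), "] ~ CumDirichlet(",
                       paste(rep(1, x$bias$wf$J), collapse = ", "), ")"),
    pet = paste0("PET ~ ", format(x$bias$prior)),
    peese = paste0("PEESE ~ ", format(x$bias$prior)))
  sprintf("%2d | %-18s | %-24s | %-55s | %.3f",
          x$id, eff, tau, bias, x$prior_prob)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Number of free (sampled) parameters of a model.
#' Number of free parameters of an ensemble member
#' @param spec A `model_spec`.
#' @return Integer count of sampled parameters.
#' @export
n_free_params <- function(spec) {
  d <- 0L
  if (spec$effect$family != "point") d <- d + 1L
  if (spec$tau$family != "point") d <- d + 1L
  if (spec$bias$type == "selection") d <- d + spec$bias$wf$J - 1L
  if (spec$bias$type %in% c("pet", "peese")) d <- d + 1L
  d
}

#' Build a model ensemble
#'
#' Constructs the full cross of effect (null spike at zero / slab prior),
#' heterogeneity (tau = 0 / inverse-gamma slab) and publication-bias
#' component (none, each step weight function, PET, PEESE).  With the
#' defaults this yields the 36-model ensemble: 4 models without bias
#' adjustment, 6 x 4 = 24 selection models and 2 x 4 = 8 PET/PEESE models.
#'
#' Prior model probability is allocated by component class -- 0.5 to the
#' bias-free models and 0.25 each to the selection and PET/PEESE classes
#' (0.5 to whichever is present if only one is) -- and uniformly within a
#' class, so each bias-free model receives 1/8, each selection model
#' 0.25/24 and each PET/PEESE model 1/32.
#'
#' Ordering: null-effect models first, within that fixed-effect models
#' first, and within that bias components in the order none, two-sided
#' weight functions, one-sided weight functions, PET, PEESE.
#'
#' @param effect_prior Slab prior for the mean effect ([prior_spec()]).
#' @param tau_prior Slab prior for the heterogeneity SD.
#' @param weight_fns List of [weight_fn()] objects, or `NULL` to omit the
#'   selection class.
#' @param pet_prior,peese_prior Positive-truncated slope priors, or `NULL`
#'   to omit the regression class.
#' @param class_mass Prior mass of the three component classes
#'   (no-bias / selection / PET-PEESE); rescaled to the classes present.
#' @return An object of class `bma_ensemble` (list of `model_spec`).
#' @examples
#' ens <- build_ensemble()
#' length(ens)  # 36
#' @export
build_ensemble <- function(effect_prior = default_priors()$effect,
                           tau_prior = default_priors()$tau,
                           weight_fns = default_weight_functions(),
                           pet_prior = default_priors()$pet,
                           peese_prior = default_priors()$peese,
                           class_mass = c(none = 0.5, selection = 0.25,
                                          petpeese = 0.25)) {
  has_sel <- !is.null(weight_fns) && length(weight_fns) > 0
  has_reg <- !(is.null(pet_prior) && is.null(peese_prior))
  if (is.null(effect_prior) || is.null(tau_prior))
    stop("invalid-config: effect and tau priors are required", call. = FALSE)

  # bias components in reporting order
  bias_components <- list(list(type = "none"))
  if (has_sel) {
    two <- Filter(function(w) w$sidedness == "two", weight_fns)
    one <- Filter(function(w) w$sidedness == "one", weight_fns)
    for (w in c(two, one))
      bias_components <- c(bias_components, list(list(type = "selection", wf = w)))
  }
  if (!is.null(pet_prior))
    bias_components <- c(bias_components, list(list(type = "pet", prior = pet_prior)))
  if (!is.null(peese_prior))
    bias_components <- c(bias_components, list(list(type = "peese", prior = peese_prior)))
  if (length(bias_components) == 0)
    stop("invalid-config: empty model list", call. = FALSE)

  # class masses over present classes, uniform within class
  n_sel <- if (has_sel) length(weight_fns) else 0L
  n_reg <- (!is.null(pet_prior)) + (!is.null(peese_prior))
  present <- c(none = TRUE, selection = n_sel > 0, petpeese = n_reg > 0)
  mass <- class_mass[names(present)]
  mass[!present] <- 0
  if (any(present[-1])) {
    # bias-adjusted models keep their total mass (default 0.5) even when
    # only one bias class is present; that mass is split among the classes
    # actually in the ensemble in proportion to class_mass
    mass[["none"]] <- class_mass[["none"]] / sum(class_mass)
    mass[-1] <- mass[-1] / sum(mass[-1]) * (1 - mass[["none"]])
  } else {
    mass <- c(none = 1, selection = 0, petpeese = 0)
  }
  per_component_mass <- function(bias) {
    switch(bias$type,
      none = mass[["none"]],
      selection = mass[["selection"]] / n_sel,
      pet = ,
      peese = mass[["petpeese"]] / n_reg)
  }

  effect_opts <- list(prior_spec("point", value = 0), effect_prior)
  tau_opts <- list(prior_spec("point", value = 0), tau_prior)
  models <- list()
  id <- 0L
  for (eff in effect_opts) for (tau in tau_opts) for (bias in bias_components) {
    id <- id + 1L
    # each (effect, tau) cell carries 1/4 of its bias component's class mass
    models[[id]] <- .model_spec(id, eff, tau, bias,
                                per_component_mass(bias) / 4)
  }
  stopifnot(abs(sum(vapply(models, `[[`, 0, "prior_prob")) - 1) < 1e-12)
  structure(models, class = "bma_ensemble")
}

#' @export
print.bma_ensemble <- function(x, ...) {
  cat(sprintf("bma_ensemble: %d models\n", length(x)))
  cat(" i | effect             | heterogeneity            |",
      "publication bias                                        | prior\n")
  for (m in x) cat(format(m), "\n")
  invisible(x)
}

# Internal: indices of models by component for inclusion Bayes factors.
.component_index <- function(ensemble,
                             what = c("effect", "heterogeneity", "bias",
                                      "selection", "petpeese")) {
  what <- match.arg(what)
  test <- switch(what,
    effect = function(m) m$effect$family != "point",
    heterogeneity = function(m) m$tau$family != "point",
    bias = function(m) m$bias$type != "none",
    selection = function(m) m$bias$type == "selection",
    petpeese = function(m) m$bias$type %in% c("pet", "peese"))
  which(vapply(ensemble, test, TRUE))
}

# Internal: the compiled-layer descriptor of a model on the analysis scale.
# analysis is "direct" or "d_to_z"; direction from the data.
.cmodel <- function(spec, analysis, direction = "positive") {
  eff <- .prior_on_analysis(spec$effect, analysis, "effect")
  tau <- .prior_on_analysis(spec$tau, analysis, "tau")
  out <- list(effect_type = 0L, effect_value = 0, effect_mean = 0, effect_sd = 1,
              tau_type = 0L, tau_shape = 1, tau_scale = 0.15,
              bias_type = 0L, sided = 2L, direction = 1L,
              cutoffs = numeric(0), b_scale = 1)
  if (eff$family == "point") {
    out$effect_value <- eff$params$value
  } else if (eff$family == "normal") {
    out$effect_type <- 1L
    out$effect_mean <- eff$params$mean
    out$effect_sd <- eff$params$sd
  } else if (eff$family == "normal_d") {
    out$effect_type <- 2L
    out$effect_sd <- eff$params$sd
  } else stop("unsupported effect prior family: ", eff$family)
  if (tau$family == "invgamma") {
    out$tau_type <- 1L
    out$tau_shape <- tau$params$shape
    out$tau_scale <- tau$params$scale
  } else if (tau$family != "point") stop("unsupported tau prior family: ", tau$family)
  if (spec$bias$type == "selection") {
    out$bias_type <- 1L
    out$sided <- if (spec$bias$wf$sidedness == "one") 1L else 2L
    out$cutoffs <- spec$bias$wf$cutoffs
    out$direction <- if (identical(direction, "negative")) -1L else 1L
  } else if (spec$bias$type == "pet") {
    out$bias_type <- 2L
    out$b_scale <- .prior_on_analysis(spec$bias$prior, analysis, "pet")$params$scale
  } else if (spec$bias$type == "peese") {
    out$bias_type <- 3L
    out$b_scale <- .prior_on_analysis(spec$bias$prior, analysis, "peese")$params$scale
  }
  out
}

# Internal: p-interval membership of each observed study (ties at a cutoff go
# to the more significant interval).
.interval_membership <- function(data, wf, direction = "positive") {
  p <- p_value(data$y, data$se, sidedness = wf$sidedness, direction = direction)
  vapply(p, function(pk) 1L + sum(pk > wf$cutoffs), 1L)
}
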