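#' Log-likelihood without bias adjustment
#'
#' Normal meta-analytic likelihood: each study estimate is
#' `y_k ~ Normal(mu, se_k^2 + tau^2)`.  `tau = 0` gives the fixed-effect
#' model.
#'
#' @param data A [study_data()] object (or anything with `$y`, `$se`).
#' @param mu Mean effect on the analysis scale.
#' @param tau Heterogeneity SD, `>= 0`.
#' @return Scalar log-likelihood.
#' @export
loglik_plain <- function(data, mu, tau = 0) {
  stopifnot(tau >= 0)
  sum(stats::dnorm(data$y, mu, sqrt(data$se^2 + tau^2), log = TRUE))
}

#' Probability of each p-value interval
#'
#' Probability that a study with standard error `se` lands in each p-value
#' interval of a weight function when its estimate is drawn from
#' `Normal(mu, se^2 + tau^2)`.  The p-value is computed against the
#' observed `se` (as in the selection likelihood's normalising constant).
#'
#' @param mu,tau Mean and heterogeneity SD on the analysis scale.
#' @param se Standard error of the study (positive scalar).
#' @param wf A [weight_fn()].
#' @param direction `"positive"` or `"negative"` (one-sided only).
#' @return Vector of `wf$J` probabilities summing to 1, most significant
#'   interval first.
#' @export
interval_probs <- function(mu, tau, se, wf, direction = "positive") {
  if (se <= 0) stop("invalid-input: se must be positive", call. = FALSE)
  s <- sqrt(se^2 + tau^2)
  if (wf$sidedness == "one") {
    sgn <- if (identical(direction, "negative")) -1 else 1
    mu <- sgn * mu
    thr <- se * stats::qnorm(1 - wf$cutoffs)      # descending thresholds
    surv <- stats::pnorm((thr - mu) / s, lower.tail = FALSE)
    diff(c(0, surv, 1))
  } else {
    q <- se * stats::qnorm(1 - wf$cutoffs / 2)
    g <- stats::pnorm((q - mu) / s, lower.tail = FALSE) + stats::pnorm((-q - mu) / s)
    diff(c(0, g, 1))
  }
}

#' Selection-model log-likelihood
#'
#' Weighted-density likelihood: the published estimate of study k has
#' density proportional to `omega[j(k)] * Normal(y_k; mu, se_k^2 + tau^2)`
#' where `j(k)` is the p-value interval of the observed estimate, and the
#' per-study normalising constant is `sum_j omega_j * P_j(mu, tau, se_k)`
#' with `P_j` from [interval_probs()].  With all weights 1 this reduces to
#' [loglik_plain()]; a zero weight on an interval containing an observed
#' study yields `-Inf` (an impossible datum, not an error).
#'
#' @inheritParams loglik_plain
#' @param omega Weight vector for `wf` (see [cum_dirichlet_weights()]).
#' @param wf A [weight_fn()].
#' @param direction `"positive"` or `"negative"`.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
loglik_selection <- function(data, mu, tau, omega, wf, direction = "positive") {
  stopifnot(tau >= 0, length(omega) == wf$J)
  memb <- .interval_membership(data, wf, direction)
  s <- sqrt(data$se^2 + tau^2)
  ll <- 0
  for (k in seq_along(data$y)) {
    w <- omega[memb[k]]
    if (w <= 0) return(-Inf)
    denom <- sum(omega * interval_probs(mu, tau, data$se[k], wf, direction))
    ll <- ll + log(w) + stats::dnorm(data$y[k], mu, s[k], log = TRUE) - log(denom)
  }
  ll
}

#' PET / PEESE regression log-likelihood
#'
#' Meta-regression of the estimates on their standard errors (PET) or
#' sampling variances (PEESE): `y_k ~ Normal(mu + b * se_k, se_k^2 + tau^2)`
#' or `y_k ~ Normal(mu + b * se_k^2, se_k^2 + tau^2)`.  The intercept `mu`
#' is the bias-corrected mean effect at `se = 0`.
#'
#' @inheritParams loglik_plain
#' @param b Regression slope, `>= 0`.
#' @param kind `"pet"` or `"peese"`.
#' @return Scalar log-likelihood.
#' @export
loglik_regression <- function(data, mu, tau, b, kind = c("pet", "peese")) {
  kind <- match.arg(kind)
  stopifnot(tau >= 0, b >= 0)
  shift <- if (kind == "pet") b * data$se else b * data$se^2
  sum(stats::dnorm(data$y, mu + shift, sqrt(data$se^2 + tau^2), log = TRUE))
}

#' Log prior density of a parameter vector
#'
#' Sum of the log prior densities of the free components of `theta` under a
#' model specification: normal for the mean effect, inverse-gamma for tau,
#' half-Cauchy (the positive-truncated Cauchy, density renormalised by 2)
#' for a PET/PEESE slope and flat `Dirichlet(1, ..., 1)` for the interval
#' masses eta.  Values outside the support give `-Inf`.  Densities are
#' evaluated for the priors as declared (no scale transformation).
#'
#' @param theta Named list with any of `mu`, `tau`, `eta`, `b`.
#' @param spec A `model_spec` from [build_ensemble()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, spec) {
  lp <- 0
  if (spec$effect$family != "point" && !is.null(theta$mu)) {
    p <- spec$effect$params
    lp <- lp + if (spec$effect$family == "normal_d") {
      stats::dnorm(2 * sinh(theta$mu), 0, p$sd, log = TRUE) + log(2 * cosh(theta$mu))
    } else {
      stats::dnorm(theta$mu, p$mean, p$sd, log = TRUE)
    }
  }
  if (spec$tau$family != "point" && !is.null(theta$tau)) {
    p <- spec$tau$params
    lp <- lp + if (theta$tau <= 0) -Inf else
      p$shape * log(p$scale) - lgamma(p$shape) -
        (p$shape + 1) * log(theta$tau) - p$scale / theta$tau
  }
  if (spec$bias$type == "selection" && !is.null(theta$eta)) {
    if (any(theta$eta < 0) || abs(sum(theta$eta) - 1) > 1e-10) {
      lp <- -Inf
    } else {
      lp <- lp + lgamma(spec$bias$wf$J)
    }
  }
  if (spec$bias$type %in% c("pet", "peese") && !is.null(theta$b)) {
    sc <- spec$bias$prior$params$scale
    lp <- lp + if (theta$b < 0) -Inf else
      log(2) + stats::dcauchy(theta$b, 0, sc, log = TRUE)
  }
  lp
}

# ---------------------------------------------------------------------------
# Independent vectorised R evaluation of the unconstrained log posterior.
# This mirrors src/bmapb.cpp but shares no code with it: the quadrature
# oracle integrates THIS implementation, so oracle-vs-bridge agreement
# cross-validates the compiled likelihood as well as the integrator.
# U: n x d matrix of unconstrained parameter rows.
.logpost_matrix_r <- function(U, cmodel, y, se, memb) {
  n <- nrow(U)
  i <- 0L
  logjac <- numeric(n)
  if (cmodel$effect_type > 0L) {
    i <- i + 1L
    mu <- U[, i]
  } else mu <- rep(cmodel$effect_value, n)
  if (cmodel$tau_type > 0L) {
    i <- i + 1L
    tau <- exp(U[, i])
    logjac <- logjac + U[, i]
  } else tau <- numeric(n)
  J <- if (cmodel$bias_type == 1L) length(cmodel$cutoffs) + 1L else 0L
  omega <- NULL
  b <- numeric(n)
  if (cmodel$bias_type == 1L) {
    eta <- matrix(0, n, J)
    rem <- rep(1, n)
    for (k in seq_len(J - 1L)) {
      i <- i + 1L
      v <- stats::plogis(U[, i])
      logjac <- logjac + log(rem) + log(v) + log1p(-v)
      eta[, k] <- v * rem
      rem <- rem * (1 - v)
    }
    eta[, J] <- rem
    omega <- matrix(0, n, J)
    acc <- numeric(n)
    for (k in J:1) {
      acc <- acc + eta[, k]
      omega[, k] <- acc
    }
    omega[, 1] <- 1
  } else if (cmodel$bias_type > 1L) {
    i <- i + 1L
    b <- exp(U[, i])
    logjac <- logjac + U[, i]
  }

  # log prior
  lp <- numeric(n)
  if (cmodel$effect_type == 1L) {
    lp <- lp + stats::dnorm(mu, cmodel$effect_mean, cmodel$effect_sd, log = TRUE)
  } else if (cmodel$effect_type == 2L) {
    lp <- lp + stats::dnorm(2 * sinh(mu), 0, cmodel$effect_sd, log = TRUE) +
      log(2 * cosh(mu))
  }
  if (cmodel$tau_type == 1L) {
    lp <- lp + cmodel$tau_shape * log(cmodel$tau_scale) - lgamma(cmodel$tau_shape) -
      (cmodel$tau_shape + 1) * log(tau) - cmodel$tau_scale / tau
  }
  if (cmodel$bias_type == 1L) {
    lp <- lp + lgamma(J)
  } else if (cmodel$bias_type > 1L) {
    lp <- lp + log(2) + stats::dcauchy(b, 0, cmodel$b_scale, log = TRUE)
  }

  # log likelihood
  ll <- numeric(n)
  K <- length(y)
  if (cmodel$bias_type != 1L) {
    for (k in seq_len(K)) {
      mean_k <- mu
      if (cmodel$bias_type == 2L) mean_k <- mean_k + b * se[k]
      if (cmodel$bias_type == 3L) mean_k <- mean_k + b * se[k]^2
      ll <- ll + stats::dnorm(y[k], mean_k, sqrt(se[k]^2 + tau^2), log = TRUE)
    }
  } else {
    sgn <- if (cmodel$sided == 1L && cmodel$direction < 0L) -1 else 1
    mu_s <- sgn * mu
    for (k in seq_len(K)) {
      s <- sqrt(se[k]^2 + tau^2)
      if (cmodel$sided == 1L) {
        thr <- se[k] * stats::qnorm(1 - cmodel$cutoffs)
        surv <- vapply(thr, function(t)
          stats::pnorm((t - mu_s) / s, lower.tail = FALSE), numeric(n))
        if (n == 1L) surv <- matrix(surv, nrow = 1L)
        P <- cbind(surv, 1) - cbind(0, surv)
      } else {
        q <- se[k] * stats::qnorm(1 - cmodel$cutoffs / 2)
        g <- vapply(q, function(t)
          stats::pnorm((t - mu_s) / s, lower.tail = FALSE) +
            stats::pnorm((-t - mu_s) / s), numeric(n))
        if (n == 1L) g <- matrix(g, nrow = 1L)
        P <- cbind(g, 1) - cbind(0, g)
      }
      denom <- rowSums(P * omega)
      ll <- ll + log(omega[, memb[k]]) +
        stats::dnorm(sgn * y[k], mu_s, s, log = TRUE) - log(denom)
    }
  }
  out <- ll + lp + logjac
  out[!is.finite(out)] <- -Inf
  out
}
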