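# Frequentist baselines: conditional PET-PEESE and DerSimonian-Laird.

# weighted least squares of y on x with inverse-variance weights, classical
# (multiplicative) variance estimator and t(K-2) inference
.wls_fit <- function(y, x, se) {
  K <- length(y)
  w <- 1 / se^2
  if (stats::sd(x) < 1e-12) {
    warning("collinear design: all standard errors equal; slope indeterminate",
            call. = FALSE)
    mu <- sum(w * y) / sum(w)
    return(list(intercept = mu, slope = NA_real_, se_intercept = NA_real_,
                se_slope = NA_real_, t = NA_real_, df = K - 2L, p = NA_real_,
                collinear = TRUE))
  }
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  list(intercept = co[1, 1], slope = co[2, 1],
       se_intercept = co[1, 2], se_slope = co[2, 2],
       t = co[1, 3], df = K - 2L,
       p = 2 * stats::pt(abs(co[1, 3]), K - 2L, lower.tail = FALSE),
       collinear = FALSE)
}

#' Conditional PET-PEESE estimator
#'
#' Classical two-step small-study-effect correction: PET regresses the
#' estimates on their standard errors, PEESE on their sampling variances,
#' both by weighted least squares with inverse-variance weights; the
#' bias-corrected mean effect is the intercept.  If the PET intercept is
#' significant at `alpha` (two-sided by default), the PEESE intercept is
#' reported, otherwise the PET intercept.
#'
#' @param data A [study_data()] object (`K >= 3`).
#' @param alpha Significance level of the PET decision test (model
#'   selection only; default 0.10).
#' @param one_sided Use a one-tailed PET decision test instead.
#' @return List of class `pet_peese` with the chosen `estimate`, `selected`
#'   (`"PET"`/`"PEESE"`), and both full fits (intercept, slope, SEs, t, df,
#'   p).
#' @export
pet_peese_conditional <- function(data, alpha = 0.10, one_sided = FALSE) {
  K <- nrow(data)
  if (K < 3) stop("insufficient-studies: PET-PEESE needs K >= 3", call. = FALSE)
  pet <- .wls_fit(data$y, data$se, data$se)
  peese <- .wls_fit(data$y, data$se^2, data$se)
  p_dec <- if (one_sided) {
    stats::pt(pet$t, pet$df, lower.tail = FALSE)
  } else pet$p
  use_peese <- is.finite(p_dec) && p_dec < alpha
  structure(list(estimate = if (use_peese) peese$intercept else pet$intercept,
                 selected = if (use_peese) "PEESE" else "PET",
                 pet = pet, peese = peese, alpha = alpha),
            class = "pet_peese")
}

#' @export
print.pet_peese <- function(x, ...) {
  cat(sprintf("PET:   mu = %.3f, t(%d) = %.2f, p = %.3f\n",
              x$pet$intercept, x$pet$df, x$pet$t, x$pet$p))
  cat(sprintf("PEESE: mu = %.3f, t(%d) = %.2f, p = %.3f\n",
              x$peese$intercept, x$peese$df, x$peese$t, x$peese$p))
  cat(sprintf("conditional rule (alpha = %.2f) selects %s: mu = %.3f\n",
              x$alpha, x$selected, x$estimate))
  invisible(x)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments heterogeneity estimate: Cochran's Q with
#' inverse-variance weights, `tau2 = max(0, (Q - (K-1)) / c)` with
#' `c = sum(w) - sum(w^2)/sum(w)`, then the re-weighted mean with weights
#' `1 / (se^2 + tau2)`.
#'
#' @param data A [study_data()] object (`K >= 2`).
#' @return List with `mu`, `se_mu`, `tau2`, `Q`, `p` (normal-theory
#'   two-sided p of `mu/se_mu`).
#' @export
dersimonian_laird <- function(data) {
  K <- nrow(data)
  if (K < 2) stop("insufficient-studies: need K >= 2", call. = FALSE)
  w <- 1 / data$se^2
  ybar <- sum(w * data$y) / sum(w)
  Q <- sum(w * (data$y - ybar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (K - 1)) / cc)
  w2 <- 1 / (data$se^2 + tau2)
  mu <- sum(w2 * data$y) / sum(w2)
  se_mu <- sqrt(1 / sum(w2))
  list(mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q,
       p = 2 * stats::pnorm(abs(mu) / se_mu, lower.tail = FALSE))
}
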