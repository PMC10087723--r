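#' Prior specification
#'
#' Priors for the ensemble components.  Families:
#' \describe{
#'   \item{`point`}{degenerate mass at `value` (used for null components).}
#'   \item{`normal`}{`Normal(mean, sd)` for the mean effect.}
#'   \item{`invgamma`}{`InvGamma(shape, scale)` for the heterogeneity SD tau.}
#'   \item{`cauchy_plus`}{Cauchy(0, scale) truncated to the positive range,
#'     for PET/PEESE regression slopes (density renormalised by 2).}
#'   \item{`dirichlet`}{`Dirichlet(alpha)` on the interval mass vector eta of
#'     a step weight function (the cumulative sums give the weights omega).}
#' }
#' `declared_scale = "cohens_d"` marks priors stated on the Cohen's d scale;
#' when the data are fitted on the Fisher z scale these are mapped over
#' (see the methods vignette).
#'
#' @param family One of `"point"`, `"normal"`, `"invgamma"`, `"cauchy_plus"`,
#'   `"dirichlet"`.
#' @param ... Family parameters: `value`; `mean`, `sd`; `shape`, `scale`;
#'   `scale`; `alpha`.
#' @param declared_scale `"cohens_d"` or `"analysis"`.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec("normal", mean = 0, sd = 1)
#' prior_spec("invgamma", shape = 1, scale = 0.15)
#' @export
prior_spec <- function(family = c("point", "normal", "invgamma",
                                  "cauchy_plus", "dirichlet"),
                       ..., declared_scale = c("cohens_d", "analysis")) {
  family <- match.arg(family)
  declared_scale <- match.arg(declared_scale)
  p <- list(...)
  defaults <- switch(family,
    point       = list(value = 0),
    normal      = list(mean = 0, sd = 1),
    invgamma    = list(shape = 1, scale = 0.15),
    cauchy_plus = list(scale = 1),
    dirichlet   = list(alpha = c(1, 1)))
  p <- utils::modifyList(defaults, p)
  if (family == "invgamma" && (p$shape <= 0 || p$scale <= 0))
    stop("invalid-input: invgamma shape and scale must be positive", call. = FALSE)
  if (family == "cauchy_plus" && p$scale <= 0)
    stop("invalid-input: cauchy scale must be positive", call. = FALSE)
  if (family == "point" && !is.finite(p$value))
    stop("invalid-input: point mass must be finite", call. = FALSE)
  if (family == "normal" && p$sd <= 0)
    stop("invalid-input: normal sd must be positive", call. = FALSE)
  structure(list(family = family, params = p, declared_scale = declared_scale),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.prior_spec <- function(x, ...) {
  p <- x$params
  lab <- switch(x$family,
    point       = sprintf("point(%g)", p$value),
    normal      = sprintf("Normal(%g, %g)", p$mean, p$sd),
    invgamma    = sprintf("InvGamma(%g, %g)", p$shape, p$scale),
    cauchy_plus = sprintf("Cauchy(0, %g)[0, Inf]", p$scale),
    dirichlet   = sprintf("CumDirichlet(%s)", paste(p$alpha, collapse = ", ")))
  if (x$declared_scale == "cohens_d") lab else paste0(lab, " [analysis scale]")
}

#' Default ensemble priors
#'
#' The default parameter priors, declared on the Cohen's d scale: a standard
#' normal for the mean effect, `InvGamma(1, 0.15)` for the heterogeneity SD,
#' and positive-truncated `Cauchy(0, 1)` / `Cauchy(0, 5)` for the PET
#' (slope on standard errors) and PEESE (slope on variances) coefficients.
#'
#' @return Named list with elements `effect`, `tau`, `pet`, `peese`.
#' @export
default_priors <- function() {
  list(effect = prior_spec("normal", mean = 0, sd = 1),
       tau    = prior_spec("invgamma", shape = 1, scale = 0.15),
       pet    = prior_spec("cauchy_plus", scale = 1),
       peese  = prior_spec("cauchy_plus", scale = 5))
}

# Internal: map a declared prior onto the analysis scale.
# analysis = "direct": use as declared.  analysis = "d_to_z": priors declared
# on Cohen's d are transformed -- the normal effect prior by exact change of
# variables through d = 2*sinh(z) (handled downstream as family "normal_d"),
# the tau scale by the Jacobian at zero dz/dd = 1/2, the PET slope untouched,
# and the PEESE slope scale doubled (role = "peese").
.prior_on_analysis <- function(prior, analysis, role = c("effect", "tau", "pet", "peese")) {
  role <- match.arg(role)
  if (is.null(prior) || prior$family == "point" || analysis == "direct" ||
      prior$declared_scale == "analysis") {
    return(prior)
  }
  p <- prior$params
  switch(role,
    effect = {
      if (prior$family != "normal" || p$mean != 0)
        stop("only zero-centred normal effect priors can be declared on the d scale",
             call. = FALSE)
      structure(list(family = "normal_d", params = list(sd = p$sd),
                     declared_scale = "analysis"), class = "prior_spec")
    },
    tau = prior_spec("invgamma", shape = p$shape, scale = p$scale / 2,
                     declared_scale = "analysis"),
    pet = prior_spec("cauchy_plus", scale = p$scale, declared_scale = "analysis"),
    peese = prior_spec("cauchy_plus", scale = p$scale * 2,
                       declared_scale = "analysis"))
}
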