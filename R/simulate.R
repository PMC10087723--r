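# Synthetic meta-analysis generator with p-value selection, and the
# evaluation metrics used to compare adjustment methods.

#' Simulation configuration
#'
#' Describes the data-generating process on the Cohen's d scale: per-study
#' true effects `Normal(true_mu, true_tau^2)`, total sample sizes drawn
#' uniformly from `n_range`, standard errors from the equal-group formula
#' `se^2 = (8 + d^2) / (2n)`, an optional PET-type small-study shift
#' `slope * se` of the observed estimate, and accept/reject selective
#' publication with probability `omega[j]` for a study landing in p-value
#' interval j of `selection`.
#'
#' @param true_mu,true_tau Mean and SD of the per-study true effects.
#' @param K Number of published (accepted) studies.
#' @param n_range Range of total sample sizes (drawn uniformly).
#' @param selection Optional [weight_fn()] describing the selection process.
#' @param omega Publication probabilities per interval of `selection`
#'   (each in `[0, 1]`; `omega[1]` applies to the most significant interval).
#' @param slope Small-study-effect slope on the standard error (0 = none).
#' @param direction Direction of one-sided selection.
#' @param max_attempts Guard against selection processes that accept
#'   (almost) nothing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(true_mu = 0, true_tau = 0, K = 20,
                       n_range = c(30, 150), selection = NULL, omega = NULL,
                       slope = 0, direction = "positive",
                       max_attempts = 1e6) {
  stopifnot(K >= 1, true_tau >= 0, length(n_range) == 2, n_range[1] >= 4)
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "weight_fn"))
    if (is.null(omega)) stop("omega required when selection is given", call. = FALSE)
    stopifnot(length(omega) == selection$J, all(omega >= 0), all(omega <= 1))
    if (all(omega == 0)) stop("invalid-input: all publication probabilities are zero",
                              call. = FALSE)
  }
  structure(list(true_mu = true_mu, true_tau = true_tau, K = K,
                 n_range = n_range, selection = selection, omega = omega,
                 slope = slope, direction = direction,
                 max_attempts = max_attempts),
            class = "sim_config")
}

#' Simulate a meta-analysis under selective publication
#'
#' Draws candidate studies from the configured process and accepts each
#' with the publication probability of its observed p-value interval until
#' `K` studies are published.  Deterministic given the RNG state (use
#' `set.seed()`).
#'
#' @param config A [sim_config()].
#' @return A [study_data()] object on the Cohen's d scale (with `n`).
#' @export
simulate_meta_analysis <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  y <- se <- n <- numeric(config$K)
  accepted <- 0L
  attempts <- 0L
  while (accepted < config$K) {
    attempts <- attempts + 1L
    if (attempts > config$max_attempts)
      stop("selection process accepted too few studies (infinite-loop guard)",
           call. = FALSE)
    theta_k <- stats::rnorm(1, config$true_mu, config$true_tau)
    n_k <- sample(seq(config$n_range[1], config$n_range[2]), 1)
    se_k <- sqrt((8 + theta_k^2) / (2 * n_k))
    y_k <- stats::rnorm(1, theta_k + config$slope * se_k, se_k)
    keep <- TRUE
    if (!is.null(config$selection)) {
      j <- 1L + sum(p_value(y_k, se_k, config$selection$sidedness,
                            config$direction) > config$selection$cutoffs)
      keep <- stats::runif(1) < config$omega[j]
    }
    if (keep) {
      accepted <- accepted + 1L
      y[accepted] <- y_k
      se[accepted] <- se_k
      n[accepted] <- n_k
    }
  }
  study_data(y, se, n = n, scale = "cohens_d", direction = config$direction)
}

#' Evaluate estimates and decisions against a reference
#'
#' Metrics comparing a method's estimates and qualitative decisions to a
#' bias-free reference (e.g. registered replications or the simulation
#' truth): false positive rate (method claims an effect where the
#' reference is non-significant), false negative rate (method claims
#' absence where the reference is significant), the share of undecided
#' calls in each stratum, overestimation factor `mean(est)/mean(ref)`,
#' bias and RMSE of the estimates.
#'
#' Decisions use three levels: `"effect"`, `"null"`, `"undecided"`
#' (frequentist methods have no undecided calls; for Bayes factors use
#' [evidence_category()] relabelled via `decisions_from_bf()`).
#'
#' @param estimates,reference_estimates Aligned effect estimates.
#' @param decisions Character vector in `{"effect","null","undecided"}`.
#' @param reference_significant Logical: does the reference reject the null?
#' @return A list of class `method_evaluation` with `fpr`, `fpr_undecided`,
#'   `fnr`, `fnr_undecided`, `of`, `bias`, `rmse`.
#' @export
evaluate_method <- function(estimates, decisions, reference_estimates,
                            reference_significant) {
  n <- length(estimates)
  if (length(decisions) != n || length(reference_estimates) != n ||
      length(reference_significant) != n)
    stop("invalid-input: argument lengths differ", call. = FALSE)
  if (!all(decisions %in% c("effect", "null", "undecided")))
    stop("invalid-input: decisions must be effect/null/undecided", call. = FALSE)
  ref <- as.logical(reference_significant)
  rate <- function(cond, strat) if (!any(strat)) NA_real_ else mean(cond[strat])
  structure(list(
    fpr = rate(decisions == "effect", !ref),
    fpr_undecided = rate(decisions == "undecided", !ref),
    fnr = rate(decisions == "null", ref),
    fnr_undecided = rate(decisions == "undecided", ref),
    of = mean(estimates) / mean(reference_estimates),
    bias = mean(estimates - reference_estimates),
    rmse = sqrt(mean((estimates - reference_estimates)^2))),
    class = "method_evaluation")
}

#' Decisions from Bayes factors
#'
#' Maps inclusion Bayes factors to the three-way decision labels used by
#' [evaluate_method()], with `BF >= upper` an effect claim and
#' `BF <= lower` a null claim.
#'
#' @inheritParams evidence_category
#' @return Character vector in `{"effect","null","undecided"}`.
#' @export
decisions_from_bf <- function(bf, lower = 1 / 10, upper = 10) {
  c(evidence_absence = "null", undecided = "undecided",
    evidence_presence = "effect")[evidence_category(bf, lower, upper)]
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("FPR %.3f (undecided %.3f) | FNR %.3f (undecided %.3f)\n",
              x$fpr, x$fpr_undecided, x$fnr, x$fnr_undecided))
  cat(sprintf("OF %.3f | bias %.4f | RMSE %.4f\n", x$of, x$bias, x$rmse))
  invisible(x)
}
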