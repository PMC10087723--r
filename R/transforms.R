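#' Convert Cohen's d to Fisher's z
#'
#' Converts a standardised mean difference and its standard error to the
#' Fisher z (transformed correlation) scale, the internal analysis scale of
#' the default ensemble.  The point estimate uses the exact algebraic map
#' r = d / sqrt(d^2 + 4), z = atanh(r) (equivalently z = asinh(d/2)).
#' The standard error requires a per-study sample size: when `n` is not
#' supplied it is back-calculated under the equal-group-size approximation
#' `var(d) = 4/N + d^2/(2N)`, i.e. `N = (d^2 + 8) / (2 se_d^2)`, and then
#' `se_z = 1 / sqrt(N - 3)`.
#'
#' @param d Effect size(s) on the Cohen's d scale.
#' @param se_d Standard error(s) of `d`, strictly positive.
#' @param n Optional total sample size(s); overrides the back-calculated N.
#' @param label Optional study labels used in error messages.
#' @return A list with components `z` and `se` (both numeric vectors) and
#'   `n` (the N used for the variance transformation).
#' @examples
#' cohen_d_to_fisher_z(0.5, 0.2)
#' @export
cohen_d_to_fisher_z <- function(d, se_d, n = NULL, label = NULL) {
  if (any(!is.finite(d))) stop("invalid-input: non-finite effect size", call. = FALSE)
  if (any(!is.finite(se_d)) || any(se_d <= 0))
    stop("invalid-input: standard errors must be positive", call. = FALSE)
  N <- if (is.null(n)) (d^2 + 8) / (2 * se_d^2) else rep_len(as.numeric(n), length(d))
  bad <- which(N <= 3)
  if (length(bad)) {
    who <- if (is.null(label)) paste("study", bad) else label[bad]
    stop("degenerate-study: implied sample size <= 3 for ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  list(z = asinh(d / 2), se = 1 / sqrt(N - 3), n = N)
}

#' Convert Fisher's z back to Cohen's d
#'
#' Exact inverse of [cohen_d_to_fisher_z()]: `d = 2 sinh(z)` and the
#' standard error is recovered by inverting `se_z = 1/sqrt(N - 3)` and
#' `N = (d^2 + 8) / (2 se_d^2)`.  Round-trips are exact to numerical
#' precision.
#'
#' @param z Effect size(s) on the Fisher z scale.
#' @param se_z Standard error(s) of `z`, strictly positive.
#' @param n Optional total sample size(s); overrides the N implied by `se_z`.
#' @return A list with components `d` and `se`.
#' @export
fisher_z_to_cohen_d <- function(z, se_z, n = NULL) {
  if (any(!is.finite(se_z)) || any(se_z <= 0))
    stop("invalid-input: standard errors must be positive", call. = FALSE)
  d <- 2 * sinh(z)
  N <- if (is.null(n)) 1 / se_z^2 + 3 else rep_len(as.numeric(n), length(z))
  list(d = d, se = sqrt((d^2 + 8) / (2 * N)))
}

#' p-value of a study estimate
#'
#' Normal-theory p-value of `y/se`.  Two-sided: `2 * (1 - pnorm(|y|/se))`.
#' One-sided with positive expected direction: `1 - pnorm(y/se)`; with
#' negative direction the sign is mirrored.
#'
#' @param y Effect size estimate(s).
#' @param se Standard error(s), strictly positive.
#' @param sidedness `"one"` or `"two"`.
#' @param direction `"positive"` (default) or `"negative"`; only used for
#'   one-sided p-values.
#' @return p-values in `[0, 1]`.
#' @export
p_value <- function(y, se, sidedness = c("two", "one"),
                    direction = c("positive", "negative")) {
  sidedness <- match.arg(sidedness)
  direction <- match.arg(direction)
  if (any(se <= 0)) stop("invalid-input: se must be positive", call. = FALSE)
  if (sidedness == "two") {
    2 * stats::pnorm(abs(y) / se, lower.tail = FALSE)
  } else {
    sgn <- if (direction == "positive") 1 else -1
    stats::pnorm(sgn * y / se, lower.tail = FALSE)
  }
}

#' Effect-size boundary for a p-value cutoff
#'
#' Inverse of [p_value()] at a fixed standard error: the y-space boundary
#' at which the p-value equals `cutoff`.  One-sided: a single threshold
#' `se * qnorm(1 - cutoff)` (sign mirrored for negative direction);
#' two-sided: the pair `+/- se * qnorm(1 - cutoff/2)`.
#'
#' @inheritParams p_value
#' @param cutoff p-value cutoff in (0, 1).
#' @return A numeric vector of length 1 (one-sided) or 2 (two-sided).
#' @export
p_cutoff_to_y_threshold <- function(cutoff, sidedness = c("two", "one"),
                                    direction = c("positive", "negative"),
                                    se = 1) {
  sidedness <- match.arg(sidedness)
  direction <- match.arg(direction)
  if (cutoff <= 0 || cutoff >= 1)
    stop("invalid-input: cutoff must lie in (0, 1)", call. = FALSE)
  if (se <= 0) stop("invalid-input: se must be positive", call. = FALSE)
  if (sidedness == "two") {
    q <- se * stats::qnorm(1 - cutoff / 2)
    c(-q, q)
  } else {
    sgn <- if (direction == "positive") 1 else -1
    sgn * se * stats::qnorm(1 - cutoff)
  }
}

#' Study-level meta-analytic data
#'
#' Container for the per-study estimates entering the ensemble.  The scale
#' attribute records whether `y` is a Cohen's d, a Fisher z, or a generic
#' ("raw") effect; `direction` records the expected sign of the effect for
#' one-sided selection.
#'
#' @param y Effect sizes (finite numeric).
#' @param se Standard errors, strictly positive.
#' @param n Optional total sample sizes (integers >= 4).
#' @param label Optional study labels.
#' @param scale `"cohens_d"`, `"fishers_z"` or `"raw"`.
#' @param direction `"positive"` or `"negative"`.
#' @return An object of class `study_data` (a data frame with attributes).
#' @export
study_data <- function(y, se, n = NULL, label = NULL,
                       scale = c("raw", "cohens_d", "fishers_z"),
                       direction = c("positive", "negative")) {
  scale <- match.arg(scale)
  direction <- match.arg(direction)
  y <- as.numeric(y); se <- as.numeric(se)
  if (length(y) < 1L) stop("invalid-input: need at least one study", call. = FALSE)
  if (length(se) != length(y)) stop("invalid-input: y and se lengths differ", call. = FALSE)
  if (any(!is.finite(y))) stop("invalid-input: non-finite effect sizes", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("invalid-input: all standard errors must be positive", call. = FALSE)
  if (!is.null(n)) {
    n <- as.numeric(n)
    if (any(!is.na(n) & n < 4)) stop("invalid-input: n must be >= 4", call. = FALSE)
  }
  if (is.null(label)) label <- paste0("study_", seq_along(y))
  out <- data.frame(label = as.character(label), y = y, se = se,
                    n = if (is.null(n)) NA_real_ else n,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  attr(out, "direction") <- direction
  class(out) <- c("study_data", "data.frame")
  out
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("study_data: K = %d studies on the %s scale (direction: %s)\n",
              nrow(x), attr(x, "scale"), attr(x, "direction")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Internal: move study_data onto the analysis scale used for fitting.
# Returns list(data, analysis = "direct"|"d_to_z").
.to_analysis_scale <- function(data, transform = TRUE) {
  scale <- attr(data, "scale")
  if (identical(scale, "cohens_d") && transform) {
    n <- if (all(is.na(data$n))) NULL else ifelse(is.na(data$n),
                                                  (data$y^2 + 8) / (2 * data$se^2),
                                                  data$n)
    tr <- cohen_d_to_fisher_z(data$y, data$se, n = n, label = data$label)
    out <- study_data(tr$z, tr$se, n = tr$n, label = data$label,
                      scale = "fishers_z", direction = attr(data, "direction"))
    list(data = out, analysis = "d_to_z")
  } else {
    list(data = data, analysis = "direct")
  }
}
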