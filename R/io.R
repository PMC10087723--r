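# Study-table I/O and the end-to-end analysis driver.

#' Read a study table from CSV
#'
#' Expects a header with an effect column (`y`, `d`, `z` or `effect`), a
#' standard-error column `se`, and optionally `n` (total sample size) and a
#' label column (`study` or `label`).  Rows missing both `se` and `n` are
#' rejected with row-numbered messages; on the Cohen's d scale a missing
#' `se` is back-filled from `n` via `se^2 = (8 + d^2)/(2n)`.
#'
#' @param path CSV file path.
#' @param scale Scale of the effect column.
#' @param direction Expected effect direction for one-sided selection.
#' @return A [study_data()] object.
#' @export
read_studies <- function(path, scale = c("cohens_d", "fishers_z", "raw"),
                         direction = c("positive", "negative")) {
  scale <- match.arg(scale)
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  eff_col <- intersect(c("y", "d", "z", "effect"), names(df))[1]
  if (is.na(eff_col)) stop("malformed CSV: no effect column (y/d/z/effect)",
                           call. = FALSE)
  if (!"se" %in% names(df) && !"n" %in% names(df))
    stop("malformed CSV: need an se or n column", call. = FALSE)
  y <- as.numeric(df[[eff_col]])
  se <- if ("se" %in% names(df)) as.numeric(df$se) else rep(NA_real_, nrow(df))
  n <- if ("n" %in% names(df)) as.numeric(df$n) else rep(NA_real_, nrow(df))
  lab_col <- intersect(c("study", "label"), names(df))[1]
  label <- if (!is.na(lab_col)) as.character(df[[lab_col]]) else NULL

  bad <- which(is.na(se) & is.na(n))
  if (length(bad))
    stop("rows missing both se and n: ", paste(bad, collapse = ", "),
         call. = FALSE)
  fill <- which(is.na(se))
  if (length(fill)) {
    if (scale != "cohens_d")
      stop("rows missing se can only be back-filled on the Cohen's d scale: ",
           paste(fill, collapse = ", "), call. = FALSE)
    se[fill] <- sqrt((8 + y[fill]^2) / (2 * n[fill]))
  }
  bad_se <- which(se <= 0)
  if (length(bad_se))
    stop("non-positive se in rows: ", paste(bad_se, collapse = ", "),
         call. = FALSE)
  study_data(y, se, n = if (all(is.na(n))) NULL else n, label = label,
             scale = scale, direction = direction)
}

#' Run a complete analysis from a configuration
#'
#' Drives the full pipeline: read the study table, build the requested
#' ensemble, fit every model, aggregate, and (optionally) write a JSON
#' report plus a human-readable per-model table.
#'
#' @param config Named list (or path to a JSON file) with entries `input`
#'   (CSV path), and optionally `scale`, `direction`, `models` (one of
#'   `"psma"`, `"selection"`, `"petpeese"`, `"none"`), `chains`,
#'   `iterations`, `burnin`, `seed`, `out` (output path stem),
#'   `no_transform`, `verbose`.
#' @return The `ensemble_fit`, invisibly, with attribute `"report"` (the
#'   report list written to JSON).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$input))
  cfg <- utils::modifyList(
    list(scale = "cohens_d", direction = "positive", models = "psma",
         chains = 4, iterations = 5000, burnin = 1000, seed = 1,
         out = NULL, no_transform = FALSE, verbose = FALSE),
    config)
  data <- read_studies(cfg$input, scale = cfg$scale, direction = cfg$direction)
  pri <- default_priors()
  ens <- switch(cfg$models,
    psma = build_ensemble(),
    selection = build_ensemble(pet_prior = NULL, peese_prior = NULL),
    petpeese = build_ensemble(weight_fns = NULL),
    none = build_ensemble(weight_fns = NULL, pet_prior = NULL, peese_prior = NULL),
    stop("unknown models choice: ", cfg$models, call. = FALSE))
  settings <- mcmc_settings(chains = cfg$chains, iterations = cfg$iterations,
                            burnin = cfg$burnin, seed = cfg$seed)
  fit <- fit_ensemble(data, ens, settings, transform = !cfg$no_transform,
                      verbose = isTRUE(cfg$verbose))

  report <- list(
    seed = cfg$seed,
    K = nrow(data),
    scale = cfg$scale,
    models = cfg$models,
    bf = list(effect = fit$bf_effect, heterogeneity = fit$bf_heterogeneity,
              bias = fit$bf_bias,
              selection_vs_petpeese = fit$bf_selection_vs_petpeese,
              effect_reciprocal = 1 / fit$bf_effect),
    evidence_effect = unname(evidence_category(fit$bf_effect)),
    mu = list(mean = fit$mu$mean, ci = fit$mu$ci,
              spike_weight = fit$mu$spike_weight),
    tau = list(mean = fit$tau$mean, ci = fit$tau$ci,
               spike_weight = fit$tau$spike_weight),
    mu_analysis_scale = list(mean = fit$mu_analysis$mean, ci = fit$mu_analysis$ci),
    tau_analysis_scale = list(mean = fit$tau_analysis$mean, ci = fit$tau_analysis$ci),
    model_table = ensemble_table(fit))
  if (!is.null(cfg$out)) {
    jsonlite::write_json(report, paste0(cfg$out, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- utils::capture.output(summary(fit))
    writeLines(txt, paste0(cfg$out, ".txt"))
  }
  attr(fit, "report") <- report
  invisible(fit)
}
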