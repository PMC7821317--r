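# Reading and writing small configuration and result files.

#' Read or write a stress-scenario configuration
#'
#' Scenario configs are YAML key-value files with fields `label`, `sigma_f`,
#' `sigma_m` and optionally `n_per_sex` and `seed`.
#'
#' @param path file path.
#' @return `read_scenario()` returns a list with `scenario` (a
#'   [stress_scenario()]) plus any `n_per_sex`/`seed` present;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$label)) stop_invalid("scenario config needs a `label` field.")
  list(
    scenario = stress_scenario(cfg$label,
                               sigma_f = cfg$sigma_f %||% 0,
                               sigma_m = cfg$sigma_m %||% 0),
    n_per_sex = cfg$n_per_sex,
    seed = cfg$seed
  )
}

#' @rdname read_scenario
#' @param scenario a [stress_scenario()].
#' @param n_per_sex,seed optional run settings stored alongside the scenario.
#' @export
write_scenario <- function(scenario, path, n_per_sex = NULL, seed = NULL) {
  if (!inherits(scenario, "stress_scenario")) {
    stop_invalid("`scenario` must be a stress_scenario.")
  }
  cfg <- list(label = scenario$label, sigma_f = scenario$sigma_f,
              sigma_m = scenario$sigma_m)
  if (!is.null(n_per_sex)) cfg$n_per_sex <- n_per_sex
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read or write reproduction-model parameters
#'
#' Parameter configs are YAML files mirroring the [reproduction_params()]
#' arguments: coefficients `g_m`, `g_f`, `mc`, `harm`, `gift` and logical
#' variant flags. Missing fields take the package defaults (baseline model,
#' `g_m = 2`).
#'
#' @param path file path.
#' @return `read_reproduction_params()` returns a [reproduction_params()];
#'   `write_reproduction_params()` returns `path` invisibly.
#' @export
read_reproduction_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- reproduction_params()
  reproduction_params(
    g_m = cfg$g_m %||% defaults$g_m,
    g_f = cfg$g_f %||% defaults$g_f,
    mc = cfg$mc %||% defaults$mc,
    harm = cfg$harm %||% defaults$harm,
    gift = cfg$gift %||% defaults$gift,
    female_competition = cfg$female_competition %||% FALSE,
    sperm_limitation = cfg$sperm_limitation %||% FALSE,
    male_harm = cfg$male_harm %||% FALSE,
    nuptial_gift = cfg$nuptial_gift %||% FALSE
  )
}

#' @rdname read_reproduction_params
#' @param params a [reproduction_params()].
#' @export
write_reproduction_params <- function(params, path) {
  if (!inherits(params, "reproduction_params")) {
    stop_invalid("`params` must be a reproduction_params object.")
  }
  cfg <- c(
    params[c("g_m", "g_f", "mc", "harm", "gift")],
    as.list(params$flags)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a population or assay table to a delimited file
#'
#' @param x a `population` (written as TSV with columns `sex`, `condition`)
#'   or an assay tibble (written as CSV with the standard assay header).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(x, path) {
  utils::write.table(population_table(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_tsv
#' @export
write_assays_csv <- function(x, path) {
  cols <- c("focal_sex", "treatment", "assay_date", "offspring_count",
            "total_offspring_weight")
  if (!all(cols %in% names(x))) stop_invalid("`x` is not an assay table.")
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Run the full estimation pipeline and collect a report
#'
#' Convenience wrapper running every estimator on one assay table: group mean
#' fitness with percent change vs control, per-group opportunity for
#' selection, per-treatment log male/female variance ratios with contrasts,
#' offspring-weight summaries and per-treatment skewness.
#'
#' @param records a validated assay tibble.
#' @param n_boot bootstrap replicates shared by all estimators.
#' @param seed integer seed.
#' @return A list of class `assay_report` with components `mean_fitness`,
#'   `opportunity`, `sex_bias`, `weights`, `skewness`.
#' @export
analyze_assays <- function(records, n_boot = 2000, seed = 1) {
  structure(
    list(
      mean_fitness = group_mean_fitness(records, n_boot = n_boot, seed = seed),
      opportunity = estimate_opportunity(records, n_boot = n_boot, seed = seed),
      sex_bias = compare_sex_bias(records, n_boot = n_boot, seed = seed),
      weights = offspring_weight_summary(records, n_boot = n_boot, seed = seed),
      skewness = skewness_by_treatment(records)
    ),
    class = "assay_report"
  )
}

#' @export
print.assay_report <- function(x, ...) {
  print(x$mean_fitness)
  cat("\nOpportunity for selection per sex x treatment:\n")
  print(x$opportunity)
  cat("\n")
  print(x$sex_bias)
  if (nrow(x$weights)) {
    cat("\nOffspring weight per treatment:\n")
    print(x$weights)
  }
  cat("\nSkewness of raw fitness per treatment:\n")
  print(x$skewness)
  invisible(x)
}

#' Serialize an assay report to JSON
#'
#' @param report an [analyze_assays()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "assay_report")) stop_invalid("`report` must be an assay_report.")
  out <- list(
    mean_fitness = report$mean_fitness$group_means,
    percent_change = report$mean_fitness$percent_change,
    opportunity = report$opportunity,
    log_variance_ratios = report$sex_bias$log_ratios,
    contrasts = report$sex_bias$contrasts,
    weights = report$weights,
    skewness = report$skewness
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
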