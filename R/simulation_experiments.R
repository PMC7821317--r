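#' Run one simulation replicate
#'
#' Draws a population under the stress scenario, randomly partitions each sex
#' into disjoint mating groups of two females and two males, resolves
#' reproduction in every group, and computes the opportunity for selection per
#' sex from the fitness of all individuals pooled across groups.
#'
#' With both sigmas at zero every individual is identical, all fitness values
#' equal 1, and both I values are exactly 0.
#'
#' @param scenario a [stress_scenario()].
#' @param params a [reproduction_params()].
#' @param n_per_sex individuals per sex (even; default 1000).
#' @param seed integer seed; population draw and group partition use
#'   independent sub-streams derived from it.
#' @param details if `TRUE`, also return the population, the group assignment
#'   and the per-individual fitness vectors (used for cross-checking against
#'   hand evaluation of the group equations).
#' @return A list with elements `I_f`, `I_m` (and, when `details = TRUE`,
#'   `female_fitness`, `male_fitness`, `female_groups`, `male_groups`,
#'   `population`).
#' @examples
#' sc <- stress_scenario("female_only", sigma_f = 0.2, sigma_m = 0.05)
#' simulate_replicate(sc, reproduction_params(), n_per_sex = 200, seed = 1)[c("I_f", "I_m")]
#' @export
simulate_replicate <- function(scenario, params = reproduction_params(),
                               n_per_sex = 1000, seed = 1, details = FALSE) {
  n_per_sex <- check_count(n_per_sex, "n_per_sex", min = 2L)
  if (n_per_sex %% 2L != 0L) stop_invalid("`n_per_sex` must be even.")
  seed <- check_seed(seed)
  pop <- make_population(n_per_sex, scenario, seed)

  # Uniform random partition into groups: a permutation of each sex, read off
  # in consecutive pairs.
  perm_f <- with_seed(derive_seed(seed, "partition", "F"), sample.int(n_per_sex))
  perm_m <- with_seed(derive_seed(seed, "partition", "M"), sample.int(n_per_sex))
  i1 <- seq(1L, n_per_sex, by = 2L)
  f1 <- perm_f[i1]; f2 <- perm_f[i1 + 1L]
  m1 <- perm_m[i1]; m2 <- perm_m[i1 + 1L]

  w <- group_fitness_vec(pop$female[f1], pop$female[f2],
                         pop$male[m1], pop$male[m2], params)
  wf <- numeric(n_per_sex); wm <- numeric(n_per_sex)
  wf[f1] <- w$wf1; wf[f2] <- w$wf2
  wm[m1] <- w$wm1; wm[m2] <- w$wm2

  out <- list(
    I_f = if (stats::var(wf) == 0) 0 else opportunity_for_selection(wf),
    I_m = if (stats::var(wm) == 0) 0 else opportunity_for_selection(wm)
  )
  if (details) {
    out$female_fitness <- wf
    out$male_fitness <- wm
    out$female_groups <- cbind(f1, f2)
    out$male_groups <- cbind(m1, m2)
    out$population <- pop
  }
  out
}

scenario_for_level <- function(scenario_label, stress, baseline_sigma) {
  switch(scenario_label,
    both = stress_scenario("both", sigma_f = stress, sigma_m = stress),
    female_only = stress_scenario("female_only", sigma_f = stress, sigma_m = baseline_sigma),
    male_only = stress_scenario("male_only", sigma_f = baseline_sigma, sigma_m = stress),
    stop_invalid("unknown sweep scenario '", scenario_label, "'.")
  )
}

#' Sweep stress levels across scenarios
#'
#' For each scenario and each stress level (the SD of the condition
#' distribution of the stressed sex or sexes), runs independent replicates and
#' records per-replicate `I_f`, `I_m` and `log(I_m / I_f)`. In the `"both"`
#' scenario the two sigmas move together; in the sex-limited scenarios the
#' unstressed sex is held at `baseline_sigma` (small but nonzero so its
#' opportunity for selection is defined and positive).
#'
#' @param scenarios character vector from
#'   `c("both", "female_only", "male_only")`.
#' @param stress_grid numeric vector of condition SD values
#'   (default 0.05 to 0.50 by 0.05).
#' @param params a [reproduction_params()].
#' @param n_per_sex individuals per sex per replicate (default 1000).
#' @param replicates replicates per scenario x stress cell (default 20).
#' @param seed top-level seed; each cell and replicate uses an independent
#'   derived sub-stream.
#' @param baseline_sigma condition SD of the unstressed sex (default 0.05).
#' @return A tibble of class `sweep_result` with one row per replicate:
#'   columns `scenario`, `stress`, `rep`, `I_f`, `I_m`, `log_ratio`.
#' @examples
#' res <- run_sweep("both", stress_grid = c(0.1, 0.3), replicates = 2,
#'                  n_per_sex = 200, seed = 7)
#' summarize_sweep(res)
#' @export
run_sweep <- function(scenarios = c("both", "female_only", "male_only"),
                      stress_grid = seq(0.05, 0.5, by = 0.05),
                      params = reproduction_params(),
                      n_per_sex = 1000, replicates = 20, seed = 1,
                      baseline_sigma = 0.05) {
  scenarios <- match.arg(scenarios, c("both", "female_only", "male_only"),
                         several.ok = TRUE)
  if (!is.numeric(stress_grid) || length(stress_grid) == 0 || any(stress_grid < 0)) {
    stop_invalid("`stress_grid` must be a nonempty vector of nonnegative SDs.")
  }
  replicates <- check_count(replicates, "replicates")
  seed <- check_seed(seed)

  cells <- expand.grid(
    rep = seq_len(replicates), stress = stress_grid, scenario = scenarios,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    sc <- scenario_for_level(row$scenario, row$stress, baseline_sigma)
    r <- simulate_replicate(
      sc, params, n_per_sex,
      seed = derive_seed(seed, row$scenario, row$stress, row$rep)
    )
    tibble::tibble(
      scenario = row$scenario, stress = row$stress, rep = row$rep,
      I_f = r$I_f, I_m = r$I_m,
      log_ratio = ifelse(r$I_f > 0 & r$I_m > 0, log(r$I_m / r$I_f), NA_real_)
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Summarize a stress sweep
#'
#' Collapses per-replicate sweep results to one row per scenario x stress
#' cell, averaging the opportunity for selection per sex and the log ratio and
#' retaining replicate dispersion.
#'
#' @param results a [run_sweep()] tibble.
#' @return A tibble with columns `scenario`, `stress`, `replicates`,
#'   `mean_I_f`, `mean_I_m`, `mean_log_ratio`, `sd_I_f`, `sd_I_m`,
#'   `sd_log_ratio`.
#' @export
summarize_sweep <- function(results) {
  required <- c("scenario", "stress", "rep", "I_f", "I_m", "log_ratio")
  if (!all(required %in% names(results))) {
    stop_invalid("`results` must contain columns ", paste(required, collapse = ", "), ".")
  }
  results |>
    dplyr::group_by(.data$scenario, .data$stress) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mean_I_f = mean(.data$I_f),
      mean_I_m = mean(.data$I_m),
      mean_log_ratio = mean(.data$log_ratio, na.rm = TRUE),
      sd_I_f = stats::sd(.data$I_f),
      sd_I_m = stats::sd(.data$I_m),
      sd_log_ratio = stats::sd(.data$log_ratio),
      .groups = "drop"
    )
}

#' Plot a stress sweep
#'
#' Two-panel view of a summarized sweep: sex-specific opportunity for
#' selection against stress, and the logged male/female ratio (positive =
#' male-biased).
#'
#' @param summary a [summarize_sweep()] table.
#' @param which `"I"` for the sex-specific panel, `"ratio"` for the log-ratio
#'   panel.
#' @return A ggplot object.
#' @export
plot_sweep <- function(summary, which = c("I", "ratio")) {
  which <- match.arg(which)
  if (which == "I") {
    long <- summary |>
      tidyr::pivot_longer(c("mean_I_f", "mean_I_m"),
                          names_to = "sex", values_to = "I") |>
      dplyr::mutate(sex = ifelse(.data$sex == "mean_I_f", "females", "males"))
    ggplot2::ggplot(long, ggplot2::aes(.data$stress, .data$I,
                                       colour = .data$sex, shape = .data$sex)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(x = "Stress (condition SD)",
                    y = "Opportunity for selection (I)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(summary, ggplot2::aes(.data$stress, .data$mean_log_ratio,
                                          colour = .data$scenario)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Stress (condition SD)",
                    y = "log(I_m / I_f)") +
      ggplot2::theme_minimal()
  }
}
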