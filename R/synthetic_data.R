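#' Configuration for the synthetic fitness-assay generator
#'
#' Describes a synthetic counterpart of a competitive fitness-assay dataset:
#' per sex-by-treatment group sizes (defaults follow the study design the
#' generator emulates: 102/102 CT, 105 male / 87 female HT, 101 male / 97
#' female AT), mean adult offspring counts per treatment (defaults encode a
#' 14% HT and 36% AT reduction from a CT mean of 40), a target opportunity
#' for selection (variance of relative fitness) per group with a male bias in
#' every treatment, an assay-date random effect, and per-treatment individual
#' offspring weights.
#'
#' @param n named integer vector of group sizes with names `F_CT`, `M_CT`,
#'   `F_HT`, `M_HT`, `F_AT`, `M_AT`.
#' @param mean_count named numeric vector of mean offspring counts per
#'   treatment (`CT`, `HT`, `AT`), shared by the sexes.
#' @param target_I_f,target_I_m named numeric vectors per treatment: the
#'   within-date variance of relative fitness the count distribution should
#'   realize for females and males.
#' @param n_dates number of distinct assay dates (default 10).
#' @param date_sd between-date standard deviation on the relative-fitness
#'   scale (default 0.1); the date effect multiplies group means by a
#'   mean-one lognormal factor shared by all assays of a date.
#' @param weight_mean named numeric vector of mean individual offspring
#'   weight (mg) per treatment; default gives AT offspring 1.3 times the CT
#'   weight.
#' @param weight_cv coefficient of variation of individual offspring weight
#'   (default 0.1).
#' @param max_count optional ceiling on counts (scalar or named per
#'   treatment); truncating the upper tail induces negative skew, mimicking
#'   an environment that caps reproductive performance. `NULL` disables it.
#' @param seed integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n = c(F_CT = 102L, M_CT = 102L, F_HT = 87L, M_HT = 105L,
          F_AT = 97L, M_AT = 101L),
    mean_count = c(CT = 40, HT = 34.4, AT = 25.6),
    target_I_f = c(CT = 0.30, HT = 0.20, AT = 0.45),
    target_I_m = c(CT = 0.55, HT = 0.50, AT = 0.80),
    n_dates = 10L,
    date_sd = 0.1,
    weight_mean = c(CT = 5.0, HT = 4.8, AT = 6.5),
    weight_cv = 0.1,
    max_count = NULL,
    seed = 1L) {
  needed_n <- c("F_CT", "M_CT", "F_HT", "M_HT", "F_AT", "M_AT")
  if (!all(needed_n %in% names(n))) {
    stop_invalid("`n` must be named with ", paste(needed_n, collapse = ", "), ".")
  }
  if (any(n < 2)) stop_invalid("all group sizes must be >= 2.")
  for (nm in list(mean_count = mean_count, target_I_f = target_I_f,
                  target_I_m = target_I_m, weight_mean = weight_mean)) {
    if (!all(TREATMENT_LEVELS %in% names(nm))) {
      stop_invalid("per-treatment vectors must be named CT, HT, AT.")
    }
  }
  if (any(mean_count <= 0) || any(weight_mean <= 0)) {
    stop_invalid("means must be > 0.")
  }
  if (any(target_I_f < 0) || any(target_I_m < 0)) {
    stop_invalid("target I must be >= 0.")
  }
  n_dates <- check_count(n_dates, "n_dates")
  check_nonneg(date_sd, "date_sd", 1L)
  check_nonneg(weight_cv, "weight_cv", 1L)
  if (!is.null(max_count)) {
    if (is.null(names(max_count))) {
      max_count <- stats::setNames(rep(max_count[1], 3), TREATMENT_LEVELS)
    }
    if (!all(TREATMENT_LEVELS %in% names(max_count))) {
      stop_invalid("`max_count` must be a scalar or named per treatment.")
    }
  }
  structure(
    list(n = n, mean_count = mean_count, target_I_f = target_I_f,
         target_I_m = target_I_m, n_dates = n_dates, date_sd = date_sd,
         weight_mean = weight_mean, weight_cv = weight_cv,
         max_count = max_count, seed = check_seed(seed)),
    class = "generator_config"
  )
}

# Negative-binomial size parameter realizing a target variance of relative
# fitness at mean mu: Var = mu + mu^2/k, so Var/mu^2 = 1/mu + 1/k = I.
nb_size_for_target <- function(mu, target_I) {
  if (target_I * mu <= 1) {
    stop_invalid(
      "target I = ", target_I, " is infeasible for a negative-binomial count ",
      "with mean ", mu, ": it requires I > 1/mean = ", signif(1 / mu, 3),
      " (sub-Poisson dispersion; use a different count family or a larger I)."
    )
  }
  mu / (target_I * mu - 1)
}

#' Generate a synthetic fitness-assay table with known ground truth
#'
#' Counts are drawn from a negative binomial whose dispersion is solved so
#' that the within-date variance of relative fitness equals the configured
#' target `I` for each sex-by-treatment group. A mean-one lognormal assay-date
#' factor multiplies the group mean of every assay run on the same date,
#' creating the between-date variance component the estimation pipeline
#' decomposes. Offspring weights are drawn per treatment. The returned ground
#' truth records everything a recovery test needs: the negative-binomial
#' sizes, the exact total variance of relative fitness implied by the
#' configuration (`1/mu + (1 + v_d)/k + v_d`, with `v_d` the squared date
#' SD), and the true per-treatment log male/female variance ratio.
#'
#' @param config a [generator_config()].
#' @return A list with `records` (validated assay tibble) and `truth` (list
#'   with per-group tibble `groups`, `date_sd`, and per-treatment
#'   `log_ratio`).
#' @examples
#' sim <- generate_assays(generator_config(seed = 42))
#' head(sim$records)
#' sim$truth$log_ratio
#' @export
generate_assays <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_invalid("`config` must be a generator_config.")
  }
  v_d <- config$date_sd^2
  groups <- expand.grid(
    focal_sex = SEX_LEVELS, treatment = TREATMENT_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  groups$n <- config$n[paste(groups$focal_sex, groups$treatment, sep = "_")]
  groups$mu <- config$mean_count[groups$treatment]
  groups$target_I <- ifelse(
    groups$focal_sex == "F",
    config$target_I_f[groups$treatment],
    config$target_I_m[groups$treatment]
  )
  groups$nb_size <- mapply(nb_size_for_target, groups$mu, groups$target_I)
  groups$total_var <- 1 / groups$mu + (1 + v_d) / groups$nb_size + v_d

  records <- with_seed(config$seed, {
    s_log <- sqrt(log1p(v_d))
    date_factor <- exp(stats::rnorm(config$n_dates, -s_log^2 / 2, s_log))
    date_labels <- sprintf("d%02d", seq_len(config$n_dates))
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      date_idx <- sample.int(config$n_dates, g$n, replace = TRUE)
      counts <- stats::rnbinom(g$n, size = g$nb_size,
                               mu = g$mu * date_factor[date_idx])
      if (!is.null(config$max_count)) {
        counts <- pmin(counts, config$max_count[[g$treatment]])
      }
      w_mu <- config$weight_mean[[g$treatment]]
      indiv_w <- pmax(stats::rnorm(g$n, w_mu, config$weight_cv * w_mu), 0.01 * w_mu)
      data.frame(
        focal_sex = g$focal_sex, treatment = g$treatment,
        assay_date = date_labels[date_idx],
        offspring_count = counts,
        total_offspring_weight = counts * indiv_w,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })

  truth_groups <- tibble::as_tibble(groups)
  lr <- vapply(TREATMENT_LEVELS, function(tr) {
    vm <- groups$total_var[groups$focal_sex == "M" & groups$treatment == tr]
    vf <- groups$total_var[groups$focal_sex == "F" & groups$treatment == tr]
    log(vm / vf)
  }, numeric(1))

  list(
    records = validate_assays(records, origin = seq_len(nrow(records))),
    truth = list(
      groups = truth_groups,
      date_sd = config$date_sd,
      log_ratio = lr,
      config = config
    )
  )
}

#' Generate assay data from the mechanistic reproduction model
#'
#' Bridges the individual-based simulator and the estimation pipeline: each
#' synthetic assay is one mating group of two females and two males drawn
#' from the treatment's stress scenario, reproduction is resolved with
#' [group_reproduction()], and the focal individual's continuous fitness is
#' converted to an adult offspring count by Poisson sampling around
#' `mean_count * fitness`. The ground truth is the realized opportunity for
#' selection of the continuous focal fitness values, before count noise.
#'
#' @param scenario_map named list mapping each treatment (`CT`, `HT`, `AT`)
#'   to a [stress_scenario()].
#' @param params a [reproduction_params()].
#' @param config a [generator_config()]; group sizes, mean counts, number of
#'   dates and seed are taken from it (targets and date effect are ignored —
#'   the mechanism, not a target, sets the variances here).
#' @return A list with `records` and `truth` (per-group tibble with the
#'   realized continuous-fitness `I_true`).
#' @export
generate_from_mechanism <- function(scenario_map, params = reproduction_params(),
                                    config = generator_config()) {
  if (!all(TREATMENT_LEVELS %in% names(scenario_map))) {
    stop_invalid("`scenario_map` must name a scenario for each of CT, HT, AT.")
  }
  for (tr in TREATMENT_LEVELS) {
    if (!inherits(scenario_map[[tr]], "stress_scenario")) {
      stop_invalid("scenario for ", tr, " is not a stress_scenario.")
    }
  }
  groups <- expand.grid(
    focal_sex = SEX_LEVELS, treatment = TREATMENT_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  groups$n <- config$n[paste(groups$focal_sex, groups$treatment, sep = "_")]

  out <- with_seed(derive_seed(config$seed, "mechanism"), {
    date_labels <- sprintf("d%02d", seq_len(config$n_dates))
    rows <- list(); truth_rows <- list()
    for (i in seq_len(nrow(groups))) {
      g <- groups[i, ]
      sc <- scenario_map[[g$treatment]]
      cf1 <- pmax(0, stats::rnorm(g$n, 1, sc$sigma_f))
      cf2 <- pmax(0, stats::rnorm(g$n, 1, sc$sigma_f))
      cm1 <- pmax(0, stats::rnorm(g$n, 1, sc$sigma_m))
      cm2 <- pmax(0, stats::rnorm(g$n, 1, sc$sigma_m))
      w <- group_fitness_vec(cf1, cf2, cm1, cm2, params)
      w_focal <- if (g$focal_sex == "F") w$wf1 else w$wm1
      mu <- config$mean_count[[g$treatment]]
      counts <- stats::rpois(g$n, lambda = mu * w_focal)
      rows[[i]] <- data.frame(
        focal_sex = g$focal_sex, treatment = g$treatment,
        assay_date = date_labels[(seq_len(g$n) - 1L) %% config$n_dates + 1L],
        offspring_count = counts,
        total_offspring_weight = NA_real_,
        stringsAsFactors = FALSE
      )
      truth_rows[[i]] <- tibble::tibble(
        focal_sex = g$focal_sex, treatment = g$treatment, n = g$n,
        I_true = if (stats::var(w_focal) == 0) 0 else opportunity_for_selection(w_focal)
      )
    }
    list(records = do.call(rbind, rows), truth = dplyr::bind_rows(truth_rows))
  })

  list(
    records = validate_assays(out$records, origin = seq_len(nrow(out$records))),
    truth = list(groups = out$truth, scenario_map = scenario_map)
  )
}
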