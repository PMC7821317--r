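SEX_LEVELS <- c("F", "M")
TREATMENT_LEVELS <- c("CT", "HT", "AT")

# Validate a raw assay data frame; `origin` labels rows in error messages
# (file line numbers when reading from disk, row numbers otherwise).
validate_assays <- function(df, origin = seq_len(nrow(df)) + 1L) {
  required <- c("focal_sex", "treatment", "assay_date", "offspring_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_invalid("assay table is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), ".")
  }
  if (!"total_offspring_weight" %in% names(df)) {
    df$total_offspring_weight <- NA_real_
  }
  if (nrow(df) == 0L) stop_invalid("assay table has no rows.")

  sex <- as.character(df$focal_sex)
  trt <- as.character(df$treatment)
  cnt <- suppressWarnings(as.numeric(df$offspring_count))
  wgt_raw <- df$total_offspring_weight
  wgt_missing <- is.na(wgt_raw) | trimws(as.character(wgt_raw)) == ""
  wgt <- suppressWarnings(as.numeric(ifelse(wgt_missing, NA, wgt_raw)))

  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows)) {
      problems <<- c(problems, paste0(
        what, " (line ", paste(origin[which(rows)], collapse = ", "), ")"
      ))
    }
  }
  bad(!sex %in% SEX_LEVELS, "focal_sex not in {F, M}")
  bad(!trt %in% TREATMENT_LEVELS, "treatment not in {CT, HT, AT}")
  bad(is.na(cnt) | !is.finite(cnt) | cnt < 0 | cnt != round(cnt),
      "offspring_count not a nonnegative integer")
  bad(!wgt_missing & (is.na(wgt) | !is.finite(wgt) | wgt < 0),
      "total_offspring_weight not a nonnegative number")
  if (length(problems)) {
    stop_invalid("invalid assay rows:\n  ", paste(problems, collapse = "\n  "))
  }

  tibble::tibble(
    focal_sex = sex,
    treatment = trt,
    assay_date = as.character(df$assay_date),
    offspring_count = as.integer(cnt),
    total_offspring_weight = wgt,
    individual_offspring_weight = ifelse(cnt > 0, wgt / cnt, NA_real_)
  )
}

#' Load a fitness-assay table
#'
#' Reads a CSV or TSV of lifetime competitive fitness assays: one row per
#' focal individual, with its sex, experimental treatment, assay date, adult
#' offspring count (the fitness measure) and optionally the total weight of
#' those offspring. All rows are validated against the closed sex/treatment
#' vocabularies and integer count requirement; malformed rows are reported
#' with their file line numbers.
#'
#' @param path path to a delimited file with header columns `focal_sex`
#'   (`F`/`M`), `treatment` (`CT`/`HT`/`AT`), `assay_date`,
#'   `offspring_count`, and optionally `total_offspring_weight` (mg).
#'   Tab-delimited files are detected from a `.tsv`/`.txt` extension or an
#'   embedded tab in the header.
#' @return A tibble of validated assay records with a derived
#'   `individual_offspring_weight` column (`total / count`, `NA` when the
#'   count is 0 or the weight is missing).
#' @export
load_assays <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header) || grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  validate_assays(df)
}

#' Construct an assay table from vectors
#'
#' In-memory counterpart of [load_assays()] with the same validation;
#' convenient for simulated data and tests.
#'
#' @param focal_sex,treatment,assay_date,offspring_count,total_offspring_weight
#'   parallel vectors, one entry per assay.
#' @return A validated assay tibble.
#' @export
assay_table <- function(focal_sex, treatment, assay_date, offspring_count,
                        total_offspring_weight = NA_real_) {
  df <- data.frame(
    focal_sex = focal_sex, treatment = treatment,
    assay_date = assay_date, offspring_count = offspring_count,
    total_offspring_weight = total_offspring_weight,
    stringsAsFactors = FALSE
  )
  validate_assays(df, origin = seq_len(nrow(df)))
}

# One-way random-effects method-of-moments (ANOVA estimator) on a numeric
# vector grouped by date. Returns within/between components; between is
# floored at 0. Falls back to a within-only decomposition (between = 0) when
# there are not at least 2 dates and at least one within-date residual df.
mom_decompose <- function(w, date) {
  date <- factor(date)
  n_i <- tabulate(date)
  k <- nlevels(date)
  n <- length(w)
  if (k < 2L || n - k < 1L) {
    return(list(within = stats::var(w), between = 0,
                total = stats::var(w), n_dates = k, degenerate = TRUE))
  }
  means_i <- as.vector(rowsum(w, date)) / n_i
  ssw <- sum((w - means_i[as.integer(date)])^2)
  msw <- ssw / (n - k)
  grand <- mean(w)
  msb <- sum(n_i * (means_i - grand)^2) / (k - 1)
  # standard unbalanced-design coefficient for the expected between-group MS
  n0 <- (n - sum(n_i^2) / n) / (k - 1)
  between <- max(0, (msb - msw) / n0)
  list(within = msw, between = between, total = msw + between,
       n_dates = k, degenerate = FALSE)
}

#' Decompose variance in relative fitness by assay date
#'
#' Within one sex-by-treatment group, mean-standardizes fitness (offspring
#' count) and partitions its variance into a between-date component (the
#' assay-date random effect) and a within-date component, using the one-way
#' random-effects method-of-moments (ANOVA) estimator with the standard
#' unbalanced-design coefficient. The total phenotypic variance is the sum of
#' the two components; the between-date component is floored at zero.
#'
#' Groups with fewer than two dates (or no within-date residual degrees of
#' freedom) fall back, with a warning, to a within-only decomposition whose
#' total is the ordinary sample variance.
#'
#' @param records a validated assay tibble ([load_assays()]/[assay_table()]).
#' @param focal_sex `"F"` or `"M"`.
#' @param treatment `"CT"`, `"HT"` or `"AT"`.
#' @return A list of class `variance_decomposition`: `focal_sex`,
#'   `treatment`, `n`, `n_dates`, `within`, `between`, `total`.
#' @export
decompose_variance <- function(records, focal_sex, treatment) {
  focal_sex <- match.arg(focal_sex, SEX_LEVELS)
  treatment <- match.arg(treatment, TREATMENT_LEVELS)
  sub <- records[records$focal_sex == focal_sex & records$treatment == treatment, ]
  if (nrow(sub) < 2L) {
    stop_invalid("group ", focal_sex, " x ", treatment, " has fewer than 2 records.")
  }
  w <- mean_standardize(sub$offspring_count)
  d <- mom_decompose(w, sub$assay_date)
  if (d$degenerate) {
    warning("group ", focal_sex, " x ", treatment,
            ": fewer than 2 informative assay dates; between-date component set to 0.",
            call. = FALSE)
  }
  structure(
    list(focal_sex = focal_sex, treatment = treatment, n = nrow(sub),
         n_dates = d$n_dates, within = d$within, between = d$between,
         total = d$total),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> %s x %s (n = %d, %d dates): total = %.4g (between %.4g + within %.4g)\n",
    x$focal_sex, x$treatment, x$n, x$n_dates, x$total, x$between, x$within
  ))
  invisible(x)
}

# Stratified (by date) resampling machinery shared by the bootstrap
# estimators: resample individuals with replacement within each date stratum,
# keeping stratum sizes fixed.
make_strata <- function(date) {
  split(seq_along(date), date)
}

resample_strata <- function(strata) {
  unlist(lapply(strata, function(s) {
    s[sample.int(length(s), length(s), replace = TRUE)]
  }), use.names = FALSE)
}

# Total variance of mean-standardized w under the date decomposition, for a
# resampled index vector; dates travel with the indices.
boot_total_variance <- function(w_raw, date, idx) {
  w <- w_raw[idx]
  m <- mean(w)
  if (m <= 0) return(NA_real_)
  mom_decompose(w / m, date[idx])$total
}

#' Opportunity for selection per sex-by-treatment group
#'
#' For every sex-by-treatment group: mean-standardizes offspring counts so
#' the group mean is 1, estimates the total phenotypic variance of relative
#' fitness (between-date + within-date components via
#' [decompose_variance()]), and reports it as Crow's opportunity for
#' selection `I`, with a nonparametric bootstrap percentile interval obtained
#' by resampling individuals within assay dates.
#'
#' @param records a validated assay tibble.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return A tibble with one row per group: `focal_sex`, `treatment`, `n`,
#'   `n_dates`, `I`, `ci_low`, `ci_high`.
#' @export
estimate_opportunity <- function(records, n_boot = 2000, seed = 1, level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  groups <- unique(records[c("focal_sex", "treatment")])
  groups <- groups[order(groups$treatment, groups$focal_sex), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sx <- groups$focal_sex[i]; tr <- groups$treatment[i]
    dec <- suppressWarnings(decompose_variance(records, sx, tr))
    sub <- records[records$focal_sex == sx & records$treatment == tr, ]
    strata <- make_strata(sub$assay_date)
    w_raw <- as.numeric(sub$offspring_count)
    boots <- with_seed(derive_seed(seed, "I", sx, tr), {
      vapply(seq_len(n_boot), function(b) {
        boot_total_variance(w_raw, sub$assay_date, resample_strata(strata))
      }, numeric(1))
    })
    ci <- boot_ci(boots, level)
    tibble::tibble(
      focal_sex = sx, treatment = tr, n = dec$n, n_dates = dec$n_dates,
      I = dec$total, ci_low = ci[1], ci_high = ci[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean fitness per group and percent change relative to control
#'
#' Arithmetic mean adult offspring count per sex-by-treatment group with
#' bootstrap percentile intervals, plus, pooling sexes, the percent reduction
#' in mean fitness of each treatment relative to the control (CT):
#' `100 * (1 - mean_T / mean_CT)`.
#'
#' @param records a validated assay tibble.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return A list of class `mean_fitness_summary` with `group_means` (tibble:
#'   `focal_sex`, `treatment`, `n`, `mean_fitness`, `ci_low`, `ci_high`) and
#'   `percent_change` (tibble: `treatment`, `mean_fitness`,
#'   `percent_change_vs_ct`).
#' @export
group_mean_fitness <- function(records, n_boot = 2000, seed = 1, level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  if (!"CT" %in% records$treatment) {
    stop_invalid("no CT (control) records: percent change has no reference.")
  }
  groups <- unique(records[c("focal_sex", "treatment")])
  groups <- groups[order(groups$treatment, groups$focal_sex), ]
  gm <- lapply(seq_len(nrow(groups)), function(i) {
    sx <- groups$focal_sex[i]; tr <- groups$treatment[i]
    w <- records$offspring_count[records$focal_sex == sx & records$treatment == tr]
    if (length(w) < 2L) {
      stop_invalid("group ", sx, " x ", tr, " has fewer than 2 records.")
    }
    boots <- with_seed(derive_seed(seed, "mean", sx, tr), {
      vapply(seq_len(n_boot), function(b) {
        mean(w[sample.int(length(w), length(w), replace = TRUE)])
      }, numeric(1))
    })
    ci <- boot_ci(boots, level)
    tibble::tibble(focal_sex = sx, treatment = tr, n = length(w),
                   mean_fitness = mean(w), ci_low = ci[1], ci_high = ci[2])
  })
  gm <- dplyr::bind_rows(gm)

  pooled <- vapply(split(records$offspring_count, records$treatment), mean, numeric(1))
  trts <- intersect(TREATMENT_LEVELS, names(pooled))
  pc <- tibble::tibble(
    treatment = trts,
    mean_fitness = unname(pooled[trts]),
    percent_change_vs_ct = 100 * (1 - unname(pooled[trts]) / pooled[["CT"]])
  )
  structure(list(group_means = gm, percent_change = pc),
            class = "mean_fitness_summary")
}

#' @export
print.mean_fitness_summary <- function(x, ...) {
  cat("Mean fitness per sex x treatment:\n")
  print(x$group_means)
  cat("\nPercent change vs CT (pooled sexes):\n")
  print(x$percent_change)
  invisible(x)
}

#' Sex bias in the opportunity for selection, with treatment contrasts
#'
#' Per treatment, computes the log ratio of male over female total variance
#' in relative fitness, `log(V_m / V_f)` (positive = male-biased opportunity
#' for selection), with a bootstrap percentile interval obtained by
#' resampling individuals within sex and assay date. Pairwise treatment
#' contrasts of the log ratio are tested by two-sided bootstrap exceedance of
#' zero, Bonferroni-corrected for the number of contrasts.
#'
#' @param records a validated assay tibble; both sexes must be present in
#'   every treatment.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return A list of class `sex_bias_summary` with `log_ratios` (tibble:
#'   `treatment`, `n_m`, `n_f`, `log_ratio`, `ci_low`, `ci_high`) and
#'   `contrasts` (tibble: `treatment_1`, `treatment_2`, `difference`,
#'   `p_value`, `p_bonferroni`).
#' @export
compare_sex_bias <- function(records, n_boot = 2000, seed = 1, level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  trts <- intersect(TREATMENT_LEVELS, unique(records$treatment))
  if (length(trts) == 0L) stop_invalid("no recognized treatments present.")

  boot_lr <- matrix(NA_real_, nrow = n_boot, ncol = length(trts),
                    dimnames = list(NULL, trts))
  point <- numeric(length(trts)); n_m <- integer(length(trts)); n_f <- integer(length(trts))

  for (j in seq_along(trts)) {
    tr <- trts[j]
    sub_m <- records[records$focal_sex == "M" & records$treatment == tr, ]
    sub_f <- records[records$focal_sex == "F" & records$treatment == tr, ]
    if (nrow(sub_m) < 2L || nrow(sub_f) < 2L) {
      stop_invalid("treatment ", tr, " needs both sexes with >= 2 records.")
    }
    v_m <- suppressWarnings(decompose_variance(records, "M", tr))$total
    v_f <- suppressWarnings(decompose_variance(records, "F", tr))$total
    if (v_f == 0 || v_m == 0) {
      stop_degenerate("zero variance in relative fitness in treatment ", tr, ".")
    }
    point[j] <- log(v_m / v_f)
    n_m[j] <- nrow(sub_m); n_f[j] <- nrow(sub_f)

    strata_m <- make_strata(sub_m$assay_date)
    strata_f <- make_strata(sub_f$assay_date)
    w_m <- as.numeric(sub_m$offspring_count)
    w_f <- as.numeric(sub_f$offspring_count)
    boot_lr[, j] <- with_seed(derive_seed(seed, "lr", tr), {
      vapply(seq_len(n_boot), function(b) {
        vm <- boot_total_variance(w_m, sub_m$assay_date, resample_strata(strata_m))
        vf <- boot_total_variance(w_f, sub_f$assay_date, resample_strata(strata_f))
        if (is.na(vm) || is.na(vf) || vf == 0 || vm == 0) NA_real_ else log(vm / vf)
      }, numeric(1))
    })
  }

  cis <- apply(boot_lr, 2, boot_ci, level = level)
  log_ratios <- tibble::tibble(
    treatment = trts, n_m = n_m, n_f = n_f, log_ratio = point,
    ci_low = cis[1, ], ci_high = cis[2, ]
  )

  contrasts <- NULL
  if (length(trts) >= 2L) {
    pairs <- utils::combn(trts, 2)
    n_contrasts <- ncol(pairs)
    contrasts <- lapply(seq_len(n_contrasts), function(p) {
      t1 <- pairs[1, p]; t2 <- pairs[2, p]
      diff_b <- boot_lr[, t1] - boot_lr[, t2]
      diff_b <- diff_b[is.finite(diff_b)]
      p_raw <- 2 * min(mean(diff_b <= 0), mean(diff_b >= 0))
      p_raw <- max(p_raw, 1 / length(diff_b))  # bootstrap resolution floor
      tibble::tibble(
        treatment_1 = t1, treatment_2 = t2,
        difference = point[match(t1, trts)] - point[match(t2, trts)],
        p_value = min(1, p_raw),
        p_bonferroni = min(1, p_raw * n_contrasts)
      )
    })
    contrasts <- dplyr::bind_rows(contrasts)
  }
  structure(list(log_ratios = log_ratios, contrasts = contrasts),
            class = "sex_bias_summary")
}

#' @export
print.sex_bias_summary <- function(x, ...) {
  cat("log(V_m / V_f) per treatment (positive = male-biased):\n")
  print(x$log_ratios)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise treatment contrasts of the log ratio:\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' Offspring weight summaries per treatment
#'
#' Mean total offspring weight and mean individual offspring weight
#' (total / count, defined only for assays with at least one offspring) per
#' treatment, with bootstrap percentile intervals. Assays without weight
#' measurements are excluded; if no weights are present at all an empty
#' summary is returned.
#'
#' @param records a validated assay tibble.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return A tibble with one row per treatment and measure (`total` /
#'   `individual`): `treatment`, `measure`, `n`, `mean_weight`, `ci_low`,
#'   `ci_high`. Zero rows if no weights are available.
#' @export
offspring_weight_summary <- function(records, n_boot = 2000, seed = 1, level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  seed <- check_seed(seed)
  has_weight <- !is.na(records$total_offspring_weight)
  if (!any(has_weight)) {
    message("no offspring weights present; returning empty summary.")
    return(tibble::tibble(
      treatment = character(0), measure = character(0), n = integer(0),
      mean_weight = numeric(0), ci_low = numeric(0), ci_high = numeric(0)
    ))
  }
  recs <- records[has_weight, ]
  trts <- intersect(TREATMENT_LEVELS, unique(recs$treatment))
  rows <- list()
  for (tr in trts) {
    sub <- recs[recs$treatment == tr, ]
    series <- list(
      total = sub$total_offspring_weight,
      individual = sub$individual_offspring_weight[!is.na(sub$individual_offspring_weight)]
    )
    for (ms in names(series)) {
      w <- series[[ms]]
      if (length(w) < 2L) next
      boots <- with_seed(derive_seed(seed, "weight", tr, ms), {
        vapply(seq_len(n_boot), function(b) {
          mean(w[sample.int(length(w), length(w), replace = TRUE)])
        }, numeric(1))
      })
      ci <- boot_ci(boots, level)
      rows[[paste(tr, ms)]] <- tibble::tibble(
        treatment = tr, measure = ms, n = length(w),
        mean_weight = mean(w), ci_low = ci[1], ci_high = ci[2]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Skewness of the fitness distribution per treatment
#'
#' Skewness of raw offspring counts per treatment, pooling the sexes. A
#' negative value flags a compressed upper tail, e.g. an environmental
#' ceiling on reproductive performance; a positive value a long right tail.
#'
#' @param records a validated assay tibble.
#' @return A tibble with columns `treatment`, `n`, `skewness`.
#' @export
skewness_by_treatment <- function(records) {
  trts <- intersect(TREATMENT_LEVELS, unique(records$treatment))
  dplyr::bind_rows(lapply(trts, function(tr) {
    w <- records$offspring_count[records$treatment == tr]
    tibble::tibble(treatment = tr, n = length(w),
                   skewness = fitness_skewness(as.numeric(w)))
  }))
}
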