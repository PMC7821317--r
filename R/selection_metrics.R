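#' Mean-standardize a fitness vector
#'
#' Divides fitness by its mean so the group mean is exactly 1; the variance of
#' the result is then the opportunity for selection. Rank order is preserved.
#'
#' @param w numeric fitness vector, length >= 2, finite, nonnegative, with a
#'   strictly positive mean.
#' @return Relative-fitness vector with mean 1.
#' @examples
#' mean_standardize(c(2, 4, 6))
#' @export
mean_standardize <- function(w) {
  check_fitness_vector(w)
  w / mean(w)
}

check_fitness_vector <- function(w, min_n = 2L) {
  if (!is.numeric(w) || length(w) < min_n) {
    stop_invalid("fitness vector must be numeric with at least ", min_n, " values.")
  }
  if (anyNA(w) || any(!is.finite(w)) || any(w < 0)) {
    stop_invalid("fitness values must be finite and >= 0.")
  }
  if (mean(w) <= 0) {
    stop_degenerate("fitness vector has nonpositive mean (all zero?); ",
                    "relative fitness is undefined.")
  }
  invisible(w)
}

#' Crow's opportunity for selection
#'
#' `I = var(w) / mean(w)^2`, the variance in relative fitness: the upper bound
#' on the strength of selection on any trait, since it equals the selection
#' differential on a trait perfectly correlated with fitness. Uses the
#' unbiased (n - 1) sample variance. Scale-invariant: `I(k * w) = I(w)` for
#' any `k > 0`.
#'
#' @param w numeric fitness vector (length >= 2, nonnegative, positive mean).
#' @return Nonnegative scalar `I`.
#' @examples
#' opportunity_for_selection(c(1, 3))  # 0.5
#' @export
opportunity_for_selection <- function(w) {
  check_fitness_vector(w)
  stats::var(w) / mean(w)^2
}

#' Log ratio of male over female variance in relative fitness
#'
#' Both vectors are mean-standardized, then the natural log of the ratio of
#' their variances is taken: `log(V_m / V_f)`. Values above zero indicate
#' male-biased opportunity for selection. Invariant to separately rescaling
#' either sex's fitness; antisymmetric under swapping the sexes.
#'
#' @param w_m,w_f male and female fitness vectors.
#' @return Scalar log variance ratio.
#' @examples
#' log_variance_ratio(c(0, 2, 4), c(1, 2, 3))
#' @export
log_variance_ratio <- function(w_m, w_f) {
  check_fitness_vector(w_m)
  check_fitness_vector(w_f)
  v_m <- stats::var(mean_standardize(w_m))
  v_f <- stats::var(mean_standardize(w_f))
  if (v_f == 0) {
    stop_degenerate("female relative fitness has zero variance; ",
                    "log variance ratio is infinite.")
  }
  log(v_m / v_f)
}

#' Skewness of a fitness distribution
#'
#' Adjusted Fisher-Pearson standardized third moment (the `type = 2`
#' estimator, the default of major statistical software): negative values
#' indicate a left tail, e.g. a ceiling on reproductive performance
#' compressing the upper end of the fitness distribution.
#'
#' @param w numeric vector, length >= 3, with positive variance.
#' @return Scalar skewness; 0 for symmetric samples.
#' @examples
#' fitness_skewness(c(0, 0, 0, 1))  # right tail, positive
#' @export
fitness_skewness <- function(w) {
  if (!is.numeric(w) || length(w) < 3L || anyNA(w) || any(!is.finite(w))) {
    stop_invalid("`w` must be a finite numeric vector with at least 3 values.")
  }
  if (stats::var(w) == 0) {
    stop_degenerate("zero variance: skewness is undefined.")
  }
  e1071::skewness(w, type = 2)
}
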