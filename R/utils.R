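# Internal helpers: argument checks and deterministic seed handling.

stop_invalid <- function(...) {
  rlang::abort(paste0(...), class = "oppsel_invalid_argument")
}

stop_degenerate <- function(...) {
  rlang::abort(paste0(...), class = "oppsel_degenerate_input")
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`", name, "` must be a single integer >= ", min, ".")
  }
  as.integer(x)
}

check_nonneg <- function(x, name, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid("`", name, "` must be finite and >= 0.")
  }
  if (!is.null(len) && length(x) != len) {
    stop_invalid("`", name, "` must have length ", len, ".")
  }
  x
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) || seed != round(seed)) {
    stop_invalid("`seed` must be a single integer.")
  }
  as.integer(seed %% 2147483647)
}

# Deterministically mix a top-level seed with a stream label so that
# sub-streams (per sex, per replicate, per bootstrap) are independent and the
# whole analysis is reproducible from one integer. Polynomial string hash into
# the 31-bit range set.seed() accepts.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Percentile bootstrap interval from a vector of replicate statistics.
boot_ci <- function(stat, level = 0.95) {
  stat <- stat[is.finite(stat)]
  if (length(stat) == 0L) return(c(NA_real_, NA_real_))
  alpha <- (1 - level) / 2
  unname(stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7))
}
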