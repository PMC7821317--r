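#' Reproduction model parameters
#'
#' Collects the coefficients of the mating-group reproduction model. The
#' baseline model uses only `g_m`, the intensity of male-male competition in
#' the contest success function (default 2, intense competition). Four
#' optional variants are switched on by flags:
#'
#' * `female_competition`: the two females contest the pooled group fecundity
#'   with intensity `g_f` (at `g_f = 1` and linear fecundity this reproduces
#'   the baseline exactly, a useful calibration identity).
#' * `sperm_limitation`: the fraction of eggs fertilized is
#'   `min(1, mc * mean(male condition))` instead of 1.
#' * `male_harm`: female fecundity is multiplied by
#'   `max(0, 1 - harm * mean(male condition))`.
#' * `nuptial_gift`: female fecundity is multiplied by
#'   `1 + gift * mean(male condition)`.
#'
#' With all flags off and zero variant coefficients the baseline model is
#' recovered exactly.
#'
#' @param g_m male-male competition intensity (>= 0).
#' @param g_f female-female competition intensity (>= 0); used only when
#'   `female_competition` is on.
#' @param mc male contribution-to-fertility coefficient (> 0); used only when
#'   `sperm_limitation` is on.
#' @param harm male-harm coefficient (>= 0).
#' @param gift nuptial-gift coefficient (>= 0).
#' @param female_competition,sperm_limitation,male_harm,nuptial_gift logical
#'   variant flags, all off by default.
#' @return An object of class `reproduction_params`.
#' @examples
#' reproduction_params()                      # baseline, g_m = 2
#' reproduction_params(sperm_limitation = TRUE, mc = 0.5)
#' @export
reproduction_params <- function(g_m = 2, g_f = 1, mc = 1, harm = 0, gift = 0,
                                female_competition = FALSE,
                                sperm_limitation = FALSE,
                                male_harm = FALSE,
                                nuptial_gift = FALSE) {
  check_nonneg(g_m, "g_m", 1L)
  check_nonneg(g_f, "g_f", 1L)
  check_nonneg(mc, "mc", 1L)
  check_nonneg(harm, "harm", 1L)
  check_nonneg(gift, "gift", 1L)
  if (sperm_limitation && mc <= 0) {
    stop_invalid("`mc` must be > 0 when sperm limitation is on.")
  }
  flags <- c(
    female_competition = isTRUE(female_competition),
    sperm_limitation = isTRUE(sperm_limitation),
    male_harm = isTRUE(male_harm),
    nuptial_gift = isTRUE(nuptial_gift)
  )
  structure(
    list(g_m = g_m, g_f = g_f, mc = mc, harm = harm, gift = gift, flags = flags),
    class = "reproduction_params"
  )
}

#' @export
print.reproduction_params <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat(sprintf(
    "<reproduction_params> g_m = %g, g_f = %g, mc = %g, harm = %g, gift = %g; variants: %s\n",
    x$g_m, x$g_f, x$mc, x$harm, x$gift,
    if (length(on)) paste(on, collapse = ", ") else "none (baseline)"
  ))
  invisible(x)
}

#' A mating group of two females and two males
#'
#' The reproduction unit: fitness is resolved jointly for the four members.
#'
#' @param cf1,cf2 female condition values (>= 0).
#' @param cm1,cm2 male condition values (>= 0).
#' @return An object of class `mating_group`.
#' @export
mating_group <- function(cf1, cf2, cm1, cm2) {
  check_nonneg(c(cf1, cf2, cm1, cm2), "conditions", len = 4L)
  structure(list(cf1 = cf1, cf2 = cf2, cm1 = cm1, cm2 = cm2),
            class = "mating_group")
}

#' Contest success function
#'
#' Share of a contested resource won by the focal individual against one
#' rival: `c_focal^g / (c_focal^g + c_rival^g)`. `g` tunes how strongly
#' condition decides the contest: `g = 0` removes condition dependence (always
#' 1/2), large `g` approaches winner-take-all. Vectorized over conditions.
#'
#' Conventions: `c^0 = 1` for all `c >= 0`, so `g = 0` always yields 1/2; the
#' doubly degenerate tie `c_focal = c_rival = 0` with `g > 0` is defined as
#' 1/2 (the limit along the diagonal), preserving symmetry.
#'
#' @param c_focal,c_rival nonnegative condition of the focal and rival
#'   individual.
#' @param g contest intensity (>= 0).
#' @return Share in \[0, 1\]; `contest_share(a, b, g) + contest_share(b, a, g)`
#'   is always 1.
#' @examples
#' contest_share(2, 1, 2)  # 4/5
#' contest_share(1, 1, 200)
#' @export
contest_share <- function(c_focal, c_rival, g) {
  check_nonneg(c_focal, "c_focal")
  check_nonneg(c_rival, "c_rival")
  check_nonneg(g, "g", 1L)
  n <- max(length(c_focal), length(c_rival))
  c_focal <- rep_len(c_focal, n)
  c_rival <- rep_len(c_rival, n)
  if (g == 0) return(rep(0.5, n))
  # log-space ratio form is stable for large g; powers of values near 1 taken
  # directly would overflow around g * log(c) > 709
  share <- rep(0.5, n)
  both_pos <- c_focal > 0 & c_rival > 0
  share[both_pos] <- 1 / (1 + exp(g * (log(c_rival[both_pos]) - log(c_focal[both_pos]))))
  share[c_focal > 0 & c_rival == 0] <- 1
  share[c_focal == 0 & c_rival > 0] <- 0
  share
}

mean_male_condition <- function(cm1, cm2) (cm1 + cm2) / 2

#' Female fecundity as a function of condition
#'
#' In the baseline model fecundity scales linearly with female condition:
#' a female of condition `cf` produces `cf` fertile-egg equivalents,
#' independent of the males in her group. The `nuptial_gift` and `male_harm`
#' variants make fecundity depend on the mean condition of the two group
#' males: gifts multiply it by `1 + gift * c_m_bar`, harm by
#' `max(0, 1 - harm * c_m_bar)`. Zero coefficients recover the baseline
#' exactly. Vectorized.
#'
#' @param cf female condition (>= 0).
#' @param cm1,cm2 conditions of the two males in the group (>= 0); only used
#'   by the gift/harm variants.
#' @param params a [reproduction_params()].
#' @return Nonnegative fecundity (egg count equivalent).
#' @export
female_fecundity <- function(cf, cm1 = 1, cm2 = 1, params = reproduction_params()) {
  check_nonneg(cf, "cf")
  check_nonneg(cm1, "cm1")
  check_nonneg(cm2, "cm2")
  eggs <- cf
  cbar <- mean_male_condition(cm1, cm2)
  if (params$flags[["nuptial_gift"]]) eggs <- eggs * (1 + params$gift * cbar)
  if (params$flags[["male_harm"]]) eggs <- eggs * pmax(0, 1 - params$harm * cbar)
  eggs
}

#' Fraction of a female's eggs that get fertilized
#'
#' The baseline model assumes sperm is never limiting, so the fraction is
#' exactly 1. With the `sperm_limitation` variant on, the fraction is a
#' saturating function of mean male condition, `min(1, mc * c_m_bar)`:
#' below-average males fertilize fewer eggs, and the map is capped so it stays
#' a proportion. Vectorized.
#'
#' @param cm1,cm2 conditions of the two group males (>= 0).
#' @param params a [reproduction_params()].
#' @return Proportion in \[0, 1\], nondecreasing in mean male condition.
#' @export
fertilized_fraction <- function(cm1, cm2, params = reproduction_params()) {
  check_nonneg(cm1, "cm1")
  check_nonneg(cm2, "cm2")
  if (!params$flags[["sperm_limitation"]]) {
    return(rep(1, max(length(cm1), length(cm2))))
  }
  pmin(1, params$mc * mean_male_condition(cm1, cm2))
}

# Vectorized group fitness over parallel condition vectors; the engine behind
# group_reproduction() and the simulation sweeps.
group_fitness_vec <- function(cf1, cf2, cm1, cm2, params) {
  fert <- fertilized_fraction(cm1, cm2, params)
  f1 <- female_fecundity(cf1, cm1, cm2, params)
  f2 <- female_fecundity(cf2, cm1, cm2, params)
  if (params$flags[["female_competition"]]) {
    pool <- f1 + f2
    s_f <- contest_share(cf1, cf2, params$g_f)
    wf1 <- pool * s_f * fert
    wf2 <- pool * (1 - s_f) * fert
  } else {
    wf1 <- f1 * fert
    wf2 <- f2 * fert
  }
  total <- wf1 + wf2
  s_m <- contest_share(cm1, cm2, params$g_m)
  list(wf1 = wf1, wf2 = wf2, wm1 = total * s_m, wm2 = total * (1 - s_m))
}

#' Resolve reproduction within one mating group
#'
#' Computes the fitness of all four group members. Each female's fitness is
#' her (variant-modified) fecundity times the fertilized fraction; under
#' female competition the two females instead contest the pooled fecundity.
#' The two males then share the realized total female fitness through the
#' contest success function with intensity `g_m`. Because male fitness is a
#' partition of total female fitness, `wm1 + wm2 == wf1 + wf2` in every
#' variant (conservation).
#'
#' @param group a [mating_group()].
#' @param params a [reproduction_params()].
#' @return An object of class `group_fitness`: list with `wf1`, `wf2`,
#'   `wm1`, `wm2`.
#' @examples
#' g <- mating_group(cf1 = 1, cf2 = 1, cm1 = 2, cm2 = 1)
#' group_reproduction(g, reproduction_params(g_m = 2))
#' @export
group_reproduction <- function(group, params = reproduction_params()) {
  if (!inherits(group, "mating_group")) stop_invalid("`group` must be a mating_group.")
  if (!inherits(params, "reproduction_params")) {
    stop_invalid("`params` must be a reproduction_params object.")
  }
  w <- group_fitness_vec(group$cf1, group$cf2, group$cm1, group$cm2, params)
  structure(w, class = "group_fitness")
}

#' @export
print.group_fitness <- function(x, ...) {
  cat(sprintf(
    "<group_fitness> wf = (%.4g, %.4g), wm = (%.4g, %.4g)\n",
    x$wf1, x$wf2, x$wm1, x$wm2
  ))
  invisible(x)
}
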