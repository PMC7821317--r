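# Independent brute-force evaluation of the mating-group equations: a literal
# scalar transcription of the model (direct power form, no shared code with
# the package implementation). Used to cross-check group_reproduction() and
# simulate_replicate().
oracle_group_fitness <- function(cf1, cf2, cm1, cm2,
                                 g_m = 2, g_f = 1, mc = 1, harm = 0, gift = 0,
                                 female_competition = FALSE,
                                 sperm_limitation = FALSE,
                                 male_harm = FALSE,
                                 nuptial_gift = FALSE) {
  cbar <- (cm1 + cm2) / 2
  fec <- function(cf) {
    e <- cf
    if (nuptial_gift) e <- e * (1 + gift * cbar)
    if (male_harm) e <- e * max(0, 1 - harm * cbar)
    e
  }
  fert <- if (sperm_limitation) min(1, mc * cbar) else 1
  share <- function(a, b, g) {
    if (g == 0 || (a == 0 && b == 0)) 0.5 else a^g / (a^g + b^g)
  }
  f1 <- fec(cf1); f2 <- fec(cf2)
  if (female_competition) {
    sf <- share(cf1, cf2, g_f)
    wf1 <- (f1 + f2) * sf * fert
    wf2 <- (f1 + f2) * (1 - sf) * fert
  } else {
    wf1 <- f1 * fert
    wf2 <- f2 * fert
  }
  sm <- share(cm1, cm2, g_m)
  total <- wf1 + wf2
  c(wf1 = wf1, wf2 = wf2, wm1 = total * sm, wm2 = total * (1 - sm))
}

# All 16 on/off combinations of the four variant flags.
variant_flag_grid <- function() {
  expand.grid(
    female_competition = c(FALSE, TRUE),
    sperm_limitation = c(FALSE, TRUE),
    male_harm = c(FALSE, TRUE),
    nuptial_gift = c(FALSE, TRUE)
  )
}

params_from_row <- function(row, g_m = 2, g_f = 1.5, mc = 0.8, harm = 0.3, gift = 0.4) {
  reproduction_params(
    g_m = g_m, g_f = g_f, mc = mc, harm = harm, gift = gift,
    female_competition = row$female_competition,
    sperm_limitation = row$sperm_limitation,
    male_harm = row$male_harm,
    nuptial_gift = row$nuptial_gift
  )
}

# Small well-formed assay table for pipeline unit tests: two dates per group,
# both sexes, all three treatments.
toy_assays <- function() {
  set.seed(99)
  grid <- expand.grid(
    focal_sex = c("F", "M"), treatment = c("CT", "HT", "AT"),
    assay_date = c("d1", "d2"), idx = 1:6,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  assay_table(
    focal_sex = grid$focal_sex,
    treatment = grid$treatment,
    assay_date = grid$assay_date,
    offspring_count = rpois(nrow(grid), 30),
    total_offspring_weight = rpois(nrow(grid), 30) * 5
  )
}

write_assay_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
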