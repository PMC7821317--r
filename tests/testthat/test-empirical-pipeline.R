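test_that("assay files load, validate and report bad rows with line numbers", {
  good <- write_assay_fixture(c(
    "focal_sex,treatment,assay_date,offspring_count,total_offspring_weight",
    "F,CT,d1,12,60", "M,CT,d1,20,100", "F,HT,d1,8,40",
    "M,HT,d2,15,75", "F,AT,d2,0,", "M,AT,d2,31,155"
  ))
  rec <- load_assays(good)
  expect_equal(nrow(rec), 6)
  expect_true(is.na(rec$total_offspring_weight[5]))
  expect_true(is.na(rec$individual_offspring_weight[5]))  # zero count
  expect_equal(rec$individual_offspring_weight[1], 5)

  frac <- write_assay_fixture(c(
    "focal_sex,treatment,assay_date,offspring_count",
    "F,CT,d1,3.5", "M,CT,d1,20"
  ))
  expect_error(load_assays(frac), "line 2", class = "oppsel_invalid_argument")

  unk <- write_assay_fixture(c(
    "focal_sex,treatment,assay_date,offspring_count",
    "F,XX,d1,3", "M,CT,d1,20"
  ))
  expect_error(load_assays(unk), "treatment", class = "oppsel_invalid_argument")

  miss <- write_assay_fixture(c("focal_sex,assay_date,offspring_count", "F,d1,3"))
  expect_error(load_assays(miss), "treatment", class = "oppsel_invalid_argument")

  tsv <- write_assay_fixture(c(
    "focal_sex\ttreatment\tassay_date\toffspring_count",
    "F\tCT\td1\t12", "M\tCT\td1\t20"
  ), ext = ".tsv")
  expect_equal(nrow(load_assays(tsv)), 2)
})

test_that("mean fitness recovers the generator's percent reductions", {
  n <- setNames(rep(2000L, 6), c("F_CT", "M_CT", "F_HT", "M_HT", "F_AT", "M_AT"))
  cfg <- generator_config(n = n, seed = 202)
  sim <- generate_assays(cfg)
  mf <- group_mean_fitness(sim$records, n_boot = 200, seed = 1)
  pc <- mf$percent_change
  expect_equal(pc$percent_change_vs_ct[pc$treatment == "CT"], 0)
  expect_lt(abs(pc$percent_change_vs_ct[pc$treatment == "HT"] - 14), 2)
  expect_lt(abs(pc$percent_change_vs_ct[pc$treatment == "AT"] - 36), 2)
  expect_true(all(mf$group_means$ci_low <= mf$group_means$mean_fitness &
                    mf$group_means$mean_fitness <= mf$group_means$ci_high))
})

test_that("identical treatment distributions give zero percent change", {
  rec <- assay_table(
    focal_sex = rep(c("F", "M"), 30),
    treatment = rep(c("CT", "HT", "AT"), each = 20),
    assay_date = "d1",
    offspring_count = rep(c(10, 20, 30, 40), 15)
  )
  pc <- group_mean_fitness(rec, n_boot = 50, seed = 1)$percent_change
  expect_equal(pc$percent_change_vs_ct, rep(0, 3), tolerance = 1e-12)

  no_ct <- rec[rec$treatment != "CT", ]
  expect_error(group_mean_fitness(no_ct, n_boot = 50, seed = 1),
               "CT", class = "oppsel_invalid_argument")
})

test_that("variance decomposition recovers generator components and handles degeneracy", {
  # one large group with a strong date effect: between ~ date_sd^2
  n <- setNames(c(4000L, rep(2L, 5)), c("F_CT", "M_CT", "F_HT", "M_HT", "F_AT", "M_AT"))
  cfg <- generator_config(n = n, target_I_f = c(CT = 0.16, HT = 0.2, AT = 0.45),
                          n_dates = 80L, date_sd = 0.2, seed = 7)
  sim <- generate_assays(cfg)
  truth <- sim$truth$groups
  tv <- truth$total_var[truth$focal_sex == "F" & truth$treatment == "CT"]
  d <- decompose_variance(sim$records, "F", "CT")
  expect_lt(abs(d$total - tv) / tv, 0.25)
  expect_lt(abs(d$between - 0.04) / 0.04, 0.5)
  expect_equal(d$total, d$between + d$within, tolerance = 1e-12)

  # single date: between = 0 and total is the plain sample variance
  rec1 <- assay_table(rep("F", 10), rep("CT", 10), rep("d1", 10),
                      c(5, 9, 12, 20, 33, 7, 15, 11, 28, 40))
  expect_warning(d1 <- decompose_variance(rec1, "F", "CT"), "dates")
  expect_equal(d1$between, 0)
  w <- mean_standardize(rec1$offspring_count)
  expect_equal(d1$total, var(w), tolerance = 1e-12)
})

test_that("no date effect in the generator gives a near-zero between component", {
  n <- setNames(c(4000L, rep(2L, 5)), c("F_CT", "M_CT", "F_HT", "M_HT", "F_AT", "M_AT"))
  cfg <- generator_config(n = n, date_sd = 0, n_dates = 20L, seed = 31)
  sim <- generate_assays(cfg)
  d <- decompose_variance(sim$records, "F", "CT")
  expect_lt(d$between, 0.02)  # MoM noise floor around zero
})

test_that("opportunity estimates are scale invariant with sensible intervals", {
  rec <- toy_assays()
  est <- estimate_opportunity(rec, n_boot = 100, seed = 5)
  expect_equal(nrow(est), 6)
  expect_true(all(est$I >= 0))
  expect_true(all(est$ci_low <= est$ci_high))

  rec3 <- rec
  rec3$offspring_count <- rec3$offspring_count * 3L
  est3 <- estimate_opportunity(rec3, n_boot = 100, seed = 5)
  expect_equal(est3$I, est$I, tolerance = 1e-12)

  const <- assay_table(rep("F", 8), rep("CT", 8), rep(c("d1", "d2"), 4),
                       rep(7L, 8))
  estc <- estimate_opportunity(const, n_boot = 50, seed = 1)
  expect_equal(estc$I, 0)
})

test_that("mean-standardized groups have mean exactly one before variance estimation", {
  sim <- generate_assays(generator_config(seed = 77))
  recs <- sim$records
  for (tr in c("CT", "HT", "AT")) {
    for (sx in c("F", "M")) {
      w <- recs$offspring_count[recs$treatment == tr & recs$focal_sex == sx]
      expect_equal(mean(mean_standardize(w)), 1, tolerance = 1e-12)
    }
  }
})

test_that("sex-bias log ratios negate under sex relabeling and contrasts are tidy", {
  sim <- generate_assays(generator_config(seed = 12))
  sb <- compare_sex_bias(sim$records, n_boot = 100, seed = 3)
  expect_equal(sb$log_ratios$treatment, c("CT", "HT", "AT"))

  flipped <- sim$records
  flipped$focal_sex <- ifelse(flipped$focal_sex == "F", "M", "F")
  sb_f <- compare_sex_bias(flipped, n_boot = 100, seed = 3)
  expect_equal(sb_f$log_ratios$log_ratio, -sb$log_ratios$log_ratio,
               tolerance = 1e-12)

  expect_equal(nrow(sb$contrasts), 3)
  expect_true(all(sb$contrasts$p_bonferroni >= sb$contrasts$p_value))
  expect_true(all(sb$contrasts$p_bonferroni <= 1))
})

test_that("offspring weight summaries recover ordering and handle edge cases", {
  sim <- generate_assays(generator_config(seed = 8))
  ws <- offspring_weight_summary(sim$records, n_boot = 100, seed = 2)
  ind <- ws[ws$measure == "individual", ]
  expect_gt(ind$mean_weight[ind$treatment == "AT"],
            ind$mean_weight[ind$treatment == "CT"])

  uni <- assay_table(rep(c("F", "M"), 12), rep("CT", 24), rep(c("d1", "d2"), 12),
                     rep(10L, 24), rep(50, 24))
  wu <- offspring_weight_summary(uni, n_boot = 50, seed = 1)
  expect_equal(wu$mean_weight[wu$measure == "individual"], 5)
  expect_equal(wu$mean_weight[wu$measure == "total"], 50)

  zero <- assay_table(rep("F", 6), rep("CT", 6), "d1",
                      c(0L, 0L, 10L, 10L, 10L, 10L), c(0, 0, 40, 60, 40, 60))
  wz <- offspring_weight_summary(zero, n_boot = 50, seed = 1)
  expect_equal(wz$n[wz$measure == "individual"], 4)  # zero-count rows excluded

  now <- assay_table(rep("F", 4), rep("CT", 4), "d1", c(1L, 2L, 3L, 4L))
  expect_message(we <- offspring_weight_summary(now, n_boot = 50, seed = 1),
                 "no offspring weights")
  expect_equal(nrow(we), 0)
})

test_that("per-treatment skewness delegates to the pooled-sex skewness", {
  sim <- generate_assays(generator_config(seed = 21))
  sk <- skewness_by_treatment(sim$records)
  for (tr in c("CT", "HT", "AT")) {
    pooled <- as.numeric(sim$records$offspring_count[sim$records$treatment == tr])
    expect_equal(sk$skewness[sk$treatment == tr], fitness_skewness(pooled))
  }
  # a hard ceiling on counts compresses the right tail: negative skew
  capped <- generate_assays(generator_config(seed = 21, max_count = 45,
                                             date_sd = 0))$records
  sk_c <- skewness_by_treatment(capped)
  expect_lt(sk_c$skewness[sk_c$treatment == "CT"], 0)
})
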