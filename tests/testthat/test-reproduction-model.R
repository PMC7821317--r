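test_that("contest share matches direct evaluation and its conventions", {
  expect_equal(contest_share(1, 1, 2), 0.5)
  expect_equal(contest_share(2, 1, 2), 0.8, tolerance = 1e-12)
  expect_equal(contest_share(0.3, 1.7, 0), 0.5)   # g = 0: condition-blind
  expect_equal(contest_share(0, 0, 2), 0.5)       # diagonal-limit tie
  expect_equal(contest_share(0, 1, 2), 0)
  expect_equal(contest_share(1, 0, 2), 1)
  expect_error(contest_share(-1, 1, 2), class = "oppsel_invalid_argument")
})

test_that("contest shares of the two rivals always sum to one", {
  set.seed(21)
  a <- runif(200, 0, 3); b <- runif(200, 0, 3)
  for (g in c(0, 0.5, 2, 10)) {
    expect_equal(contest_share(a, b, g) + contest_share(b, a, g),
                 rep(1, 200), tolerance = 1e-12)
  }
  # strictly increasing in focal condition when g > 0
  s <- contest_share(seq(0.1, 3, by = 0.1), 1, 2)
  expect_true(all(diff(s) > 0))
})

test_that("large g approaches winner-take-all", {
  expect_lt(1 - contest_share(1.1, 1.0, 200), 1e-6)
  expect_lt(contest_share(1.0, 1.1, 200), 1e-6)
})

test_that("female fecundity is linear in condition, with gift/harm modifiers", {
  base <- reproduction_params()
  expect_equal(female_fecundity(0.8, 2, 1, base), 0.8)
  gift0 <- reproduction_params(nuptial_gift = TRUE, gift = 0)
  expect_equal(female_fecundity(1, 1, 1, gift0), 1)
  harm <- reproduction_params(male_harm = TRUE, harm = 0.5)
  expect_equal(female_fecundity(1, 1, 1, harm), 0.5)
  gift <- reproduction_params(nuptial_gift = TRUE, gift = 0.25)
  expect_equal(female_fecundity(2, 1, 3, gift), 2 * (1 + 0.25 * 2))
  # harm floors at zero rather than going negative
  harsh <- reproduction_params(male_harm = TRUE, harm = 2)
  expect_equal(female_fecundity(1, 1, 1, harsh), 0)
})

test_that("fertilized fraction is 1 without sperm limitation, saturating with it", {
  expect_equal(fertilized_fraction(0.1, 5, reproduction_params()), 1)
  sl <- reproduction_params(sperm_limitation = TRUE, mc = 0.5)
  expect_equal(fertilized_fraction(1, 1, sl), 0.5)
  sl10 <- reproduction_params(sperm_limitation = TRUE, mc = 10)
  expect_equal(fertilized_fraction(1, 1, sl10), 1)
  # nondecreasing in mean male condition
  f <- fertilized_fraction(seq(0, 3, by = 0.1), seq(0, 3, by = 0.1), sl)
  expect_true(all(diff(f) >= 0))
})

test_that("group reproduction matches hand evaluation of the equations", {
  sym <- group_reproduction(mating_group(1, 1, 1, 1), reproduction_params(g_m = 2))
  expect_equal(unlist(sym[c("wf1", "wf2", "wm1", "wm2")]), c(wf1 = 1, wf2 = 1, wm1 = 1, wm2 = 1))

  w <- group_reproduction(mating_group(1, 1, 2, 1), reproduction_params(g_m = 2))
  expect_equal(unlist(w[c("wf1", "wf2", "wm1", "wm2")]),
               c(wf1 = 1, wf2 = 1, wm1 = 1.6, wm2 = 0.4), tolerance = 1e-12)

  set.seed(33)
  for (i in 1:25) {
    cs <- runif(4, 0, 2.5)
    grid <- variant_flag_grid()
    row <- grid[sample.int(nrow(grid), 1), ]
    p <- params_from_row(row)
    got <- unlist(group_reproduction(mating_group(cs[1], cs[2], cs[3], cs[4]), p))
    want <- oracle_group_fitness(cs[1], cs[2], cs[3], cs[4],
                                 g_m = p$g_m, g_f = p$g_f, mc = p$mc,
                                 harm = p$harm, gift = p$gift,
                                 female_competition = row$female_competition,
                                 sperm_limitation = row$sperm_limitation,
                                 male_harm = row$male_harm,
                                 nuptial_gift = row$nuptial_gift)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("male fitness partitions total female fitness in every variant", {
  set.seed(13)
  grid <- variant_flag_grid()
  for (i in seq_len(nrow(grid))) {
    p <- params_from_row(grid[i, ])
    cf1 <- runif(500, 0, 3); cf2 <- runif(500, 0, 3)
    cm1 <- runif(500, 0, 3); cm2 <- runif(500, 0, 3)
    w <- oppsel:::group_fitness_vec(cf1, cf2, cm1, cm2, p)
    expect_lt(max(abs((w$wm1 + w$wm2) - (w$wf1 + w$wf2))), 1e-12)
  }
})

test_that("baseline female fitness is independent of the males", {
  p <- reproduction_params()
  w1 <- oppsel:::group_fitness_vec(1.2, 0.7, 0.5, 0.9, p)
  w2 <- oppsel:::group_fitness_vec(1.2, 0.7, 2.4, 0.1, p)
  expect_identical(c(w1$wf1, w1$wf2), c(w2$wf1, w2$wf2))
})

test_that("female competition with g_f = 1 reproduces the baseline exactly", {
  set.seed(55)
  base <- reproduction_params()
  fc <- reproduction_params(female_competition = TRUE, g_f = 1)
  for (i in 1:50) {
    cs <- runif(4, 0.01, 3)
    wb <- unlist(group_reproduction(mating_group(cs[1], cs[2], cs[3], cs[4]), base))
    wf <- unlist(group_reproduction(mating_group(cs[1], cs[2], cs[3], cs[4]), fc))
    expect_equal(wf, wb, tolerance = 1e-12)
  }
})

test_that("zero variant coefficients reduce every variant to the baseline", {
  set.seed(77)
  base <- reproduction_params()
  off <- reproduction_params(
    female_competition = TRUE, g_f = 1,
    sperm_limitation = TRUE, mc = 1000,  # cap saturates at 1
    male_harm = TRUE, harm = 0,
    nuptial_gift = TRUE, gift = 0
  )
  for (i in 1:25) {
    cs <- runif(4, 0.01, 1.8)
    wb <- unlist(group_reproduction(mating_group(cs[1], cs[2], cs[3], cs[4]), base))
    wo <- unlist(group_reproduction(mating_group(cs[1], cs[2], cs[3], cs[4]), off))
    expect_equal(wo, wb, tolerance = 1e-12)
  }
})
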