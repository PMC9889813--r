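test_that("crude rates and proportions reproduce national-scale arithmetic", {
  expect_equal(crude_rate(2, 4), 0.5)
  expect_equal(crude_rate(0, 10), 0)
  expect_true(is.na(crude_rate(0, 0)))
  expect_error(crude_rate(5, 4))
  expect_equal(crude_rate(415076, 5041685), 0.0823288, tolerance = 1e-6)
  expect_equal(outcome_proportion(415076, 5041685), 8.23)
  expect_equal(outcome_proportion(239026, 5041685), 4.74)
  expect_equal(outcome_proportion(263641, 5041685), 5.23)
  expect_equal(outcome_proportion(151435, 5041685), 3.00)
  expect_equal(outcome_proportion(111256, 5041685), 2.21)
  expect_equal(outcome_proportion(0, 100), 0)
  expect_error(outcome_proportion(2, 0))
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(1.1974, 2), 1.20)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("direct standardization is a reference-weighted sum with imputed empties", {
  w <- c(0.5, 0.5, rep(0, 7))
  expect_equal(direct_asr(c(10, 10, rep(0, 7)), c(1, 3, rep(0, 7)), w), 0.2)
  # all strata empty: imputation forces zero
  expect_equal(direct_asr(rep(0, 9), rep(0, 9)), 0)
  # randomized table vs independent weighted-sum oracle
  set.seed(21)
  for (rep_i in 1:20) {
    n <- rpois(9, 40)
    o <- rbinom(9, n, 0.1)
    w <- runif(9); w <- w / sum(w)
    oracle <- 0
    for (a in 1:9) {
      ra <- if (n[a] == 0) 0 else o[a] / n[a]
      oracle <- oracle + w[a] * ra
    }
    asr <- direct_asr(n, o, w)
    expect_equal(asr, oracle, tolerance = 1e-12)
    # bounded by the stratum rate range
    r <- ifelse(n == 0, 0, o / n)
    expect_gte(asr, min(r) - 1e-12)
    expect_lte(asr, max(r) + 1e-12)
  }
  expect_error(direct_asr(c(-1, rep(0, 8)), rep(0, 9)))
})

test_that("pooled age rates and calibrated expected counts behave", {
  counts <- data.frame(
    municipality_id = rep(c("A", "B"), each = 9),
    age_class = rep(1:9, 2),
    n_births = c(rep(10, 9), rep(30, 9)),
    n_cases = c(rep(1, 9), rep(3, 9))
  )
  rho <- national_age_rates(counts)
  expect_equal(rho, rep(0.1, 9))
  ind <- indirect_expected(counts)
  expect_equal(ind$expected, c(9, 27))
  expect_equal(sum(ind$expected), sum(ind$observed))
  # homogeneous rates: E_i proportional to n_i and O/E near 1
  expect_equal(ind$expected / ind$n_births, rep(0.1, 2))
  # external rho gets calibrated so totals still match
  ind2 <- indirect_expected(counts, rho = rep(0.25, 9))
  expect_equal(sum(ind2$expected), sum(ind2$observed))
  expect_equal(ind2$expected, c(9, 27))
})

test_that("O/E is unbiased under a uniform rate surface", {
  cfg <- synthetic_config(grid_shape = c(5, 5), denominator_median = 300,
                          denominator_sdlog = 1, seed = 3)
  muni <- generate_municipalities(cfg)
  denom <- generate_denominators(cfg, muni$geos)
  risk <- plant_risk_surface(muni$geos, list())
  set.seed(99)
  ratios <- replicate(200, {
    cnt <- simulate_cases(denom, rep(0.08, 9), risk,
                          seed = sample.int(1e6, 1))
    ind <- indirect_expected(cnt)
    mean(ind$observed / ind$expected)
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.01)
})

test_that("planted relative risk shows up in O/E at the planted size", {
  cfg <- synthetic_config(grid_shape = c(7, 7), denominator_median = 400,
                          denominator_sdlog = 0, seed = 8,
                          planted_clusters = list(
                            list(center = 25, radius_km = 10, rr = 2,
                                 outcome = "all")))
  muni <- generate_municipalities(cfg)
  denom <- generate_denominators(cfg, muni$geos)
  risk <- plant_risk_surface(muni$geos, cfg$planted_clusters)
  inside <- names(risk)[risk > 1]
  expect_equal(length(inside), 5)  # center + 4 orthogonal neighbors
  set.seed(500)
  oe <- replicate(500, {
    cnt <- simulate_cases(denom, rep(0.05, 9), risk,
                          seed = sample.int(1e6, 1))
    ind <- indirect_expected(cnt, rho = rep(0.05, 9))
    sel <- ind$municipality_id %in% inside
    sum(ind$observed[sel]) / sum(ind$expected[sel])
  })
  # calibration dilutes the planted RR slightly (cluster cases inflate E)
  frac_inside <- 5 / 49
  expected_oe <- 2 / (1 + frac_inside * (2 - 1))
  se <- sd(oe) / sqrt(length(oe))
  expect_lt(abs(mean(oe) - expected_oe), 3 * se + 0.02)
})

test_that("summary table mirrors the cohort composition", {
  rec <- make_records(
    list(birthweight_g = 2400, gestational_weeks = 38, maternal_age = 19,
         sex = "male", year = 2012),
    list(birthweight_g = 2400, gestational_weeks = 30, maternal_age = 30,
         sex = "female", year = 2013),
    list(birthweight_g = 3000, gestational_weeks = 40, maternal_age = 40,
         sex = "male", year = 2013),
    list(birthweight_g = 3000, gestational_weeks = 40, maternal_age = 30,
         sex = "female", year = 2014)
  )
  tab <- summary_table(rec)
  expect_equal(tab$totals$n, c(4, 2, 1, 1, 1))
  expect_equal(tab$totals$percent[1], 100)
  expect_equal(tab$totals$percent[2], 50)
  lbw_by_age <- tab$by_age[tab$by_age$group == "LBW", ]
  expect_equal(lbw_by_age$n[lbw_by_age$level == "<=20"], 1)
  # all-same-birthweight: IQR bounds collapse to the common value
  same <- make_records(list(), list(), list())
  dist <- summary_table(same)$distributions
  expect_equal(dist$birthweight_q25[1], 3100)
  expect_equal(dist$birthweight_q75[1], 3100)
})
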