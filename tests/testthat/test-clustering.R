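test_that("Tango's statistic matches a brute-force double sum", {
  set.seed(71)
  for (rep_i in 1:10) {
    geos <- data.frame(municipality_id = sprintf("T%d", 1:6),
                       x = runif(6, 0, 50), y = runif(6, 0, 50))
    D <- distance_matrix(geos)
    E <- runif(6, 5, 20)
    O <- rpois(6, E)
    if (sum(O) == 0) O[1] <- 1
    lambda <- runif(1, 5, 30)
    expect_equal(tango_statistic(O, E, D, lambda),
                 tango_brute(O, E, D, lambda), tolerance = 1e-12)
  }
})

test_that("Tango's statistic is zero for proportional shares and has a kernel limit", {
  geos <- data.frame(municipality_id = letters[1:5],
                     x = c(0, 1, 5, 9, 20), y = 0)
  D <- distance_matrix(geos)
  O <- c(10, 20, 30, 20, 10)
  expect_equal(tango_statistic(O, O * 2.5, D, 10), 0, tolerance = 1e-15)
  # lambda -> 0: kernel collapses to the identity, C -> sum z_i^2
  E <- c(15, 15, 30, 15, 15)
  z <- O / sum(O) - E / sum(E)
  expect_equal(tango_statistic(O, E, D, 1e-9), sum(z^2), tolerance = 1e-12)
  expect_gte(tango_statistic(O, E, D, 10), 0)
  expect_error(tango_statistic(O, E, D, 0))
})

test_that("Tango Monte Carlo p-value hits the rank floor and is reproducible", {
  geos <- grid_geos(3, 3)
  D <- distance_matrix(geos)
  E <- rep(10, 9)
  O <- c(40, 40, 5, 40, 5, 5, 5, 5, 5)  # strong aggregation in one corner
  O <- O * sum(E) / sum(O)
  t1 <- tango_mc_test(O, E, D, nsim = 99, seed = 4)
  t2 <- tango_mc_test(O, E, D, nsim = 99, seed = 4)
  expect_identical(t1$p_value, t2$p_value)
  expect_gte(t1$p_value, 1 / 100)
  expect_error(tango_mc_test(O, E, D, nsim = 10, seed = 1))
})

test_that("Poisson scan LLR has the closed form and one-sided gating", {
  expect_equal(poisson_llr(10, 10, 100), 0)
  expect_equal(poisson_llr(5, 10, 100), 0)   # deficit: inactive branch
  expect_equal(poisson_llr(20, 10, 100),
               20 * log(2) + 80 * log(80 / 90), tolerance = 1e-12)
  expect_equal(poisson_llr(20, 10, 100), 4.4403, tolerance = 1e-4)
  # whole-study window: outside expectation zero, inactive
  expect_equal(poisson_llr(100, 100, 100), 0)
  expect_error(poisson_llr(5, 0, 100))
  # monotone in O_Z on the active branch
  llrs <- poisson_llr(15:40, 10, 100)
  expect_true(all(diff(llrs) > 0))
  # low-rate direction picks up the deficit instead
  expect_gt(poisson_llr(5, 20, 100, direction = "low"), 0)
  expect_equal(poisson_llr(30, 20, 100, direction = "low"), 0)
})

test_that("zone enumeration is nested, capped and deduplicated", {
  one <- data.frame(municipality_id = "solo", x = 0, y = 0)
  expect_equal(length(enumerate_zones(one, n_births = 5)), 1)
  # 3 equal units on a line, no cap: hand enumeration gives 5 distinct sets
  line <- data.frame(municipality_id = c("a", "b", "c"),
                     x = c(0, 1, 2), y = 0)
  zones <- enumerate_zones(line, n_births = c(1, 1, 1), max_fraction = 1)
  keys <- sort(vapply(zones, function(z) {
    paste(sort(z$member_ids), collapse = "|")
  }, character(1)))
  expect_equal(keys, c("a", "a|b", "a|b|c", "b", "b|c", "c"))
  # cap at half the births: no zone may hold more than half the units
  zones2 <- enumerate_zones(line, n_births = c(1, 1, 1), max_fraction = 0.5)
  expect_true(all(vapply(zones2, function(z) length(z$member_ids),
                         integer(1)) <= 1))
  expect_error(enumerate_zones(line, n_births = c(1, 1, 1), max_fraction = 0))
})

test_that("scan MLC equals the exhaustive oracle on small instances", {
  for (s in 1:20) {
    inst <- random_scan_instance(sample(4:10, 1), seed = 100 + s)
    res <- scan_test(inst$O, inst$E, inst$geos, nsim = 0)
    oracle <- scan_brute_mlc(inst$O, inst$E, inst$geos)
    if (nrow(res) == 0) {
      expect_lte(oracle$llr, 1e-12)
    } else {
      expect_equal(res$llr[1], oracle$llr, tolerance = 1e-9)
      expect_equal(sort(strsplit(res$member_ids[1], ";")[[1]]),
                   oracle$members)
    }
  }
})

test_that("the C++ null kernel agrees with the R observed-zone path", {
  inst <- random_scan_instance(30, seed = 900)
  res <- scan_test(inst$O, inst$E, inst$geos, nsim = 0, n_report = 1)
  # feed the observed counts through the simulation kernel
  sk <- natalclust:::scan_orderings(inst$geos, inst$E, 0.5)
  ecum <- vapply(seq_len(30), function(c_i) {
    cumsum(inst$E[sk$ord[, c_i]])
  }, numeric(30))
  mx <- natalclust:::scan_max_llr_cpp(matrix(as.integer(inst$O)), sk$ord,
                                      sk$zlen, ecum, sum(inst$E), 1L)
  expect_equal(mx, res$llr[1], tolerance = 1e-9)
})

test_that("scan reports are disjoint, ranked, deterministic and labelled", {
  set.seed(301)
  g <- grid_geos(6, 6)
  E <- runif(36, 5, 20)
  O <- rpois(36, E)
  O[c(8, 9)] <- O[c(8, 9)] + 15   # force a hotspot
  E <- E * sum(O) / sum(E)
  r1 <- scan_test(O, E, g, nsim = 99, seed = 7)
  r2 <- scan_test(O, E, g, nsim = 99, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "null_maxllr"), attr(r2, "null_maxllr"))
  expect_equal(r1$rank, c("MLC", "SLC", "TLC")[seq_len(nrow(r1))])
  expect_true(all(diff(r1$llr) <= 1e-12))
  members <- strsplit(r1$member_ids, ";")
  expect_equal(anyDuplicated(unlist(members)), 0)
  expect_true(all(r1$p_value >= 1 / 100 & r1$p_value <= 1))
  # relabeling municipalities leaves the LLR ranking unchanged (tie-free
  # layout: on exact lattices the id tie-break itself defines the zones)
  inst <- random_scan_instance(25, seed = 808)
  ra <- scan_test(inst$O, inst$E, inst$geos, nsim = 0)
  perm <- sample(25)
  g2 <- inst$geos[perm, ]
  g2$municipality_id <- sprintf("Z%03d", seq_len(25))
  rb <- scan_test(inst$O[perm], inst$E[perm], g2, nsim = 0)
  expect_equal(rb$llr, ra$llr, tolerance = 1e-9)
})

test_that("relative risks reproduce printed cluster arithmetic", {
  expect_equal(round_half_up(reported_rr(15174, 12672.10), 2), 1.20)
  expect_equal(round_half_up(reported_rr(12890, 11743.66), 2), 1.10)
  expect_equal(round_half_up(reported_rr(106, 68.49), 2), 1.55)
  expect_equal(round_half_up(reported_rr(206, 123.41), 2), 1.67)
  expect_equal(round_half_up(reported_rr(28, 13.05), 2), 2.15)
  expect_equal(reported_rr(7, 7), 1)
  # the Kulldorff-style indirect RR is slightly larger inside a hotspot
  expect_gt(kulldorff_rr(15174, 12672.10, 415076), 15174 / 12672.10)
})

test_that("a strongly planted cluster is recovered exactly at large counts", {
  cfg <- synthetic_config(grid_shape = c(8, 8), denominator_median = 2000,
                          denominator_sdlog = 0, seed = 19,
                          planted_clusters = list(
                            list(center = 28, n_units = 5, rr = 3,
                                 outcome = "all")))
  muni <- generate_municipalities(cfg)
  denom <- generate_denominators(cfg, muni$geos)
  risk <- plant_risk_surface(muni$geos, cfg$planted_clusters)
  truth <- sort(names(risk)[risk > 1])
  cnt <- simulate_cases(denom, rep(0.05, 9), risk, seed = 77)
  ind <- indirect_expected(cnt)
  res <- scan_test(ind$observed, ind$expected, muni$geos, nsim = 0,
                   n_births = ind$n_births)
  expect_equal(sort(strsplit(res$member_ids[1], ";")[[1]]), truth)
})
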