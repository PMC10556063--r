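test_that("simulation is fully reproducible from its seed", {
  s1 <- simulate_monitoring(n_species = 10, seed = 5)
  s2 <- simulate_monitoring(n_species = 10, seed = 5)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)

  p1 <- planted_threshold_cohort(n_species = 30, t_star = 10,
                                 sites_range = c(1, 30),
                                 records_per_species = 60, seed = 5)
  p2 <- planted_threshold_cohort(n_species = 30, t_star = 10,
                                 sites_range = c(1, 30),
                                 records_per_species = 60, seed = 5)
  expect_identical(p1$records, p2$records)
  # and the seed wrapper leaves the caller's RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_monitoring(n_species = 5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("impossible configurations are rejected before generation", {
  expect_error(simulate_monitoring(n_species = 0), "positive integer")
  expect_error(simulate_monitoring(sites_range = c(10, 2)), "sites_range")
  expect_error(simulate_monitoring(records_per_site_range = c(0, 3)),
               "records_per_site_range")
  expect_error(simulate_monitoring(t_star = 500), "within")
  expect_error(simulate_monitoring(epsilon = 0.6), "0.5")
  expect_error(planted_threshold_cohort(epsilon = 0.6), "0.5")
  expect_error(planted_threshold_cohort(below_fraction = 0.4), "0.25")
  expect_error(planted_threshold_cohort(records_per_species = 10,
                                        sites_range = c(1, 80)),
               "at least the maximum")
})

test_that("generator bookkeeping agrees with summarize_species", {
  sim <- simulate_monitoring(n_species = 25, sites_range = c(1, 40),
                             t_star = 10, seed = 33)
  s <- summarize_species(sim$records)
  merged <- dplyr::inner_join(s, sim$truth, by = "species_id")
  expect_identical(nrow(merged), 25L)
  expect_identical(merged$n_sites.x, merged$n_sites.y)
  expect_identical(sum(s$n_values), nrow(sim$records))

  pc <- planted_threshold_cohort(n_species = 30, t_star = 10,
                                 sites_range = c(1, 30),
                                 records_per_species = 60, seed = 34)
  sp <- summarize_species(pc$records)
  mp <- dplyr::inner_join(sp, pc$truth, by = "species_id")
  expect_identical(mp$n_sites.x, mp$n_sites.y)
  expect_true(all(sp$n_values == 60L))
})

test_that("compliant species comply and degraded species do not", {
  # iid log-uniform species at 200 records over 4 decades: direct sampling
  # puts the long-run rate of R-squared >= 0.9 at about 0.87 (median R2
  # 0.95); assert a level safely inside that, and near-certain compliance
  # at the laxer 0.8 cut
  set.seed(51)
  r2 <- replicate(100, benford_r_squared(r_abundance_loguniform(200, 4))$r_squared)
  expect_gte(mean(r2 >= 0.9), 0.80)
  expect_gte(mean(r2 >= 0.8), 0.95)
  expect_gte(median(r2), 0.9)

  # fixed-leading-digit tampering: degenerate digit distribution, low
  # R-squared for any forced digit 2-9, and a failed classification
  sim <- simulate_monitoring(n_species = 20, sites_range = c(1, 30),
                             t_star = 10, epsilon = 0,
                             degradation = "digit_tamper", seed = 52)
  audit <- benford_audit(sim$records)
  merged <- dplyr::inner_join(tidy(audit), sim$truth, by = "species_id")
  expect_true(all(merged$r_squared[!merged$compliant] < 0.1, na.rm = TRUE))
  expect_true(all(!merged$passed[!merged$compliant]))

  # narrow-range and rounding degradations produce valid positive integers
  for (deg in c("narrow_uniform", "round_1sf")) {
    simd <- simulate_monitoring(n_species = 8, sites_range = c(1, 10),
                                t_star = 5, degradation = deg, seed = 53)
    expect_true(all(simd$records$abundance >= 1))
    expect_true(all(simd$records$abundance == trunc(simd$records$abundance)))
  }
})

test_that("the balanced compliant model concentrates R-squared near one", {
  pc <- planted_threshold_cohort(n_species = 40, t_star = 10,
                                 sites_range = c(1, 40),
                                 records_per_species = 100, seed = 54)
  audit <- benford_audit(pc$records)
  merged <- dplyr::inner_join(tidy(audit), pc$truth, by = "species_id")
  r2c <- merged$r_squared[merged$compliant]
  expect_true(all(r2c > 0.99))
  # identical record totals make the compliant R-squared exactly constant,
  # which is what collapses the cohort IQR and guarantees separability
  expect_identical(length(unique(r2c)), 1L)
  expect_true(all(merged$passed == merged$compliant))
})

test_that("planted labels follow the threshold rule with flip noise", {
  pc <- planted_threshold_cohort(n_species = 60, t_star = 10, epsilon = 0,
                                 sites_range = c(1, 40),
                                 records_per_species = 50, seed = 55)
  expect_identical(pc$truth$compliant, pc$truth$n_sites >= 10L)
  # anchors straddle the planted boundary
  expect_true(any(pc$truth$n_sites == 9L) && any(pc$truth$n_sites == 10L))

  pcn <- planted_threshold_cohort(n_species = 200, t_star = 10,
                                  epsilon = 0.3, sites_range = c(1, 40),
                                  records_per_species = 50, seed = 56)
  flips <- with(pcn$truth, compliant != (n_sites >= 10L))
  expect_identical(flips, pcn$truth$flipped)
  expect_gt(mean(flips), 0.15)
  expect_lt(mean(flips), 0.45)
})
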