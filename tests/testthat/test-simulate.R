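test_that("invalid configuration values name the offending field", {
  expect_error(simulation_config(monthly_fecundability = 1.4),
               "monthly_fecundability")
  expect_error(simulation_config(contraceptive_prevalence = -0.1),
               "contraceptive_prevalence")
  expect_error(simulation_config(desired_parity_distribution = rep(1, 13)),
               "desired_parity_distribution")
  expect_error(simulation_config(marriage_age_distribution = rep(0.05, 21)),
               "marriage_age_distribution")
  expect_error(simulation_config(cohort_size = 0), "cohort_size")
  expect_error(simulation_config(sterility_onset_hazard = rep(0.1, 3)),
               "sterility_onset_hazard")
})

test_that("zero fecundability with zero desired parity yields no births", {
  cfg <- simulation_config(
    monthly_fecundability = 0,
    desired_parity_distribution = c(1, rep(0, 12)),
    cohort_size = 300, seed = 4)
  s <- simulate_survey(cfg)
  expect_true(all(s$parity == 0))
  expect_false(any(s$currently_pregnant))
  expect_true(all(is.na(s$last_birth_cmc)))
})

test_that("identical seeds give identical surveys; cohorts extend stably", {
  cfg <- regime_preset("colombia", cohort_size = 300, seed = 9)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1, s2)
  # enlarging the cohort leaves earlier women untouched
  cfg_big <- regime_preset("colombia", cohort_size = 450, seed = 9)
  s3 <- simulate_survey(cfg_big)
  expect_identical(as.data.frame(s3)[1:300, ], as.data.frame(s1))
})

test_that("simulated records are internally consistent", {
  s <- cached_survey("niger", n = 2000, seed = 11)
  births <- strsplit(s$birth_cmcs, ";", fixed = TRUE)
  n_births <- lengths(lapply(births, function(b) b[nzchar(b)]))
  expect_equal(s$parity, n_births)
  has <- s$parity > 0
  last <- vapply(births[has], function(b) max(as.integer(b)), integer(1))
  expect_equal(s$last_birth_cmc[has], last)
  m <- s$interview_cmc - s$last_birth_cmc
  expect_true(all(m >= 0, na.rm = TRUE))
  expect_true(all(is.na(s$last_birth_cmc[!has])))
  expect_true(all(s$age_years >= 15 & s$age_years <= 49))
  # no births precede exact age 15 or the interview
  all_b <- as.integer(unlist(births[has]))
  dob <- rep(s$woman_dob_cmc[has], n_births[has])
  expect_true(all(all_b - dob >= 180))
  expect_true(all(all_b <= rep(s$interview_cmc[has], n_births[has])))
})

test_that("high-fertility survey produces the descending interval curve", {
  s <- simulate_survey(regime_preset("niger", cohort_size = 20000, seed = 21))
  pct <- tabulate_distribution(s)$percentages
  # strictly descending at the sensitive start of the curve
  expect_true(all(diff(pct[1:4]) < 0))
  # descending overall, up to multinomial noise in the sparse tail
  expect_lt(cor(1:20, pct, method = "spearman"), -0.9)
  expect_true(all(diff(pct) < 0.5))
})

test_that("calendar translation leaves the stable-state distribution unchanged", {
  cfg <- regime_preset("niger", cohort_size = 1500, seed = 13)
  d1 <- tabulate_distribution(simulate_survey(cfg, interview_cmc = 1453L))
  d2 <- tabulate_distribution(simulate_survey(cfg, interview_cmc = 1453L + 360L))
  expect_equal(d1$counts, d2$counts)
})

test_that("power-law sampler obeys its contracts", {
  expect_error(sample_power_law_survey(0, 1, 100), "a must be positive")
  expect_error(sample_power_law_survey(0.5, 1.5, 0), "n must be")

  one <- sample_power_law_survey(0.5, 1.5, 1, seed = 2)
  expect_equal(sum(one$counts), 1)
  expect_equal(sum(one$counts == 1), 1)

  d <- sample_power_law_survey(0.5, 1.5, 5000, seed = 2)
  expect_equal(sum(d$counts), 5000)
  expect_identical(d$counts,
                   sample_power_law_survey(0.5, 1.5, 5000, seed = 2)$counts)

  # b = 0 degenerates to uniform: every bin within 5 s.e. of n/20
  u <- sample_power_law_survey(0.5, 0, 20000, seed = 3)
  se <- sqrt(20000 * 0.05 * 0.95)
  expect_true(all(abs(u$counts - 1000) < 5 * se))
})

test_that("renewal sampler matches closed forms for memoryless and fixed intervals", {
  # exponential closed intervals: backward recurrence is exponential (rate
  # unchanged, by memorylessness)
  bw <- sample_stationary_renewal(function(n) rexp(n, rate = 1 / 24),
                                  n = 30000, seed = 5)
  ks <- suppressWarnings(
    stats::ks.test(bw$backward, stats::pexp, rate = 1 / 24))
  expect_lt(unname(ks$statistic), 0.02)

  # degenerate closed interval c: backward recurrence uniform on [0, c)
  bu <- sample_stationary_renewal(function(n) rep(24, n), n = 20000, seed = 6)
  expect_true(all(bu$backward >= 0 & bu$backward < 24))
  ksu <- suppressWarnings(
    stats::ks.test(bu$backward, stats::punif, min = 0, max = 24))
  expect_lt(unname(ksu$statistic), 0.02)

  # uniform(0, 24) closed: empirical backward density near 0 is ~ 1/12
  bv <- sample_stationary_renewal(function(n) runif(n, 0, 24),
                                  n = 50000, seed = 7)
  dens0 <- mean(bv$backward < 2) / 2
  expect_equal(dens0, (1 - 1 / 24) / 12, tolerance = 0.05)
})

test_that("renewal sampler rejects invalid inputs", {
  expect_error(
    sample_stationary_renewal(function(n) rep(-1, n), n = 100, seed = 1),
    "positive")
  expect_error(
    sample_stationary_renewal(function(n) rexp(n), n = 100,
                              burn_in_events = 10, seed = 1),
    "burn_in_events")
})
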