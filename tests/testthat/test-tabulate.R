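test_that("interval-year assignment follows the inclusion rules", {
  recs <- make_records(m = c(NA, 6, 30, 240, 239, 15),
                       parity = c(0L, 2L, 2L, 1L, 1L, 1L),
                       pregnant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                       married = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  yr <- open_interval_year(recs)
  # pregnant parity-0 woman goes to year 1; m=6 -> 1; m=30 -> 3;
  # m=240 excluded; m=239 is the last included month; unmarried excluded
  expect_equal(yr, c(1L, 1L, 3L, NA, 20L, NA), ignore_attr = TRUE)
  excl <- attr(yr, "exclusions")
  expect_equal(unname(excl["unmarried"]), 1)
  expect_equal(unname(excl["over_20_years"]), 1)
})

test_that("non-pregnant nulliparae have no open interval", {
  recs <- make_records(parity = c(0L, 0L), pregnant = c(FALSE, TRUE))
  expect_equal(open_interval_year(recs), c(NA, 1L), ignore_attr = TRUE)
})

test_that("pregnant women are forced to year 1 even with an old last birth", {
  recs <- make_records(m = 100, parity = 3L, pregnant = TRUE)
  expect_equal(open_interval_year(recs), 1L, ignore_attr = TRUE)
})

test_that("negative time since last birth is a data error", {
  recs <- make_records(m = 5, parity = 1L)
  recs$last_birth_cmc <- recs$interview_cmc + 1L
  class(recs) <- "data.frame"
  expect_error(open_interval_year(recs), "negative months")
})

test_that("tabulation counts, percentages, and exclusions are exact", {
  recs <- make_records(m = c(3, 15, 15, 250), parity = 1L)
  d <- tabulate_distribution(recs, label = "hand-built")
  expect_equal(d$counts, c(1L, 2L, rep(0L, 18)))
  expect_equal(d$n_eligible, 3)
  expect_equal(d$percentages[1:2], c(100 / 3, 200 / 3))
  expect_equal(sum(d$percentages), 100, tolerance = 1e-9)

  preg <- make_records(m = NA, parity = 0L, pregnant = TRUE)
  expect_equal(tabulate_distribution(preg)$percentages[1], 100)

  none <- make_records(parity = 0L, pregnant = FALSE)
  expect_error(tabulate_distribution(none), "empty-input")
})

test_that("percentages are invariant to record order and dataset duplication", {
  recs <- cached_survey("colombia", n = 1500, seed = 17)
  d <- tabulate_distribution(recs)
  shuffled <- as_woman_survey(as.data.frame(recs)[sample(nrow(recs)), ])
  doubled <- as_woman_survey(rbind(as.data.frame(recs), as.data.frame(recs)))
  expect_equal(tabulate_distribution(shuffled)$percentages, d$percentages)
  expect_equal(tabulate_distribution(doubled)$percentages, d$percentages)
})

test_that("composition shares sum to 100 and empty bins are flagged", {
  recs <- make_records(m = c(6, 18, 18, 30), parity = c(1L, 2L, 6L, 7L),
                       age = 20L)
  comp <- composition_by_interval(recs, "age")
  expect_equal(unname(comp$shares["20-24", 1:3]), c(100, 100, 100))
  expect_true(all(abs(colSums(comp$shares[, comp$n_by_interval > 0]) - 100)
                  < 1e-6))
  expect_true(4 %in% comp$empty_intervals)
  expect_true(all(is.na(comp$shares[, 4])))

  pc <- composition_by_interval(recs, "parity")
  expect_equal(unname(pc$shares["6+", 2]), 50)
  expect_equal(pc$mean_by_interval[2], mean(c(2, 6)))
  expect_equal(pc$mean_by_interval[3], 7)
})

test_that("mean age rises with interval length in a stable simulated regime", {
  s <- cached_survey("niger", n = 4000, seed = 11)
  comp <- composition_by_interval(s, "age")
  ok <- comp$n_by_interval >= 20
  expect_gt(cor((1:20)[ok], comp$mean_by_interval[ok], method = "spearman"),
            0.8)
  expect_gt(mean(comp$mean_by_interval[15:20], na.rm = TRUE),
            mean(comp$mean_by_interval[1:5], na.rm = TRUE))
})

test_that("low parities dominate long intervals in a transitional regime", {
  s <- cached_survey("colombia", n = 4000, seed = 11)
  comp <- composition_by_interval(s, "parity")
  share13 <- colSums(comp$shares[c("1", "2", "3"), ])
  expect_gt(mean(share13[7:14], na.rm = TRUE), share13[1])
})

test_that("age-parity table reproduces direct arithmetic", {
  recs <- make_records(m = c(rep(NA, 4), rep(6, 5), 6),
                       parity = c(rep(0L, 4), rep(1L, 5), 2L), age = 17L)
  apt <- age_parity_table(recs)
  expect_equal(unname(apt$percentages["15-19", ]), c(40, 50, 10, 0, 0, 0, 0))
  expect_equal(unname(apt$row_means["15-19"]), 0.7)
  expect_true("45-49" %in% apt$empty_rows)

  zero <- make_records(parity = 0L, age = c(17L, 26L, 33L))
  aptz <- age_parity_table(zero)
  expect_equal(unname(aptz$percentages["25-29", ]), c(100, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(aptz$row_means["25-29"]), 0)
})

test_that("age-parity row means agree with mean CEB when weighted by row counts", {
  s <- cached_survey("colombia", n = 1500, seed = 17)
  apt <- age_parity_table(s, married_only = FALSE)
  weighted <- sum(apt$row_means * apt$row_n, na.rm = TRUE) / sum(apt$row_n)
  expect_equal(weighted, mean_ceb(s), tolerance = 1e-9)
})

test_that("mean parity from a printed row matches published values", {
  expect_equal(mean_parity_from_printed_row(c(41.6, 48.7, 7.1, 0.9, 1.6, 0, 0)),
               0.72)
  expect_equal(mean_parity_from_printed_row(c(19.6, 48.8, 22.4, 7.7, 1.3, 0.2, 0)),
               1.23)
  expect_equal(mean_parity_from_printed_row(c(100, 0, 0, 0, 0, 0, 0)), 0)
  expect_error(mean_parity_from_printed_row(c(-1, 101, 0, 0, 0, 0, 0)),
               "negative")
  expect_error(mean_parity_from_printed_row(c(10, 10, 10, 10, 10, 10, 10)),
               "sum to 100")
})

test_that("mean open interval: midpoint rule and microdata agree", {
  all_first <- make_distribution(c(100, rep(0, 19)))
  expect_equal(mean_open_interval(all_first), 0.5)
  uniform <- make_distribution(rep(5, 20))
  expect_equal(mean_open_interval(uniform), 10)

  s <- cached_survey("niger", n = 4000, seed = 11)
  d <- tabulate_distribution(s)
  expect_equal(mean_open_interval(s), mean_open_interval(d), tolerance = 0.5)
})
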