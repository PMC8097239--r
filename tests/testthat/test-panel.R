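test_that("pearson handles exact linear relations and error cases", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  p <- pearson(x, x^2)
  expect_equal(p$r_squared, p$r^2)
  expect_equal(p$n, 10)
  expect_error(pearson(x, rep(3, 10)), "constant series")
  expect_error(pearson(x, 1:9), "equal length")
  expect_error(pearson(1:2, 2:3), ">= 3")
})

test_that("pearson is symmetric and affine-invariant", {
  set.seed(8)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(pearson(x, y)$r, pearson(y, x)$r)
  expect_equal(pearson(3 * x - 7, y)$r, pearson(x, y)$r, tolerance = 1e-12)
  expect_equal(pearson(x, -2 * y)$r, -pearson(x, y)$r, tolerance = 1e-12)
})

test_that("collinear synthetic panel yields |r| = 1 everywhere", {
  panel <- data.frame(a_value = c(0.1, 0.3, 0.5),
                      b_value = -c(0.5, 1.0, 1.5),
                      tfr = c(2, 4, 6), gfr = c(70, 140, 210))
  s <- panel_correlations(panel)
  expect_equal(nrow(s), 5)
  expect_true(all(abs(abs(s$pearson_r) - 1) < 1e-12))
})

test_that("panel correlations show the expected sign pattern on the fixture", {
  s <- panel_correlations(load_country_panel())
  get <- function(xn, yn) s$pearson_r[s$x_name == xn & s$y_name == yn]
  # a rises and b falls with fertility; a and b move together strongly
  expect_lt(get("a_value", "b_value"), -0.95)
  expect_gt(get("a_value", "tfr"), 0.85)
  expect_gt(get("a_value", "gfr"), 0.85)
  expect_lt(get("b_value", "tfr"), -0.9)
  expect_lt(get("b_value", "gfr"), -0.9)
  expect_match(attr(s, "notes"), "3 b value")
})

test_that("panel correlations are invariant to row order", {
  panel <- load_country_panel()
  s1 <- panel_correlations(panel)
  set.seed(2)
  s2 <- panel_correlations(panel[sample(nrow(panel)), ])
  expect_equal(s1$pearson_r, s2$pearson_r)
})

test_that("fertility vs interval handles exact relations and missing columns", {
  panel <- data.frame(mean_open_interval = c(2, 3, 4, 5),
                      tfr = 8 - c(2, 3, 4, 5),
                      gfr = c(250, 200, 150, 100))
  s <- fertility_vs_interval(panel)
  expect_equal(s$pearson_r[s$x_name == "tfr"], -1)
  expect_true(any(grepl("mean_ceb not available", attr(s, "notes"))))
  expect_true(any(grepl("quadratic", attr(s, "notes"))))
  expect_error(fertility_vs_interval(data.frame(tfr = 1:3)),
               "mean_open_interval")
})

test_that("survey labels parse to mid-fieldwork years", {
  expect_equal(parse_survey_year("Colombia 2015"), 2015)
  expect_equal(parse_survey_year("Benin 2017-18"), 2017.5)
  expect_equal(parse_survey_year("Central African Republic 1994-95"), 1994.5)
})

test_that("two-point trend slopes and exclusions are exact", {
  surveys <- data.frame(
    country = c("A", "A", "B"),
    survey_label = c("A 2000", "A 2010", "B 2005"),
    first_interval_pct = c(47, 45, 30),
    tfr = c(5, 4, 3),
    mean_open_interval = c(3, 4, 5))
  tr <- repeat_survey_trends(surveys)
  expect_equal(tr$trends$first_interval_slope[tr$trends$country == "A"], -0.2)
  expect_equal(tr$trends$dtfr_dinterval_slope[tr$trends$country == "A"], -1)
  expect_equal(tr$excluded, "B")
  expect_equal(tr$summary$n_negative_first_interval, 1)
})

test_that("a constant regime across surveys has near-zero slopes", {
  surveys <- data.frame(
    country = "C", survey_label = paste("C", c(2000, 2005, 2010)),
    first_interval_pct = c(40, 40, 40), tfr = c(5, 5, 5),
    mean_open_interval = c(3, 3.01, 2.99))
  tr <- repeat_survey_trends(surveys)
  expect_equal(tr$trends$first_interval_slope, 0, tolerance = 1e-9)
})

test_that("declining fecundability across survey rounds gives a negative dTFR/dinterval slope", {
  # three synthetic rounds of one country, fertility falling between rounds
  grid <- fertility_regime_grid(n_regimes = 5, cohort_size = 1500, seed = 23)
  rounds <- lapply(grid[c(4, 3, 2)], simulate_survey)
  surveys <- data.frame(
    country = "sim",
    mid_year = c(2000, 2005, 2010),
    first_interval_pct = vapply(rounds, function(s)
      tabulate_distribution(s)$percentages[1], numeric(1)),
    tfr = vapply(rounds, compute_tfr, numeric(1)),
    mean_open_interval = vapply(rounds, mean_open_interval, numeric(1)))
  tr <- repeat_survey_trends(surveys)
  expect_lt(tr$trends$dtfr_dinterval_slope, 0)
  expect_lt(tr$trends$first_interval_slope, 0)
})
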