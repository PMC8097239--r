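# Open-interval tabulation and age/parity decompositions.
#
# Interval year k covers months [12(k-1), 12k) since the last birth; the
# distribution runs from birth through the 20th year, so months >= 240 are
# excluded and percentages are renormalised over bins 1..20.

.age_breaks <- seq(15, 50, by = 5)
.age_labels <- paste(.age_breaks[-8], .age_breaks[-1] - 1, sep = "-")

.age_group <- function(age_years) {
  cut(age_years, breaks = .age_breaks, labels = .age_labels, right = FALSE)
}

new_open_interval_distribution <- function(counts, label = "") {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 20, all(counts >= 0))
  n <- sum(counts)
  structure(list(label = label,
                 counts = counts,
                 percentages = 100 * counts / n,
                 n_eligible = n),
            class = "open_interval_distribution")
}

#' @export
print.open_interval_distribution <- function(x, ...) {
  cat("Open birth interval distribution", if (nzchar(x$label))
    paste0("(", x$label, ")"), "\n")
  cat("  eligible women:", x$n_eligible, "\n")
  cat("  first-interval share:", sprintf("%.1f%%", x$percentages[1]), "\n")
  invisible(x)
}

#' Assign each woman to an open-interval year
#'
#' Maps records to interval years 1..20 using the tabulation rules:
#' currently pregnant women go to year 1 regardless of parity (they are close
#' to a birth and resemble the first-year group); otherwise a woman with
#' parity >= 1 and `m` months since her last birth goes to year
#' `floor(m/12) + 1`. Women beyond the 20th year (`m >= 240`), non-pregnant
#' nulliparous women, and unmarried women have no open interval and are
#' excluded (`NA`).
#'
#' @param records a `woman_survey` data frame.
#' @return integer vector of interval years (1..20), `NA` for excluded
#'   records, with an `"exclusions"` attribute tabulating the reasons.
#' @export
open_interval_year <- function(records) {
  stopifnot(is.data.frame(records))
  m <- records$interview_cmc - records$last_birth_cmc
  if (any(m < 0, na.rm = TRUE)) {
    stop("data error: negative months since last birth")
  }
  year <- ifelse(records$currently_pregnant, 1L, m %/% 12L + 1L)
  year[!records$currently_pregnant & records$parity == 0] <- NA_integer_
  year[!records$currently_pregnant & !is.na(m) & m >= 240L] <- NA_integer_
  year[!records$currently_married] <- NA_integer_
  year <- as.integer(year)

  excl <- c(unmarried = sum(!records$currently_married),
            nulliparous = sum(records$currently_married &
                                !records$currently_pregnant &
                                records$parity == 0),
            over_20_years = sum(records$currently_married &
                                  !records$currently_pregnant &
                                  !is.na(m) & m >= 240L))
  attr(year, "exclusions") <- excl
  year
}

#' Tabulate the open-interval distribution
#'
#' Counts eligible women (currently married, aged 15--49, pregnant or with at
#' least one birth in the last 20 years) into interval years 1..20 and
#' expresses each bin as a percentage of the eligible total, which sums
#' to 100.
#'
#' @param records a `woman_survey` data frame.
#' @param label optional label carried on the result.
#' @return an `open_interval_distribution`: list with `label`, `counts`
#'   (length 20), `percentages` (sum 100), `n_eligible`.
#' @export
tabulate_distribution <- function(records, label = "") {
  year <- open_interval_year(records)
  if (all(is.na(year))) {
    stop("empty-input error: no eligible records to tabulate")
  }
  counts <- tabulate(year, nbins = 20L)
  new_open_interval_distribution(counts, label = label)
}

#' Age or parity composition within each interval year
#'
#' For each interval year 1..20, the percentage distribution of eligible
#' women across age groups (15-19 .. 45-49) or parity categories (1..5, 6+),
#' together with the per-interval mean of the axis variable (mean age in
#' years, or mean parity using true untopcoded parities). Interval years with
#' no women are flagged in `empty_intervals` and their shares set to `NA`
#' rather than propagating 0/0.
#'
#' @param records a `woman_survey` data frame.
#' @param axis `"age"` or `"parity"`.
#' @return an `interval_composition`: list with `axis`, `shares` (categories
#'   x 20 matrix of percentages, columns summing to 100), `mean_by_interval`
#'   (length 20), `n_by_interval`, `empty_intervals`.
#' @export
composition_by_interval <- function(records, axis = c("age", "parity")) {
  axis <- match.arg(axis)
  year <- open_interval_year(records)
  keep <- !is.na(year)
  if (!any(keep)) stop("empty-input error: no eligible records")
  year <- year[keep]

  if (axis == "age") {
    value <- records$age_years[keep]
    cat_f <- .age_group(value)
  } else {
    value <- records$parity[keep]
    # pregnant nulliparae sit in interval 1 at parity 0, so the parity axis
    # keeps a "0" category; categories above 5 are top-coded as 6+ while the
    # per-interval mean uses true parity.
    cat_f <- cut(value, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, Inf),
                 labels = c("0", "1", "2", "3", "4", "5", "6+"))
  }

  tab <- table(cat_f, factor(year, levels = 1:20))
  n_by_interval <- as.integer(colSums(tab))
  shares <- 100 * sweep(unclass(tab), 2, pmax(n_by_interval, 1L), "/")
  shares[, n_by_interval == 0] <- NA_real_
  mean_by_interval <- vapply(1:20, function(k) {
    if (n_by_interval[k] == 0) NA_real_ else mean(value[year == k])
  }, numeric(1))

  structure(list(axis = axis,
                 shares = shares,
                 mean_by_interval = mean_by_interval,
                 n_by_interval = n_by_interval,
                 empty_intervals = which(n_by_interval == 0)),
            class = "interval_composition")
}

#' Parity distribution within age groups
#'
#' The percentage distribution of women across parities 0..5 and 6+ within
#' each five-year age group, with the mean parity per age group computed from
#' true (untopcoded) parities. Unlike interval tabulation this includes
#' parity-0 women; by default it keeps the currently married, consistent with
#' the survey universe of the packaged Colombia table.
#'
#' @param records a `woman_survey` data frame.
#' @param married_only restrict to currently married women (default `TRUE`).
#' @return an `age_parity_table`: list with `percentages` (7 age groups x
#'   7 parity columns, rows summing to 100), `row_means`, `row_n`, and
#'   `empty_rows` flagging age groups with no women.
#' @export
age_parity_table <- function(records, married_only = TRUE) {
  stopifnot(is.data.frame(records))
  keep <- records$age_years >= 15 & records$age_years <= 49
  if (married_only) keep <- keep & records$currently_married
  age <- .age_group(records$age_years[keep])
  parity <- records$parity[keep]
  pcat <- cut(parity, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, Inf),
              labels = c("0", "1", "2", "3", "4", "5", "6+"))
  tab <- table(age, pcat)
  row_n <- as.integer(rowSums(tab))
  pct <- 100 * sweep(unclass(tab), 1, pmax(row_n, 1L), "/")
  pct[row_n == 0, ] <- NA_real_
  row_means <- vapply(levels(age), function(g) {
    if (sum(age == g) == 0) NA_real_ else mean(parity[age == g])
  }, numeric(1))
  structure(list(percentages = pct, row_means = row_means, row_n = row_n,
                 empty_rows = levels(age)[row_n == 0]),
            class = "age_parity_table")
}

#' Mean parity implied by a printed parity-distribution row
#'
#' Reconstructs the mean parity from a printed percentage row over parities
#' 0..5 and 6+, coding the open-ended 6+ column as parity 6 and rounding to
#' two decimals for comparison with published means. Where a row has no 6+
#' mass the reconstruction is exact; rows with 6+ mass are underestimated
#' because the true parities above 6 are not recoverable from the printed
#' distribution.
#'
#' @param percentages numeric vector of length 7 (parities 0..5, 6+),
#'   summing to 100 within 0.5.
#' @return mean parity, rounded to 2 decimals.
#' @export
mean_parity_from_printed_row <- function(percentages) {
  if (length(percentages) != 7 || any(!is.finite(percentages))) {
    stop("expected 7 finite percentages (parities 0..5, 6+)")
  }
  if (any(percentages < 0)) stop("domain error: negative percentage")
  if (abs(sum(percentages) - 100) > 0.5) {
    stop("percentages must sum to 100 within 0.5")
  }
  round(sum((0:6) * percentages) / 100, 2)
}

#' Mean open interval in years
#'
#' From microdata: the mean of exact months-since-last-birth over eligible
#' women, divided by 12, with currently pregnant women contributing 0.5 years
#' (the midpoint of the first interval year they are assigned to). From a
#' binned distribution: the percentage-weighted mean of the bin midpoints
#' (k - 0.5 years for interval year k).
#'
#' @param x a `woman_survey` data frame or an `open_interval_distribution`.
#' @return mean open interval in years.
#' @export
mean_open_interval <- function(x) {
  UseMethod("mean_open_interval")
}

#' @export
mean_open_interval.open_interval_distribution <- function(x) {
  sum((1:20 - 0.5) * x$percentages) / 100
}

#' @export
mean_open_interval.woman_survey <- function(x) {
  year <- open_interval_year(x)
  keep <- !is.na(year)
  if (!any(keep)) stop("empty-input error: no eligible records")
  m <- (x$interview_cmc - x$last_birth_cmc) / 12
  m[x$currently_pregnant] <- 0.5
  mean(m[keep])
}

#' @export
mean_open_interval.data.frame <- function(x) {
  mean_open_interval.woman_survey(x)
}
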