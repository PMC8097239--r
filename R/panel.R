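# Cross-survey analyses: parameter--fertility correlations over the country
# panel, fertility-vs-mean-interval relations, and repeat-survey trend
# slopes. The source tables print signed values labelled "R2"; we therefore
# report both the signed product-moment r and r^2 for every pair.

#' Pearson correlation with both signed r and r-squared
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` (signed), `r_squared`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant series")
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, n = length(x))
}

.assoc_row <- function(x_name, y_name, x, y) {
  p <- pearson(x, y)
  data.frame(x_name = x_name, y_name = y_name, pearson_r = p$r,
             r_squared = p$r_squared, n = p$n, stringsAsFactors = FALSE)
}

#' Parameter--fertility correlations over a country panel
#'
#' Computes the five headline correlations over a cleaned panel (signed `b`,
#' misprint corrections applied): (a, b), (a, TFR), (b, TFR), (a, GFR),
#' (b, GFR). In the expected pattern the level `a` correlates positively and
#' the signed slope `b` negatively with both fertility rates, and `a` and
#' `b` move together strongly (high level implies steep descent, because the
#' distribution must total 100%).
#'
#' @param panel a `country_panel` data frame (see [load_country_panel()]).
#' @return an `association_summary` data frame with one row per pair
#'   (`x_name`, `y_name`, `pearson_r`, `r_squared`, `n`); the number of
#'   b-corrected rows is noted in `attr(x, "notes")`.
#' @export
panel_correlations <- function(panel) {
  stopifnot(all(c("a_value", "b_value", "tfr", "gfr") %in% names(panel)))
  out <- rbind(
    .assoc_row("a_value", "b_value", panel$a_value, panel$b_value),
    .assoc_row("a_value", "tfr", panel$a_value, panel$tfr),
    .assoc_row("b_value", "tfr", panel$b_value, panel$tfr),
    .assoc_row("a_value", "gfr", panel$a_value, panel$gfr),
    .assoc_row("b_value", "gfr", panel$b_value, panel$gfr))
  notes <- if ("b_corrected" %in% names(panel)) {
    sprintf("%d b value(s) carry the x10 misprint correction",
            sum(panel$b_corrected))
  } else {
    character(0)
  }
  attr(out, "notes") <- notes
  class(out) <- c("association_summary", "data.frame")
  out
}

#' Fertility measures versus the mean open interval
#'
#' Correlates TFR, GFR, and mean CEB with the mean open interval across
#' surveys. The relationship is curvilinear -- the slope flattens at long
#' intervals as the TFR approaches replacement -- so the note records the
#' p-value of a quadratic term in a TFR-on-interval regression. Measures
#' absent from the panel are skipped with a note.
#'
#' @param panel data frame with a `mean_open_interval` column and any of
#'   `tfr`, `gfr`, `mean_ceb`.
#' @return an `association_summary` data frame (one row per available
#'   measure), with curvature and skip notes in `attr(x, "notes")`.
#' @export
fertility_vs_interval <- function(panel) {
  if (!"mean_open_interval" %in% names(panel)) {
    stop("panel lacks a mean_open_interval column")
  }
  measures <- c("tfr", "gfr", "mean_ceb")
  notes <- character(0)
  rows <- list()
  for (m in measures) {
    if (!m %in% names(panel) || all(is.na(panel[[m]]))) {
      notes <- c(notes, paste0(m, " not available; pair skipped"))
      next
    }
    rows[[m]] <- .assoc_row(m, "mean_open_interval",
                            panel[[m]], panel$mean_open_interval)
  }
  if (length(rows) == 0) stop("no fertility measures available")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("tfr" %in% names(rows)) {
    quad <- stats::lm(tfr ~ mean_open_interval + I(mean_open_interval^2),
                      data = panel)
    pq <- suppressWarnings(stats::coef(summary(quad)))
    if (nrow(pq) == 3) {
      notes <- c(notes, sprintf(
        "curvilinearity: quadratic term p = %.3g in TFR ~ interval", pq[3, 4]))
    }
  }
  attr(out, "notes") <- notes
  class(out) <- c("association_summary", "data.frame")
  out
}

#' Parse a survey mid-fieldwork year from its label
#'
#' `"Colombia 2015"` gives 2015; a split fieldwork label such as
#' `"Benin 2017-18"` gives the midpoint 2017.5.
#'
#' @param label character vector of survey labels ending in a year or
#'   year-range.
#' @return numeric mid-year.
#' @export
parse_survey_year <- function(label) {
  token <- sub(".*?([0-9]{4}(-[0-9]{2,4})?)\\s*$", "\\1", label)
  vapply(token, function(tok) {
    parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
    y1 <- as.numeric(parts[1])
    if (length(parts) == 1 || is.na(y1)) return(y1)
    y2 <- as.numeric(parts[2])
    if (y2 < 100) y2 <- 100 * (y1 %/% 100) + y2
    (y1 + y2) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trend slopes for countries with repeated surveys
#'
#' For each country with at least two surveys: the ordinary least-squares
#' slope of the first-interval percentage on survey mid-year (percentage
#' points per calendar year), and the slope of the TFR on the mean open
#' interval (TFR change per year of interval change). Single-survey
#' countries are excluded with a note. All of a country's surveys enter one
#' least-squares fit; setting `first_vs_last = TRUE` instead differences the
#' earliest and latest surveys, as a sensitivity variant.
#'
#' @param surveys data frame with columns `country`, `survey_label` (or
#'   `mid_year`), `first_interval_pct`, and optionally `tfr` and
#'   `mean_open_interval`.
#' @param first_vs_last use two-point differencing instead of OLS.
#' @return a `trend_result` list: `trends` (one row per multi-survey
#'   country: `country`, `n_surveys`, `first_interval_slope`,
#'   `dtfr_dinterval_slope`), `summary` (count of negative
#'   first-interval slopes, their median and mean, and the same for the
#'   dTFR/dinterval slopes), and `excluded` (single-survey countries).
#' @export
repeat_survey_trends <- function(surveys, first_vs_last = FALSE) {
  stopifnot(all(c("country", "first_interval_pct") %in% names(surveys)))
  if (!"mid_year" %in% names(surveys)) {
    surveys$mid_year <- parse_survey_year(surveys$survey_label)
  }
  slope <- function(y, x) {
    if (first_vs_last) {
      i <- which.min(x); j <- which.max(x)
      (y[j] - y[i]) / (x[j] - x[i])
    } else {
      unname(stats::coef(stats::lm(y ~ x))[2])
    }
  }
  counts <- table(surveys$country)
  excluded <- names(counts)[counts < 2]
  rows <- lapply(names(counts)[counts >= 2], function(ctry) {
    s <- surveys[surveys$country == ctry, ]
    dtfr <- if (all(c("tfr", "mean_open_interval") %in% names(s)) &&
                stats::sd(s$mean_open_interval) > 0) {
      slope(s$tfr, s$mean_open_interval)
    } else {
      NA_real_
    }
    data.frame(country = ctry, n_surveys = nrow(s),
               first_interval_slope = slope(s$first_interval_pct, s$mid_year),
               dtfr_dinterval_slope = dtfr, stringsAsFactors = FALSE)
  })
  trends <- do.call(rbind, rows)
  if (is.null(trends)) stop("no country has >= 2 surveys")
  fi <- trends$first_interval_slope
  dt <- trends$dtfr_dinterval_slope
  structure(list(
    trends = trends,
    summary = list(
      n_countries = nrow(trends),
      n_negative_first_interval = sum(fi < 0),
      median_first_interval_slope = stats::median(fi),
      mean_first_interval_slope = mean(fi),
      n_negative_dtfr = sum(dt < 0, na.rm = TRUE),
      median_dtfr_dinterval = stats::median(dt, na.rm = TRUE),
      mean_dtfr_dinterval = mean(dt, na.rm = TRUE)),
    excluded = excluded),
    class = "trend_result")
}
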