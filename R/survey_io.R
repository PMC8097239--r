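#' openinterval: open birth interval analysis for survey microdata
#'
#' Tools to tabulate and model the distribution of women by open birth
#' interval -- the time elapsed since the most recent live birth, observed at
#' interview. The package covers the full analysis chain: reading DHS-style
#' microdata, constructing interval distributions and their age/parity
#' decompositions, computing fertility measures (TFR, GFR, mean CEB) from
#' birth histories, fitting a two-parameter power curve plus three comparator
#' models, cross-survey panel correlations and trend slopes, stationary
#' renewal-theory relations between closed and open intervals, and a
#' reproductive-history microsimulator that generates survey-style cohorts
#' under configurable fertility regimes.
#'
#' Dates are handled as century-month codes (CMC): months elapsed since
#' January 1900, the DHS convention, so all interval arithmetic is integer.
#'
#' @keywords internal
#' @aliases openinterval-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Microdata CSV schema
# ---------------------------------------------------------------------------

# Required columns, in canonical order. `birth_cmcs` (semicolon-separated CMC
# list) and `woman_dob_cmc` are optional extensions carried by the simulator
# and used by the fertility-rate functions. The DHS recode mapping is:
# v008 -> interview_cmc, v012 -> age_years, v201 -> parity,
# b3 (last) -> last_birth_cmc, v213 -> currently_pregnant,
# v502 -> currently_married, v011 -> woman_dob_cmc.
.survey_columns <- c("woman_id", "interview_cmc", "age_years", "parity",
                     "last_birth_cmc", "currently_pregnant",
                     "currently_married")
.survey_optional <- c("birth_cmcs", "woman_dob_cmc")

#' Read survey microdata from CSV
#'
#' Reads a comma-separated, UTF-8 microdata file with one row per woman and a
#' header matching the documented schema (`woman_id`, `interview_cmc`,
#' `age_years`, `parity`, `last_birth_cmc`, `currently_pregnant`,
#' `currently_married`, optionally `birth_cmcs` and `woman_dob_cmc`). Empty
#' strings encode missing values. Rows violating the record invariants are
#' rejected and logged rather than silently kept.
#'
#' Record invariants: `last_birth_cmc` is missing iff `parity` is 0;
#' `last_birth_cmc <= interview_cmc` when present; `age_years` within 15--49.
#'
#' @param path path to a CSV file.
#' @param strict if `TRUE`, any invalid row is an error; if `FALSE` (default)
#'   invalid rows are dropped and reported in the `"rejections"` attribute.
#' @return a `woman_survey` data frame of validated records. The attribute
#'   `attr(x, "rejections")` is a data frame with columns `row`, `woman_id`,
#'   `reason`, one entry per rejected input row.
#' @seealso [write_survey_csv()], [simulate_survey()]
#' @export
read_survey_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(.survey_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("survey schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("interview_cmc", "age_years", "parity", "last_birth_cmc")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("currently_pregnant", "currently_married")) {
    df[[col]] <- as.logical(df[[col]])
  }
  if ("birth_cmcs" %in% names(df)) {
    # empty history is the empty string, not missing
    df$birth_cmcs <- ifelse(is.na(df$birth_cmcs), "",
                            as.character(df$birth_cmcs))
  }
  as_woman_survey(df, strict = strict)
}

#' Validate a data frame of woman records
#'
#' Applies the record invariants to an in-memory data frame and returns a
#' validated `woman_survey` object; see [read_survey_csv()] for the rules.
#'
#' @param df data frame with the schema columns.
#' @param strict error on the first invalid row instead of rejecting it.
#' @return a `woman_survey` data frame with a `"rejections"` attribute.
#' @export
as_woman_survey <- function(df, strict = FALSE) {
  missing_cols <- setdiff(.survey_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("survey schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- msg
  }
  flag(is.na(df$parity) | df$parity < 0, "missing or negative parity")
  flag(df$parity > 0 & is.na(df$last_birth_cmc),
       "parity>0 without last birth")
  flag(df$parity == 0 & !is.na(df$last_birth_cmc),
       "last birth recorded for parity-0 woman")
  flag(!is.na(df$last_birth_cmc) & df$last_birth_cmc > df$interview_cmc,
       "last birth after interview")
  flag(is.na(df$age_years) | df$age_years < 15 | df$age_years > 49,
       "age outside 15-49")
  flag(is.na(df$interview_cmc) | df$interview_cmc <= 0,
       "missing interview date")

  bad <- !is.na(reason)
  if (strict && any(bad)) {
    i <- which(bad)[1]
    stop("invalid survey record at row ", i, ": ", reason[i])
  }
  rejections <- data.frame(row = which(bad),
                           woman_id = as.character(df$woman_id[bad]),
                           reason = reason[bad],
                           stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  class(out) <- c("woman_survey", "data.frame")
  out
}

#' Write survey microdata to CSV
#'
#' Inverse of [read_survey_csv()]: writes the schema columns (plus any
#' optional extension columns present) with empty strings for missing values,
#' so that a write/read round trip reproduces the records exactly.
#'
#' @param records a `woman_survey` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  cols <- c(.survey_columns, intersect(.survey_optional, names(records)))
  utils::write.csv(as.data.frame(records)[, cols], path,
                   row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Packaged fixtures
# ---------------------------------------------------------------------------

# Parse "key=value" integrity tokens out of the fixture comment header and
# stop if the recomputed quantities disagree (guards against a corrupted or
# truncated transcription).
.check_fixture_integrity <- function(path, values) {
  header <- grep("integrity:", readLines(path, n = 10), value = TRUE)
  if (length(header) != 1) stop("fixture missing integrity line: ", path)
  tokens <- regmatches(header, gregexpr("[a-z_]+=[0-9.]+", header))[[1]]
  declared <- stats::setNames(
    as.numeric(sub(".*=", "", tokens)), sub("=.*", "", tokens))
  for (key in names(values)) {
    if (!key %in% names(declared) ||
        abs(declared[[key]] - values[[key]]) > 1e-6) {
      stop("fixture integrity error in ", basename(path), ": ", key,
           " recomputed as ", values[[key]])
    }
  }
  invisible(TRUE)
}

#' Load the 75-survey country panel of power-curve parameters
#'
#' Loads the packaged cross-country panel: for the latest DHS survey in each
#' of 75 countries, the fitted power-curve level `a` and slope `b`, the total
#' fertility rate (TFR), the general fertility rate (GFR), and the R-squared
#' of the fit. In the source table the slope is printed in accounting
#' convention -- parentheses denote a negative value -- and three rows carry
#' an apparent decimal-shift misprint: a printed slope magnitude below 0.2
#' alongside a level above 0.4 (Benin 2017-18, Guinea 2018, Haiti 2016-17),
#' which contradicts the systematic level--slope relationship seen in every
#' other row. By default these are corrected by a factor of 10 before
#' negation and flagged in `b_corrected`.
#'
#' @param path optional path to an alternative panel CSV in the same layout;
#'   defaults to the packaged fixture.
#' @param b_correction apply the documented x10 correction to the three
#'   anomalous slope magnitudes (default `TRUE`).
#' @return a `country_panel` data frame with columns `survey_label`,
#'   `a_value` (> 0), `b_value` (signed, negative), `tfr`, `gfr`, `r2`, and
#'   `b_corrected`. The `r2` column is carried as metadata from the source
#'   fits; it cannot be re-derived without the underlying microdata.
#' @export
load_country_panel <- function(path = NULL, b_correction = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "country_panel.csv",
                        package = "openinterval", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(raw) != 75) {
    stop("fixture integrity error: expected 75 panel rows, got ", nrow(raw))
  }
  .check_fixture_integrity(path, list(
    rows = nrow(raw),
    colsum_a = round(sum(raw$a_value), 3),
    colsum_tfr = round(sum(raw$tfr), 1)))

  b_mag <- suppressWarnings(as.numeric(gsub("[()]", "", raw$b_printed)))
  if (anyNA(b_mag)) stop("unparseable b value in panel fixture")
  misprint <- b_mag < 0.2 & raw$a_value > 0.4
  if (b_correction) b_mag[misprint] <- b_mag[misprint] * 10
  out <- data.frame(survey_label = raw$survey_label,
                    a_value = raw$a_value,
                    b_value = -b_mag,
                    tfr = raw$tfr,
                    gfr = raw$gfr,
                    r2 = raw$r2,
                    b_corrected = b_correction & misprint,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$a_value > 0), all(out$b_value < 0),
            all(out$r2 > 0 & out$r2 <= 1))
  class(out) <- c("country_panel", "data.frame")
  out
}

#' Load the Colombia parity-within-age table, 1990--2015
#'
#' Loads the packaged table of percentage distributions of currently married
#' women by parity (0--5 and 6+) within each five-year age group, for six
#' Colombia DHS surveys spanning a 25-year fertility decline, together with
#' the published mean parities. Each row is checked to sum to 100 within the
#' printed rounding tolerance (0.3).
#'
#' @param path optional alternative CSV path; defaults to the packaged
#'   fixture.
#' @return a data frame with columns `age_group`, `year`, `p0`..`p5`,
#'   `p6plus`, `total`, `mean_parity` (42 rows: 7 age groups x 6 surveys).
#' @seealso [mean_parity_from_printed_row()]
#' @export
load_colombia_parity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "colombia_parity.csv",
                        package = "openinterval", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) != 42) {
    stop("fixture integrity error: expected 42 rows, got ", nrow(tab))
  }
  .check_fixture_integrity(path, list(
    rows = nrow(tab), colsum_mean = round(sum(tab$mean_parity), 2)))
  pcols <- c("p0", "p1", "p2", "p3", "p4", "p5", "p6plus")
  sums <- rowSums(tab[, pcols])
  off <- abs(sums - 100) > 0.3
  if (any(off)) {
    stop("fixture integrity error: row (", tab$age_group[which(off)[1]], ", ",
         tab$year[which(off)[1]], ") sums to ", sums[which(off)[1]])
  }
  tab
}
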