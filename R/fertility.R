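# Period fertility measures from survey records carrying full birth
# histories (the simulator's `birth_cmcs` column). Rates are computed over
# all women, not only the currently married: interval tabulation uses the
# married-women universe, but TFR/GFR are conventionally population rates.

.parse_birth_cmcs <- function(records) {
  if (!"birth_cmcs" %in% names(records)) {
    stop("records lack a birth_cmcs column; full birth histories are ",
         "required for rate computation")
  }
  lapply(strsplit(ifelse(is.na(records$birth_cmcs), "",
                         records$birth_cmcs), ";", fixed = TRUE),
         function(s) as.integer(s[nzchar(s)]))
}

# Woman's age in months at interview: exact when woman_dob_cmc is present,
# otherwise the midpoint of the reported single-year age.
.age_months_at_interview <- function(records) {
  if ("woman_dob_cmc" %in% names(records)) {
    records$interview_cmc - records$woman_dob_cmc
  } else {
    records$age_years * 12L + 6L
  }
}

# Births and exposure (in months) by 5-year age group over the rate window.
# Window covers the `window_months` months ending at the interview month.
.births_exposure_by_age <- function(records, window_months) {
  stopifnot(window_months >= 1)
  births <- .parse_birth_cmcs(records)
  age_at_interview <- .age_months_at_interview(records)
  n_groups <- 7L # 15-19 .. 45-49

  expo <- numeric(n_groups)
  bcount <- numeric(n_groups)
  group_of_month <- function(age_m) {
    g <- (age_m %/% 60L) - 2L # 180..239 months -> group 1
    g[age_m < 180L | g > n_groups] <- NA_integer_
    g
  }
  for (i in seq_len(nrow(records))) {
    # exposure: the woman's age in each of the window months
    offsets <- 0:(window_months - 1L)
    ages <- age_at_interview[i] - offsets
    g <- group_of_month(ages)
    tg <- tabulate(g[!is.na(g)], nbins = n_groups)
    expo <- expo + tg
    # births inside the window, classified by mother's age at birth
    b <- births[[i]]
    if (length(b) > 0) {
      in_window <- b > records$interview_cmc[i] - window_months &
        b <= records$interview_cmc[i]
      if (any(in_window)) {
        age_at_birth <- age_at_interview[i] -
          (records$interview_cmc[i] - b[in_window])
        gb <- group_of_month(age_at_birth)
        bcount <- bcount + tabulate(gb[!is.na(gb)], nbins = n_groups)
      }
    }
  }
  list(births = bcount, exposure_months = expo)
}

#' Total fertility rate from birth histories
#'
#' Computes the period TFR from the births and woman-months of exposure
#' observed in the window before the interview: the sum over the seven
#' five-year age groups 15-19..45-49 of the age-specific fertility rate
#' (births per woman-year) times 5. Age groups with zero exposure contribute
#' 0 with a warning. Exposure below exact age 15 is excluded, as are births
#' occurring there.
#'
#' @param records a `woman_survey` data frame with a `birth_cmcs` column.
#' @param window_months length of the rate window ending at interview
#'   (default 36, the conventional three-year DHS window).
#' @return TFR in births per woman.
#' @export
compute_tfr <- function(records, window_months = 36L) {
  be <- .births_exposure_by_age(records, window_months)
  zero <- be$exposure_months == 0
  if (any(zero)) {
    warning("zero exposure in age group(s) ",
            paste(.age_labels[zero], collapse = ", "),
            "; contributing 0 to the TFR")
  }
  asfr <- ifelse(zero, 0, be$births / (be$exposure_months / 12))
  sum(5 * asfr)
}

#' General fertility rate from birth histories
#'
#' Births in the rate window per 1,000 woman-years of exposure at ages
#' 15--44 (the conventional GFR denominator).
#'
#' @inheritParams compute_tfr
#' @return GFR in births per 1,000 women per year.
#' @export
compute_gfr <- function(records, window_months = 36L) {
  be <- .births_exposure_by_age(records, window_months)
  idx <- 1:6 # ages 15-44
  expo_years <- sum(be$exposure_months[idx]) / 12
  if (expo_years == 0) {
    warning("zero exposure at ages 15-44; GFR set to 0")
    return(0)
  }
  1000 * sum(be$births[idx]) / expo_years
}

#' Mean children ever born
#'
#' Arithmetic mean parity over women aged 15--49.
#'
#' @param records a `woman_survey` data frame.
#' @return mean CEB per woman.
#' @export
mean_ceb <- function(records) {
  keep <- records$age_years >= 15 & records$age_years <= 49
  if (!any(keep)) stop("empty-input error: no women aged 15-49")
  mean(records$parity[keep])
}
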