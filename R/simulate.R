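# Reproductive-history microsimulation on a monthly clock, plus direct
# samplers used in fit-recovery and renewal tests. All dates are
# century-month codes (CMC, months since January 1900).

#' Build a microsimulation configuration
#'
#' Assembles and validates the parameter set for [simulate_survey()]. The
#' conception model is Bernoulli per month: an exposed woman (married, not
#' pregnant, not postpartum-infecund, not sterile) conceives with probability
#' `monthly_fecundability * spousal_absence_factor`, reduced proportionally
#' by `contraceptive_effectiveness` once a contracepting woman has reached
#' her desired parity. Imperfect effectiveness therefore generates unplanned
#' births and the long right tail of the open-interval distribution.
#'
#' @param monthly_fecundability probability of conception per exposed month,
#'   in (0, 1]. Natural-fertility populations are typically 0.15--0.25.
#' @param gestation_months gestation length in months (default 9).
#' @param postpartum_infecundable_months birth-free months after a delivery
#'   during which conception is suppressed (lactational amenorrhea); 5--18 in
#'   observed populations.
#' @param contraceptive_prevalence probability that a woman uses
#'   contraception to stop at her desired parity, in \[0, 1\].
#' @param contraceptive_effectiveness proportional reduction of
#'   fecundability while contracepting, in \[0, 1\].
#' @param desired_parity_distribution probability vector over desired
#'   parities 0..12 (length 13, sums to 1).
#' @param sterility_onset_hazard per-month hazard of permanent sterility
#'   onset, piecewise constant over the seven age groups 15-19..45-49
#'   (length 7, non-decreasing in realistic regimes).
#' @param marriage_age_distribution probability vector over marriage ages
#'   15..35 (length 21, sums to 1).
#' @param spousal_absence_factor monthly exposure-reduction factor in
#'   (0, 1\]; 1 means the spouse is always present.
#' @param cohort_size number of women to simulate (>= 1).
#' @param survey_age_range two integers, the age range sampled at interview
#'   (default c(15, 49)).
#' @param seed master integer seed; per-woman streams are derived from it by
#'   counter, so enlarging `cohort_size` does not reshuffle earlier women.
#' @return a validated `simulation_config` object (a named list).
#' @seealso [regime_preset()], [fertility_regime_grid()]
#' @export
simulation_config <- function(monthly_fecundability = 0.20,
                              gestation_months = 9L,
                              postpartum_infecundable_months = 9L,
                              contraceptive_prevalence = 0.5,
                              contraceptive_effectiveness = 0.92,
                              desired_parity_distribution =
                                parity_target_distribution(4),
                              sterility_onset_hazard =
                                c(7e-4, 1.1e-3, 1.2e-3, 1.9e-3,
                                  3.7e-3, 9e-3, 1.4e-2),
                              marriage_age_distribution =
                                marriage_age_profile(20),
                              spousal_absence_factor = 1.0,
                              cohort_size = 2000L,
                              survey_age_range = c(15L, 49L),
                              seed = 1L) {
  cfg <- list(monthly_fecundability = monthly_fecundability,
              gestation_months = as.integer(gestation_months),
              postpartum_infecundable_months =
                as.integer(postpartum_infecundable_months),
              contraceptive_prevalence = contraceptive_prevalence,
              contraceptive_effectiveness = contraceptive_effectiveness,
              desired_parity_distribution = desired_parity_distribution,
              sterility_onset_hazard = sterility_onset_hazard,
              marriage_age_distribution = marriage_age_distribution,
              spousal_absence_factor = spousal_absence_factor,
              cohort_size = as.integer(cohort_size),
              survey_age_range = as.integer(survey_age_range),
              seed = as.integer(seed))

  chk_prob <- function(x, field, lo = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > 1) {
      stop("configuration error: ", field, " must be a probability in [",
           lo, ", 1]")
    }
  }
  chk_prob(cfg$monthly_fecundability, "monthly_fecundability")
  chk_prob(cfg$contraceptive_prevalence, "contraceptive_prevalence")
  chk_prob(cfg$contraceptive_effectiveness, "contraceptive_effectiveness")
  chk_prob(cfg$spousal_absence_factor, "spousal_absence_factor")
  chk_pvec <- function(x, field, len) {
    if (length(x) != len || any(!is.finite(x)) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-9) {
      stop("configuration error: ", field, " must be a length-", len,
           " probability vector summing to 1")
    }
  }
  chk_pvec(cfg$desired_parity_distribution, "desired_parity_distribution", 13)
  chk_pvec(cfg$marriage_age_distribution, "marriage_age_distribution", 21)
  if (length(cfg$sterility_onset_hazard) != 7 ||
      any(cfg$sterility_onset_hazard < 0) ||
      any(cfg$sterility_onset_hazard > 1)) {
    stop("configuration error: sterility_onset_hazard must be 7 per-month ",
         "hazards in [0, 1]")
  }
  if (cfg$gestation_months < 1) {
    stop("configuration error: gestation_months must be >= 1")
  }
  if (cfg$postpartum_infecundable_months < 0) {
    stop("configuration error: postpartum_infecundable_months must be >= 0")
  }
  if (is.na(cfg$cohort_size) || cfg$cohort_size < 1) {
    stop("configuration error: cohort_size must be >= 1")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Discretised Poisson distribution over desired parities 0..12
#'
#' Convenience constructor for `desired_parity_distribution`: a Poisson
#' distribution with the given mean, truncated to 0..12 and renormalised.
#'
#' @param mean_parity mean of the untruncated Poisson.
#' @return probability vector of length 13.
#' @export
parity_target_distribution <- function(mean_parity) {
  stopifnot(mean_parity >= 0)
  p <- stats::dpois(0:12, lambda = mean_parity)
  p / sum(p)
}

#' Discretised normal distribution over marriage ages 15..35
#'
#' @param mean_age mean marriage age in years.
#' @param sd_age standard deviation (default 2.5 years).
#' @return probability vector of length 21.
#' @export
marriage_age_profile <- function(mean_age, sd_age = 2.5) {
  p <- stats::dnorm(15:35, mean = mean_age, sd = sd_age)
  p / sum(p)
}

#' Preset fertility regimes
#'
#' Two qualitative regimes bracketing the observed range: a high-fertility
#' regime ("niger": early marriage, high desired parity, long lactational
#' infecundability, little contraception) and a transitional low-fertility
#' regime ("colombia": later marriage, two-to-three-child norm, high
#' contraceptive prevalence). The presets are qualitative; they are not
#' calibrated to reproduce any particular country's published distribution.
#'
#' @param name `"niger"` or `"colombia"`.
#' @param cohort_size,seed passed through to [simulation_config()].
#' @return a `simulation_config`.
#' @export
regime_preset <- function(name = c("niger", "colombia"),
                          cohort_size = 2000L, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    niger = simulation_config(
      monthly_fecundability = 0.14,
      postpartum_infecundable_months = 20L,
      contraceptive_prevalence = 0.08,
      contraceptive_effectiveness = 0.85,
      desired_parity_distribution = parity_target_distribution(8.5),
      marriage_age_distribution = marriage_age_profile(16.5, 1.8),
      cohort_size = cohort_size, seed = seed),
    colombia = simulation_config(
      monthly_fecundability = 0.14,
      postpartum_infecundable_months = 6L,
      contraceptive_prevalence = 0.94,
      contraceptive_effectiveness = 0.98,
      desired_parity_distribution = parity_target_distribution(1.9),
      marriage_age_distribution = marriage_age_profile(23),
      cohort_size = cohort_size, seed = seed))
}

#' Grid of fertility regimes spanning the observed TFR range
#'
#' Interpolates the configuration parameters between a low-fertility
#' transitional regime and a high natural-fertility regime, producing a panel
#' of regimes whose simulated total fertility rates span roughly 1.5 to 7.5
#' births per woman -- the range covered by the 75-country panel. Used for
#' direction-of-effect checks of the parameter--fertility relationships.
#'
#' Because fertility responds concavely to the interpolated parameters
#' (postpartum infecundability and sterility cap the high end), the
#' interpolation coordinate is warped through fixed knots so that successive
#' regimes are spaced approximately evenly in expected TFR rather than
#' bunching at the natural-fertility ceiling.
#'
#' @param n_regimes number of regimes (>= 2, default 12).
#' @param cohort_size women per regime.
#' @param seed master seed; regime i uses `seed + i`.
#' @return a named list of `simulation_config` objects, ordered from lowest
#'   to highest fertility.
#' @export
fertility_regime_grid <- function(n_regimes = 12L, cohort_size = 2000L,
                                  seed = 1L) {
  stopifnot(n_regimes >= 2)
  # warp knots chosen so expected TFR is ~equidistant across regimes
  knots <- c(0, 0.06, 0.11, 0.16, 0.21, 0.27, 0.33, 0.40, 0.48, 0.58,
             0.72, 1)
  tt <- stats::approx(seq(0, 1, length.out = length(knots)), knots,
                      xout = seq(0, 1, length.out = n_regimes))$y
  out <- lapply(seq_along(tt), function(i) {
    t <- tt[i]
    simulation_config(
      monthly_fecundability = 0.12 + 0.03 * t,
      postpartum_infecundable_months = round(5 + 15 * t),
      contraceptive_prevalence = 0.97 - 0.89 * t,
      contraceptive_effectiveness = 0.99 - 0.14 * t,
      desired_parity_distribution = parity_target_distribution(1.4 + 7.1 * t),
      marriage_age_distribution = marriage_age_profile(27 - 10.5 * t),
      cohort_size = cohort_size,
      seed = seed + i)
  })
  names(out) <- sprintf("regime_%02d", seq_along(out))
  out
}

# Sample the woman-age month (from exact age 15y = month 180) at which
# permanent sterility begins, or Inf. Hazard is piecewise constant over
# 5-year bands; geometric draws per band.
.sterility_onset_month <- function(hazard) {
  for (band in seq_len(7)) {
    h <- hazard[band]
    if (h > 0) {
      g <- stats::rgeom(1, h)
      if (g < 60) return(180L + (band - 1L) * 60L + g)
    }
  }
  Inf
}

# Simulate one woman's reproductive history up to woman-age month `A`
# (RNG stream must already be seeded by the caller).
.simulate_woman <- function(A, cfg) {
  mage <- sample(15:35, 1, prob = cfg$marriage_age_distribution)
  M <- mage * 12L + sample(0:11, 1)
  desired <- sample(0:12, 1, prob = cfg$desired_parity_distribution)
  contraceptor <- stats::runif(1) < cfg$contraceptive_prevalence
  ster <- .sterility_onset_month(cfg$sterility_onset_hazard)

  births <- integer(0)
  pregnant <- FALSE
  if (M <= A) {
    t <- max(M, 180L)
    lim <- min(A, ster)
    repeat {
      if (t >= lim) break
      using <- contraceptor && length(births) >= desired
      p <- cfg$monthly_fecundability * cfg$spousal_absence_factor *
        (1 - cfg$contraceptive_effectiveness * using)
      if (p <= 0) break
      conc <- t + stats::rgeom(1, p)
      if (conc >= lim) break
      due <- conc + cfg$gestation_months
      if (due > A) {
        pregnant <- TRUE
        break
      }
      births <- c(births, due)
      t <- due + cfg$postpartum_infecundable_months
    }
  }
  list(births = births, pregnant = pregnant, married = M <= A)
}

#' Simulate a cross-sectional survey of reproductive histories
#'
#' Runs the monthly-step microsimulation for `cohort_size` women and emits
#' one record per woman as observed at a single census instant. Each woman's
#' age at interview is drawn uniformly over the survey age range (the
#' cross-section of a stationary population with constant annual cohorts);
#' her history is then simulated forward from exact age 15 under
#' time-invariant rates, so the sample approximates the stable state. All
#' women aged 15--49 are emitted, with `currently_married` flagging exposure;
#' interval tabulation restricts to married women downstream while fertility
#' rates use all women. Never-pregnant nulliparous women are identifiable as
#' `parity == 0 & !currently_pregnant`, so both first-interval denominators
#' can be formed.
#'
#' Determinism: per-woman random streams are derived from the master seed by
#' counter, so the same seed gives byte-identical output and enlarging the
#' cohort extends, rather than reshuffles, the sample.
#'
#' @param config a [simulation_config()].
#' @param interview_cmc census date as a CMC month (default 1453 = Jan 2021).
#' @return a `woman_survey` data frame with the schema columns plus
#'   `woman_dob_cmc` and `birth_cmcs` (semicolon-separated CMC list of all
#'   births, oldest first).
#' @export
simulate_survey <- function(config, interview_cmc = 1453L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$cohort_size
  a_lo <- config$survey_age_range[1] * 12L
  a_hi <- config$survey_age_range[2] * 12L + 11L

  set.seed(config$seed)
  woman_seeds <- sample.int(.Machine$integer.max, n, replace = TRUE)

  age_years <- integer(n)
  parity <- integer(n)
  last_birth <- rep(NA_integer_, n)
  pregnant <- logical(n)
  married <- logical(n)
  dob <- integer(n)
  birth_lists <- character(n)

  for (i in seq_len(n)) {
    set.seed(woman_seeds[i])
    A <- sample(a_lo:a_hi, 1)
    w <- .simulate_woman(A, config)
    dob[i] <- interview_cmc - A
    age_years[i] <- A %/% 12L
    parity[i] <- length(w$births)
    if (parity[i] > 0) {
      last_birth[i] <- dob[i] + w$births[parity[i]]
      birth_lists[i] <- paste(dob[i] + w$births, collapse = ";")
    }
    pregnant[i] <- w$pregnant
    married[i] <- w$married
  }

  out <- data.frame(woman_id = sprintf("w%06d", seq_len(n)),
                    interview_cmc = as.integer(interview_cmc),
                    age_years = age_years,
                    parity = parity,
                    last_birth_cmc = last_birth,
                    currently_pregnant = pregnant,
                    currently_married = married,
                    woman_dob_cmc = dob,
                    birth_cmcs = birth_lists,
                    stringsAsFactors = FALSE)
  as_woman_survey(out)
}

#' Sample a survey-sized open-interval distribution from the power model
#'
#' Draws `n` women across interval years 1..20 as one multinomial sample with
#' cell probabilities proportional to `x^(-b)`. The level parameter `a` does
#' not affect the cell probabilities (the distribution is normalised to
#' 100%); it is carried in the label so that fit-recovery exercises can state
#' the generating parameters.
#'
#' @param a level parameter of the generating curve (> 0, proportion units).
#' @param b slope magnitude of the generating curve (> 0).
#' @param n number of women (>= 1).
#' @param seed integer seed.
#' @return an `open_interval_distribution` (see [tabulate_distribution()]).
#' @export
sample_power_law_survey <- function(a, b, n, seed = 1L) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= 0) {
    stop("domain error: a must be positive")
  }
  if (!is.numeric(b) || length(b) != 1 || is.na(b) || b < 0) {
    stop("domain error: b must be non-negative")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("domain error: n must be >= 1")
  }
  set.seed(seed)
  x <- 1:20
  p <- x^(-b)
  counts <- as.integer(stats::rmultinom(1, size = n, prob = p / sum(p)))
  new_open_interval_distribution(
    counts, label = sprintf("power(a=%g, b=%g) n=%d", a, b, as.integer(n)))
}

#' Backward and forward recurrence times from a simulated renewal process
#'
#' Event-driven simulation of a stationary renewal process: closed birth
#' intervals are drawn from `closed_interval_sampler`, the event times
#' accumulated, and `n` inspection times placed uniformly at random in the
#' window following a burn-in of `burn_in_events` events. For each inspection
#' time the backward recurrence time (time since the last event -- the open
#' interval) and the forward recurrence time (time to the next event) are
#' returned. Used as the simulation arm of the renewal-identity checks
#' against the analytic form S(t)/mu.
#'
#' @param closed_interval_sampler function of one argument `n` returning `n`
#'   positive finite durations in months.
#' @param n number of (backward, forward) pairs.
#' @param burn_in_events events discarded before inspection (>= 50).
#' @param seed integer seed.
#' @return data frame with numeric columns `backward` and `forward`.
#' @export
sample_stationary_renewal <- function(closed_interval_sampler, n,
                                      burn_in_events = 200L, seed = 1L) {
  stopifnot(is.function(closed_interval_sampler), n >= 1)
  if (burn_in_events < 50) {
    stop("burn_in_events must be >= 50")
  }
  set.seed(seed)
  k <- as.integer(burn_in_events + n)
  d <- closed_interval_sampler(k)
  if (length(d) != k || any(!is.finite(d)) || any(d <= 0)) {
    stop("domain error: closed-interval sampler must return positive ",
         "finite durations")
  }
  times <- cumsum(d)
  t0 <- times[burn_in_events]
  tt <- sort(stats::runif(n, min = t0, max = times[k]))
  idx <- findInterval(tt, times)
  data.frame(backward = tt - times[idx], forward = times[idx + 1L] - tt)
}
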