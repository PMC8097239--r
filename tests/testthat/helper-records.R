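# Builders for small hand-crafted woman_survey fixtures. All arguments are
# recycled to the longest length; `m` is months since last birth (NA for no
# birth), translated into last_birth_cmc relative to a fixed interview date.
make_records <- function(m = NA, parity = 1L, age = 30L, pregnant = FALSE,
                         married = TRUE, interview = 1200L) {
  n <- max(lengths(list(m, parity, age, pregnant, married)))
  m <- rep_len(m, n)
  parity <- rep_len(as.integer(parity), n)
  df <- data.frame(
    woman_id = sprintf("t%03d", seq_len(n)),
    interview_cmc = rep_len(as.integer(interview), n),
    age_years = rep_len(as.integer(age), n),
    parity = parity,
    last_birth_cmc = ifelse(is.na(m) | parity == 0, NA_integer_,
                            as.integer(interview - m)),
    currently_pregnant = rep_len(pregnant, n),
    currently_married = rep_len(married, n),
    stringsAsFactors = FALSE)
  as_woman_survey(df)
}

# Deterministic multinomial-free distribution object from percentages.
make_distribution <- function(percentages, n = 10000L) {
  counts <- round(percentages / sum(percentages) * n)
  openinterval:::new_open_interval_distribution(counts)
}

# One simulated survey per helper call is expensive; cache the presets used
# across test files within a session.
.sim_cache <- new.env(parent = emptyenv())
cached_survey <- function(preset, n = 4000L, seed = 11L) {
  key <- paste(preset, n, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_survey(
      regime_preset(preset, cohort_size = n, seed = seed))
  }
  .sim_cache[[key]]
}
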