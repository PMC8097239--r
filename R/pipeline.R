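# Orchestration: simulate -> tabulate -> fit -> panel, with tidy CSV outputs
# and a run manifest (config snapshot, stage timings, output checksums) so a
# run can be reproduced and verified. These functions are the programmatic
# entry points; scripts/ wraps them for shell use.

.write_tidy <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Tidy data frame from an open-interval distribution
#'
#' @param dist an `open_interval_distribution`.
#' @return data frame with columns `interval_year`, `count`, `percentage`.
#' @export
distribution_to_df <- function(dist) {
  data.frame(interval_year = 1:20, count = dist$counts,
             percentage = dist$percentages)
}

#' Tidy data frame from an interval composition
#'
#' @param comp an `interval_composition`.
#' @return long data frame with columns `interval_year`, `category`,
#'   `share_pct`, `mean_value`.
#' @export
composition_to_df <- function(comp) {
  cats <- rownames(comp$shares)
  data.frame(interval_year = rep(1:20, each = length(cats)),
             category = rep(cats, times = 20),
             share_pct = as.vector(comp$shares),
             mean_value = rep(comp$mean_by_interval, each = length(cats)))
}

.manifest <- function(stages, files, seed = NA_integer_) {
  checks <- if (length(files) > 0) {
    data.frame(file = basename(unlist(files)),
               md5 = unname(tools::md5sum(unlist(files))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(file = character(0), md5 = character(0))
  }
  list(package_version = as.character(utils::packageVersion("openinterval")),
       seed = seed,
       stage_seconds = stages,
       outputs = checks)
}

#' Run the full survey-level analysis
#'
#' From microdata (a `woman_survey` data frame or a CSV path) produces the
#' open-interval distribution, the age and parity compositions by interval,
#' the parity-within-age table, and the four-model comparison, optionally
#' writing each as a tidy CSV under `out_dir`. A manifest records the stage
#' timings and MD5 checksums of every file written; deterministic inputs
#' reproduce identical checksums.
#'
#' @param survey a `woman_survey` data frame or path to a survey CSV.
#' @param out_dir optional output directory (created if needed).
#' @param label label attached to the distribution.
#' @return a `survey_analysis` list: `distribution`, `composition_age`,
#'   `composition_parity`, `age_parity`, `model_comparison`,
#'   `mean_open_interval`, `manifest`.
#' @export
run_survey_analysis <- function(survey, out_dir = NULL, label = "survey") {
  stages <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  records <- tick("read", {
    if (is.character(survey)) read_survey_csv(survey) else
      as_woman_survey(as.data.frame(survey))
  })
  dist <- tick("tabulate", tabulate_distribution(records, label = label))
  comp_age <- tick("composition_age", composition_by_interval(records, "age"))
  comp_par <- tick("composition_parity",
                   composition_by_interval(records, "parity"))
  apt <- tick("age_parity", age_parity_table(records))
  fits <- tick("fit", compare_models(dist))

  files <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files$dist <- .write_tidy(distribution_to_df(dist),
                              file.path(out_dir, "distribution.csv"))
    files$age <- .write_tidy(composition_to_df(comp_age),
                             file.path(out_dir, "composition_age.csv"))
    files$parity <- .write_tidy(composition_to_df(comp_par),
                                file.path(out_dir, "composition_parity.csv"))
    files$fits <- .write_tidy(as.data.frame(fits),
                              file.path(out_dir, "model_comparison.csv"))
  }
  structure(list(distribution = dist,
                 composition_age = comp_age,
                 composition_parity = comp_par,
                 age_parity = apt,
                 model_comparison = fits,
                 mean_open_interval = mean_open_interval(records),
                 manifest = .manifest(stages, files)),
            class = "survey_analysis")
}

#' Run the panel-level analysis
#'
#' Computes the parameter--fertility correlations over a country panel (the
#' packaged 75-survey panel by default), and, when the panel carries mean
#' open intervals or repeated surveys per country, the fertility-vs-interval
#' correlations and per-country trend slopes.
#'
#' @param panel a `country_panel` data frame; `NULL` loads the packaged one.
#' @param surveys optional repeat-survey data frame for
#'   [repeat_survey_trends()].
#' @param out_dir optional output directory for tidy CSVs.
#' @return a `panel_analysis` list: `correlations`, optionally
#'   `fertility_vs_interval` and `trends`, and `manifest`.
#' @export
run_panel_analysis <- function(panel = NULL, surveys = NULL, out_dir = NULL) {
  stages <- c()
  t0 <- proc.time()[["elapsed"]]
  if (is.null(panel)) panel <- load_country_panel()
  correlations <- panel_correlations(panel)
  stages[["correlations"]] <- round(proc.time()[["elapsed"]] - t0, 3)

  fvi <- NULL
  if ("mean_open_interval" %in% names(panel)) {
    fvi <- fertility_vs_interval(panel)
  }
  trends <- NULL
  if (!is.null(surveys)) {
    trends <- repeat_survey_trends(surveys)
  }
  files <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files$corr <- .write_tidy(as.data.frame(correlations),
                              file.path(out_dir, "panel_correlations.csv"))
    if (!is.null(trends)) {
      files$trends <- .write_tidy(trends$trends,
                                  file.path(out_dir, "trends.csv"))
    }
  }
  structure(list(correlations = correlations,
                 fertility_vs_interval = fvi,
                 trends = trends,
                 manifest = .manifest(stages, files)),
            class = "panel_analysis")
}
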