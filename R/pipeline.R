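#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end analysis so a run is fully
#' reproducible from its manifest: exclusion-rule bounds, chronotype and
#' nap cut-offs, the minimum number of complete weeks for MSFsc, analysis
#' toggles and the seed used by the random-forest stage.
#'
#' @param min_sleep_h,max_sleep_h,age_range,bmi_range,min_nights,per_night
#'   Exclusion rules, see [apply_exclusions()].
#' @param cutoffs Chronotype cut-offs (clock hours), see
#'   [classify_chronotype()].
#' @param nap_long_cutoff Nap-group cut-off (minutes).
#' @param min_weeks Complete weeks required for MSFsc.
#' @param require_age_for_msfsc Drop MSFsc/chronotype for subjects with
#'   missing age (the chronotype cohort requires age; default `TRUE`).
#' @param correlations,tests,regressions,importance Analysis toggles.
#' @param seed Seed for the random-forest stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_sleep_h = 3, max_sleep_h = 13,
                       age_range = c(10, 90), bmi_range = c(10, 50),
                       min_nights = 7, per_night = FALSE,
                       cutoffs = c(3, 5), nap_long_cutoff = 30,
                       min_weeks = 2, require_age_for_msfsc = TRUE,
                       correlations = TRUE, tests = TRUE,
                       regressions = TRUE, importance = TRUE,
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full chronotype and social-jetlag analysis
#'
#' The end-to-end pipeline: exclusion filters ([apply_exclusions()]),
#' per-subject chronobiology statistics ([chrono_summary()]), then the
#' cohort-level analyses — report tables ([summarize_cohort()]),
#' correlations, sex-difference t tests, SJL regressions and random-forest
#' feature importance for both SJL and MSFsc. Given the same inputs and
#' config the result is deterministic.
#'
#' @param records Validated records tibble ([read_sleep_records()] or
#'   [simulate_cohort()]`$records`).
#' @param subjects Subject tibble.
#' @param config A [run_config()].
#' @return A list of class `cohort_analysis`: `summaries` (per-subject
#'   table, joined with subject metadata), `report`
#'   ([summarize_cohort()]), `exclusions` (ledger), `correlations`,
#'   `sex_tests`, `regressions`, `importance` (list with `sjl` and `msfsc`
#'   [feature_importance()] fits), and `manifest`.
#' @examples
#' sim <- simulate_cohort(n_subjects = 60, n_weeks = 2, seed = 3)
#' res <- analyze_cohort(sim$records, sim$subjects,
#'                       config = run_config(importance = FALSE))
#' res$report
#' @export
analyze_cohort <- function(records, subjects, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  need <- c("subject_id", "anchor_date", "onset_axis", "wake_axis",
            "waso_min", "nap_min", "night_type")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records table lacks columns: ",
         paste(missing_cols, collapse = ", "),
         " (run read_sleep_records()/validate_records() first)")
  }

  coh <- apply_exclusions(
    records, subjects,
    min_sleep_h = config$min_sleep_h, max_sleep_h = config$max_sleep_h,
    age_range = config$age_range, bmi_range = config$bmi_range,
    min_nights = config$min_nights, per_night = config$per_night
  )

  summaries <- chrono_summary(
    coh$records, min_weeks = config$min_weeks, cutoffs = config$cutoffs,
    long_cutoff = config$nap_long_cutoff
  )
  summaries <- join_cohort(summaries, coh$subjects)
  if (config$require_age_for_msfsc) {
    no_age <- is.na(summaries$age_years)
    summaries$msfsc_h[no_age] <- NA_real_
    summaries$chronotype[no_age] <- NA
  }

  report <- if (nrow(summaries)) summarize_cohort(summaries) else NULL
  correlations <- if (config$correlations && nrow(summaries)) {
    cohort_correlations(summaries)
  }
  sex_tests <- if (config$tests && nrow(summaries)) {
    sjl_sex_tests(summaries)
  }
  regressions <- if (config$regressions && nrow(summaries)) {
    tryCatch(sjl_regressions(summaries), error = function(e) NULL)
  }
  imp <- if (config$importance && nrow(summaries)) {
    list(
      sjl = tryCatch(
        feature_importance(summaries, target = "sjl", seed = config$seed),
        error = function(e) NULL
      ),
      msfsc = tryCatch(
        feature_importance(summaries, target = "msfsc", seed = config$seed),
        error = function(e) NULL
      )
    )
  }

  manifest <- list(
    config = serialize_config(config),
    n_input_subjects = length(unique(subjects$subject_id)),
    n_retained_subjects = nrow(coh$subjects),
    n_records = nrow(coh$records),
    n_sjl = sum(!is.na(summaries$sjl_h)),
    n_chronotyped = sum(!is.na(summaries$msfsc_h)),
    seed = config$seed
  )

  structure(
    list(
      summaries = summaries, report = report, exclusions = coh$ledger,
      correlations = correlations, sex_tests = sex_tests,
      regressions = regressions, importance = imp, manifest = manifest
    ),
    class = "cohort_analysis"
  )
}

serialize_config <- function(config) {
  lapply(unclass(config), function(x) if (inherits(x, "Date")) format(x) else x)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat("  retained subjects:", x$manifest$n_retained_subjects,
      "of", x$manifest$n_input_subjects, "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
glance.cohort_analysis <- function(x, ...) {
  if (is.null(x$report)) {
    return(tibble::tibble(n_subjects = 0L))
  }
  glance(x$report)
}

#' Write a cohort analysis to a report directory
#'
#' Serialises every table of a [analyze_cohort()] result as CSV plus one
#' JSON manifest mapping table names to files and recording the full run
#' configuration, cohort sizes and seed.
#'
#' @param analysis A `cohort_analysis` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    chrono_summary = analysis$summaries,
    exclusion_ledger = analysis$exclusions,
    correlations = analysis$correlations,
    sex_tests = analysis$sex_tests,
    regressions = analysis$regressions
  )
  if (!is.null(analysis$report)) {
    rep <- analysis$report
    tables <- c(tables, list(
      report_counts = rep$counts, report_sjl = rep$sjl,
      report_chronotype = rep$chronotype, report_neg_sjl = rep$neg_sjl,
      report_by_nap_group = rep$by_nap_group, report_by_sex = rep$by_sex,
      report_hist_sjl = rep$hist_sjl, report_hist_msfsc = rep$hist_msfsc
    ))
  }
  for (nm in c("sjl", "msfsc")) {
    fit <- analysis$importance[[nm]]
    if (!is.null(fit)) {
      tables[[paste0("importance_", nm)]] <- dplyr::bind_cols(
        glance(fit)[rep(1, nrow(tidy(fit))), c("trees", "depth", "cv_r2")],
        tidy(fit)
      )
    }
  }
  tables <- tables[!vapply(tables, is.null, logical(1))]
  files <- vapply(names(tables), function(nm) {
    f <- paste0(nm, ".csv")
    readr::write_csv(tables[[nm]], file.path(dir, f), na = "")
    f
  }, character(1))
  manifest <- c(
    analysis$manifest,
    list(tables = as.list(files), n_tables = length(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
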