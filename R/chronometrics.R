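#' Sleep-debt-corrected mid-sleep on free days (weekly formula)
#'
#' The chronotype statistic: mid-sleep on free days corrected for the sleep
#' debt accumulated on work days,
#' \deqn{MSF_{sc} = MSF - 0.5\,[SD_f - (5\,SD_w + 2\,SD_f)/7]}
#' where \eqn{SD_w} and \eqn{SD_f} are the mean nocturnal sleep durations on
#' the week's work and free nights. The correction is applied
#' unconditionally, also when \eqn{SD_f < SD_w} (then \eqn{MSF_{sc} > MSF});
#' when \eqn{SD_f = SD_w} the bracket vanishes and \eqn{MSF_{sc} = MSF}
#' identically.
#'
#' @param msf Mean mid-sleep on the week's free nights (hours; clock hours
#'   or night-axis hours — the correction is a pure offset).
#' @param sdf,sdw Mean nocturnal sleep duration (hours) on free and work
#'   nights of the week.
#' @return `msf - 0.5 * (sdf - (5 * sdw + 2 * sdf) / 7)`, vectorised.
#' @examples
#' msfsc_week(msf = 4.5, sdf = 9, sdw = 7) # 3.7857
#' msfsc_week(msf = 4.1, sdf = 6.5, sdw = 6.5) # = msf
#' @export
msfsc_week <- function(msf, sdf, sdw) {
  msf - 0.5 * (sdf - (5 * sdw + 2 * sdf) / 7)
}

#' Per-subject MSFsc from weekly values
#'
#' A subject's chronotype statistic is the arithmetic mean of the weekly
#' MSFsc values over their complete recording weeks; subjects with fewer
#' than `min_weeks` complete weeks have no MSFsc.
#'
#' @param weekly Numeric vector of weekly MSFsc values (night-axis or clock
#'   hours, consistently).
#' @param min_weeks Minimum number of complete weeks required (default 2).
#' @return The mean, or `NA_real_` when fewer than `min_weeks` values.
#' @export
msfsc_subject <- function(weekly, min_weeks = 2) {
  weekly <- weekly[!is.na(weekly)]
  if (length(weekly) < min_weeks) return(NA_real_)
  mean(weekly)
}

#' Classify chronotype from MSFsc
#'
#' Arbitrary cut-offs on MSFsc clock hours: early below `cutoffs[1]`
#' (default 3:00 am), late above `cutoffs[2]` (default 5:00 am),
#' intermediate in the closed interval between them (boundary values fall
#' to intermediate because the early/late inequalities are strict).
#'
#' @param msfsc Numeric vector of MSFsc values, clock hours in `[0, 24)`.
#' @param cutoffs Length-2 numeric, early/intermediate and
#'   intermediate/late boundaries in clock hours.
#' @return Factor with levels `early`, `intermediate`, `late` (`NA` kept).
#' @examples
#' classify_chronotype(c(2.9, 3.0, 5.0, 5.2))
#' @export
classify_chronotype <- function(msfsc, cutoffs = c(3, 5)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  out <- ifelse(
    is.na(msfsc), NA_character_,
    ifelse(msfsc < cutoffs[1], "early",
           ifelse(msfsc > cutoffs[2], "late", "intermediate"))
  )
  factor(out, levels = c("early", "intermediate", "late"))
}

#' Classify nap subgroup from mean daily nap duration
#'
#' `zero` for a mean of exactly 0 minutes, `long` for a mean strictly above
#' `long_cutoff` (default 30) minutes, `short` otherwise.
#'
#' @param mean_nap_min Numeric vector of mean daily nap minutes, `>= 0`.
#' @param long_cutoff Boundary (minutes) between short and long naps; the
#'   boundary value itself is `short` because `long` is a strict inequality.
#' @return Factor with levels `zero`, `short`, `long`.
#' @examples
#' classify_nap_group(c(0, 12, 30, 45))
#' @export
classify_nap_group <- function(mean_nap_min, long_cutoff = 30) {
  stopifnot(all(mean_nap_min >= 0, na.rm = TRUE))
  out <- ifelse(
    is.na(mean_nap_min), NA_character_,
    ifelse(mean_nap_min == 0, "zero",
           ifelse(mean_nap_min > long_cutoff, "long", "short"))
  )
  factor(out, levels = c("zero", "short", "long"))
}

#' Per-subject chronobiology summary
#'
#' Computes, for every subject in a validated records tibble, the full set
#' of per-subject statistics:
#'
#' * `msw`, `msf` — mean mid-sleep point (clock hours after midnight) on
#'   work and free nights, averaged on the noon-anchored night axis where
#'   linear means are exact;
#' * `sdw_h`, `sdf_h` — mean nocturnal sleep duration (hours, WASO removed)
#'   on work (Sunday-Thursday) and free (Friday-Saturday) nights;
#' * `sjl_h` — signed social jetlag, `MSF - MSW` on the night axis; negative
#'   when free-night mid-sleep is earlier than work-night mid-sleep;
#' * `msfsc_h` — mean over complete Sunday-anchored weeks of the weekly
#'   sleep-debt-corrected mid-sleep ([msfsc_week()]); `NA` when the subject
#'   has fewer than `min_weeks` complete weeks;
#' * `chronotype`, `nap_group` — classifications ([classify_chronotype()],
#'   [classify_nap_group()]);
#' * `mean_nap_min`, `mean_sleep_min`, `mean_steps`, and mean total
#'   (nocturnal + nap) sleep minutes by day type.
#'
#' Subjects lacking either work or free nights get `NA` for `msw`/`msf`/
#' `sjl_h` and are flagged `complete = FALSE`; they are left out of SJL
#' tables downstream.
#'
#' @param records Validated records tibble ([read_sleep_records()]),
#'   normally after [apply_exclusions()].
#' @param min_weeks Complete weeks required for MSFsc (default 2).
#' @param cutoffs Chronotype cut-offs, passed to [classify_chronotype()].
#' @param long_cutoff Nap cut-off, passed to [classify_nap_group()].
#' @return A tibble with one row per subject.
#' @examples
#' sim <- simulate_cohort(n_subjects = 10, n_weeks = 2, seed = 1)
#' chrono_summary(sim$records)
#' @export
chrono_summary <- function(records, min_weeks = 2, cutoffs = c(3, 5),
                           long_cutoff = 30) {
  records <- tibble::as_tibble(records)
  records$mid_axis <- (records$onset_axis + records$wake_axis) / 2
  records$noct_min <- nocturnal_minutes(records)
  records$is_free <- records$night_type == "free"

  base <- dplyr::summarise(
    dplyr::group_by(records, .data$subject_id),
    n_nights = dplyr::n(),
    msw_axis = mean(.data$mid_axis[!.data$is_free]),
    msf_axis = mean(.data$mid_axis[.data$is_free]),
    sdw_h = mean(.data$noct_min[!.data$is_free]) / 60,
    sdf_h = mean(.data$noct_min[.data$is_free]) / 60,
    mean_nap_min = mean(.data$nap_min),
    mean_sleep_min = mean(.data$noct_min),
    mean_steps = if (all(is.na(.data$steps))) NA_real_
                 else mean(.data$steps, na.rm = TRUE),
    .groups = "drop"
  )

  wk <- complete_weeks(records)
  weekly <- dplyr::summarise(
    dplyr::group_by(wk, .data$subject_id, .data$week_start),
    msf_axis = mean(.data$mid_axis[.data$is_free]),
    sdf = mean(.data$noct_min[.data$is_free]) / 60,
    sdw = mean(.data$noct_min[!.data$is_free]) / 60,
    .groups = "drop"
  )
  weekly$msfsc_axis <- msfsc_week(weekly$msf_axis, weekly$sdf, weekly$sdw)
  per_subj_msfsc <- dplyr::summarise(
    dplyr::group_by(weekly, .data$subject_id),
    n_weeks = dplyr::n(),
    msfsc_axis = msfsc_subject(.data$msfsc_axis, min_weeks = min_weeks),
    .groups = "drop"
  )

  out <- dplyr::left_join(base, per_subj_msfsc, by = "subject_id")
  out$n_weeks[is.na(out$n_weeks)] <- 0L
  out <- dplyr::mutate(
    out,
    msw = axis_to_clock(.data$msw_axis),
    msf = axis_to_clock(.data$msf_axis),
    sjl_h = .data$msf_axis - .data$msw_axis,
    msfsc_h = axis_to_clock(.data$msfsc_axis),
    chronotype = classify_chronotype(axis_to_clock(.data$msfsc_axis),
                                     cutoffs = cutoffs),
    nap_group = classify_nap_group(.data$mean_nap_min,
                                   long_cutoff = long_cutoff),
    total_sleep_work_min = .data$sdw_h * 60 + .data$mean_nap_min,
    total_sleep_free_min = .data$sdf_h * 60 + .data$mean_nap_min,
    complete = !is.na(.data$msw_axis) & !is.na(.data$msf_axis)
  )
  dplyr::select(
    out, "subject_id", "n_nights", "n_weeks", "msw", "msf",
    "sdw_h", "sdf_h", "sjl_h", "msfsc_h", "chronotype", "nap_group",
    "mean_nap_min", "mean_sleep_min", "mean_steps",
    "total_sleep_work_min", "total_sleep_free_min", "complete"
  )
}

#' Write a chronobiology summary table to CSV
#'
#' Hours columns are printed with 4 decimals; the layout matches the
#' documented ChronoSummary dialect.
#'
#' @param summaries Tibble from [chrono_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chrono_summary <- function(summaries, path) {
  out <- dplyr::mutate(summaries, dplyr::across(
    c("msw", "msf", "sdw_h", "sdf_h", "sjl_h", "msfsc_h"),
    ~ round(.x, 4)
  ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
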