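#' Apply cohort exclusion rules
#'
#' Removes subjects that fail the standard screening rules for wearable
#' sleep cohorts:
#'
#' * mean nocturnal sleep duration (time in bed minus WASO, averaged over
#'   all recorded nights) below `min_sleep_h` or above `max_sleep_h`;
#' * age outside `age_range` or BMI outside `bmi_range`, when present
#'   (missing age or BMI does not exclude a subject here — the minimum-weeks
#'   and age requirements of the chronotype cohort are enforced downstream
#'   by [chrono_summary()]);
#' * fewer than `min_nights` consecutive recorded nights.
#'
#' With `per_night = TRUE` the sleep-duration rule is instead applied to
#' each night (nights outside the band are dropped before the subject-level
#' rules run).
#'
#' @param records Validated records tibble from [read_sleep_records()].
#' @param subjects Subject tibble from [read_subjects()].
#' @param min_sleep_h,max_sleep_h Bounds (hours) on nocturnal sleep duration.
#' @param age_range,bmi_range Inclusive bounds on age (years) and BMI
#'   (kg/m^2).
#' @param min_nights Minimum number of consecutive recorded nights.
#' @param per_night Apply the sleep-duration band per night instead of to
#'   the subject mean.
#' @return A list of class `cohort`: `records`, `subjects` (filtered), and
#'   `ledger` — a tibble (`rule`, `n_subjects_removed`) counting removals
#'   per rule, with a final `any` row giving distinct subjects removed
#'   (rules can overlap).
#' @examples
#' sim <- simulate_cohort(n_subjects = 20, n_weeks = 2, seed = 1)
#' coh <- apply_exclusions(sim$records, sim$subjects)
#' coh$ledger
#' @export
apply_exclusions <- function(records, subjects,
                             min_sleep_h = 3, max_sleep_h = 13,
                             age_range = c(10, 90), bmi_range = c(10, 50),
                             min_nights = 7, per_night = FALSE) {
  records <- tibble::as_tibble(records)
  subjects <- tibble::as_tibble(subjects)

  records$noct_min <- nocturnal_minutes(records)
  if (per_night) {
    keep <- records$noct_min / 60 >= min_sleep_h &
      records$noct_min / 60 <= max_sleep_h
    records <- records[keep, ]
  }

  per_subj <- dplyr::summarise(
    dplyr::group_by(records, .data$subject_id),
    mean_sleep_h = mean(.data$noct_min) / 60,
    max_run = longest_consecutive_run(.data$anchor_date),
    .groups = "drop"
  )
  info <- dplyr::left_join(subjects, per_subj, by = "subject_id")
  info$mean_sleep_h[is.na(info$mean_sleep_h)] <- 0
  info$max_run[is.na(info$max_run)] <- 0

  viol <- tibble::tibble(
    `sleep<3h` = !per_night & info$mean_sleep_h < min_sleep_h,
    `sleep>13h` = !per_night & info$mean_sleep_h > max_sleep_h,
    `age<10` = !is.na(info$age_years) & info$age_years < age_range[1],
    `age>90` = !is.na(info$age_years) & info$age_years > age_range[2],
    `bmi<10` = !is.na(info$bmi) & info$bmi < bmi_range[1],
    `bmi>50` = !is.na(info$bmi) & info$bmi > bmi_range[2],
    `nights<7` = info$max_run < min_nights
  )
  names(viol)[1:2] <- c(
    sprintf("sleep<%gh", min_sleep_h), sprintf("sleep>%gh", max_sleep_h)
  )
  names(viol)[7] <- sprintf("nights<%d", min_nights)
  drop <- Reduce(`|`, viol)

  ledger <- tibble::tibble(
    rule = c(names(viol), "any"),
    n_subjects_removed = unname(c(vapply(viol, sum, integer(1)), sum(drop)))
  )

  kept <- info$subject_id[!drop]
  out_records <- records[records$subject_id %in% kept, ]
  out_records$noct_min <- NULL
  structure(
    list(
      records = out_records,
      subjects = subjects[subjects$subject_id %in% kept, ],
      ledger = ledger
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$records), " subject-nights\n", sep = "")
  removed <- x$ledger[x$ledger$n_subjects_removed > 0 &
                        x$ledger$rule != "any", ]
  if (nrow(removed)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(removed))) {
      cat("  ", removed$rule[i], ": ", removed$n_subjects_removed[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Nocturnal sleep duration in minutes
#'
#' Time in bed (wake minus onset on the night axis) minus wake after sleep
#' onset. WASO is removed from durations only; mid-sleep points always use
#' the raw onset and wake timestamps.
#'
#' @param records Validated records tibble.
#' @return Numeric vector of nocturnal sleep minutes, one per record.
#' @export
nocturnal_minutes <- function(records) {
  (records$wake_axis - records$onset_axis) * 60 - records$waso_min
}

longest_consecutive_run <- function(dates) {
  d <- sort(unique(as.integer(dates)))
  if (!length(d)) return(0L)
  gaps <- c(TRUE, diff(d) != 1L)
  runs <- rle(cumsum(gaps))$lengths
  max(runs)
}

#' Partition a subject's nights into complete Sunday-anchored weeks
#'
#' Groups nights by the Sunday starting their calendar week and keeps only
#' weeks in which all 7 nights are present — exactly 5 work nights
#' (Sunday-Thursday) and 2 free nights (Friday, Saturday). Weekly MSFsc is
#' computed on these blocks only.
#'
#' @param records Validated records tibble (one or more subjects).
#' @return The input restricted to nights in complete weeks, with an added
#'   `week_start` (`Date`) column identifying each block.
#' @examples
#' sim <- simulate_cohort(n_subjects = 3, n_weeks = 2, seed = 1)
#' nrow(complete_weeks(sim$records)) # 3 subjects x 14 nights
#' @export
complete_weeks <- function(records) {
  records <- tibble::as_tibble(records)
  records$week_start <- week_start(records$anchor_date)
  dplyr::ungroup(dplyr::filter(
    dplyr::group_by(records, .data$subject_id, .data$week_start),
    dplyr::n() == 7L
  ))
}
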