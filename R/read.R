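#' Read and validate nightly sleep records
#'
#' Reads a records CSV with columns `subject_id`, `anchor_date` (ISO 8601),
#' `onset` (HH:MM), `wake` (HH:MM), `waso_min`, `nap_min` and optionally
#' `steps`, normalises the clock times onto the noon-anchored night axis,
#' and validates every row. Row-level problems (malformed times, wake not
#' after onset on the night axis, WASO at least as long as time in bed,
#' nap minutes outside `[0, 720]`) are collected with their line numbers;
#' a duplicated `(subject_id, anchor_date)` pair is always a hard error
#' because the two rows cannot be reconciled.
#'
#' @param path Path to the records CSV.
#' @param strict If `TRUE` (default) any invalid row aborts with a
#'   line-numbered report; if `FALSE` invalid rows are dropped and returned
#'   in the `problems` attribute.
#' @return A tibble with one row per subject-night: `subject_id`,
#'   `anchor_date`, `onset_axis`, `wake_axis`, `waso_min`, `nap_min`,
#'   `steps`, and `night_type` (`work`/`free`). When `strict = FALSE` the
#'   attribute `problems` holds a tibble of rejected rows (`row`, `reason`).
#' @seealso [read_subjects()], [apply_exclusions()]
#' @export
read_sleep_records <- function(path, strict = TRUE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      anchor_date = readr::col_date(),
      onset = readr::col_character(),
      wake = readr::col_character(),
      waso_min = readr::col_double(),
      nap_min = readr::col_double(),
      steps = readr::col_double()
    ),
    progress = FALSE
  )
  validate_records(raw, strict = strict)
}

#' Validate an in-memory records table
#'
#' Same checks and output as [read_sleep_records()] for a data frame that is
#' already in the records-CSV layout (clock times as `HH:MM` strings).
#'
#' @param records Data frame with the records-CSV columns.
#' @inheritParams read_sleep_records
#' @return See [read_sleep_records()].
#' @export
validate_records <- function(records, strict = TRUE) {
  records <- tibble::as_tibble(records)
  if (!"steps" %in% names(records)) records$steps <- NA_real_
  need <- c("subject_id", "anchor_date", "onset", "wake", "waso_min", "nap_min")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(records$anchor_date, "Date")) {
    records$anchor_date <- as.Date(records$anchor_date)
  }

  dup <- duplicated(records[c("subject_id", "anchor_date")]) |
    duplicated(records[c("subject_id", "anchor_date")], fromLast = TRUE)
  if (any(dup)) {
    rows <- which(dup)
    stop(
      "duplicate (subject_id, anchor_date) pairs at rows ",
      paste(head(rows, 10), collapse = ", "),
      if (length(rows) > 10) " ..." else ""
    )
  }

  onset_clock <- parse_clock(records$onset)
  wake_clock <- parse_clock(records$wake)
  onset_axis <- clock_to_axis(onset_clock)
  wake_axis <- clock_to_axis(wake_clock)
  tib_min <- (wake_axis - onset_axis) * 60

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(records$anchor_date), "unparseable anchor_date")
  reason <- flag(is.na(onset_clock), "malformed onset time")
  reason <- flag(is.na(wake_clock), "malformed wake time")
  reason <- flag(
    !is.na(onset_axis) & !is.na(wake_axis) &
      (wake_axis <= onset_axis | onset_axis <= 0),
    "wake not after onset on the night axis"
  )
  reason <- flag(
    is.na(records$waso_min) | records$waso_min < 0 |
      (!is.na(tib_min) & records$waso_min >= tib_min),
    "waso_min invalid or >= time in bed"
  )
  reason <- flag(
    is.na(records$nap_min) | records$nap_min < 0 | records$nap_min > 720,
    "nap_min outside [0, 720]"
  )
  reason <- flag(!is.na(records$steps) & records$steps < 0, "negative steps")

  bad <- !is.na(reason)
  if (any(bad) && strict) {
    msg <- paste0("  row ", which(bad), ": ", reason[bad])
    stop(
      "invalid records (", sum(bad), " rows):\n",
      paste(head(msg, 20), collapse = "\n"),
      if (sum(bad) > 20) "\n  ..." else ""
    )
  }

  out <- tibble::tibble(
    subject_id = records$subject_id,
    anchor_date = records$anchor_date,
    onset_axis = onset_axis,
    wake_axis = wake_axis,
    waso_min = records$waso_min,
    nap_min = records$nap_min,
    steps = records$steps
  )[!bad, ]
  out$night_type <- classify_night(out$anchor_date)
  attr(out, "problems") <- tibble::tibble(
    row = which(bad),
    reason = reason[bad]
  )
  out
}

#' Read and validate the subject table
#'
#' Reads a subjects CSV with columns `subject_id`, `age_years`, `sex`
#' (`male`/`female`/`unknown`) and `bmi`. Missing age, sex or BMI are kept
#' as `NA`; validity bounds are enforced later by [apply_exclusions()].
#'
#' @param path Path to the subjects CSV.
#' @return A tibble: `subject_id`, `age_years`, `sex` (factor), `bmi`.
#' @export
read_subjects <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      age_years = readr::col_double(),
      sex = readr::col_character(),
      bmi = readr::col_double()
    ),
    progress = FALSE
  )
  dup <- duplicated(raw$subject_id)
  if (any(dup)) {
    stop("duplicate subject_id in subjects table: ",
         paste(unique(raw$subject_id[dup]), collapse = ", "))
  }
  sex <- tolower(trimws(raw$sex))
  sex[is.na(sex) | !sex %in% c("male", "female")] <- "unknown"
  tibble::tibble(
    subject_id = raw$subject_id,
    age_years = raw$age_years,
    sex = factor(sex, levels = c("male", "female", "unknown")),
    bmi = raw$bmi
  )
}
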