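# Shared fixtures: small deterministic record tables in the raw CSV dialect.
# 2017-04-02 is a Sunday, so nights 2017-04-02 .. 2017-04-08 form one
# complete Sunday-anchored week (5 work + 2 free nights).

make_raw_records <- function(subject_id = "S1",
                             start = as.Date("2017-04-02"),
                             n_nights = 14,
                             onset = "00:15", wake = "07:00",
                             onset_free = onset, wake_free = wake,
                             waso = 0, nap = 0, steps = 8000) {
  dates <- start + 0:(n_nights - 1)
  free <- as.integer(format(dates, "%w")) %in% c(5L, 6L)
  tibble::tibble(
    subject_id = subject_id,
    anchor_date = dates,
    onset = ifelse(free, onset_free, onset),
    wake = ifelse(free, wake_free, wake),
    waso_min = waso,
    nap_min = nap,
    steps = steps
  )
}

make_subjects <- function(ids, age = 30, sex = "male", bmi = 23) {
  tibble::tibble(
    subject_id = ids,
    age_years = rep_len(age, length(ids)),
    sex = factor(rep_len(sex, length(ids)),
                 levels = c("male", "female", "unknown")),
    bmi = rep_len(bmi, length(ids))
  )
}

# Shift an HH:MM string by a whole number of hours (wrapping at 24).
shift_clock <- function(x, dh) {
  h <- (as.integer(sub(":.*", "", x)) + dh) %% 24
  sprintf("%02d:%s", h, sub(".*:", "", x))
}
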