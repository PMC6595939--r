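test_that("records parse onto the night axis per the documented dialect", {
  raw <- tibble::tibble(
    subject_id = c("S1", "S1"),
    anchor_date = as.Date(c("2017-04-03", "2017-04-04")),
    onset = c("00:15", "23:30"),
    wake = c("07:00", "07:17"),
    waso_min = c(12, 0), nap_min = c(35, 0), steps = c(8000, NA)
  )
  rec <- validate_records(raw)
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$onset_axis, c(12.25, 11.5))
  expect_equal(rec$wake_axis, c(19, 19 + 17 / 60))
  expect_equal(as.character(rec$night_type), c("work", "work"))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path, na = "")
  rec2 <- read_sleep_records(path)
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("duplicate (subject, anchor_date) is a hard error naming rows", {
  raw <- make_raw_records(n_nights = 3)
  raw <- dplyr::bind_rows(raw, raw[2, ])
  expect_error(validate_records(raw), "duplicate.*rows 2, 4")
})

test_that("invalid rows are reported with row context or dropped", {
  raw <- make_raw_records(n_nights = 5)
  raw$onset[2] <- "25:00"          # malformed time
  raw$wake[3] <- "23:40"           # wake before onset on the night axis
  raw$waso_min[4] <- 1e5           # waso >= time in bed
  expect_error(validate_records(raw), "row 2: malformed onset")
  loose <- validate_records(raw, strict = FALSE)
  expect_equal(nrow(loose), 2)
  probs <- attr(loose, "problems")
  expect_equal(probs$row, c(2L, 3L, 4L))
  expect_match(probs$reason[2], "wake not after onset")
})

test_that("exclusion rules remove the right subjects and fill the ledger", {
  recs <- dplyr::bind_rows(
    make_raw_records("ok", n_nights = 14, onset = "00:15", wake = "07:00"),
    make_raw_records("short_sleeper", n_nights = 14,
                     onset = "02:00", wake = "04:30"),  # 2.5 h mean
    make_raw_records("long_sleeper", n_nights = 14,
                     onset = "20:00", wake = "09:40"),  # 13.7 h mean
    make_raw_records("few_nights", n_nights = 5),
    make_raw_records("high_bmi", n_nights = 14)
  )
  subs <- make_subjects(
    c("ok", "short_sleeper", "long_sleeper", "few_nights", "high_bmi"),
    age = c(45, 30, 30, 30, 30), bmi = c(24, 22, 22, 22, 55)
  )
  coh <- apply_exclusions(validate_records(recs), subs)
  expect_setequal(coh$subjects$subject_id, "ok")
  led <- setNames(coh$ledger$n_subjects_removed, coh$ledger$rule)
  expect_equal(unname(led["sleep<3h"]), 1L)
  expect_equal(unname(led["sleep>13h"]), 1L)
  expect_equal(unname(led["bmi>50"]), 1L)
  expect_equal(unname(led["nights<7"]), 1L)
  expect_equal(unname(led["any"]), 4L)
})

test_that("ledger accounts for rule overlap: any = input - output subjects", {
  sim <- simulate_cohort(n_subjects = 80, n_weeks = 1, seed = 5)
  subs <- sim$subjects
  # force overlapping violations: young age AND extreme bmi on one subject
  subs$age_years[1] <- 5
  subs$bmi[1] <- 55
  subs$bmi[2] <- 8
  coh <- apply_exclusions(sim$records, subs)
  led <- setNames(coh$ledger$n_subjects_removed, coh$ledger$rule)
  expect_equal(unname(led["any"]), nrow(subs) - nrow(coh$subjects))
  expect_gte(sum(led[names(led) != "any"]), led[["any"]])
})

test_that("apply_exclusions is idempotent", {
  sim <- simulate_cohort(n_subjects = 50, n_weeks = 2, seed = 8)
  once <- apply_exclusions(sim$records, sim$subjects)
  twice <- apply_exclusions(once$records, once$subjects)
  expect_equal(as.data.frame(twice$records), as.data.frame(once$records))
  expect_equal(as.data.frame(twice$subjects), as.data.frame(once$subjects))
  expect_equal(twice$ledger$n_subjects_removed[twice$ledger$rule == "any"], 0L)
})

test_that("missing age or BMI does not exclude a subject", {
  recs <- validate_records(make_raw_records("S1", n_nights = 14))
  subs <- tibble::tibble(subject_id = "S1", age_years = NA_integer_,
                         sex = factor("unknown"), bmi = NA_real_)
  coh <- apply_exclusions(recs, subs)
  expect_equal(nrow(coh$subjects), 1)
})

test_that("per-night sleep filter drops nights instead of subjects", {
  raw <- make_raw_records("S1", n_nights = 14)
  raw$wake[3] <- "02:30"  # a single 2.25 h night
  recs <- validate_records(raw)
  coh <- apply_exclusions(recs, make_subjects("S1"), per_night = TRUE)
  expect_equal(nrow(coh$records), 13)
  expect_equal(nrow(coh$subjects), 1)
})

test_that("complete_weeks keeps only full Sunday-anchored blocks", {
  # 14 consecutive nights starting Sunday -> 2 complete weeks
  recs <- validate_records(make_raw_records("S1", n_nights = 14))
  wk <- complete_weeks(recs)
  expect_equal(nrow(wk), 14)
  expect_equal(length(unique(wk$week_start)), 2)
  tab <- table(wk$week_start, wk$night_type)
  expect_true(all(tab[, "work"] == 5) && all(tab[, "free"] == 2))

  # 13 nights with one mid-week night missing -> 1 complete week
  raw <- make_raw_records("S1", n_nights = 14)
  raw <- raw[raw$anchor_date != as.Date("2017-04-12"), ]
  expect_equal(length(unique(complete_weeks(validate_records(raw))$week_start)), 1)

  # 6 nights -> no complete weeks
  expect_equal(nrow(complete_weeks(validate_records(
    make_raw_records("S1", n_nights = 6)
  ))), 0)
})
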