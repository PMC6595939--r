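test_that("identical seed and config give identical output", {
  s1 <- simulate_cohort(n_subjects = 40, n_weeks = 2, seed = 4)
  s2 <- simulate_cohort(n_subjects = 40, n_weeks = 2, seed = 4)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(n_subjects = 40, n_weeks = 2, seed = 5)
  expect_false(identical(s3$records, s1$records))
  # and byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_cohort(s1, d1); write_sim_cohort(s2, d2)
  for (f in c("records.csv", "subjects.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

noiseless_config <- function(n_subjects, seed) {
  sim_config(
    n_subjects = n_subjects, n_weeks = 2, seed = seed,
    night_sd_min = 0, waso_mean_min = 0, sjl_sd = 0,
    free_onset_shift_min = 0, free_wake_shift_min = 0, nap_daily_sd = 0
  )
}

test_that("noiseless cohorts have SJL 0 and MSFsc equal to latent truth", {
  sim <- simulate_cohort(config = noiseless_config(60, seed = 6))
  s <- chrono_summary(sim$records)
  expect_equal(max(abs(s$sjl_h)), 0, tolerance = 1e-10)
  rec <- recover_truth(s, sim$truth)
  expect_equal(rec$rmse[rec$metric == "msfsc"], 0, tolerance = 1e-10)
  expect_equal(rec$rmse[rec$metric == "sjl"], 0, tolerance = 1e-10)
})

test_that("MSFsc recovery error shrinks as recording weeks double", {
  sim2 <- simulate_cohort(n_subjects = 300, n_weeks = 2, seed = 14)
  sim4 <- simulate_cohort(n_subjects = 300, n_weeks = 4, seed = 14)
  r2 <- recover_truth(chrono_summary(sim2$records), sim2$truth)
  r4 <- recover_truth(chrono_summary(sim4$records), sim4$truth)
  expect_lt(r4$rmse[r4$metric == "msfsc"], r2$rmse[r2$metric == "msfsc"])
})

test_that("generated cohorts match their configured structure at n = 5000", {
  sim <- simulate_cohort(n_subjects = 5000, n_weeks = 2, seed = 19)
  s <- chrono_summary(sim$records)
  cfg <- sim$config

  # napper fraction within a 99.9% binomial interval of 0.94
  phat <- mean(s$mean_nap_min > 0)
  se <- sqrt(cfg$napper_frac * (1 - cfg$napper_frac) / 5000)
  expect_lt(abs(phat - cfg$napper_frac), 3.3 * se)

  # nap-nocturnal coupling close to the calibrated r = -0.22
  expect_lt(abs(cor(s$mean_nap_min, s$mean_sleep_min) - (-0.22)), 0.05)

  # cohort mean work-night onset/wake near 00:15 / 7:00 (axis 12.25 / 19)
  w <- sim$records[sim$records$night_type == "work", ]
  expect_lt(abs(mean(w$onset_axis) - clock_to_axis(cfg$onset_work_h)),
            4.5 * (cfg$onset_sd_min / 60) / sqrt(5000))
  expect_lt(abs(mean(w$wake_axis) - clock_to_axis(cfg$wake_work_h)),
            4.5 * (cfg$wake_sd_min / 60) / sqrt(5000))

  # mean SJL matches the closed form from the configured free-night shifts
  implied <- (cfg$free_onset_shift_min + cfg$free_wake_shift_min) / 2 / 60
  expect_lt(abs(mean(s$sjl_h) - implied), 4.5 * sd(s$sjl_h) / sqrt(5000))

  # most naps are shorter than 60 minutes
  expect_gt(mean(s$mean_nap_min[s$mean_nap_min > 0] < 60), 0.75)
})

test_that("the age trajectory peaks at the configured age", {
  sim <- simulate_cohort(n_subjects = 6000, n_weeks = 1, seed = 23)
  s <- chrono_summary(sim$records, min_weeks = 1)
  d <- join_cohort(s, sim$subjects)
  d <- d[!is.na(d$age_years) & !is.na(d$msfsc_h), ]
  at <- function(ages) d$msfsc_h[d$age_years %in% ages]
  t_peak_young <- two_sample_t(at(21:23), at(13:15))
  t_peak_mid <- two_sample_t(at(21:23), at(39:41))
  expect_gt(t_peak_young$t, 2)
  expect_gt(t_peak_mid$t, 2)
})

test_that("config validation rejects bad values", {
  expect_error(sim_config(napper_frac = 1.2))
  expect_error(sim_config(night_sd_min = -1))
  expect_error(sim_config(start_date = as.Date("2017-04-03")), "Sunday")
})

test_that("sim_config round-trips through YAML with overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 25, napper_frac = 0.5, seed = 3), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_subjects, 25)
  expect_equal(cfg$napper_frac, 0.5)
  expect_equal(cfg$n_weeks, sim_config()$n_weeks)
  yaml::write_yaml(list(no_such_field = 1), path)
  expect_error(read_sim_config(path), "unknown sim_config fields")
})

test_that("recover_truth flags unknown subjects", {
  sim <- simulate_cohort(n_subjects = 10, n_weeks = 2, seed = 2)
  s <- chrono_summary(sim$records)
  s$subject_id[1] <- "nope"
  expect_error(recover_truth(s, sim$truth), "not found")
})

test_that("written CSVs round-trip through the readers", {
  sim <- simulate_cohort(n_subjects = 15, n_weeks = 2, seed = 9)
  dir <- withr::local_tempdir()
  write_sim_cohort(sim, dir)
  rec <- read_sleep_records(file.path(dir, "records.csv"))
  expect_equal(as.data.frame(rec), as.data.frame(sim$records))
  subs <- read_subjects(file.path(dir, "subjects.csv"))
  expect_equal(subs$subject_id, sim$subjects$subject_id)
  expect_equal(subs$bmi, sim$subjects$bmi)
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg$n_subjects, 15)
})
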