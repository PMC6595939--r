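#' Synthetic-cohort generator configuration
#'
#' All parameters of the synthetic wearable-sleep cohort, with defaults set
#' to the population structure the pipeline is designed for: work-night
#' sleep onset 00:15 (SD 70.5 min) and wake 7:00 (SD 66.3 min); free nights
#' shifted +13 min (onset) and +22 min (wake); ~94% of subjects napping,
#' most naps under 60 minutes; a negative nap-nocturnal-duration coupling
#' calibrated to r of about -0.22; and a biphasic age trajectory of
#' chronotype peaking at 4.0 clock hours at age 22.
#'
#' Between-subject schedule variation is driven by a single latent circadian
#' phase per subject that loads on both onset and wake (their printed SDs
#' and the printed duration SD imply a shared component of about 59 min;
#' the residual onset/wake SDs are derived from that decomposition). The
#' per-subject free-night shift SD (`sjl_sd`) is likewise derived from the
#' excess of the printed free-night onset SD over the work-night onset SD.
#'
#' @param n_subjects Number of subjects.
#' @param n_weeks Complete Sunday-anchored recording weeks per subject.
#' @param seed Integer root seed; all draws flow from it in a fixed order.
#' @param start_date First anchor date (must be a Sunday).
#' @param age_range Integer age bounds.
#' @param age_mix List of mixture components for age (weights `w`, means
#'   `mean`, SDs `sd`; the first component is uniform over 10-19).
#' @param p_missing_age,p_missing_bmi Probability that age/BMI is missing
#'   in the subject table (the latent value still drives the simulation).
#' @param sex_props Named proportions for male/female/unknown.
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (normal, truncated).
#' @param onset_work_h,wake_work_h Mean work-night onset/wake, clock hours.
#' @param onset_sd_min,wake_sd_min Between-subject SDs of onset/wake (min).
#' @param phase_sd_min SD (minutes) of the shared latent phase component.
#' @param free_onset_shift_min,free_wake_shift_min Mean free-night shifts.
#' @param sjl_sd SD (hours) of the per-subject free-night mid-sleep shift
#'   (true SJL heterogeneity).
#' @param night_sd_min Night-to-night noise SD (minutes) on onset and wake.
#' @param waso_mean_min,waso_shape Mean and gamma shape of nightly WASO
#'   minutes (0 mean disables WASO).
#' @param napper_frac Fraction of subjects who nap.
#' @param nap_shape,nap_scale Gamma parameters of a napper's mean daily nap
#'   (minutes); defaults give mean 36, mode 24, most naps < 60.
#' @param nap_daily_sd Day-to-day SD (minutes) around a subject's nap mean.
#' @param nap_coupling Minutes of nocturnal sleep lost per minute of
#'   (centred) nap; applied symmetrically around mid-sleep so naps affect
#'   durations but not mid-sleep timing. The default reproduces a
#'   nap-nocturnal correlation of about -0.22 under the default SDs.
#' @param peak_age,peak_msfsc_h Age and height (clock hours) of the
#'   chronotype trajectory peak.
#' @param msfsc_at_10_h,msfsc_at_80_h Trajectory values at ages 10 and 80
#'   (piecewise-linear hinge; flat outside).
#' @param female_sleep_bonus_min Extra total sleep (minutes) for females,
#'   applied symmetrically (no effect on mid-sleep) and centred so the
#'   cohort mean schedule is unchanged.
#' @param steps_meanlog,steps_sdlog,steps_daily_sdlog Log-normal subject
#'   mean and day-to-day step-count variation.
#' @param p_missing_steps Probability a day's step count is missing.
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @export
sim_config <- function(n_subjects = 1000,
                       n_weeks = 2,
                       seed = 1,
                       start_date = as.Date("2017-04-02"),
                       age_range = c(10L, 90L),
                       age_mix = list(w = c(0.10, 0.70, 0.20),
                                      mean = c(15, 33, 55),
                                      sd = c(3, 8, 10)),
                       p_missing_age = 0.05,
                       p_missing_bmi = 0.18,
                       sex_props = c(male = 0.64, female = 0.14,
                                     unknown = 0.22),
                       bmi_mean = 23.5, bmi_sd = 3.2,
                       bmi_range = c(12, 45),
                       onset_work_h = 0.25, wake_work_h = 7.0,
                       onset_sd_min = 70.5, wake_sd_min = 66.3,
                       phase_sd_min = 58.8,
                       free_onset_shift_min = 13,
                       free_wake_shift_min = 22,
                       sjl_sd = 0.70,
                       night_sd_min = 30,
                       waso_mean_min = 18, waso_shape = 2,
                       napper_frac = 0.94,
                       nap_shape = 3, nap_scale = 12,
                       nap_daily_sd = 10,
                       nap_coupling = 0.52,
                       peak_age = 22, peak_msfsc_h = 4.0,
                       msfsc_at_10_h = 3.0, msfsc_at_80_h = 2.8,
                       female_sleep_bonus_min = 17,
                       steps_meanlog = log(7500), steps_sdlog = 0.45,
                       steps_daily_sdlog = 0.25,
                       p_missing_steps = 0.03) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1, cfg$n_weeks >= 1,
    abs(sum(cfg$sex_props) - 1) < 1e-8,
    all(unlist(cfg[c("onset_sd_min", "wake_sd_min", "phase_sd_min",
                     "night_sd_min", "sjl_sd", "nap_daily_sd")]) >= 0),
    cfg$napper_frac >= 0, cfg$napper_frac <= 1,
    cfg$p_missing_age >= 0, cfg$p_missing_age <= 1,
    cfg$p_missing_bmi >= 0, cfg$p_missing_bmi <= 1,
    cfg$phase_sd_min <= cfg$onset_sd_min,
    cfg$phase_sd_min <= cfg$wake_sd_min
  )
  if (format(cfg$start_date, "%w") != "0") {
    stop("start_date must be a Sunday so weeks hold 5 work + 2 free nights")
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' Unknown fields are an error; omitted fields keep their defaults.
#'
#' @param path Path to a YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown sim_config fields in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  if ("start_date" %in% names(vals)) vals$start_date <- as.Date(vals$start_date)
  if ("sex_props" %in% names(vals)) vals$sex_props <- unlist(vals$sex_props)
  do.call(sim_config, vals)
}

#' Population chronotype trajectory over age
#'
#' Piecewise-linear hinge: rising from `msfsc_at_10_h` at age 10 to
#' `peak_msfsc_h` at `peak_age`, then declining linearly to `msfsc_at_80_h`
#' at age 80; flat outside that range.
#'
#' @param age Numeric vector of ages (years).
#' @param config A [sim_config()].
#' @return Mean MSFsc (clock hours) at each age.
#' @export
msfsc_age_trajectory <- function(age, config = sim_config()) {
  with(config, {
    ifelse(
      age <= 10, msfsc_at_10_h,
      ifelse(
        age <= peak_age,
        msfsc_at_10_h + (peak_msfsc_h - msfsc_at_10_h) *
          (age - 10) / (peak_age - 10),
        ifelse(
          age <= 80,
          peak_msfsc_h + (msfsc_at_80_h - peak_msfsc_h) *
            (age - peak_age) / (80 - peak_age),
          msfsc_at_80_h
        )
      )
    )
  })
}

format_clock <- function(clock) {
  total <- round(clock * 60) %% 1440
  sprintf("%02d:%02d", total %/% 60, total %% 60)
}

round_clock_min <- function(clock) (round(clock * 60) %% 1440) / 60

#' Simulate a synthetic wearable-sleep cohort
#'
#' Draws a cohort of subjects (age, sex, BMI), gives each a latent circadian
#' phase tied to the age trajectory, derives per-night onset/wake times by
#' day type with night-to-night noise, and adds WASO, zero-inflated naps
#' (negatively coupled to nocturnal duration), and daily step counts. All
#' schedule times are rounded to the minute, like device output. Returns the
#' validated records and subjects tables in the standard dialect plus a
#' ground-truth table that the pipeline never reads.
#'
#' Ground truth is computed from each subject's latent (minute-rounded)
#' schedule: `true_msfsc_h` is the MSFsc the pipeline would recover with no
#' night-to-night noise, `true_sjl_h` the latent free-work mid-sleep
#' difference. Identical seed and config give byte-identical output.
#'
#' @param n_subjects,n_weeks,seed Convenience overrides of the same
#'   [sim_config()] fields.
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `records` (validated nightly
#'   records on the night axis), `subjects`, `truth` (tibble `subject_id`,
#'   `true_msfsc_h`, `true_sjl_h`, `true_phase_h`, `napper`), and `config`.
#' @examples
#' sim <- simulate_cohort(n_subjects = 20, n_weeks = 2, seed = 42)
#' sim$truth
#' @export
simulate_cohort <- function(n_subjects = NULL, n_weeks = NULL, seed = NULL,
                            config = sim_config()) {
  if (!is.null(n_subjects)) config$n_subjects <- n_subjects
  if (!is.null(n_weeks)) config$n_weeks <- n_weeks
  if (!is.null(seed)) config$seed <- seed
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  ids <- sprintf("S%05d", seq_len(n))

  # --- subjects ---------------------------------------------------------
  comp <- sample.int(length(cfg$age_mix$w), n, replace = TRUE,
                     prob = cfg$age_mix$w)
  age <- ifelse(
    comp == 1L,
    runif(n, cfg$age_range[1], 19.99),
    rnorm(n, cfg$age_mix$mean[comp], cfg$age_mix$sd[comp])
  )
  age <- as.integer(round(pmin(pmax(age, cfg$age_range[1]), cfg$age_range[2])))
  sex <- factor(
    sample(names(cfg$sex_props), n, replace = TRUE, prob = cfg$sex_props),
    levels = c("male", "female", "unknown")
  )
  bmi <- round(pmin(pmax(rnorm(n, cfg$bmi_mean, cfg$bmi_sd),
                         cfg$bmi_range[1]), cfg$bmi_range[2]), 1)

  # --- latent schedules -------------------------------------------------
  mu_age <- msfsc_age_trajectory(age, cfg)
  phase_resid_sd <- sqrt(max((cfg$phase_sd_min / 60)^2 - var_or0(mu_age), 0))
  phase <- (mu_age - mean(mu_age)) + rnorm(n, 0, phase_resid_sd)

  on_resid_sd <- sqrt(max((cfg$onset_sd_min / 60)^2 -
                            (cfg$phase_sd_min / 60)^2, 0))
  wk_resid_sd <- sqrt(max((cfg$wake_sd_min / 60)^2 -
                            (cfg$phase_sd_min / 60)^2, 0))
  onset_work <- cfg$onset_work_h + phase + rnorm(n, 0, on_resid_sd)
  wake_work <- cfg$wake_work_h + phase + rnorm(n, 0, wk_resid_sd)

  # naps (zero-inflated gamma), coupled to nocturnal duration symmetrically
  napper <- rbinom(n, 1, cfg$napper_frac) == 1
  nap_mean <- ifelse(napper, rgamma(n, cfg$nap_shape, scale = cfg$nap_scale), 0)
  nap_mean <- pmin(nap_mean, 360)
  nap_center <- cfg$napper_frac * cfg$nap_shape * cfg$nap_scale
  dur_cut_h <- cfg$nap_coupling * (nap_mean - nap_center) / 60
  # female total-sleep bonus, centred so the cohort mean schedule is fixed
  p_f <- unname(cfg$sex_props["female"])
  dur_bonus_h <- cfg$female_sleep_bonus_min *
    ((sex == "female") - p_f) / 60
  onset_work <- onset_work + dur_cut_h / 2 - dur_bonus_h / 2
  wake_work <- wake_work - dur_cut_h / 2 + dur_bonus_h / 2

  sjl_shift <- rnorm(n, 0, cfg$sjl_sd)
  onset_free <- onset_work + cfg$free_onset_shift_min / 60 + sjl_shift
  wake_free <- wake_work + cfg$free_wake_shift_min / 60 + sjl_shift

  # device-like minute grid for the latent schedules
  onset_work <- round_clock_min(onset_work)
  wake_work <- round_clock_min(wake_work)
  onset_free <- round_clock_min(onset_free)
  wake_free <- round_clock_min(wake_free)

  subjects <- tibble::tibble(
    subject_id = ids,
    age_years = ifelse(runif(n) < cfg$p_missing_age, NA_integer_, age),
    sex = sex,
    bmi = ifelse(runif(n) < cfg$p_missing_bmi, NA_real_, bmi)
  )

  # --- ground truth -----------------------------------------------------
  mid_w <- (clock_to_axis(onset_work) + clock_to_axis(wake_work)) / 2
  mid_f <- (clock_to_axis(onset_free) + clock_to_axis(wake_free)) / 2
  true_sjl <- mid_f - mid_w
  sdw_lat <- (clock_to_axis(wake_work) - clock_to_axis(onset_work)) -
    cfg$waso_mean_min / 60
  sdf_lat <- (clock_to_axis(wake_free) - clock_to_axis(onset_free)) -
    cfg$waso_mean_min / 60
  true_msfsc <- axis_to_clock(msfsc_week(mid_f, sdf_lat, sdw_lat))
  truth <- tibble::tibble(
    subject_id = ids,
    true_msfsc_h = true_msfsc,
    true_sjl_h = true_sjl,
    true_phase_h = phase,
    napper = napper
  )

  # --- nightly records --------------------------------------------------
  n_nights <- cfg$n_weeks * 7L
  dates <- rep(cfg$start_date + 0:(n_nights - 1), times = n)
  idx <- rep(seq_len(n), each = n_nights)
  is_free <- as.integer(format(dates, "%w")) %in% c(5L, 6L)
  total <- n * n_nights

  onset <- ifelse(is_free, onset_free[idx], onset_work[idx]) +
    rnorm(total, 0, cfg$night_sd_min / 60)
  wake <- ifelse(is_free, wake_free[idx], wake_work[idx]) +
    rnorm(total, 0, cfg$night_sd_min / 60)
  # keep every night inside the noon-to-noon window with a sane episode
  onset_ax <- pmin(pmax(clock_to_axis(onset), 6), 18)
  wake_ax <- pmin(pmax(clock_to_axis(wake), onset_ax + 1), 23.5)
  onset <- round_clock_min(axis_to_clock(onset_ax))
  wake <- round_clock_min(axis_to_clock(wake_ax))

  tib_min <- (clock_to_axis(wake) - clock_to_axis(onset)) * 60
  waso <- if (cfg$waso_mean_min > 0) {
    round(pmin(rgamma(total, cfg$waso_shape,
                      scale = cfg$waso_mean_min / cfg$waso_shape),
               tib_min / 2))
  } else {
    rep(0, total)
  }

  nap <- nap_mean[idx]
  if (cfg$nap_daily_sd > 0) {
    nap <- ifelse(nap > 0,
                  pmax(nap + rnorm(total, 0, cfg$nap_daily_sd), 0), 0)
  }
  nap <- round(pmin(nap, 720))

  steps_mean <- rlnorm(n, cfg$steps_meanlog, cfg$steps_sdlog)
  steps <- round(steps_mean[idx] * rlnorm(total, 0, cfg$steps_daily_sdlog))
  steps[runif(total) < cfg$p_missing_steps] <- NA_real_

  raw <- tibble::tibble(
    subject_id = ids[idx],
    anchor_date = dates,
    onset = format_clock(onset),
    wake = format_clock(wake),
    waso_min = as.numeric(waso),
    nap_min = as.numeric(nap),
    steps = steps
  )
  records <- validate_records(raw, strict = TRUE)

  structure(
    list(records = records, subjects = subjects, truth = truth,
         config = cfg),
    class = "sim_cohort"
  )
}

var_or0 <- function(x) if (length(x) > 1) var(x) else 0

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d subjects x %d weeks (seed %d): %d subject-nights\n",
    x$config$n_subjects, x$config$n_weeks, x$config$seed, nrow(x$records)
  ))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Emits `records.csv`, `subjects.csv` and `truth.csv` in the dialects read
#' by [read_sleep_records()] and [read_subjects()], plus `config.yaml`.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- sim$records
  out <- tibble::tibble(
    subject_id = rec$subject_id,
    anchor_date = rec$anchor_date,
    onset = format_clock(axis_to_clock(rec$onset_axis)),
    wake = format_clock(axis_to_clock(rec$wake_axis)),
    waso_min = rec$waso_min,
    nap_min = rec$nap_min,
    steps = rec$steps
  )
  readr::write_csv(out, file.path(dir, "records.csv"), na = "")
  readr::write_csv(sim$subjects, file.path(dir, "subjects.csv"), na = "")
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  cfg <- sim$config
  cfg$start_date <- format(cfg$start_date)
  cfg$sex_props <- as.list(cfg$sex_props)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Compare pipeline estimates with simulation ground truth
#'
#' Joins a [chrono_summary()] table with the generator's truth table and
#' reports bias (estimate minus truth), RMSE and Spearman rank correlation
#' for MSFsc and SJL over subjects where both are available.
#'
#' @param summaries Tibble from [chrono_summary()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @return Tibble: `metric`, `n`, `bias`, `rmse`, `rank_cor`.
#' @export
recover_truth <- function(summaries, truth) {
  if (!all(summaries$subject_id %in% truth$subject_id)) {
    stop("subject ids in summaries not found in truth table")
  }
  d <- dplyr::inner_join(summaries, truth, by = "subject_id")
  one <- function(est, tru, name) {
    ok <- !is.na(est) & !is.na(tru)
    e <- est[ok]; t <- tru[ok]
    tibble::tibble(
      metric = name, n = sum(ok),
      bias = mean(e - t),
      rmse = sqrt(mean((e - t)^2)),
      rank_cor = if (sum(ok) > 2 && sd(e) > 0 && sd(t) > 0) {
        stats::cor(e, t, method = "spearman")
      } else {
        NA_real_
      }
    )
  }
  dplyr::bind_rows(
    one(d$msfsc_h, d$true_msfsc_h, "msfsc"),
    one(d$sjl_h, d$true_sjl_h, "sjl")
  )
}
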