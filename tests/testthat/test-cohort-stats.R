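# hand formulas used as independent oracles
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df = df))
}

test_that("cohort_pearson matches the product-moment formula oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.3, 6.6, 2.9, 3.8, 5.0)
  y <- c(2.0, 3.1, 2.7, 6.1, 3.3, 1.1, 5.9, 3.5, 3.2, 4.4)
  got <- cohort_pearson(x, y)
  exp <- pearson_oracle(x, y)
  expect_equal(got$r, exp$r, tolerance = 1e-10)
  expect_equal(got$p, exp$p, tolerance = 1e-10)
  expect_equal(got$n, 10)
  expect_equal(cohort_pearson(x, x)$r, 1)
  expect_equal(cohort_pearson(x, -x)$r, -1)
  # pairwise deletion drops incomplete pairs only
  x2 <- c(x, NA); y2 <- c(y, 5)
  expect_equal(cohort_pearson(x2, y2)$n, 10)
  expect_error(cohort_pearson(x, rep(1, 10)), "zero variance")
})

test_that("two_sample_t matches the Welch formula oracle", {
  a <- c(5.1, 4.7, 6.2, 5.9, 4.4, 5.5, 6.8, 5.0)
  b <- c(4.2, 3.9, 5.1, 4.0, 4.8, 3.6)
  got <- two_sample_t(a, b)
  exp <- welch_oracle(a, b)
  expect_equal(got$t, exp$t, tolerance = 1e-10)
  expect_equal(got$p, exp$p, tolerance = 1e-10)
  # antisymmetry
  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  # identical samples
  same <- two_sample_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(a, 4.2), "n >= 2")
})

test_that("sjl regressions recover noise-free coefficients exactly", {
  d <- tibble::tibble(
    mean_nap_min = seq(0, 90, length.out = 30),
    mean_sleep_min = seq(350, 440, length.out = 30),
    sjl_h = NA_real_
  )
  # scramble to break collinearity with nap, deterministically
  d$mean_sleep_min <- d$mean_sleep_min[withr::with_seed(1, sample.int(30))]
  d$sjl_h <- 0.1 + 0.0066 * d$mean_nap_min + 0.0007 * d$mean_sleep_min
  fit <- suppressWarnings(sjl_regressions(d))  # lm warns on a perfect fit
  both <- fit[fit$model == "sjl ~ nap + nocturnal", ]
  expect_equal(both$estimate[both$term == "mean_nap_min"], 0.0066,
               tolerance = 1e-9)
  expect_equal(both$estimate[both$term == "mean_sleep_min"], 0.0007,
               tolerance = 1e-9)
  # constant nap -> rank-deficient design
  d$mean_nap_min <- 30
  expect_error(sjl_regressions(d), "rank-deficient")
})

test_that("slope recovery at generator truth 0.0066 h per nap minute", {
  withr::with_seed(42, {
    n <- 2000
    nap <- pmax(rnorm(n, 34, 22), 0)
    noct <- rnorm(n, 390, 50)
    sjl <- 0.0066 * nap + rnorm(n, 0, 0.5)
  })
  d <- tibble::tibble(mean_nap_min = nap, mean_sleep_min = noct, sjl_h = sjl)
  fit <- sjl_regressions(d)
  row <- fit[fit$model == "sjl ~ nap" & fit$term == "mean_nap_min", ]
  expect_lt(abs(row$estimate - 0.0066), 2 * row$std_error)
})

test_that("summarize_cohort counts SJL fractions and chronotype shares", {
  d <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    sjl_h = c(-0.5, -0.2, -0.1, 0.1, 0.2, 0.5, 0.8, 1.2, 1.5, 0.4),
    msfsc_h = c(2.5, 2.8, 3.5, 4.0, 4.2, 4.5, 4.8, 5.5, 3.9, 4.1),
    chronotype = classify_chronotype(
      c(2.5, 2.8, 3.5, 4.0, 4.2, 4.5, 4.8, 5.5, 3.9, 4.1)),
    nap_group = classify_nap_group(c(0, 0, 10, 10, 10, 40, 40, 40, 40, 40)),
    sdw_h = 6.5, sdf_h = 6.6, mean_nap_min = 20, mean_sleep_min = 390,
    total_sleep_work_min = 410, total_sleep_free_min = 416
  )
  rep <- summarize_cohort(d)
  expect_equal(rep$sjl$frac_lt_0, 0.3)
  expect_equal(rep$sjl$frac_gt_1h, 0.2)
  expect_equal(sum(rep$chronotype$prop), 1)
  expect_equal(rep$chronotype$n[rep$chronotype$chronotype == "early"], 2L)
  # negative-SJL composition: all 3 negatives are early (2) or interm. (1)
  expect_equal(
    rep$neg_sjl$n_negative,
    c(2L, 1L, 0L)
  )
  expect_equal(rep$neg_sjl$prop_within_type[1], 1)   # 2/2 early are negative
  expect_equal(sum(rep$neg_sjl$prop_of_negative), 1)
  # histograms use 0.5-h bins anchored at integer hours
  expect_equal(rep$hist_sjl$bin_left, c(-0.5, 0, 0.5, 1, 1.5))
  expect_equal(sum(rep$hist_sjl$count), 10L)
  expect_error(summarize_cohort(d[0, ]), "empty")
})

test_that("cohort fractions are invariant to ordering and add-then-remove", {
  sim <- simulate_cohort(n_subjects = 80, n_weeks = 2, seed = 13)
  s <- join_cohort(chrono_summary(sim$records), sim$subjects)
  r1 <- summarize_cohort(s)
  r2 <- summarize_cohort(s[sample.int(nrow(s)), ])
  expect_equal(r2$sjl, r1$sjl)
  expect_equal(r2$chronotype, r1$chronotype)
  extra <- s[7, ]
  extra$subject_id <- "ghost"
  r3 <- summarize_cohort(dplyr::bind_rows(s, extra)[-(nrow(s) + 1), ])
  expect_equal(r3$sjl, r1$sjl)
})

test_that("identical free/work schedules give a degenerate SJL report", {
  recs <- validate_records(dplyr::bind_rows(lapply(1:6, function(i) {
    make_raw_records(paste0("S", i), n_nights = 14,
                     onset = "00:15", wake = "07:00", nap = 10 * (i %% 3))
  })))
  rep <- summarize_cohort(chrono_summary(recs))
  expect_equal(rep$sjl$frac_lt_0, 0)
  expect_equal(rep$sjl$frac_gt_1h, 0)
  expect_equal(rep$sjl$mean_h, 0)
})

test_that("correlation and sex-test tables cover the analysis groups", {
  sim <- simulate_cohort(n_subjects = 250, n_weeks = 2, seed = 17)
  d <- join_cohort(chrono_summary(sim$records), sim$subjects)
  ct <- cohort_correlations(d)
  expect_true(all(c("all", "zero_nap", "long_nap") %in% ct$group))
  nap_noct <- ct[ct$group == "all" & ct$x == "mean_nap_min", ]
  expect_lt(nap_noct$r, 0)  # negative nap-nocturnal coupling
  expect_lte(max(ct$n[ct$group == "zero_nap"]), max(ct$n[ct$group == "all"]))
  st <- sjl_sex_tests(d)
  expect_true("all" %in% st$group)
  expect_true(all(is.finite(st$t)))
})
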