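#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation with a two-sided test, after dropping pairs
#' with a missing value in either vector (pairwise deletion, as cohort n's
#' differ across correlated variables).
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `r`, `p`, `n`.
#' @examples
#' cohort_pearson(1:10, (1:10) * 2 + rnorm(10))
#' @export
cohort_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample t test
#'
#' Two-sided two-sample t test, Welch by default (`welch = FALSE` pools the
#' variance).
#'
#' @param a,b Numeric vectors (each `n >= 2`), `NA`s dropped.
#' @param welch Use the Welch statistic (default) or pooled variance.
#' @return One-row tibble: `t`, `p`, `df`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b, welch = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0 && !welch) stop("both groups degenerate")
  tt <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  tibble::tibble(
    t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
    n_a = length(a), n_b = length(b)
  )
}

#' SJL regressions on nap and nocturnal sleep durations
#'
#' Ordinary least squares fits of (1) `sjl_h ~ mean_nap_min` and (2)
#' `sjl_h ~ mean_nap_min + mean_sleep_min`. Units are fixed — SJL in hours,
#' durations in minutes — so a slope of 0.0066 h/min reads as 0.4 min of SJL
#' per extra nap minute.
#'
#' @param summaries Tibble from [chrono_summary()] (needs `sjl_h`,
#'   `mean_nap_min`, `mean_sleep_min`).
#' @return Tibble with one row per model term: `model`, `term`, `estimate`,
#'   `std_error`, `p`, `n`.
#' @export
sjl_regressions <- function(summaries) {
  d <- summaries[!is.na(summaries$sjl_h) & !is.na(summaries$mean_nap_min) &
                   !is.na(summaries$mean_sleep_min), ]
  fits <- list(
    `sjl ~ nap` = lm(sjl_h ~ mean_nap_min, data = d),
    `sjl ~ nap + nocturnal` = lm(sjl_h ~ mean_nap_min + mean_sleep_min,
                                 data = d)
  )
  purrr::map_dfr(names(fits), function(nm) {
    fit <- fits[[nm]]
    if (any(is.na(coef(fit)))) {
      stop("rank-deficient design in model '", nm, "'")
    }
    cf <- summary(fit)$coefficients
    tibble::tibble(
      model = nm, term = rownames(cf), estimate = unname(cf[, 1]),
      std_error = unname(cf[, 2]), p = unname(cf[, 4]), n = nrow(d)
    )
  })
}

#' Correlation table for a cohort
#'
#' The correlation analyses run on a cohort table: SJL against age, BMI and
#' MSFsc, and nap against nocturnal duration — in all subjects and in the
#' zero- and long-nap subgroups (the short-nap group is left out of the
#' subgroup analyses because its nap effect is minor).
#'
#' @param data Cohort table: [chrono_summary()] joined with the subject
#'   table ([join_cohort()]).
#' @return Tibble: `group`, `x`, `y`, `r`, `p`, `n`.
#' @export
cohort_correlations <- function(data) {
  pairs <- list(
    c("sjl_h", "age_years"), c("sjl_h", "bmi"), c("sjl_h", "msfsc_h"),
    c("mean_nap_min", "mean_sleep_min")
  )
  groups <- list(
    all = rep(TRUE, nrow(data)),
    zero_nap = data$nap_group == "zero",
    long_nap = data$nap_group == "long"
  )
  purrr::map_dfr(names(groups), function(g) {
    d <- data[groups[[g]] & !is.na(groups[[g]]), ]
    purrr::map_dfr(pairs, function(pr) {
      res <- tryCatch(cohort_pearson(d[[pr[1]]], d[[pr[2]]]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble::tibble(group = g, x = pr[1], y = pr[2],
                     r = res$r, p = res$p, n = res$n)
    })
  })
}

#' Sex-difference tests on SJL
#'
#' Welch two-sample t tests of SJL between males and females, in all
#' subjects and in the zero- and long-nap subgroups.
#'
#' @inheritParams cohort_correlations
#' @return Tibble: `group`, plus the [two_sample_t()] columns (`mean_a` is
#'   the male mean, `mean_b` the female mean).
#' @export
sjl_sex_tests <- function(data) {
  groups <- list(
    all = rep(TRUE, nrow(data)),
    zero_nap = data$nap_group == "zero",
    long_nap = data$nap_group == "long"
  )
  purrr::map_dfr(names(groups), function(g) {
    d <- data[groups[[g]] & !is.na(groups[[g]]), ]
    res <- tryCatch(
      two_sample_t(d$sjl_h[d$sex == "male"], d$sjl_h[d$sex == "female"]),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(group = g), res)
  })
}

#' Join per-subject summaries with subject metadata
#'
#' @param summaries Tibble from [chrono_summary()].
#' @param subjects Subject tibble ([read_subjects()]).
#' @return The summaries with `age_years`, `sex`, `bmi` columns added.
#' @export
join_cohort <- function(summaries, subjects) {
  dplyr::left_join(summaries, subjects, by = "subject_id")
}

half_hour_hist <- function(x, width = 0.5) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(tibble::tibble(bin_left = numeric(), bin_right = numeric(),
                          count = integer()))
  }
  left <- floor(x / width) * width
  tab <- table(left)
  tibble::tibble(
    bin_left = as.numeric(names(tab)),
    bin_right = as.numeric(names(tab)) + width,
    count = as.integer(tab)
  )
}

#' Cohort-level report
#'
#' Aggregates a cohort table into the population-level summaries:
#' chronotype proportions; the SJL distribution (mean, SD, fraction above
#' 1 h, fraction below 0); the composition of the negative-SJL subset by
#' chronotype and the share of each chronotype with negative SJL;
#' descriptive means/SDs of durations and schedules by sex and by nap
#' group; and 0.5-h histograms (anchored at integer hours) of SJL and
#' MSFsc.
#'
#' @param data Cohort table: [chrono_summary()] output, optionally joined
#'   with subjects via [join_cohort()] (sex descriptives need `sex`).
#' @return A list of class `cohort_report` with elements `counts`, `sjl`,
#'   `chronotype`, `neg_sjl`, `by_nap_group`, `by_sex` (if sex present),
#'   `hist_sjl`, `hist_msfsc`.
#' @examples
#' sim <- simulate_cohort(n_subjects = 50, n_weeks = 2, seed = 1)
#' rep <- summarize_cohort(join_cohort(chrono_summary(sim$records),
#'                                     sim$subjects))
#' rep$sjl
#' @export
summarize_cohort <- function(data) {
  if (!nrow(data)) stop("empty cohort")
  sjl <- data$sjl_h[!is.na(data$sjl_h)]
  n_sjl <- length(sjl)
  if (!n_sjl) stop("no subjects with both work and free nights")

  sjl_tbl <- tibble::tibble(
    n = n_sjl,
    mean_h = mean(sjl),
    sd_h = sd(sjl),
    frac_gt_1h = mean(sjl > 1),
    frac_lt_0 = mean(sjl < 0)
  )

  typed <- data[!is.na(data$chronotype), ]
  chronotype_tbl <- dplyr::count(typed, .data$chronotype, .drop = FALSE,
                                 name = "n")
  chronotype_tbl$prop <- if (nrow(typed)) chronotype_tbl$n / nrow(typed)
                         else NA_real_

  neg <- typed[!is.na(typed$sjl_h) & typed$sjl_h < 0, ]
  neg_tbl <- dplyr::count(neg, .data$chronotype, .drop = FALSE,
                          name = "n_negative")
  neg_tbl$prop_of_negative <- if (nrow(neg)) neg_tbl$n_negative / nrow(neg)
                              else NA_real_
  neg_tbl <- dplyr::left_join(
    neg_tbl,
    dplyr::count(typed[!is.na(typed$sjl_h), ], .data$chronotype,
                 .drop = FALSE, name = "n_type"),
    by = "chronotype"
  )
  neg_tbl$prop_within_type <- ifelse(
    neg_tbl$n_type > 0, neg_tbl$n_negative / neg_tbl$n_type, NA_real_
  )

  desc <- function(d) {
    tibble::tibble(
      n = nrow(d),
      mean_sjl_h = mean(d$sjl_h, na.rm = TRUE),
      sd_sjl_h = sd(d$sjl_h, na.rm = TRUE),
      mean_sleep_work_min = mean(d$sdw_h * 60, na.rm = TRUE),
      mean_sleep_free_min = mean(d$sdf_h * 60, na.rm = TRUE),
      mean_total_work_min = mean(d$total_sleep_work_min, na.rm = TRUE),
      mean_total_free_min = mean(d$total_sleep_free_min, na.rm = TRUE),
      mean_nap_min = mean(d$mean_nap_min, na.rm = TRUE)
    )
  }
  by_nap <- dplyr::group_modify(
    dplyr::group_by(data[!is.na(data$nap_group), ], .data$nap_group),
    ~ desc(.x)
  )
  by_sex <- NULL
  if ("sex" %in% names(data)) {
    by_sex <- dplyr::group_modify(
      dplyr::group_by(data[!is.na(data$sex), ], .data$sex), ~ desc(.x)
    )
  }

  out <- list(
    counts = tibble::tibble(
      n_subjects = nrow(data),
      n_sjl = n_sjl,
      n_chronotyped = nrow(typed)
    ),
    sjl = sjl_tbl,
    chronotype = chronotype_tbl,
    neg_sjl = neg_tbl,
    by_nap_group = dplyr::ungroup(by_nap),
    by_sex = if (!is.null(by_sex)) dplyr::ungroup(by_sex),
    hist_sjl = half_hour_hist(sjl),
    hist_msfsc = half_hour_hist(typed$msfsc_h)
  )
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf(
    "  subjects: %d (SJL n = %d, chronotyped n = %d)\n",
    x$counts$n_subjects, x$counts$n_sjl, x$counts$n_chronotyped
  ))
  cat(sprintf(
    "  SJL: mean %.2f h (SD %.2f); P(SJL > 1 h) = %.1f%%, P(SJL < 0) = %.1f%%\n",
    x$sjl$mean_h, x$sjl$sd_h, 100 * x$sjl$frac_gt_1h, 100 * x$sjl$frac_lt_0
  ))
  if (x$counts$n_chronotyped > 0) {
    p <- setNames(x$chronotype$prop, as.character(x$chronotype$chronotype))
    cat(sprintf(
      "  chronotypes: early %.1f%%, intermediate %.1f%%, late %.1f%%\n",
      100 * p[["early"]], 100 * p[["intermediate"]], 100 * p[["late"]]
    ))
  }
  invisible(x)
}

#' @export
glance.cohort_report <- function(x, ...) {
  p <- setNames(as.list(x$chronotype$prop),
                paste0("prop_", x$chronotype$chronotype))
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(
      mean_sjl_h = x$sjl$mean_h, sd_sjl_h = x$sjl$sd_h,
      frac_sjl_gt_1h = x$sjl$frac_gt_1h, frac_sjl_lt_0 = x$sjl$frac_lt_0
    ),
    tibble::as_tibble(p)
  )
}
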