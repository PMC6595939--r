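#' Histogram of social jetlag
#'
#' 0.5-hour bins anchored at integer hours, matching the report tables.
#'
#' @param summaries Tibble from [chrono_summary()].
#' @return A ggplot object.
#' @export
plot_sjl_histogram <- function(summaries) {
  d <- summaries[!is.na(summaries$sjl_h), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sjl_h)) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "social jetlag (h)", y = "subjects")
}

#' Histogram of MSFsc coloured by chronotype
#'
#' @inheritParams plot_sjl_histogram
#' @param cutoffs Chronotype cut-offs used for the fill.
#' @return A ggplot object.
#' @export
plot_msfsc_histogram <- function(summaries, cutoffs = c(3, 5)) {
  d <- summaries[!is.na(summaries$msfsc_h), ]
  d$chronotype <- classify_chronotype(d$msfsc_h, cutoffs = cutoffs)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$msfsc_h, fill = .data$chronotype)
  ) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0,
                            colour = "white") +
    ggplot2::labs(x = "MSFsc (clock hours after midnight)", y = "subjects",
                  fill = "chronotype")
}

#' Age trajectory of MSFsc
#'
#' Mean MSFsc per age in years with standard-deviation error bars; ages with
#' fewer than `min_n` subjects are dropped.
#'
#' @inheritParams plot_sjl_histogram
#' @param min_n Minimum subjects per age to plot.
#' @return A ggplot object.
#' @export
plot_age_msfsc <- function(summaries, min_n = 5) {
  if (!"age_years" %in% names(summaries)) {
    stop("summaries must be joined with subjects (join_cohort())")
  }
  d <- summaries[!is.na(summaries$msfsc_h) & !is.na(summaries$age_years), ]
  agg <- dplyr::summarise(
    dplyr::group_by(d, .data$age_years),
    n = dplyr::n(), mean = mean(.data$msfsc_h), sd = sd(.data$msfsc_h),
    .groups = "drop"
  )
  agg <- agg[agg$n >= min_n, ]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$age_years, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age (years)", y = "MSFsc (clock hours)")
}

#' @export
autoplot.cohort_report <- function(object, ...) {
  d <- object$hist_sjl
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_left + 0.25,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 0.5, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "social jetlag (h)", y = "subjects")
}
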