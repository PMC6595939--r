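#' Random-forest feature importance for SJL or MSFsc
#'
#' Grid-searches a random-forest regression of the target on the six
#' subject-level predictors — sex, age, BMI, mean daily step count (an
#' exercise indicator), mean nocturnal sleep duration and mean daytime nap
#' duration — over the number of trees (10 to 50 in steps of 10) and the
#' maximal tree depth (2 to 5). The grid point with the highest mean 5-fold
#' cross-validated R-squared is selected, the forest is refit on all
#' complete cases, and impurity-based importances are returned normalised to
#' sum to 1 (relative feature importance). All predictors are considered at
#' every split (`mtry = p`), the conventional regression-forest default. Only complete cases across all
#' predictors are used, so missing BMI or age does not distort the weights.
#' When the target is SJL, MSFsc is excluded as a predictor by construction
#' (it is strongly correlated with SJL and would mask the others).
#'
#' Fold assignment and tree randomness are fully determined by `seed`;
#' fits run single-threaded so repeated calls are bit-identical.
#'
#' @param data Cohort table: [chrono_summary()] joined with subjects
#'   ([join_cohort()]). Needs `sjl_h` or `msfsc_h` plus `sex`, `age_years`,
#'   `bmi`, `mean_steps`, `mean_sleep_min`, `mean_nap_min`.
#' @param target `"sjl"` or `"msfsc"`.
#' @param trees Integer vector of forest sizes to try.
#' @param depths Integer vector of maximal tree depths to try.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling folds and tree randomness.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An object of class `chrono_rf`: list with `importance` (tibble
#'   `feature`, `importance`, sorted descending), `trees`, `depth`,
#'   `cv_r2`, `grid` (all grid points with their mean CV R-squared), `n`,
#'   `target`, `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(n_subjects = 300, n_weeks = 2, seed = 1)
#' coh <- join_cohort(chrono_summary(sim$records), sim$subjects)
#' fit <- feature_importance(coh, target = "msfsc", seed = 1)
#' tidy(fit)
#' }
#' @export
feature_importance <- function(data, target = c("sjl", "msfsc"),
                               trees = seq(10L, 50L, by = 10L),
                               depths = 2:5, folds = 5, seed = 1,
                               importance = c("impurity", "permutation")) {
  target <- match.arg(target)
  importance <- match.arg(importance)
  ycol <- switch(target, sjl = "sjl_h", msfsc = "msfsc_h")

  predictors <- c("sex", "age_years", "bmi", "mean_steps",
                  "mean_sleep_min", "mean_nap_min")
  d <- data[, c(ycol, predictors)]
  d <- d[complete.cases(d), ]
  names(d)[1] <- "y"
  d$sex <- factor(d$sex)
  if (nrow(d) < folds) stop("fewer complete cases (", nrow(d),
                            ") than folds (", folds, ")")

  fold_id <- withr::with_seed(
    seed, sample(rep_len(seq_len(folds), nrow(d)))
  )

  grid <- tidyr::expand_grid(trees = as.integer(trees),
                             depth = as.integer(depths))
  grid$cv_r2 <- purrr::pmap_dbl(grid, function(trees, depth) {
    r2 <- vapply(seq_len(folds), function(k) {
      train <- d[fold_id != k, ]
      test <- d[fold_id == k, ]
      fit <- ranger::ranger(
        y ~ ., data = train, num.trees = trees, max.depth = depth,
        mtry = ncol(train) - 1, seed = seed + k, num.threads = 1
      )
      pred <- predict(fit, data = test, num.threads = 1)$predictions
      1 - sum((test$y - pred)^2) / sum((test$y - mean(test$y))^2)
    }, numeric(1))
    mean(r2)
  })

  best <- grid[order(-grid$cv_r2, grid$trees, grid$depth), ][1, ]
  final <- ranger::ranger(
    y ~ ., data = d, num.trees = best$trees, max.depth = best$depth,
    mtry = ncol(d) - 1, importance = importance, seed = seed,
    num.threads = 1
  )
  imp <- ranger::importance(final)
  imp <- pmax(imp, 0)
  rel <- if (sum(imp) > 0) imp / sum(imp) else imp

  structure(
    list(
      importance = tibble::tibble(
        feature = names(rel), importance = unname(rel)
      )[order(-rel), ],
      trees = best$trees, depth = best$depth, cv_r2 = best$cv_r2,
      grid = grid, n = nrow(d), target = target, seed = seed,
      importance_type = importance
    ),
    class = "chrono_rf"
  )
}

#' @export
print.chrono_rf <- function(x, ...) {
  cat(sprintf(
    "<chrono_rf> target = %s, n = %d; best grid point: %d trees, depth %d (CV R^2 = %.3f)\n",
    x$target, x$n, x$trees, x$depth, x$cv_r2
  ))
  print(x$importance)
  invisible(x)
}

#' @rdname feature_importance
#' @param x A `chrono_rf` object.
#' @param ... Unused.
#' @export
tidy.chrono_rf <- function(x, ...) x$importance

#' @rdname feature_importance
#' @export
glance.chrono_rf <- function(x, ...) {
  tibble::tibble(
    target = x$target, trees = x$trees, depth = x$depth,
    cv_r2 = x$cv_r2, n = x$n, seed = x$seed
  )
}

#' @rdname feature_importance
#' @param object A `chrono_rf` object.
#' @export
autoplot.chrono_rf <- function(object, ...) {
  d <- object$importance
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$feature, .data$importance),
      y = .data$importance
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "relative feature importance",
      title = sprintf("Predictors of %s (%d trees, depth %d)",
                      toupper(object$target), object$trees, object$depth)
    )
}
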