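#' Build a 2x2 classification table
#'
#' @param tp,fp,fn,tn Non-negative integer counts: true/false positives,
#'   false/true negatives, with "condition" the true oxygen requirement and
#'   "test" the LUS-based prediction.
#' @return A `two_by_two` object.
#' @export
#' @examples
#' two_by_two(28, 1, 1, 76)
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("2x2 cells must be non-negative integers",
                 class = "bronchlus_domain_error")
  }
  if (sum(cells) == 0) {
    rlang::abort("2x2 table must contain at least one observation",
                 class = "bronchlus_domain_error")
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              condition = c("yes", "no")))
  cat("2x2 classification table (n =", sum(unlist(x[c("tp","fp","fn","tn")])), ")\n")
  print(m)
  invisible(x)
}

#' Tabulate the oxygen-need classifier against the observed outcome
#'
#' Applies the LUS oxygen rule ([predict_oxygen_need()]) to each infant and
#' cross-tabulates the prediction against the recorded oxygen requirement.
#'
#' @param data Cohort data frame.
#' @param lus_total Column with the LUS total (0-8).
#' @param oxygen_required Logical column: did the infant need supplementary
#'   oxygen.
#' @param threshold Rule threshold, predicted positive iff total > threshold.
#' @return A [two_by_two()] object.
#' @export
#' @examples
#' d <- tibble::tibble(lus_total = c(5, 1), oxygen_required = c(TRUE, FALSE))
#' oxygen_two_by_two(d)
oxygen_two_by_two <- function(data, lus_total = lus_total,
                              oxygen_required = oxygen_required,
                              threshold = 3) {
  tot <- rlang::eval_tidy(rlang::enquo(lus_total), data)
  oxy <- rlang::eval_tidy(rlang::enquo(oxygen_required), data)
  if (length(tot) == 0) {
    rlang::abort("cannot tabulate an empty cohort", class = "bronchlus_domain_error")
  }
  if (!is.logical(oxy) || anyNA(oxy)) {
    rlang::abort("`oxygen_required` must be logical without missing values",
                 class = "bronchlus_domain_error")
  }
  pred <- predict_oxygen_need(tot, threshold = threshold)
  two_by_two(tp = sum(pred & oxy), fp = sum(pred & !oxy),
             fn = sum(!pred & oxy), tn = sum(!pred & !oxy))
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble with `conf.low` and `conf.high`. Vectorised over `x`, `n`.
#' @export
#' @examples
#' wilson_interval(76, 77)
wilson_interval <- function(x, n, conf_level = 0.95) {
  check_xn(x, n, conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(conf.low = pmax(0, centre - half),
                 conf.high = pmin(1, centre + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' Exact beta-quantile interval; the lower bound is 0 when `x = 0` and the
#' upper bound is 1 when `x = n`.
#'
#' @inheritParams wilson_interval
#' @return Tibble with `conf.low` and `conf.high`. Vectorised over `x`, `n`.
#' @export
#' @examples
#' clopper_pearson_interval(28, 29)
clopper_pearson_interval <- function(x, n, conf_level = 0.95) {
  check_xn(x, n, conf_level)
  a <- (1 - conf_level) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  tibble::tibble(conf.low = lo, conf.high = hi)
}

check_xn <- function(x, n, conf_level) {
  if (any(n <= 0) || any(x < 0) || any(x > n) ||
      any(x != round(x)) || any(n != round(n))) {
    rlang::abort("need integer 0 <= x <= n with n > 0",
                 class = "bronchlus_domain_error")
  }
  if (conf_level <= 0 || conf_level >= 1) {
    rlang::abort("`conf_level` must be in (0, 1)", class = "bronchlus_domain_error")
  }
  invisible(TRUE)
}

proportion_estimate <- function(metric, x, n, ci_method, conf_level) {
  if (n == 0) {
    rlang::abort(sprintf("%s is undefined: its denominator is zero", metric),
                 class = "bronchlus_undefined_metric_error")
  }
  ci <- switch(ci_method,
               wilson = wilson_interval(x, n, conf_level),
               `clopper-pearson` = clopper_pearson_interval(x, n, conf_level))
  tibble::tibble(metric = metric, numerator = as.integer(x),
                 denominator = as.integer(n), estimate = x / n,
                 conf.low = ci$conf.low, conf.high = ci$conf.high,
                 ci_method = ci_method, conf_level = conf_level)
}

#' Diagnostic accuracy of a binary classifier
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)` with
#' binomial confidence intervals. The default interval is the Wilson score
#' interval; the Clopper-Pearson exact interval is available via
#' `ci_method`.
#'
#' @param t A [two_by_two()] table.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `binary_diagnostics` tibble: one row per metric with numerator,
#'   denominator, estimate and interval.
#' @export
#' @examples
#' binary_diagnostics(two_by_two(28, 1, 1, 76))
binary_diagnostics <- function(t, ci_method = c("wilson", "clopper-pearson"),
                               conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  ci_method <- match.arg(ci_method)
  out <- dplyr::bind_rows(
    proportion_estimate("sensitivity", t$tp, t$tp + t$fn, ci_method, conf_level),
    proportion_estimate("specificity", t$tn, t$tn + t$fp, ci_method, conf_level),
    proportion_estimate("ppv", t$tp, t$tp + t$fp, ci_method, conf_level),
    proportion_estimate("npv", t$tn, t$tn + t$fn, ci_method, conf_level)
  )
  class(out) <- c("binary_diagnostics", class(out))
  out
}

#' @rdname binary_diagnostics
#' @export
sensitivity <- function(t, ci_method = c("wilson", "clopper-pearson"),
                        conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  proportion_estimate("sensitivity", t$tp, t$tp + t$fn, match.arg(ci_method), conf_level)
}

#' @rdname binary_diagnostics
#' @export
specificity <- function(t, ci_method = c("wilson", "clopper-pearson"),
                        conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  proportion_estimate("specificity", t$tn, t$tn + t$fp, match.arg(ci_method), conf_level)
}

#' @rdname binary_diagnostics
#' @export
ppv <- function(t, ci_method = c("wilson", "clopper-pearson"),
                conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  proportion_estimate("ppv", t$tp, t$tp + t$fp, match.arg(ci_method), conf_level)
}

#' @rdname binary_diagnostics
#' @export
npv <- function(t, ci_method = c("wilson", "clopper-pearson"),
                conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  proportion_estimate("npv", t$tn, t$tn + t$fn, match.arg(ci_method), conf_level)
}

#' Plot diagnostic accuracy estimates with confidence intervals
#'
#' @param object A `binary_diagnostics` tibble.
#' @param ... Unused.
#' @return A ggplot point-range chart.
#' @export
autoplot.binary_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = sprintf("Diagnostic accuracy (%s %.0f%% CI)",
                                  object$ci_method[1],
                                  100 * object$conf_level[1])) +
    ggplot2::theme_minimal()
}

#' Counts-by-group to a 2x2 contingency table
#'
#' Turns "x/n in group A vs y/m in group B" rows, the way contingency
#' comparisons are printed in clinical tables, into the 2x2 count matrix a
#' chi-squared test consumes.
#'
#' @param pos_a,n_a Positives and total in group A.
#' @param pos_b,n_b Positives and total in group B.
#' @return 2x2 integer matrix, rows = groups, columns = finding yes/no.
#' @export
#' @examples
#' two_by_two_from_groups(61, 76, 3, 30)
two_by_two_from_groups <- function(pos_a, n_a, pos_b, n_b) {
  v <- c(pos_a, n_a, pos_b, n_b)
  if (any(v < 0) || any(v != round(v)) || pos_a > n_a || pos_b > n_b) {
    rlang::abort("need integer counts with 0 <= pos <= n in each group",
                 class = "bronchlus_domain_error")
  }
  matrix(as.integer(c(pos_a, n_a - pos_a, pos_b, n_b - pos_b)),
         nrow = 2, byrow = TRUE,
         dimnames = list(group = c("a", "b"), finding = c("yes", "no")))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Pearson's chi-squared statistic without continuity correction (the
#' uncorrected statistic is what clinical contingency tables of this kind
#' print), one degree of freedom. A warning is raised when any expected
#' cell is below 5, but the statistic is still computed.
#'
#' @param tab 2x2 count matrix, e.g. from [two_by_two_from_groups()].
#' @param correct Apply the Yates continuity correction. Default `FALSE`.
#' @return One-row tibble with `statistic`, `df`, `p.value` and
#'   `min_expected`; the expected counts are attached as attribute
#'   `"expected"`.
#' @export
#' @examples
#' pearson_chi2_2x2(two_by_two_from_groups(61, 76, 3, 30))
pearson_chi2_2x2 <- function(tab, correct = FALSE) {
  m <- as.matrix(tab)
  if (!all(dim(m) == 2) || any(m < 0)) {
    rlang::abort("`tab` must be a 2x2 matrix of non-negative counts",
                 class = "bronchlus_domain_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("chi-squared test needs positive row and column totals",
                 class = "bronchlus_degenerate_error")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  min_exp <- min(ct$expected)
  if (min_exp < 5) {
    rlang::warn(sprintf(
      "minimum expected cell count %.2f is below 5; chi-squared approximation may be poor",
      min_exp), class = "bronchlus_expected_count_warning")
  }
  out <- tibble::tibble(statistic = unname(ct$statistic),
                        df = unname(ct$parameter),
                        p.value = unname(ct$p.value),
                        min_expected = min_exp)
  attr(out, "expected") <- ct$expected
  out
}

#' Chi-squared comparison battery over printed group counts
#'
#' Runs [pearson_chi2_2x2()] on every row of a table of "pos/n vs pos/n"
#' group comparisons. Rows whose table is degenerate (a zero row or column
#' total) are skipped with a warning and returned with `NA` statistics.
#'
#' @param rows Data frame with columns `pos_a`, `n_a`, `pos_b`, `n_b` (other
#'   columns are carried through).
#' @param correct Continuity correction, default `FALSE`.
#' @return The input tibble with `statistic`, `df`, `p.value` and
#'   `min_expected` appended.
#' @export
#' @examples
#' compare_groups(tibble::tibble(pos_a = 61, n_a = 76, pos_b = 3, n_b = 30))
compare_groups <- function(rows, correct = FALSE) {
  rows <- tibble::as_tibble(rows)
  res <- purrr::pmap(rows[c("pos_a", "n_a", "pos_b", "n_b")],
                     function(pos_a, n_a, pos_b, n_b) {
    tab <- two_by_two_from_groups(pos_a, n_a, pos_b, n_b)
    tryCatch(
      suppressWarnings(pearson_chi2_2x2(tab, correct = correct)),
      bronchlus_degenerate_error = function(e) {
        rlang::warn(sprintf("skipping degenerate comparison %d/%d vs %d/%d",
                            pos_a, n_a, pos_b, n_b))
        tibble::tibble(statistic = NA_real_, df = NA_integer_,
                       p.value = NA_real_, min_expected = NA_real_)
      })
  })
  dplyr::bind_cols(rows, dplyr::bind_rows(res))
}
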