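#' Cross-tabulate two raters' grades
#'
#' Builds the k x k confusion matrix of paired categorical ratings over a
#' fixed, shared, ordered category set. Categories with zero counts keep
#' their row/column, so kappa marginals retain full length even when one
#' rater never used a level.
#'
#' @param grade_a,grade_b Equal-length vectors of ratings (rows = rater A,
#'   columns = rater B).
#' @param levels Ordered category labels; defaults to [severity_levels()].
#' @return A `table` with one row/column per category.
#' @export
#' @examples
#' confusion_from_pairs(c("mild", "mild"), c("mild", "moderate"))
confusion_from_pairs <- function(grade_a, grade_b, levels = severity_levels()) {
  if (length(grade_a) != length(grade_b)) {
    rlang::abort("rater vectors must have equal length",
                 class = "bronchlus_domain_error")
  }
  if (length(grade_a) == 0) {
    rlang::abort("cannot tabulate an empty pair sequence",
                 class = "bronchlus_domain_error")
  }
  a <- as.character(grade_a)
  b <- as.character(grade_b)
  unknown <- setdiff(stats::na.omit(unique(c(a, b))), levels)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown categor%s: %s",
                         if (length(unknown) > 1) "ies" else "y",
                         paste(unknown, collapse = ", ")),
                 class = "bronchlus_domain_error")
  }
  if (anyNA(a) || anyNA(b)) {
    rlang::abort("missing ratings are not allowed in an agreement table",
                 class = "bronchlus_domain_error")
  }
  table(rater_a = factor(a, levels = levels),
        rater_b = factor(b, levels = levels))
}

check_cm <- function(cm) {
  m <- as.matrix(cm)
  if (nrow(m) != ncol(m)) {
    rlang::abort("confusion matrix must be square", class = "bronchlus_domain_error")
  }
  if (any(m < 0) || sum(m) <= 0) {
    rlang::abort("confusion matrix needs non-negative counts and a positive total",
                 class = "bronchlus_domain_error")
  }
  m
}

#' Observed agreement proportion
#'
#' @param cm Square confusion matrix of counts (rows = rater A).
#' @return Proportion of pairs on the diagonal, trace(cm) / n.
#' @export
#' @examples
#' observed_agreement(diag(c(3, 2)))
observed_agreement <- function(cm) {
  m <- check_cm(cm)
  sum(diag(m)) / sum(m)
}

check_marginals <- function(row_marginals, col_marginals, n) {
  if (length(row_marginals) != length(col_marginals)) {
    rlang::abort("marginal vectors must have the same length",
                 class = "bronchlus_domain_error")
  }
  if (sum(row_marginals) != n || sum(col_marginals) != n) {
    rlang::abort("marginal vectors must each sum to n",
                 class = "bronchlus_domain_error")
  }
  if (n <= 0) {
    rlang::abort("n must be positive", class = "bronchlus_domain_error")
  }
  invisible(TRUE)
}

#' Chance-expected agreement from marginal counts
#'
#' Expected agreement under rater independence,
#' \eqn{P_e = \sum_i (r_i/n)(c_i/n)}, the denominator correction in Cohen's
#' kappa.
#'
#' @param row_marginals,col_marginals Category count vectors for the two
#'   raters, each summing to `n`.
#' @param n Total number of rated pairs.
#' @return Expected agreement proportion.
#' @export
#' @examples
#' expected_agreement(c(76, 27, 3, 0), c(68, 26, 3, 9), 106)
expected_agreement <- function(row_marginals, col_marginals, n) {
  check_marginals(row_marginals, col_marginals, n)
  sum((row_marginals / n) * (col_marginals / n))
}

#' Cohen's kappa from observed and expected agreement
#'
#' \eqn{\kappa = (P_o - P_e) / (1 - P_e)}: chance-corrected agreement, 1 at
#' perfect agreement, 0 at chance level.
#'
#' @param po Observed agreement proportion in \[0, 1\].
#' @param pe Expected (chance) agreement proportion in \[0, 1).
#' @return Kappa.
#' @export
#' @examples
#' cohen_kappa(0.9057, 0.5232)
cohen_kappa <- function(po, pe) {
  if (any(po < 0 | po > 1)) {
    rlang::abort("`po` must lie in [0, 1]", class = "bronchlus_domain_error")
  }
  if (any(pe < 0) || any(pe >= 1)) {
    rlang::abort("`pe` must lie in [0, 1); pe = 1 means degenerate marginals",
                 class = "bronchlus_degenerate_error")
  }
  (po - pe) / (1 - pe)
}

#' Standard error of kappa under the null hypothesis of chance agreement
#'
#' Large-sample standard error of Cohen's kappa under H0: kappa = 0,
#' \deqn{se_0 = \frac{\sqrt{P_e + P_e^2 - \sum_i p_{i\cdot} p_{\cdot i}
#'   (p_{i\cdot} + p_{\cdot i})}}{(1 - P_e)\sqrt{n}},}
#' where \eqn{p_{i\cdot}, p_{\cdot i}} are the marginal proportions. This is
#' the denominator of the standard kappa z test.
#'
#' @inheritParams expected_agreement
#' @return Positive standard error.
#' @export
#' @examples
#' kappa_se0(c(76, 27, 3, 0), c(68, 26, 3, 9), 106)
kappa_se0 <- function(row_marginals, col_marginals, n) {
  check_marginals(row_marginals, col_marginals, n)
  p <- row_marginals / n
  q <- col_marginals / n
  pe <- sum(p * q)
  if (pe >= 1) {
    rlang::abort("degenerate marginals: expected agreement is 1",
                 class = "bronchlus_degenerate_error")
  }
  sqrt(pe + pe^2 - sum(p * q * (p + q))) / ((1 - pe) * sqrt(n))
}

#' z test for kappa against chance agreement
#'
#' @param kappa Kappa estimate.
#' @param se0 Null standard error from [kappa_se0()].
#' @return Tibble with `z = kappa / se0` and the one-sided upper-tail normal
#'   `p.value`.
#' @export
#' @examples
#' kappa_z_test(0.8064, 0.0711)
kappa_z_test <- function(kappa, se0) {
  if (any(se0 <= 0)) {
    rlang::abort("`se0` must be positive", class = "bronchlus_domain_error")
  }
  z <- kappa / se0
  tibble::tibble(z = z, p.value = stats::pnorm(z, lower.tail = FALSE))
}

new_rater_agreement <- function(cm, comparison = NULL) {
  m <- check_cm(cm)
  n <- sum(m)
  rm_ <- rowSums(m)
  cm_ <- colSums(m)
  po <- sum(diag(m)) / n
  pe <- expected_agreement(rm_, cm_, n)
  if (pe >= 1 && po == 1) {
    # single-category degenerate table: agreement is perfect but chance
    # correction and the null test are undefined
    rlang::warn("degenerate marginals with perfect agreement; kappa set to 1, test undefined",
                class = "bronchlus_degenerate_warning")
    k <- 1
    se0 <- NA_real_
    zt <- tibble::tibble(z = NA_real_, p.value = NA_real_)
  } else {
    k <- cohen_kappa(po, pe)
    se0 <- kappa_se0(rm_, cm_, n)
    zt <- kappa_z_test(k, se0)
  }
  structure(
    list(confusion = m, n = n, po = po, pe = pe, kappa = k, se0 = se0,
         z = zt$z, p.value = zt$p.value, comparison = comparison),
    class = "rater_agreement"
  )
}

#' Inter-rater agreement with Cohen's kappa
#'
#' Cross-tabulates two raters' severity grades and computes observed and
#' chance-expected agreement, unweighted Cohen's kappa, its standard error
#' under the null hypothesis of chance agreement, and the one-sided z test.
#' Severity is ordinal but the agreement statistic is the plain unweighted
#' kappa.
#'
#' @param data Data frame with one row per rated subject.
#' @param rater_a,rater_b Columns holding each rater's grade (labels from
#'   [severity_levels()] or factors over them).
#' @param levels Shared ordered category labels.
#' @param comparison Optional label describing the rater pair.
#' @return A `rater_agreement` object; see [tidy.rater_agreement()] and
#'   [glance.rater_agreement()].
#' @export
#' @examples
#' d <- tibble::tibble(a = c("mild", "mild", "moderate"),
#'                     b = c("mild", "moderate", "moderate"))
#' rater_agreement(d, a, b)
rater_agreement <- function(data, rater_a, rater_b,
                            levels = severity_levels(), comparison = NULL) {
  a <- rlang::eval_tidy(rlang::enquo(rater_a), data)
  b <- rlang::eval_tidy(rlang::enquo(rater_b), data)
  new_rater_agreement(confusion_from_pairs(a, b, levels), comparison)
}

#' Kappa statistics from marginal counts and a diagonal count
#'
#' Reconstructs the full kappa report when only the two raters' marginal
#' grade counts and the number of agreeing pairs are known — the form in
#' which agreement studies are usually printed.
#'
#' @inheritParams expected_agreement
#' @param diagonal Number of pairs on which the raters agreed.
#' @param comparison Optional label.
#' @return A `rater_agreement` object without a stored confusion matrix
#'   (the joint distribution is not identified by the marginals).
#' @export
#' @examples
#' kappa_from_marginals(96, c(76, 27, 3, 0), c(68, 26, 3, 9), 106)
kappa_from_marginals <- function(diagonal, row_marginals, col_marginals, n,
                                 comparison = NULL) {
  check_marginals(row_marginals, col_marginals, n)
  if (diagonal < 0 || diagonal > n) {
    rlang::abort("`diagonal` must lie in [0, n]", class = "bronchlus_domain_error")
  }
  po <- diagonal / n
  pe <- expected_agreement(row_marginals, col_marginals, n)
  k <- cohen_kappa(po, pe)
  se0 <- kappa_se0(row_marginals, col_marginals, n)
  zt <- kappa_z_test(k, se0)
  structure(
    list(confusion = NULL, n = n, po = po, pe = pe, kappa = k, se0 = se0,
         z = zt$z, p.value = zt$p.value, comparison = comparison),
    class = "rater_agreement"
  )
}

#' @export
print.rater_agreement <- function(x, ...) {
  cat("Inter-rater agreement (Cohen's kappa)\n")
  if (!is.null(x$comparison)) cat("  comparison:", x$comparison, "\n")
  cat(sprintf("  n = %d pairs\n", x$n))
  cat(sprintf("  observed agreement  %.1f%%\n", 100 * x$po))
  cat(sprintf("  expected agreement  %.1f%%\n", 100 * x$pe))
  if (is.na(x$se0)) {
    cat(sprintf("  kappa = %.3f  (null test undefined: degenerate marginals)\n",
                x$kappa))
  } else {
    cat(sprintf("  kappa = %.3f  (se0 = %.4f, z = %.2f, one-sided p %s)\n",
                x$kappa, x$se0, x$z,
                if (x$p.value < 5e-4) "< 0.001" else sprintf("= %.3f", x$p.value)))
  }
  invisible(x)
}

#' Tidy an inter-rater agreement fit
#'
#' @param x A `rater_agreement` object.
#' @param ... Unused.
#' @return One-row tibble with the agreement proportions, kappa, its null
#'   standard error, the z statistic and one-sided p value.
#' @export
tidy.rater_agreement <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison %||% NA_character_,
    n = x$n,
    observed_agreement = x$po,
    expected_agreement = x$pe,
    kappa = x$kappa,
    se0 = x$se0,
    z = x$z,
    p.value = x$p.value
  )
}

#' @rdname tidy.rater_agreement
#' @export
glance.rater_agreement <- function(x, ...) {
  tidy.rater_agreement(x)[, c("n", "kappa", "se0", "z", "p.value")]
}

#' Plot an agreement confusion matrix
#'
#' @param object A `rater_agreement` built from paired ratings.
#' @param ... Unused.
#' @return A ggplot heat map of the confusion matrix with cell counts.
#' @export
autoplot.rater_agreement <- function(object, ...) {
  if (is.null(object$confusion)) {
    rlang::abort("no confusion matrix stored (fit was built from marginals)",
                 class = "bronchlus_domain_error")
  }
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("rater_a", "rater_b", "count")
  lv <- rownames(object$confusion)
  df$rater_a <- factor(df$rater_a, levels = lv)
  df$rater_b <- factor(df$rater_b, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_b, y = .data$rater_a,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "rater B", y = "rater A",
      title = sprintf("Agreement %.1f%%, kappa = %.2f",
                      100 * object$po, object$kappa)
    ) +
    ggplot2::theme_minimal()
}
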