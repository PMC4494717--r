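# independent chi-squared oracle: expected counts under independence,
# then the definition sum (obs - exp)^2 / exp
chi2_oracle <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

# shortcut form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chi2_shortcut <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  sum(m) * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("oxygen 2x2 tabulation counts predictions against outcomes", {
  d1 <- tibble::tibble(lus_total = 5, oxygen_required = TRUE)
  t1 <- oxygen_two_by_two(d1)
  expect_equal(unlist(t1[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))
  d2 <- tibble::tibble(lus_total = c(5, 1), oxygen_required = c(TRUE, FALSE))
  t2 <- oxygen_two_by_two(d2)
  expect_equal(unlist(t2[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  expect_error(oxygen_two_by_two(d2[0, ]), class = "bronchlus_domain_error")
  expect_error(two_by_two(-1, 0, 0, 2), class = "bronchlus_domain_error")
})

test_that("accuracy metrics reproduce the study's reconstructed table", {
  t <- two_by_two(28, 1, 1, 76)
  m <- binary_diagnostics(t)
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["sensitivity"]], 28 / 29, tolerance = 1e-12)
  expect_equal(est[["specificity"]], 76 / 77, tolerance = 1e-12)
  expect_equal(est[["ppv"]], 28 / 29, tolerance = 1e-12)
  expect_equal(est[["npv"]], 76 / 77, tolerance = 1e-12)
  expect_equal(round(100 * est, 1),
               c(sensitivity = 96.6, specificity = 98.7,
                 ppv = 96.6, npv = 98.7))

  perfect <- binary_diagnostics(two_by_two(10, 0, 0, 10))
  expect_true(all(perfect$estimate == 1))

  bad <- two_by_two(0, 0, 10, 10)
  expect_equal(sensitivity(bad)$estimate, 0)
  expect_equal(npv(bad)$estimate, 0.5)
  expect_error(ppv(bad), class = "bronchlus_undefined_metric_error")
  expect_error(ppv(bad), "ppv")
})

test_that("metrics from a cohort equal brute-force record counting", {
  set.seed(3)
  d <- tibble::tibble(lus_total = sample(0:8, 200, replace = TRUE),
                      oxygen_required = sample(c(TRUE, FALSE), 200,
                                               replace = TRUE))
  t <- oxygen_two_by_two(d)
  m <- binary_diagnostics(t)
  pred <- d$lus_total > 3
  expect_equal(m$estimate[m$metric == "sensitivity"],
               sum(pred & d$oxygen_required) / sum(d$oxygen_required))
  expect_equal(m$estimate[m$metric == "specificity"],
               sum(!pred & !d$oxygen_required) / sum(!d$oxygen_required))
  expect_equal(m$estimate[m$metric == "ppv"],
               sum(pred & d$oxygen_required) / sum(pred))
  expect_equal(m$estimate[m$metric == "npv"],
               sum(!pred & !d$oxygen_required) / sum(!pred))
})

test_that("Wilson interval matches its closed form and the printed CI", {
  ci <- wilson_interval(76, 77)
  expect_equal(ci$conf.low, 0.930, tolerance = 1e-3)
  expect_equal(ci$conf.high, 0.998, tolerance = 1e-3)
  ci50 <- wilson_interval(50, 100)
  expect_equal(ci50$conf.low, 0.4038, tolerance = 1e-4)
  expect_equal(ci50$conf.high, 0.5962, tolerance = 1e-4)
  edge <- wilson_interval(20, 20)
  expect_lt(edge$conf.low, 1)
  expect_lte(edge$conf.high, 1)
  expect_error(wilson_interval(5, 4), class = "bronchlus_domain_error")
})

test_that("Clopper-Pearson interval matches the beta quantile closed form", {
  ci <- clopper_pearson_interval(29, 29)
  expect_equal(ci$conf.low, 0.025^(1 / 29), tolerance = 1e-12)
  expect_equal(ci$conf.high, 1)
  expect_equal(clopper_pearson_interval(0, 10)$conf.low, 0)
  expect_equal(clopper_pearson_interval(28, 29)$conf.low, 0.822,
               tolerance = 1e-3)
})

test_that("both intervals contain the point estimate; exact is never narrower", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    w <- wilson_interval(x, n)
    cp <- clopper_pearson_interval(x, n)
    p <- x / n
    expect_true(w$conf.low <= p && p <= w$conf.high)
    expect_true(cp$conf.low <= p && p <= cp$conf.high)
    if (x > 0 && x < n) {
      expect_gte(cp$conf.high - cp$conf.low, w$conf.high - w$conf.low)
    }
  }
})

test_that("group counts expand into the expected 2x2 tables", {
  expect_equal(unname(two_by_two_from_groups(61, 76, 3, 30)),
               matrix(c(61L, 15L, 3L, 27L), 2, byrow = TRUE))
  expect_equal(unname(two_by_two_from_groups(0, 5, 5, 5)),
               matrix(c(0L, 5L, 5L, 0L), 2, byrow = TRUE))
  expect_equal(unname(two_by_two_from_groups(4, 77, 12, 29)),
               matrix(c(4L, 73L, 12L, 17L), 2, byrow = TRUE))
  expect_error(two_by_two_from_groups(6, 5, 1, 3),
               class = "bronchlus_domain_error")
})

test_that("uncorrected chi-squared reproduces printed contingency statistics", {
  r1 <- suppressWarnings(pearson_chi2_2x2(two_by_two_from_groups(61, 76, 3, 30)))
  expect_equal(r1$statistic, 44.4, tolerance = 1e-2)
  expect_equal(r1$df, 1)
  r0 <- pearson_chi2_2x2(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  r6 <- pearson_chi2_2x2(two_by_two_from_groups(27, 33, 37, 73))
  expect_equal(r6$statistic, 9.21, tolerance = 1e-3)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2)),
               class = "bronchlus_degenerate_error")
  expect_warning(pearson_chi2_2x2(matrix(c(2, 3, 4, 3), 2)),
                 class = "bronchlus_expected_count_warning")
})

test_that("chi-squared equals both the shortcut and expected-count oracles", {
  set.seed(21)
  for (i in 1:40) {
    m <- matrix(rpois(4, 8) + 1, 2, 2)
    got <- suppressWarnings(pearson_chi2_2x2(m))$statistic
    expect_equal(got, chi2_oracle(m), tolerance = 1e-10)
    expect_equal(got, chi2_shortcut(m), tolerance = 1e-10)
    # swapping rows or columns leaves the statistic unchanged
    expect_equal(suppressWarnings(pearson_chi2_2x2(m[2:1, ]))$statistic, got,
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(pearson_chi2_2x2(m[, 2:1]))$statistic, got,
                 tolerance = 1e-10)
  }
})

test_that("the comparison battery carries rows through and skips degenerate ones", {
  rows <- tibble::tibble(label = c("a", "b"),
                         pos_a = c(61, 0), n_a = c(76, 5),
                         pos_b = c(3, 0), n_b = c(30, 5))
  expect_warning(out <- compare_groups(rows), "degenerate")
  expect_equal(out$label, c("a", "b"))
  expect_equal(out$statistic[1], 44.4, tolerance = 1e-2)
  expect_true(is.na(out$statistic[2]))
})
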