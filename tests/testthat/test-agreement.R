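# brute-force kappa oracle: marginal-proportion arithmetic written out
# independently of the package's formulas
kappa_oracle <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- 0
  for (i in seq_len(nrow(m))) pe <- pe + (sum(m[i, ]) / n) * (sum(m[, i]) / n)
  (po - pe) / (1 - pe)
}

test_that("pair tabulation fills a fixed 4x4 grid", {
  cm <- confusion_from_pairs(c("mild", "mild"), c("mild", "moderate"))
  expect_equal(dim(cm), c(4, 4))
  expect_equal(sum(cm), 2)
  expect_equal(sum(diag(cm)), 1)

  cm <- confusion_from_pairs(rep("mild", 106), rep("mild", 106))
  expect_equal(sum(diag(cm)), 106)

  grid <- expand.grid(a = severity_levels(), b = severity_levels())
  cm <- confusion_from_pairs(grid$a, grid$b)
  expect_true(all(cm == 1))

  expect_error(confusion_from_pairs("mild", "critical"),
               class = "bronchlus_domain_error")
  expect_error(confusion_from_pairs(character(), character()),
               class = "bronchlus_domain_error")
  expect_error(confusion_from_pairs(c("mild", NA), c("mild", "mild")),
               class = "bronchlus_domain_error")
})

test_that("observed agreement is the diagonal proportion", {
  expect_equal(observed_agreement(diag(c(5, 3, 2))), 1)
  expect_equal(observed_agreement(matrix(1, 4, 4)), 0.25)
  m <- diag(c(70, 23, 3, 0))
  m[1, 2] <- 10
  expect_equal(observed_agreement(m), 96 / 106, tolerance = 1e-12)
})

test_that("expected agreement reproduces the study's printed values", {
  expect_equal(expected_agreement(c(76, 27, 3, 0), c(68, 26, 3, 9), 106),
               0.5232, tolerance = 1e-4)
  expect_equal(expected_agreement(c(68, 26, 3, 9), c(65, 26, 3, 12), 106),
               0.4640, tolerance = 1e-4)
  expect_equal(expected_agreement(c(10, 0, 0, 0), c(10, 0, 0, 0), 10), 1)
  expect_error(expected_agreement(c(5, 5), c(4, 4), 10),
               class = "bronchlus_domain_error")
})

test_that("kappa is the chance-corrected agreement ratio", {
  expect_equal(cohen_kappa(0.9057, 0.5232), 0.802, tolerance = 1e-3)
  expect_equal(cohen_kappa(0.3, 0.3), 0)
  expect_equal(cohen_kappa(1, 0.9), 1)
  expect_error(cohen_kappa(0.5, 1), class = "bronchlus_degenerate_error")
})

test_that("null standard error matches printed values and its closed form", {
  expect_equal(kappa_se0(c(76, 27, 3, 0), c(68, 26, 3, 9), 106),
               0.0765, tolerance = 1e-3)
  expect_equal(kappa_se0(c(68, 26, 3, 9), c(65, 26, 3, 12), 106),
               0.0711, tolerance = 1e-3)
  # two balanced categories: se0 = sqrt(Pe + Pe^2 - 0.5) / ((1-Pe) sqrt(n))
  # with Pe = 0.5 collapses to 0.5 / (0.5 * 10) = 0.1
  expect_equal(kappa_se0(c(50, 50), c(50, 50), 100), 0.1, tolerance = 1e-12)
  expect_error(kappa_se0(c(10, 0), c(10, 0), 10),
               class = "bronchlus_degenerate_error")
})

test_that("z test divides kappa by its null standard error", {
  zt <- kappa_z_test(0.8064088, 0.07114456)
  expect_equal(zt$z, 11.33, tolerance = 1e-3)
  zt0 <- kappa_z_test(0, 0.1)
  expect_equal(zt0$z, 0)
  expect_equal(zt0$p.value, 0.5)
  zt2 <- kappa_z_test(0.196, 0.1)
  expect_equal(zt2$z, 1.96)
  expect_equal(zt2$p.value, 0.025, tolerance = 1e-3)
  expect_error(kappa_z_test(0.5, 0), class = "bronchlus_domain_error")
})

test_that("formula kappa equals the brute-force oracle on random tables", {
  set.seed(11)
  for (i in 1:40) {
    m <- matrix(rpois(9, 2), 3, 3)
    if (sum(m) == 0 || sum(diag(m)) == sum(m)) next
    fit <- rater_agreement(
      tibble::tibble(
        a = rep(rep(c("mild", "moderate", "severe"), each = 3), c(t(m))),
        b = rep(rep(c("mild", "moderate", "severe"), times = 3), c(t(m)))
      ),
      a, b, levels = c("mild", "moderate", "severe")
    )
    expect_equal(fit$kappa, kappa_oracle(fit$confusion), tolerance = 1e-12)
    # expected agreement of the marginals equals that of the independence table
    ind <- outer(rowSums(fit$confusion), colSums(fit$confusion)) / sum(m)
    expect_equal(fit$pe, sum(diag(ind)) / sum(ind), tolerance = 1e-12)
  }
})

test_that("identical ratings give kappa 1 whatever the category mix", {
  d <- tibble::tibble(g = rep(c("mild", "moderate", "severe"), c(12, 5, 2)))
  fit <- rater_agreement(d, g, g)
  expect_equal(fit$kappa, 1)
  expect_equal(fit$po, 1)
})

test_that("se0 scales as 1 / sqrt(n) at fixed marginal proportions", {
  s1 <- kappa_se0(c(30, 20), c(25, 25), 50)
  s4 <- kappa_se0(4 * c(30, 20), 4 * c(25, 25), 200)
  expect_equal(s1 / s4, 2, tolerance = 1e-12)
})

test_that("marginal-only fits agree with full-table fits", {
  set.seed(5)
  m <- matrix(rpois(16, 3) + 1, 4, 4)
  fit_full <- bronchlus:::new_rater_agreement(m)
  fit_marg <- kappa_from_marginals(sum(diag(m)), rowSums(m), colSums(m), sum(m))
  expect_equal(fit_marg$kappa, fit_full$kappa, tolerance = 1e-12)
  expect_equal(fit_marg$se0, fit_full$se0, tolerance = 1e-12)
  expect_equal(fit_marg$z, fit_full$z, tolerance = 1e-12)
})

test_that("a single-category table yields kappa 1 with an undefined test", {
  d <- tibble::tibble(g = rep("mild", 20))
  expect_warning(fit <- rater_agreement(d, g, g),
                 class = "bronchlus_degenerate_warning")
  expect_equal(fit$kappa, 1)
  expect_true(is.na(fit$se0))
})

test_that("tidy and glance return one-row summaries", {
  d <- tibble::tibble(a = c("mild", "mild", "moderate", "severe"),
                      b = c("mild", "moderate", "moderate", "severe"))
  fit <- rater_agreement(d, a, b, comparison = "demo")
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_equal(td$comparison, "demo")
  expect_equal(td$observed_agreement, 0.75)
  expect_named(glance(fit), c("n", "kappa", "se0", "z", "p.value"))
})
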