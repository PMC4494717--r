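#' Printed counts of the reference bronchiolitis agreement study
#'
#' Bundles every printed count the package can recompute statistics from:
#' the severity-grade marginals behind the two kappa analyses (with the
#' number of agreeing pairs implied by the printed observed agreement), the
#' oxygen-need 2x2 table reconstructed from the printed accuracy metrics
#' (the unique integer table with n = 106 and 29 oxygen-positive infants
#' matching sensitivity 96.6% and specificity 98.7%), and all printed
#' group-comparison rows with their chi-squared statistics.
#'
#' Two printed values are known not to follow from their own printed
#' counts and are flagged, not reproduced: the first kappa's z (10.19,
#' inconsistent with the printed kappa and standard error) and the
#' chi-squared 26.4 for consolidation >= 1 cm stratified by severity
#' (its counts give 26.0); the latter row carries
#' `known_discrepancy = TRUE`.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{kappa}{named list of two comparisons, each with `diagonal`,
#'       `row_marginals`, `col_marginals`, `n` and the printed statistics.}
#'     \item{oxygen_2x2}{a [two_by_two()] table (28, 1, 1, 76).}
#'     \item{oxygen_printed}{printed accuracy percentages and CI bounds.}
#'     \item{group_comparisons}{tibble of printed contingency rows
#'       (see `inst/extdata/group_comparisons.csv`).}
#'   }
#' @export
#' @examples
#' fx <- paper_fixtures()
#' fx$kappa$clinical_vs_pediatric$row_marginals
paper_fixtures <- function() {
  path <- system.file("extdata", "group_comparisons.csv", package = "bronchlus",
                      mustWork = TRUE)
  gc <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          printed_p = readr::col_character(),
                          known_discrepancy = readr::col_logical(),
                          .default = readr::col_guess()))
  list(
    kappa = list(
      clinical_vs_pediatric = list(
        comparison = "attending physician vs pediatric sonographer",
        diagonal = 96L,
        row_marginals = c(normal = 0L, mild = 76L, moderate = 27L, severe = 3L),
        col_marginals = c(normal = 9L, mild = 68L, moderate = 26L, severe = 3L),
        n = 106L,
        printed = list(observed_agreement = 0.906, expected_agreement = 0.523,
                       kappa = 0.8, se0 = 0.0765)
      ),
      pediatric_vs_radiologist = list(
        comparison = "pediatric vs radiologist sonographer",
        diagonal = 95L,
        row_marginals = c(normal = 9L, mild = 68L, moderate = 26L, severe = 3L),
        col_marginals = c(normal = 12L, mild = 65L, moderate = 26L, severe = 3L),
        n = 106L,
        printed = list(observed_agreement = 0.896, expected_agreement = 0.464,
                       kappa = 0.8, se0 = 0.07, z = 11.33)
      )
    ),
    oxygen_2x2 = two_by_two(tp = 28L, fp = 1L, fn = 1L, tn = 76L),
    oxygen_printed = list(
      sensitivity = 96.6, specificity = 98.7, ppv = 96.6, npv = 98.7,
      specificity_ci = c(93, 99.8), sensitivity_ci = c(82.2, 99.4)
    ),
    group_comparisons = gc
  )
}

#' Recompute the study's printed statistics from its printed counts
#'
#' Runs the package's agreement, accuracy and contingency machinery on the
#' packaged fixture counts and compares each recomputed statistic with the
#' printed value. Kappa quantities are compared at 1% relative tolerance
#' (the printing precision); chi-squared statistics at an absolute 0.105,
#' which covers one-decimal truncation; rows whose printed statistic is
#' known not to follow from its own printed counts are reported with
#' `match = FALSE`.
#'
#' @param fixtures Fixture bundle from [paper_fixtures()].
#' @return Tibble with columns `quantity`, `computed`, `printed`, `match`.
#' @export
#' @examples
#' reproduce_study()
reproduce_study <- function(fixtures = paper_fixtures()) {
  rows <- list()
  for (id in names(fixtures$kappa)) {
    k <- fixtures$kappa[[id]]
    fit <- kappa_from_marginals(k$diagonal, k$row_marginals, k$col_marginals,
                                k$n, comparison = k$comparison)
    pr <- k$printed
    add <- function(quantity, computed, printed) {
      tibble::tibble(quantity = paste0(id, "_", quantity),
                     computed = computed, printed = printed)
    }
    rows <- c(rows, list(
      add("observed_agreement_pct", 100 * fit$po, 100 * pr$observed_agreement),
      add("expected_agreement_pct", 100 * fit$pe, 100 * pr$expected_agreement),
      add("kappa", fit$kappa, pr$kappa),
      add("se0", fit$se0, pr$se0)
    ))
    if (!is.null(pr$z)) rows <- c(rows, list(add("z", fit$z, pr$z)))
  }

  t <- fixtures$oxygen_2x2
  acc_w <- binary_diagnostics(t, ci_method = "wilson")
  acc_cp <- binary_diagnostics(t, ci_method = "clopper-pearson")
  pr <- fixtures$oxygen_printed
  rows <- c(rows, list(
    tibble::tibble(quantity = paste0(acc_w$metric, "_pct"),
                   computed = 100 * acc_w$estimate,
                   printed = unlist(pr[acc_w$metric])),
    tibble::tibble(
      quantity = c("specificity_ci_low_pct", "specificity_ci_high_pct",
                   "sensitivity_ci_low_pct"),
      computed = c(100 * acc_w$conf.low[acc_w$metric == "specificity"],
                   100 * acc_w$conf.high[acc_w$metric == "specificity"],
                   100 * acc_cp$conf.low[acc_cp$metric == "sensitivity"]),
      printed = c(pr$specificity_ci, pr$sensitivity_ci[1])
    )
  ))
  kappa_tbl <- dplyr::bind_rows(rows) |>
    dplyr::mutate(match = abs(.data$computed - .data$printed) <=
                    pmax(0.01 * abs(.data$printed), 0.05))

  chi <- compare_groups(fixtures$group_comparisons) |>
    dplyr::transmute(
      quantity = paste("chi2", .data$table, .data$stratification,
                       .data$finding, sep = "_"),
      computed = .data$statistic,
      printed = .data$printed_chi2,
      match = abs(.data$computed - .data$printed) <= 0.105 &
        !.data$known_discrepancy
    )

  dplyr::bind_rows(kappa_tbl, chi)
}
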