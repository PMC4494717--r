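precoded_item_cols <- function() {
  c("respiratory_rate_item", "dyspnea_item", "accessory_muscle_item",
    "auscultation_item",
    "lus1_anterolateral_item", "lus1_posterior_interstitial_item",
    "lus1_extension_item", "lus1_consolidation_item",
    "lus2_anterolateral_item", "lus2_posterior_interstitial_item",
    "lus2_extension_item", "lus2_consolidation_item")
}

raw_obs_cols <- function() {
  c("respiratory_rate", "dyspnea_item", "accessory_muscle_item",
    "auscultation_item",
    "lus1_anterolateral_item", "lus1_posterior_interstitial_item",
    "lus1_extension_spaces", "lus1_consolidation_size_cm",
    "lus2_anterolateral_item", "lus2_posterior_interstitial_item",
    "lus2_extension_spaces", "lus2_consolidation_size_cm")
}

validate_items <- function(data, cols, maxes) {
  rows <- seq_len(nrow(data))
  for (i in seq_along(cols)) {
    data[[cols[i]]] <- check_item(data[[cols[i]]], cols[i], maxes[i], rows)
  }
  data
}

#' Read a cohort CSV
#'
#' Reads one-row-per-infant cohort files in either of two schemas:
#' `"precoded_items"`, where all score items are already coded on their
#' ordinal scales (the form produced by [write_cohort_csv()] and
#' [generate_cohort()]), or `"raw_observations"`, where the respiratory rate
#' is in breaths/min, the interstitial extension is a count of involved
#' intercostal spaces and the consolidation is a size in cm (empty for
#' absent); raw observations are passed through the item encoders. The
#' dyspnea, accessory-muscle and auscultation items are bedside judgments
#' and must be pre-coded in both schemas.
#'
#' @param path CSV file (UTF-8, comma separated, header required).
#' @param schema_mode `"precoded_items"` or `"raw_observations"`.
#' @return Validated cohort tibble in the pre-coded schema.
#' @export
read_cohort_csv <- function(path,
                            schema_mode = c("precoded_items", "raw_observations")) {
  schema_mode <- match.arg(schema_mode)
  if (!file.exists(path)) {
    rlang::abort(sprintf("cohort file not found: %s", path),
                 class = "bronchlus_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "oxygen_required",
              if (schema_mode == "precoded_items") precoded_item_cols()
              else raw_obs_cols())
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("cohort file is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "bronchlus_schema_error")
  }
  if (!is.logical(data$oxygen_required) || anyNA(data$oxygen_required)) {
    rlang::abort("`oxygen_required` must parse as TRUE/FALSE with no blanks",
                 class = "bronchlus_schema_error")
  }
  if (schema_mode == "raw_observations") {
    data$respiratory_rate_item <- encode_respiratory_rate(data$respiratory_rate)
    for (r in c("lus1", "lus2")) {
      data[[paste0(r, "_extension_item")]] <-
        encode_extension(data[[paste0(r, "_extension_spaces")]])
      data[[paste0(r, "_consolidation_item")]] <-
        encode_consolidation(data[[paste0(r, "_consolidation_size_cm")]])
    }
  }
  maxes <- c(3, 3, 3, 3, rep(2, 8))
  data <- validate_items(data, precoded_item_cols(), maxes)
  if (!"is_control" %in% names(data)) data$is_control <- FALSE
  if ("severity_true" %in% names(data) && is.character(data$severity_true)) {
    data$severity_true <- severity_grade(data$severity_true)
  }
  tibble::as_tibble(data)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble in the pre-coded schema.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  if ("severity_true" %in% names(out)) {
    out$severity_true <- as.character(out$severity_true)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

score_cohort <- function(cohort, rr_boundary_70 = 3L) {
  cohort |>
    score_clinical() |>
    score_lus(anterolateral_item = lus1_anterolateral_item,
              posterior_interstitial_item = lus1_posterior_interstitial_item,
              extension_item = lus1_extension_item,
              consolidation_item = lus1_consolidation_item,
              prefix = "lus1_") |>
    score_lus(anterolateral_item = lus2_anterolateral_item,
              posterior_interstitial_item = lus2_posterior_interstitial_item,
              extension_item = lus2_extension_item,
              consolidation_item = lus2_consolidation_item,
              prefix = "lus2_")
}

finding_definitions <- function() {
  tibble::tibble(
    finding = c("extension_lt6_spaces", "extension_6_12_spaces",
                "extension_gt12_spaces",
                "consolidation_none", "consolidation_subcm",
                "consolidation_ge1cm",
                "anterolateral_normal", "anterolateral_diffuse_spared",
                "anterolateral_diffuse_consolidation"),
    item = rep(c("lus1_extension_item", "lus1_consolidation_item",
                 "lus1_anterolateral_item"), each = 3),
    level = rep(0:2, 3)
  )
}

comparison_battery <- function(scored_cases) {
  defs <- finding_definitions()
  strata <- list(
    severity = list(a = scored_cases$clinical_grade == "mild",
                    b = scored_cases$clinical_grade %in% c("moderate", "severe"),
                    group_a = "mild", group_b = "moderate_severe"),
    oxygen = list(a = !scored_cases$oxygen_required,
                  b = scored_cases$oxygen_required,
                  group_a = "no_oxygen", group_b = "oxygen")
  )
  if ("srv_positive" %in% names(scored_cases)) {
    strata$srv <- list(a = !scored_cases$srv_positive,
                       b = scored_cases$srv_positive,
                       group_a = "srv_negative", group_b = "srv_positive")
  }
  rows <- purrr::imap(strata, function(s, nm) {
    defs |>
      dplyr::mutate(
        stratification = nm, group_a = s$group_a, group_b = s$group_b,
        pos_a = purrr::map2_int(.data$item, .data$level,
          ~ sum(scored_cases[[.x]][s$a] == .y)),
        n_a = sum(s$a),
        pos_b = purrr::map2_int(.data$item, .data$level,
          ~ sum(scored_cases[[.x]][s$b] == .y)),
        n_b = sum(s$b)
      )
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("stratification", "finding", "group_a", "group_b",
                  "pos_a", "n_a", "pos_b", "n_b") |>
    compare_groups()
}

# like binary_diagnostics() but a zero-denominator metric becomes an NA row
# with a warning instead of aborting the whole report
safe_binary_diagnostics <- function(t, ci_method, conf_level) {
  fns <- list(sensitivity = sensitivity, specificity = specificity,
              ppv = ppv, npv = npv)
  out <- purrr::imap(fns, function(f, nm) {
    tryCatch(f(t, ci_method = ci_method, conf_level = conf_level),
             bronchlus_undefined_metric_error = function(e) {
               rlang::warn(sprintf("%s is undefined for this cohort (zero denominator)", nm))
               tibble::tibble(metric = nm, numerator = NA_integer_,
                              denominator = 0L, estimate = NA_real_,
                              conf.low = NA_real_, conf.high = NA_real_,
                              ci_method = ci_method, conf_level = conf_level)
             })
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("binary_diagnostics", class(out))
  out
}

#' Run the full agreement and accuracy analysis on a cohort
#'
#' Scores every infant on both scales, cross-tabulates the clinical grade
#' against the first sonographer's LUS grade and the two sonographers
#' against each other (Cohen's kappa with null standard error and z test,
#' bronchiolitis cases only), evaluates the oxygen-need rule (2x2 table and
#' sensitivity/specificity/PPV/NPV with binomial confidence intervals), and
#' runs the chi-squared battery comparing each LUS finding between mild and
#' moderate-severe disease, between infants with and without an oxygen
#' requirement, and between SRV-positive and SRV-negative infants.
#' Degenerate comparisons (an empty group) are skipped with a warning.
#'
#' @param cohort Cohort tibble in the pre-coded schema (see
#'   [generate_cohort()] / [read_cohort_csv()]).
#' @param oxygen_threshold LUS-total threshold of the oxygen rule.
#' @param ci_method Binomial CI method for the accuracy metrics.
#' @param conf_level Confidence level for those intervals.
#' @return A `lus_analysis` object: scored cohort, per-rater grade counts,
#'   `rater_agreement` fits, oxygen diagnostics and the comparison battery.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_cases = 60, n_controls = 10))
#' run_analysis(cohort)
run_analysis <- function(cohort, oxygen_threshold = 3,
                         ci_method = c("wilson", "clopper-pearson"),
                         conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (nrow(cohort) == 0) {
    rlang::abort("cannot analyse an empty cohort", class = "bronchlus_domain_error")
  }
  scored <- score_cohort(cohort)
  cases <- scored[!scored$is_control, , drop = FALSE]
  if (nrow(cases) == 0) {
    rlang::abort("cohort contains no bronchiolitis cases",
                 class = "bronchlus_domain_error")
  }

  score_summary <- dplyr::bind_rows(
    dplyr::count(scored, grade = .data$clinical_grade, .drop = FALSE) |>
      dplyr::mutate(rater = "clinical", .before = 1),
    dplyr::count(scored, grade = .data$lus1_grade, .drop = FALSE) |>
      dplyr::mutate(rater = "lus_rater1", .before = 1),
    dplyr::count(scored, grade = .data$lus2_grade, .drop = FALSE) |>
      dplyr::mutate(rater = "lus_rater2", .before = 1)
  )

  kappa_fits <- list(
    clinical_vs_rater1 = rater_agreement(
      cases, .data$clinical_grade, .data$lus1_grade,
      comparison = "clinical vs LUS rater 1"),
    rater1_vs_rater2 = rater_agreement(
      cases, .data$lus1_grade, .data$lus2_grade,
      comparison = "LUS rater 1 vs rater 2")
  )

  oxy_tab <- oxygen_two_by_two(cases, .data$lus1_total, .data$oxygen_required,
                               threshold = oxygen_threshold)
  oxy_metrics <- safe_binary_diagnostics(oxy_tab, ci_method = ci_method,
                                         conf_level = conf_level)

  comparisons <- comparison_battery(cases)

  structure(list(
    cohort = scored,
    n = nrow(scored), n_cases = nrow(cases),
    score_summary = score_summary,
    kappa = kappa_fits,
    oxygen = list(table = oxy_tab, metrics = oxy_metrics),
    comparisons = comparisons,
    config = list(oxygen_threshold = oxygen_threshold, ci_method = ci_method,
                  conf_level = conf_level,
                  package_version = as.character(utils::packageVersion("bronchlus")))
  ), class = "lus_analysis")
}

#' @export
print.lus_analysis <- function(x, ...) {
  cat(sprintf("LUS bronchiolitis analysis: %d infants (%d cases)\n",
              x$n, x$n_cases))
  cat("\nGrade counts\n")
  print(tidyr::pivot_wider(x$score_summary, names_from = "grade",
                           values_from = "n"))
  cat("\n")
  for (fit in x$kappa) print(fit)
  cat("\nOxygen-need rule (LUS total >", x$config$oxygen_threshold, ")\n")
  m <- x$oxygen$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %5.1f%%  (%d/%d, %.0f%% CI %.1f-%.1f%%)\n",
                m$metric[i], 100 * m$estimate[i], m$numerator[i],
                m$denominator[i], 100 * m$conf_level[i],
                100 * m$conf.low[i], 100 * m$conf.high[i]))
  }
  ns <- sum(!is.na(x$comparisons$statistic))
  cat(sprintf("\nGroup comparisons: %d of %d chi-squared tests computed\n",
              ns, nrow(x$comparisons)))
  invisible(x)
}

#' Tidy / summarise a cohort analysis
#'
#' `tidy()` returns the chi-squared comparison battery, one row per finding
#' and stratification; `glance()` returns a one-row headline summary.
#'
#' @param x A `lus_analysis` object.
#' @param ... Unused.
#' @export
tidy.lus_analysis <- function(x, ...) {
  x$comparisons
}

#' @rdname tidy.lus_analysis
#' @export
glance.lus_analysis <- function(x, ...) {
  m <- x$oxygen$metrics
  tibble::tibble(
    n = x$n, n_cases = x$n_cases,
    kappa_clinical_vs_rater1 = x$kappa$clinical_vs_rater1$kappa,
    kappa_rater1_vs_rater2 = x$kappa$rater1_vs_rater2$kappa,
    sensitivity = m$estimate[m$metric == "sensitivity"],
    specificity = m$estimate[m$metric == "specificity"],
    ppv = m$estimate[m$metric == "ppv"],
    npv = m$estimate[m$metric == "npv"]
  )
}

#' Plot the grade distribution of an analysed cohort
#'
#' @param object A `lus_analysis` object.
#' @param ... Unused.
#' @return A ggplot bar chart of grade counts per rater.
#' @export
autoplot.lus_analysis <- function(object, ...) {
  ggplot2::ggplot(object$score_summary,
                  ggplot2::aes(x = .data$grade, y = .data$n,
                               fill = .data$rater)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "severity grade", y = "infants",
                  title = "Severity grading by assessment") +
    ggplot2::theme_minimal()
}
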