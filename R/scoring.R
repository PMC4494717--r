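#' Severity grade levels
#'
#' Both the clinical score and the lung-ultrasound (LUS) score band their
#' totals into the same four ordered severity grades. Grade `"normal"` means
#' a healthy infant (clinical total 0) or a normal ultrasound pattern
#' (LUS total 0).
#'
#' @return Character vector of the four grade labels, lowest first.
#' @export
#' @examples
#' severity_levels()
severity_levels <- function() {
  c("normal", "mild", "moderate", "severe")
}

#' Build an ordered severity factor
#'
#' @param x Character labels from [severity_levels()] or integer ordinal
#'   codes 0-3 (0 = normal, 3 = severe).
#' @return Ordered factor over the four severity levels.
#' @export
#' @examples
#' severity_grade(c(0, 2))
#' severity_grade(c("mild", "severe"))
severity_grade <- function(x) {
  lv <- severity_levels()
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x != as.integer(x) | x < 0 | x > 3)
    if (any(bad)) {
      rlang::abort(
        sprintf("severity ordinal codes must be integers in 0-3 (got %s)",
                paste(unique(x[bad]), collapse = ", ")),
        class = "bronchlus_domain_error"
      )
    }
    x <- lv[as.integer(x) + 1L]
  }
  bad <- !is.na(x) & !x %in% lv
  if (any(bad)) {
    rlang::abort(
      sprintf("unknown severity label(s): %s",
              paste(unique(x[bad]), collapse = ", ")),
      class = "bronchlus_domain_error"
    )
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' @rdname severity_grade
#' @param grade Ordered severity factor (or labels coercible to one).
#' @return `severity_code()`: integer ordinal codes 0-3.
#' @export
severity_code <- function(grade) {
  as.integer(severity_grade(as.character(grade))) - 1L
}

check_item <- function(x, name, max, rows = NULL) {
  bad <- which(!is.na(x) & (x != round(x) | x < 0 | x > max))
  if (length(bad)) {
    where <- if (is.null(rows)) bad else rows[bad]
    rlang::abort(
      sprintf("`%s` must be an integer in 0-%d; offending row(s): %s",
              name, max, paste(utils::head(where, 5), collapse = ", ")),
      class = "bronchlus_domain_error"
    )
  }
  as.integer(x)
}

#' Encode a raw respiratory rate as a clinical score item
#'
#' Bands: < 50 breaths/min scores 0, 50-60 scores 1, 61-69 scores 2 and
#' >= 70 scores 3. The published rubric leaves exactly 70 unassigned between
#' its "61-69" and "> 70" bands; by default 70 is scored in the higher band,
#' the usual severity-rounds-up convention, controllable via `boundary_70`.
#'
#' @param rr Respiratory rate in breaths per minute, non-negative. Vectorised.
#' @param boundary_70 Item value assigned to exactly 70 breaths/min
#'   (2 or 3, default 3).
#' @return Integer vector of item scores 0-3.
#' @export
#' @examples
#' encode_respiratory_rate(c(45, 50, 60, 61, 69, 70, 80))
encode_respiratory_rate <- function(rr, boundary_70 = 3L) {
  if (!boundary_70 %in% c(2L, 3L)) {
    rlang::abort("`boundary_70` must be 2 or 3", class = "bronchlus_config_error")
  }
  if (any(rr < 0, na.rm = TRUE)) {
    rlang::abort("respiratory rate must be non-negative",
                 class = "bronchlus_domain_error")
  }
  out <- ifelse(rr < 50, 0L,
         ifelse(rr <= 60, 1L,
         ifelse(rr < 70, 2L, 3L)))
  out[!is.na(rr) & rr == 70] <- as.integer(boundary_70)
  as.integer(out)
}

#' Encode interstitial-syndrome extension as a LUS score item
#'
#' The extension component counts posterior intercostal spaces showing
#' bilateral interstitial syndrome. The published bands ("0-6", "6-12",
#' "> 12") overlap at 6 and 12; the default rule gives shared endpoints to
#' the lower band (0-6 scores 0, 7-12 scores 1, 13+ scores 2). `rule =
#' "upper"` gives them to the higher band instead (0-5, 6-11, 12+).
#'
#' @param n_spaces Non-negative integer count of bilaterally involved
#'   posterior intercostal spaces. Vectorised.
#' @param rule `"lower"` (default) or `"upper"`; which band wins a shared
#'   endpoint.
#' @return Integer vector of item scores 0-2.
#' @export
#' @examples
#' encode_extension(c(0, 6, 7, 12, 13))
encode_extension <- function(n_spaces, rule = c("lower", "upper")) {
  rule <- match.arg(rule)
  bad <- !is.na(n_spaces) & (n_spaces < 0 | n_spaces != round(n_spaces))
  if (any(bad)) {
    rlang::abort("`n_spaces` must be a non-negative integer count",
                 class = "bronchlus_domain_error")
  }
  cuts <- if (rule == "lower") c(6, 12) else c(5, 11)
  as.integer(ifelse(n_spaces <= cuts[1], 0L, ifelse(n_spaces <= cuts[2], 1L, 2L)))
}

#' Encode subpleural consolidation size as a LUS score item
#'
#' Absent consolidation scores 0, a subcentimeter consolidation scores 1 and
#' a consolidation of 1 cm or more scores 2 (inclusive at 1 cm).
#'
#' @param max_size_cm Largest posterior subpleural consolidation in cm;
#'   `NA` means no consolidation seen. Vectorised.
#' @return Integer vector of item scores 0-2.
#' @export
#' @examples
#' encode_consolidation(c(NA, 0.6, 1.0, 2.3))
encode_consolidation <- function(max_size_cm) {
  bad <- !is.na(max_size_cm) & max_size_cm <= 0
  if (any(bad)) {
    rlang::abort(
      "a stated consolidation size must be positive; use NA for absent",
      class = "bronchlus_domain_error"
    )
  }
  out <- ifelse(is.na(max_size_cm), 0L, ifelse(max_size_cm < 1, 1L, 2L))
  as.integer(out)
}

#' Band a clinical score total into a severity grade
#'
#' Clinical total 0 grades normal (healthy infant), 1-4 mild, 5-8 moderate
#' and 9-12 severe.
#'
#' @param total Integer clinical score totals in 0-12. Vectorised.
#' @return Ordered severity factor.
#' @export
#' @examples
#' grade_clinical(c(0, 4, 5, 9))
grade_clinical <- function(total) {
  total <- check_item(total, "clinical total", 12)
  severity_grade(ifelse(total == 0, 0L,
                 ifelse(total <= 4, 1L,
                 ifelse(total <= 8, 2L, 3L))))
}

#' Band a LUS score total into a severity grade
#'
#' LUS total 0 grades normal (normal ultrasound pattern), 1-3 mild,
#' 4-6 moderate and 7-8 severe.
#'
#' @param total Integer LUS score totals in 0-8. Vectorised.
#' @return Ordered severity factor.
#' @export
#' @examples
#' grade_lus(c(0, 3, 4, 7))
grade_lus <- function(total) {
  total <- check_item(total, "LUS total", 8)
  severity_grade(ifelse(total == 0, 0L,
                 ifelse(total <= 3, 1L,
                 ifelse(total <= 6, 2L, 3L))))
}

#' Oxygen-need classification from the LUS total
#'
#' Classifies an infant as likely to need supplementary oxygen when the LUS
#' total exceeds the threshold (strictly greater, default 3). The source
#' rule defines positives as a score above 3 and negatives below 3; a total
#' of exactly 3 is classified negative so that the positive class matches
#' the strict "above 3" reading.
#'
#' @param lus_total Integer LUS totals in 0-8. Vectorised.
#' @param threshold Classification threshold; predicted positive iff
#'   `lus_total > threshold`. Default 3.
#' @return Logical vector.
#' @export
#' @examples
#' predict_oxygen_need(c(2, 3, 4))
predict_oxygen_need <- function(lus_total, threshold = 3) {
  lus_total <- check_item(lus_total, "LUS total", 8)
  lus_total > threshold
}

#' Score a cohort on the clinical severity scale
#'
#' Sums the four pre-coded clinical items (each 0-3) into a 0-12 total and
#' bands it into a severity grade. Item columns default to the canonical
#' cohort names; pass other columns with tidy evaluation. The dyspnea,
#' accessory-muscle and auscultation items are multi-sign bedside judgments
#' and are accepted only pre-coded; only the respiratory-rate item has a
#' mechanical encoder ([encode_respiratory_rate()]).
#'
#' @param data Data frame with one row per infant.
#' @param respiratory_rate_item,dyspnea_item,accessory_muscle_item,auscultation_item
#'   Columns holding the four items, each an integer 0-3.
#' @return The input as a tibble with `clinical_total` (0-12) and
#'   `clinical_grade` (ordered factor) appended.
#' @export
#' @examples
#' tibble::tibble(
#'   respiratory_rate_item = 1, dyspnea_item = 2,
#'   accessory_muscle_item = 1, auscultation_item = 1
#' ) |> score_clinical()
score_clinical <- function(data,
                           respiratory_rate_item = respiratory_rate_item,
                           dyspnea_item = dyspnea_item,
                           accessory_muscle_item = accessory_muscle_item,
                           auscultation_item = auscultation_item) {
  items <- list(
    respiratory_rate_item = rlang::eval_tidy(rlang::enquo(respiratory_rate_item), data),
    dyspnea_item = rlang::eval_tidy(rlang::enquo(dyspnea_item), data),
    accessory_muscle_item = rlang::eval_tidy(rlang::enquo(accessory_muscle_item), data),
    auscultation_item = rlang::eval_tidy(rlang::enquo(auscultation_item), data)
  )
  items <- purrr::imap(items, ~ check_item(.x, .y, 3))
  total <- items[[1]] + items[[2]] + items[[3]] + items[[4]]
  dplyr::mutate(tibble::as_tibble(data),
                clinical_total = total,
                clinical_grade = grade_clinical(total))
}

#' Score a cohort on the lung-ultrasound scale
#'
#' Sums the four LUS components (anterolateral pattern, posterior
#' interstitial syndrome, extension of interstitial syndrome, subpleural
#' consolidation; each 0-2) into a 0-8 total and bands it into a severity
#' grade. Raw observations are encoded first where applicable
#' ([encode_extension()], [encode_consolidation()]).
#'
#' @param data Data frame with one row per infant (or per infant/rater).
#' @param anterolateral_item,posterior_interstitial_item,extension_item,consolidation_item
#'   Columns holding the four components, each an integer 0-2.
#' @param prefix Prefix for the appended columns, e.g. `"lus1_"` when a
#'   cohort carries two raters' exams. Default `"lus_"`.
#' @return The input as a tibble with `<prefix>total` (0-8) and
#'   `<prefix>grade` (ordered factor) appended.
#' @export
#' @examples
#' tibble::tibble(
#'   anterolateral_item = 1, posterior_interstitial_item = 1,
#'   extension_item = 1, consolidation_item = 0
#' ) |> score_lus()
score_lus <- function(data,
                      anterolateral_item = anterolateral_item,
                      posterior_interstitial_item = posterior_interstitial_item,
                      extension_item = extension_item,
                      consolidation_item = consolidation_item,
                      prefix = "lus_") {
  items <- list(
    anterolateral_item = rlang::eval_tidy(rlang::enquo(anterolateral_item), data),
    posterior_interstitial_item = rlang::eval_tidy(rlang::enquo(posterior_interstitial_item), data),
    extension_item = rlang::eval_tidy(rlang::enquo(extension_item), data),
    consolidation_item = rlang::eval_tidy(rlang::enquo(consolidation_item), data)
  )
  items <- purrr::imap(items, ~ check_item(.x, .y, 2))
  total <- items[[1]] + items[[2]] + items[[3]] + items[[4]]
  out <- tibble::as_tibble(data)
  out[[paste0(prefix, "total")]] <- total
  out[[paste0(prefix, "grade")]] <- grade_lus(total)
  out
}
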