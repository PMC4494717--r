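clinical_bands <- list(normal = c(0L, 0L), mild = c(1L, 4L),
                       moderate = c(5L, 8L), severe = c(9L, 12L))
lus_bands <- list(normal = c(0L, 0L), mild = c(1L, 3L),
                  moderate = c(4L, 6L), severe = c(7L, 8L))

#' Parameters of the synthetic bronchiolitis cohort
#'
#' Defaults emulate the published study population: 106 bronchiolitis cases
#' and 25 healthy controls; clinical severity 76/27/3 mild/moderate/severe;
#' SRV (respiratory syncytial virus) positivity 73/106; oxygen requirement
#' calibrated so that roughly 27% of cases need oxygen and the LUS > 3 rule
#' attains sensitivity and specificity near 96%/99%. The conditional
#' frequencies of the extension and consolidation findings given severity
#' follow the study's printed contingency rows (mild vs pooled
#' moderate-severe); the severe-specific tables are skewed towards the top
#' levels so severe exams can reach the 7-8 band.
#'
#' Rater disagreement is modelled at the grade level among adjacent grades
#' only: the first sonographer's grade slips from the latent severity with
#' probabilities `rater1_slip` (down mostly towards a normal pattern, the
#' direction seen in the study), and the second sonographer's grade slips
#' from the first's with probabilities `rater2_confusion`.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param severity_probs Probabilities of mild/moderate/severe latent
#'   severity among cases; normalised if needed.
#' @param srv_prevalence SRV positivity among cases.
#' @param rater1_slip Named numeric `c(down = , up = )`: probability the
#'   first rater's LUS grade is one level below/above the latent severity.
#' @param rater2_confusion Named numeric `c(down = , up = )`: probability
#'   the second rater's grade is one level below/above the first rater's.
#' @param oxygen_rate_pos,oxygen_rate_neg Probability of a true oxygen
#'   requirement given a first-rater LUS total above / not above the
#'   classification threshold.
#' @param conditional_lus_tables Per-grade level probabilities for the
#'   extension and consolidation items: a list with elements `extension`
#'   and `consolidation`, each a list of length-3 probability vectors named
#'   `mild`, `moderate`, `severe`.
#' @param control_bline_rate Fraction of controls showing an isolated,
#'   non-pathological B line (still item 0, LUS total 0).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_params` list.
#' @export
#' @examples
#' cohort_params(n_cases = 50)
cohort_params <- function(n_cases = 106,
                          n_controls = 25,
                          severity_probs = c(mild = 76, moderate = 27, severe = 3) / 106,
                          srv_prevalence = 73 / 106,
                          rater1_slip = c(down = 0.075, up = 0.01),
                          rater2_confusion = c(down = 0.07, up = 0.02),
                          oxygen_rate_pos = 0.966,
                          oxygen_rate_neg = 0.013,
                          conditional_lus_tables = default_lus_tables(),
                          control_bline_rate = 0.20,
                          seed = 20150521) {
  probs <- c(severity_probs, srv_prevalence, rater1_slip, rater2_confusion,
             oxygen_rate_pos, oxygen_rate_neg, control_bline_rate,
             unlist(conditional_lus_tables))
  if (any(probs < 0) || any(probs > 1) || anyNA(probs)) {
    rlang::abort("all probabilities must lie in [0, 1]",
                 class = "bronchlus_config_error")
  }
  if (sum(rater1_slip) > 1 || sum(rater2_confusion) > 1) {
    rlang::abort("slip probabilities must sum to at most 1",
                 class = "bronchlus_config_error")
  }
  for (item in conditional_lus_tables) {
    for (p in item) {
      if (abs(sum(p) - 1) > 1e-8) {
        rlang::abort("conditional LUS level probabilities must sum to 1",
                     class = "bronchlus_config_error")
      }
    }
  }
  if (abs(sum(severity_probs) - 1) > 1e-8) {
    severity_probs <- severity_probs / sum(severity_probs)
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    severity_probs = severity_probs, srv_prevalence = srv_prevalence,
    rater1_slip = rater1_slip, rater2_confusion = rater2_confusion,
    oxygen_rate_pos = oxygen_rate_pos, oxygen_rate_neg = oxygen_rate_neg,
    conditional_lus_tables = conditional_lus_tables,
    control_bline_rate = control_bline_rate, seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_lus_tables <- function() {
  list(
    extension = list(
      mild = c(61, 15, 0) / 76,
      moderate = c(3, 18, 9) / 30,
      severe = c(0, 0.2, 0.8)
    ),
    consolidation = list(
      mild = c(53, 20, 3) / 76,
      moderate = c(5, 12, 13) / 30,
      severe = c(0, 0.25, 0.75)
    )
  )
}

# all 256 clinical item tuples indexed by total, for band-uniform sampling
clinical_tuples <- function() {
  g <- as.matrix(expand.grid(rr = 0:3, dysp = 0:3, acc = 0:3, ausc = 0:3))
  list(tuples = g, total = rowSums(g))
}

sample_levels <- function(n, prob) {
  if (n == 0) return(integer(0))
  sample.int(3L, n, replace = TRUE, prob = prob) - 1L
}

# LUS item tuples for n exams of one grade; returns n x 4 matrix
# (anterolateral, posterior interstitial, extension, consolidation)
sample_lus_items <- function(n, grade_label, tables) {
  out <- matrix(0L, n, 4,
                dimnames = list(NULL, c("anterolateral", "interstitial",
                                        "extension", "consolidation")))
  if (n == 0 || grade_label == "normal") return(out)
  band <- lus_bands[[grade_label]]
  ext <- sample_levels(n, tables$extension[[grade_label]])
  cons <- sample_levels(n, tables$consolidation[[grade_label]])
  target <- band[1] + floor(stats::runif(n) * (band[2] - band[1] + 1L))
  r <- pmin(pmax(target - ext - cons, 0L), 4L)
  lo <- pmax(0L, r - 2L)
  hi <- pmin(2L, r)
  antero <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  inter <- r - antero
  # clamping r at 4 can leave a severe exam below its band floor; absorb the
  # deficit into extension then consolidation (the items that drive severity)
  total <- ext + cons + antero + inter
  deficit <- pmax(0L, band[1] - total)
  bump <- pmin(2L - ext, deficit)
  ext <- ext + bump
  deficit <- deficit - bump
  cons <- cons + pmin(2L - cons, deficit)
  out[, "anterolateral"] <- antero
  out[, "interstitial"] <- inter
  out[, "extension"] <- ext
  out[, "consolidation"] <- cons
  out
}

slip_grades <- function(code, slip) {
  n <- length(code)
  u <- stats::runif(n)
  moved <- code - (u < slip[["down"]]) + (u >= slip[["down"]] &
                                          u < slip[["down"]] + slip[["up"]])
  pmax(0L, pmin(3L, as.integer(moved)))
}

#' Generate a seeded synthetic bronchiolitis cohort
#'
#' Draws a cohort under a latent-severity model: each case's severity is
#' drawn from `severity_probs`; the four clinical items are sampled
#' uniformly from the tuples whose total falls in that severity's clinical
#' band; the first rater's LUS grade slips from the severity among adjacent
#' grades, its extension/consolidation items follow the severity-conditional
#' tables and the anterolateral/interstitial items fill the total to the
#' grade's band; the second rater's grade is the first's passed through an
#' adjacent-grade confusion; oxygen requirement is drawn with a probability
#' depending on whether the first rater's total exceeds the classification
#' threshold. Controls have clinical total 0 and a normal LUS pattern (a
#' fraction show an isolated, non-pathological B line).
#'
#' The draw is fully determined by `seed`: one RNG stream per cohort and
#' the caller's RNG state is left untouched.
#'
#' @param params A [cohort_params()] list.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return Tibble with one row per infant: identifiers, demographics, the
#'   latent `severity_true`, pre-coded clinical items, both raters' LUS
#'   items (`lus1_*`, `lus2_*`), `oxygen_required`, `srv_positive`,
#'   `is_control`, `isolated_b_line` and `resolved_at_discharge`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_cases = 20, n_controls = 5))
#' dplyr::count(cohort, severity_true)
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- params$n_cases
  m <- params$n_controls
  if (n + m == 0) return(empty_cohort())

  sev_code <- if (n > 0) {
    sample(1:3, n, replace = TRUE, prob = params$severity_probs)
  } else integer(0)
  lv <- severity_levels()

  ct <- clinical_tuples()
  clin <- matrix(0L, n, 4)
  for (g in 1:3) {
    idx <- which(sev_code == g)
    if (!length(idx)) next
    band <- clinical_bands[[lv[g + 1L]]]
    pool <- which(ct$total >= band[1] & ct$total <= band[2])
    clin[idx, ] <- ct$tuples[sample(pool, length(idx), replace = TRUE), ,
                             drop = FALSE]
  }

  grade1 <- slip_grades(sev_code, params$rater1_slip)
  grade2 <- slip_grades(grade1, params$rater2_confusion)

  lus1 <- matrix(0L, n, 4)
  lus2 <- matrix(0L, n, 4)
  for (g in 0:3) {
    lab <- lv[g + 1L]
    i1 <- which(grade1 == g)
    lus1[i1, ] <- sample_lus_items(length(i1), lab, params$conditional_lus_tables)
    i2 <- which(grade2 == g)
    lus2[i2, ] <- sample_lus_items(length(i2), lab, params$conditional_lus_tables)
  }

  lus1_total <- rowSums(lus1)
  pred <- lus1_total > 3
  oxygen <- stats::runif(n) < ifelse(pred, params$oxygen_rate_pos,
                                     params$oxygen_rate_neg)

  age_cases <- pmin(239, pmax(9, round(stats::rlnorm(n, log(71), 0.6))))
  srv <- stats::runif(n) < params$srv_prevalence
  sex <- ifelse(stats::runif(n + m) < 0.56, "male", "female")

  cases <- tibble::tibble(
    patient_id = sprintf("case_%03d", seq_len(n)),
    is_control = FALSE,
    age_days = as.integer(age_cases),
    sex = sex[seq_len(n)],
    srv_positive = srv,
    severity_true = severity_grade(sev_code),
    respiratory_rate_item = clin[, 1], dyspnea_item = clin[, 2],
    accessory_muscle_item = clin[, 3], auscultation_item = clin[, 4],
    lus1_anterolateral_item = lus1[, 1], lus1_posterior_interstitial_item = lus1[, 2],
    lus1_extension_item = lus1[, 3], lus1_consolidation_item = lus1[, 4],
    lus2_anterolateral_item = lus2[, 1], lus2_posterior_interstitial_item = lus2[, 2],
    lus2_extension_item = lus2[, 3], lus2_consolidation_item = lus2[, 4],
    oxygen_required = oxygen,
    isolated_b_line = FALSE,
    resolved_at_discharge = TRUE
  )

  controls <- tibble::tibble(
    patient_id = sprintf("ctrl_%03d", seq_len(m)),
    is_control = TRUE,
    age_days = as.integer(round(stats::runif(m, 32, 160))),
    sex = sex[n + seq_len(m)],
    srv_positive = FALSE,
    severity_true = severity_grade(rep(0L, m)),
    respiratory_rate_item = 0L, dyspnea_item = 0L,
    accessory_muscle_item = 0L, auscultation_item = 0L,
    lus1_anterolateral_item = 0L, lus1_posterior_interstitial_item = 0L,
    lus1_extension_item = 0L, lus1_consolidation_item = 0L,
    lus2_anterolateral_item = 0L, lus2_posterior_interstitial_item = 0L,
    lus2_extension_item = 0L, lus2_consolidation_item = 0L,
    oxygen_required = FALSE,
    isolated_b_line = stats::runif(m) < params$control_bline_rate,
    resolved_at_discharge = NA
  )

  dplyr::bind_rows(cases, controls)
}

empty_cohort <- function() {
  generate_cohort_template <- tibble::tibble(
    patient_id = character(), is_control = logical(), age_days = integer(),
    sex = character(), srv_positive = logical(),
    severity_true = severity_grade(character()),
    respiratory_rate_item = integer(), dyspnea_item = integer(),
    accessory_muscle_item = integer(), auscultation_item = integer(),
    lus1_anterolateral_item = integer(), lus1_posterior_interstitial_item = integer(),
    lus1_extension_item = integer(), lus1_consolidation_item = integer(),
    lus2_anterolateral_item = integer(), lus2_posterior_interstitial_item = integer(),
    lus2_extension_item = integer(), lus2_consolidation_item = integer(),
    oxygen_required = logical(), isolated_b_line = logical(),
    resolved_at_discharge = logical()
  )
  generate_cohort_template
}
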