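---
title: "Scoring, agreement and diagnostic accuracy for bronchiolitis lung ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, agreement and diagnostic accuracy for bronchiolitis lung ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchlus)
library(dplyr)
```

## The problem

Bronchiolitis is graded at the bedside from clinical signs, and increasingly
also from lung ultrasound (LUS): B-line artifacts quantify interstitial
involvement and subpleural consolidations mark non-aerated lung. `bronchlus`
implements the full analytic chain of a two-scale severity-grading study:

1. a **clinical score** — four ordinal items (respiratory rate, dyspnea,
   accessory-muscle use, auscultation), each 0–3, summed to 0–12;
2. a **LUS score** — four ordinal components (anterolateral pattern,
   posterior interstitial syndrome, extension of the interstitial syndrome
   over bilaterally involved posterior intercostal spaces, subpleural
   consolidation size), each 0–2, summed to 0–8;
3. severity **banding** of each total into normal / mild / moderate / severe;
4. an **oxygen-need rule**: LUS total strictly greater than 3 predicts a
   supplementary-oxygen requirement;
5. **inter-rater agreement** via unweighted Cohen's kappa with its
   large-sample null standard error and z test;
6. **diagnostic accuracy** of the oxygen rule (sensitivity, specificity,
   PPV, NPV) with binomial confidence intervals; and
7. Pearson **chi-squared** comparisons of LUS finding frequencies between
   clinical strata.

A seeded synthetic-cohort generator emulates the reference study population
so that every stage is testable offline, and `paper_fixtures()` /
`reproduce_study()` recompute the study's printed statistics from its
printed counts.

## Scoring rules and boundary decisions

The banding is: clinical total 0 → normal, 1–4 mild, 5–8 moderate, 9–12
severe; LUS total 0 → normal, 1–3 mild, 4–6 moderate, 7–8 severe. Three
places in the published rubrics are ambiguous, and the package fixes them
with explicit, configurable defaults:

* **Respiratory rate exactly 70.** The rubric's bands are "61–69" and
  "> 70", leaving 70 unassigned. `encode_respiratory_rate()` scores it 3 by
  default (severity rounds up); `boundary_70 = 2` selects the other reading.
* **Extension bands overlap at 6 and 12** ("0–6", "6–12", "> 12").
  `encode_extension()` gives shared endpoints to the lower band by default
  (0–6 → 0, 7–12 → 1, ≥ 13 → 2); `rule = "upper"` selects the alternative.
* **LUS total exactly 3.** The oxygen rule is stated only as "> 3 positive,
  < 3 negative". `predict_oxygen_need()` classifies exactly 3 as negative,
  so the positive class matches the strict "greater than 3" wording; the
  threshold is a parameter.

Consolidation is inclusive at 1 cm (a 1.0 cm consolidation scores 2). The
dyspnea, accessory-muscle and auscultation items are multi-sign bedside
judgments with no mechanical encoding, so they are accepted only pre-coded
(0–3); only respiratory rate, extension and consolidation have raw-value
encoders.

## Agreement statistics

For a $k \times k$ cross-tabulation of two raters with cell proportions
$p_{ij}$ and marginals $p_{i\cdot}, p_{\cdot i}$:

$$P_o = \sum_i p_{ii}, \qquad
  P_e = \sum_i p_{i\cdot}\,p_{\cdot i}, \qquad
  \kappa = \frac{P_o - P_e}{1 - P_e}.$$

The null test uses the large-sample standard error of $\kappa$ under
$H_0\!: \kappa = 0$,

$$\mathrm{se}_0 = \frac{\sqrt{P_e + P_e^2 -
  \sum_i p_{i\cdot} p_{\cdot i}\,(p_{i\cdot} + p_{\cdot i})}}
  {(1 - P_e)\sqrt{n}}, \qquad z = \kappa / \mathrm{se}_0,$$

with a one-sided upper-tail normal p value. This pair $(\mathrm{se}_0, z)$
is what agreement software conventionally prints, and it reproduces the
reference study's printed standard errors exactly. Kappa is **unweighted**:
severity is ordinal, but the reference analysis used plain Cohen's kappa,
and weighted variants are deliberately out of scope. Categories are fixed
to the full four-level grade set even when a rater never used a level, so
marginals keep length 4.

Degenerate tables need a convention: when both raters used a single
category, $P_o = P_e = 1$ and $\kappa$ is formally 0/0. `rater_agreement()`
reports $\kappa = 1$ (agreement is, after all, perfect) with `NA` standard
error and test, plus a warning; the scalar primitive `cohen_kappa()` keeps
the strict contract and errors at $P_e = 1$.

```{r kappa}
fx <- paper_fixtures()$kappa$clinical_vs_pediatric
kappa_from_marginals(fx$diagonal, fx$row_marginals, fx$col_marginals, fx$n)
```

One printed value is knowingly not reproduced: the reference study reports
$z = 10.19$ for this first comparison, which is inconsistent with its own
printed $\kappa = 0.8$ and $\mathrm{se}_0 = 0.0765$ (their ratio is about
10.5, and the exact recomputation gives 10.49). The package reproduces
$P_o$, $P_e$, $\kappa$ and $\mathrm{se}_0$ and leaves that z as a documented
discrepancy; the second comparison's $z = 11.33$ is reproduced exactly.

## Diagnostic accuracy and interval choices

The oxygen-need rule is evaluated as a binary classifier against the
recorded oxygen requirement. From the reconstructed study table — the
unique integer 2×2 with $n = 106$, 29 condition positives, sensitivity
96.6% and specificity 98.7%, i.e. (TP, FP, FN, TN) = (28, 1, 1, 76) —
`binary_diagnostics()` computes the four metrics with binomial intervals.

Two interval methods are provided because the reference study mixes them
without naming either: the **Wilson score interval** (default) reproduces
its printed specificity CI (93%–99.8% for 76/77), while the
**Clopper–Pearson exact interval** reproduces its printed sensitivity lower
bound (82.2% for 28/29). No single method reproduces both ends of the
printed sensitivity CI; reports state the method used.

Group comparisons use Pearson's chi-squared **without continuity
correction** on 2×2 tables, one degree of freedom. The choice is not
aesthetic: the uncorrected statistic matches the study's printed values
(44.3, 16.2, 24.9, 41.7, 24.4, 21.5, 9.21, …) to their one-decimal
truncation, and the Yates-corrected one does not. Tables with an expected
cell below 5 raise a warning but are still computed, since the reference
analysis evidently ran them; `compare_groups()` skips only genuinely
degenerate tables (a zero row or column margin), returning `NA` with a
warning rather than failing the whole battery. One printed statistic
(26.4 for consolidation ≥ 1 cm, mild vs moderate–severe) does not follow
from its own printed counts (3/76 vs 13/30 gives 26.0 uncorrected, 23.7
corrected); the fixture row is flagged `known_discrepancy` and excluded
from reproduction matching.

## The synthetic cohort

No patient-level data are released with the reference study, so the
generator emulates its **published margins and conditional slices** under
the simplest structure that reproduces them — a latent-severity
factorization in which the clinical items and the LUS findings are
conditionally independent given a latent severity grade:

1. latent severity ~ categorical(76, 27, 3)/106 (the study's clinical
   severity distribution; its abstract prints 74/30/2, its results 76/27/3
   — the package follows the results, which reproduce the printed expected
   agreement of 52.3%);
2. clinical items drawn **uniformly from the 4-tuples whose total lies in
   the severity's band**, so the clinical grade equals the latent severity
   by construction;
3. the first sonographer's LUS grade slips from the latent severity among
   adjacent grades (default: down 0.075, up 0.01 — mostly mild → normal,
   the direction observed in the study), then its extension and
   consolidation items are drawn from severity-conditional tables taken
   from the study's printed contingency rows, and the anterolateral and
   interstitial items fill the total to a uniform draw within the grade's
   band (a severe exam whose draw cannot reach its band floor is repaired
   by raising extension, then consolidation);
4. the second sonographer's grade is the first's passed through an
   adjacent-grade confusion (default: down 0.07, up 0.02);
5. oxygen requirement ~ Bernoulli(0.966) when the first rater's total
   exceeds 3, Bernoulli(0.013) otherwise.

The oxygen probabilities are the study's own implied conditionals (its PPV
and 1 − NPV). With the default slip rates the probability that a case
grades moderate-or-worse is ≈ 0.271, so the closed-form implied prevalence
is $0.271 \times 0.966 + 0.729 \times 0.013 \approx 0.271$, matching the
study's 29/106, with implied sensitivity ≈ 0.965 and specificity ≈ 0.987.
These defaults were fixed analytically from that calculation, not fitted.

Controls have clinical total 0 and a fully normal LUS pattern; 20% carry
an isolated, non-pathological B line (recorded as a flag — it is still
component level 0). Age, sex and the discharge-resolution flag are
generated for realism only; no analysis stage consumes them.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: the joint distribution of clinical grade ×
ultrasound grade beyond what the printed marginals and diagonal constrain
(any joint matching those is admissible); item-level rater disagreement
(modelled only at the grade level); correlation between clinical items
beyond their shared band; secular or seasonal structure; and any
image-level reality behind the coded findings.

Each cohort uses a single RNG stream fully determined by its seed, and the
caller's RNG state is restored afterwards.

## Numerical and testing choices

* Proportions and kappa are kept at full double precision everywhere;
  only `print()` methods round (percentages to one decimal, the
  convention of the field's tables). Reported p values below 0.0005 print
  as "< 0.001".
* Reproduction matching uses 1% relative tolerance for agreement
  quantities and an absolute 0.105 for chi-squared statistics, which is
  exactly the slack a one-decimal truncation can introduce.
* The test-suite problem sizes are 5,000 draws for parameter recovery
  (3-standard-error bands) and 10,000 for the oxygen-prevalence
  calibration check (central 99% binomial band around 0.27); both run in
  well under a second and are ample for the binomial standard errors
  involved.
* `read_cohort_csv()` validates every item against its ordinal range and
  reports the offending column and row numbers; booleans must parse as
  TRUE/FALSE with no blanks.

## Known limitations

* Weighted kappa, multi-rater kappa and bootstrap kappa intervals are out
  of scope, as are Fisher's exact test, odds ratios and ROC analysis (the
  reference design provides no per-threshold data).
* The sample-size statement of the reference study (19 infants at α =
  0.05, power 90%, prevalence 25%) has no stated formula or comparator and
  is not implemented.
* The severity-conditional finding tables pool moderate and severe cases
  (the study prints them pooled); the severe-specific defaults are a
  scientific judgment, constrained only by the requirement that severe
  exams reach their band.
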