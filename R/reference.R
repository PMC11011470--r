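# Published summary statistics of the reference evaluation study (477
# inpatient chest radiographs in two planes, seven abnormality entities).
# These printed values are the calibration targets of the synthetic cohort
# generator and the fixture inputs for the metric-algebra checks; the
# study's raw per-patient data are not public.

#' Reference per-entity operating points and confusion counts
#'
#' The published per-entity cutoffs, AUCs and confusion counts of the
#' reference evaluation (n = 477), for the Youden-optimal policy and the
#' exploratory 95%-sensitivity policy. Feeding these counts through
#' [derive_metrics()] and [average_across_entities()] reproduces every
#' derived cell of the published per-entity tables.
#'
#' @param policy `"youden"` or `"min_sensitivity"`.
#' @return data.frame, one row per entity (canonical order): `entity`,
#'   `cutoff`, `auc`, `ci_low`, `ci_high` (AUC columns NA for the
#'   exploratory policy, whose AUCs were not reported separately), `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
reference_entity_counts <- function(policy = c("youden", "min_sensitivity")) {
  policy <- match.arg(policy)
  ent <- chest_entities()
  if (policy == "youden") {
    data.frame(
      entity = ent,
      cutoff = c(0.4891, 0.3375, 0.3853, 0.3083, 0.5215, 0.4876, 0.4173),
      auc    = c(0.845, 0.866, 0.793, 0.92, 0.839, 0.843, 0.791),
      ci_low = c(0.76, 0.82, 0.71, 0.89, 0.78, 0.65, 0.73),
      ci_high = c(0.93, 0.92, 0.88, 0.96, 0.90, 1.00, 0.86),
      tp = c(13L, 28L, 23L, 57L, 27L, 5L, 38L),
      tn = c(269L, 357L, 364L, 355L, 328L, 415L, 248L),
      fp = c(195L, 86L, 80L, 56L, 118L, 56L, 186L),
      fn = c(0L, 6L, 10L, 9L, 4L, 1L, 5L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      entity = ent,
      cutoff = c(0.4891, 0.1978, 0.0902, 0.1429, 0.2976, 0.1602, 0.3412),
      auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      tp = c(13L, 33L, 32L, 63L, 30L, 6L, 41L),
      tn = c(269L, 245L, 89L, 259L, 197L, 142L, 176L),
      fp = c(195L, 198L, 355L, 152L, 249L, 329L, 258L),
      fn = c(0L, 1L, 1L, 3L, 1L, 0L, 2L),
      stringsAsFactors = FALSE
    )
  }
}

#' Reference combined-reading category counts
#'
#' Published patient-level category counts (n = 477) of the conservative
#' combined reading of all seven entities, under both cutoff policies:
#' tp = completely correct positives, tn = completely correct negatives,
#' fp = any false alarm without a miss, fn = any missed finding.
#'
#' @param policy `"youden"` or `"min_sensitivity"`.
#' @return A `confusion_counts`.
#' @export
reference_combined_counts <- function(policy = c("youden", "min_sensitivity")) {
  policy <- match.arg(policy)
  if (policy == "youden") new_confusion_counts(tp = 16, tn = 62, fp = 364, fn = 35)
  else new_confusion_counts(tp = 3, tn = 5, fp = 461, fn = 8)
}

#' Reference score-distribution summaries per entity
#'
#' Published per-entity AI-score summaries conditional on gold-standard
#' status: median and quartiles for gold-positive cases (the positive
#' scores were not normally distributed) and mean/SD for gold-negative
#' cases (reported as approximately normal).
#'
#' @return List with data.frames `positive` (`entity`, `median`, `q1`,
#'   `q3`) and `negative` (`entity`, `mean`, `sd`, `median`, `q1`, `q3`).
#' @export
reference_score_summaries <- function() {
  ent <- chest_entities()
  list(
    positive = data.frame(
      entity = ent,
      median = c(0.6537, 0.5065, 0.5353, 0.5639, 0.6953, 0.6570, 0.6210),
      q1     = c(0.5584, 0.4280, 0.2416, 0.3798, 0.5705, 0.5016, 0.4624),
      q3     = c(0.7211, 0.6619, 0.8071, 0.6938, 0.8207, 0.8133, 0.8029),
      stringsAsFactors = FALSE
    ),
    negative = data.frame(
      entity = ent,
      mean = c(0.4668, 0.2358, 0.2417, 0.1581, 0.3747, 0.2695, 0.4230),
      sd   = c(0.1311, 0.1858, 0.1952, 0.1411, 0.2273, 0.1772, 0.1720),
      median = c(0.4556, 0.1738, 0.1718, 0.1048, 0.3403, 0.2090, 0.3826),
      q1     = c(0.3696, 0.1067, 0.1038, 0.0612, 0.1924, 0.1480, 0.2945),
      q3     = c(0.5599, 0.2964, 0.3216, 0.1940, 0.5368, 0.3325, 0.5318),
      stringsAsFactors = FALSE
    )
  )
}

#' Reference cohort composition
#'
#' Published cohort-level calibration targets: per-entity gold-positive
#' counts, the finding-multiplicity histogram (patients with 0..4
#' findings), and covariate summaries.
#'
#' @return List with `n`, `prevalence` (named integer vector), and
#'   `multiplicity` (named integer vector, names "0".."4"), `male_fraction`,
#'   `age_mean`, `age_sd`, `age_range`, `foreign_fraction`,
#'   `age_mean_positive`, `age_mean_negative`.
#' @export
reference_cohort_composition <- function() {
  list(
    n = 477L,
    prevalence = stats::setNames(
      c(13L, 34L, 33L, 66L, 31L, 6L, 43L), chest_entities()),
    multiplicity = stats::setNames(
      c(310L, 116L, 44L, 6L, 1L), as.character(0:4)),
    male_fraction = 0.5954,
    age_mean = 61.4,
    age_sd = 16.73,
    age_range = c(18, 91),
    foreign_fraction = 0.4004,
    age_mean_positive = 68.6,
    age_mean_negative = 62.1
  )
}
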