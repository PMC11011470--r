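patient_categories <- c("TP_complete", "TN_complete", "FP_any", "FN_missed")

#' Conservative patient-level category for a combined reading
#'
#' Classifies one patient read simultaneously for all seven entities, under
#' the conservative rule used for screening triage:
#' * `FN_missed` — any gold-positive entity was called negative. A miss
#'   takes precedence over everything else: a correctly detected finding
#'   elsewhere does not rescue the patient, because the missed finding
#'   would go unreviewed.
#' * `FP_any` — no missed finding, but at least one gold-negative entity
#'   was called positive (regardless of additional true positives): the
#'   patient needs human review either way.
#' * `TP_complete` — at least one gold-positive finding, every entity
#'   called correctly.
#' * `TN_complete` — no findings and no calls: the patient could be
#'   removed from the reading worklist.
#'
#' @param gold,calls named binary vectors (or named lists) covering all
#'   seven entities.
#' @return One of `"TP_complete"`, `"TN_complete"`, `"FP_any"`,
#'   `"FN_missed"`.
#' @export
classify_patient <- function(gold, calls) {
  gold <- unlist(gold); calls <- unlist(calls)
  ent <- chest_entities()
  if (!all(ent %in% names(gold)) || !all(ent %in% names(calls))) {
    stop("gold and calls must cover all seven entities")
  }
  g <- gold[ent]; cl <- calls[ent]
  if (!all(g %in% c(0, 1)) || !all(cl %in% c(0, 1))) {
    stop("gold and calls must be binary 0/1")
  }
  if (any(g == 1 & cl == 0)) return("FN_missed")
  if (any(g == 0 & cl == 1)) return("FP_any")
  if (any(g == 1)) return("TP_complete")
  "TN_complete"
}

#' Patient-level categories for a whole cohort
#'
#' Vectorized application of [classify_patient()] given per-entity cutoffs.
#'
#' @param cohort a `cohort`.
#' @param cutoffs named numeric vector (or list) of per-entity cutoffs
#'   covering all seven entities.
#' @return Character vector of categories, one per patient.
#' @export
patient_categories_for_cohort <- function(cohort, cutoffs) {
  cutoffs <- unlist(cutoffs)
  ent <- chest_entities()
  if (!all(ent %in% names(cutoffs))) stop("cutoffs must cover all seven entities")
  g <- gold_matrix(cohort)
  s <- score_matrix(cohort)
  calls <- sweep(s, 2, cutoffs[ent], ">=") * 1L
  miss <- rowSums(g == 1 & calls == 0) > 0
  alarm <- rowSums(g == 0 & calls == 1) > 0
  anypos <- rowSums(g) > 0
  unname(ifelse(miss, "FN_missed",
                ifelse(alarm, "FP_any",
                       ifelse(anypos, "TP_complete", "TN_complete"))))
}

#' Combined-reading confusion counts at patient level
#'
#' Maps the four conservative patient categories onto a confusion cell:
#' tp = complete correct positives, tn = complete correct negatives,
#' fp = patients with any false alarm (and no miss), fn = patients with any
#' missed finding. Derived metrics computed on these category counts use
#' the category-count denominators (e.g. sensitivity = TP_complete /
#' (TP_complete + FN_missed)), which is how combined-reading results are
#' reported; see [combined_reading_report()] for a companion breakdown with
#' the standard all-gold-positive denominator.
#'
#' @inheritParams patient_categories_for_cohort
#' @return A `confusion_counts` over patients.
#' @export
combined_confusion <- function(cohort, cutoffs) {
  cat_ <- patient_categories_for_cohort(cohort, cutoffs)
  new_confusion_counts(
    tp = sum(cat_ == "TP_complete"),
    tn = sum(cat_ == "TN_complete"),
    fp = sum(cat_ == "FP_any"),
    fn = sum(cat_ == "FN_missed")
  )
}

#' Workload-reduction estimate
#'
#' In combined mode, the fraction of patients whose reading is completely
#' negative under the policy (`TN_complete / n`) is the share of the
#' worklist that could be removed, at the cost of `FN_missed / n` patients
#' with at least one missed finding. In single-entity mode the rule-out
#' fraction is that entity's `tn / n`. Both the whole-cohort fraction and
#' the fraction of gold-negative readings are reported.
#'
#' @param counts a `confusion_counts` — patient-level (from
#'   [combined_confusion()]) or entity-level.
#' @return A `workload_estimate`: list with `auto_negative_fraction`,
#'   `missed_fraction` (both of the whole cohort), and
#'   `auto_negative_of_negatives` (tn / (tn + fp)).
#' @export
workload_reduction <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("workload undefined for n = 0")
  structure(list(
    auto_negative_fraction = counts$tn / counts$n,
    missed_fraction = counts$fn / counts$n,
    auto_negative_of_negatives =
      if (counts$tn + counts$fp == 0) NA_real_
      else counts$tn / (counts$tn + counts$fp)
  ), class = "workload_estimate")
}

#' @export
print.workload_estimate <- function(x, ...) {
  cat(sprintf(
    "<workload_estimate> auto-negative %.2f%% of cohort (%.2f%% of negatives), missed %.2f%%\n",
    100 * x$auto_negative_fraction, 100 * x$auto_negative_of_negatives,
    100 * x$missed_fraction))
  invisible(x)
}

#' Full combined-reading report for one cutoff policy
#'
#' Bundles the conservative category counts, their derived metrics, the
#' workload estimate, and a clearly labelled "standard" patient-level
#' breakdown in which sensitivity is computed over all patients with at
#' least one gold-positive finding (not only over the complete-correct /
#' missed categories).
#'
#' @inheritParams patient_categories_for_cohort
#' @return List with `counts`, `metrics`, `workload`, `categories`,
#'   `standard` (list: `n_gold_positive`, `sensitivity_all_positives`).
#' @export
combined_reading_report <- function(cohort, cutoffs) {
  categories <- patient_categories_for_cohort(cohort, cutoffs)
  counts <- new_confusion_counts(
    tp = sum(categories == "TP_complete"),
    tn = sum(categories == "TN_complete"),
    fp = sum(categories == "FP_any"),
    fn = sum(categories == "FN_missed")
  )
  n_gold_pos <- sum(multimorbidity(cohort) > 0)
  list(
    counts = counts,
    metrics = derive_metrics(counts),
    workload = workload_reduction(counts),
    categories = categories,
    standard = list(
      n_gold_positive = n_gold_pos,
      sensitivity_all_positives =
        if (n_gold_pos == 0) NA_real_ else counts$tp / n_gold_pos
    )
  )
}
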