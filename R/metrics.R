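#' Classify one entity's scores at a cutoff
#'
#' Applies the global call convention: a patient is called positive for the
#' entity iff `score >= cutoff`.
#'
#' @param cohort a `cohort`.
#' @param entity one of [chest_entities()].
#' @param cutoff numeric cutoff in \[0, 1\].
#' @return Integer vector of per-patient calls (0/1), in cohort row order.
#' @export
classify_entity <- function(cohort, entity, cutoff) {
  if (!entity %in% chest_entities()) stop("unknown entity: ", entity)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  as.integer(as.data.frame(cohort)[[paste0("score_", entity)]] >= cutoff)
}

#' Confusion counts of binary calls against gold labels
#'
#' @param calls,gold binary vectors of equal length.
#' @return A `confusion_counts`: list with `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion_counts <- function(calls, gold) {
  if (length(calls) != length(gold)) stop("calls and gold differ in length")
  if (!all(calls %in% c(0, 1)) || !all(gold %in% c(0, 1))) {
    stop("calls and gold must be binary 0/1")
  }
  tp <- sum(calls == 1 & gold == 1)
  tn <- sum(calls == 0 & gold == 0)
  fp <- sum(calls == 1 & gold == 0)
  fn <- sum(calls == 0 & gold == 1)
  new_confusion_counts(tp, tn, fp, fn)
}

#' Build confusion counts directly from the four cells
#'
#' Useful for feeding externally reported counts (e.g. a published table)
#' into the metric algebra.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return A `confusion_counts`.
#' @export
new_confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (any(counts != round(counts))) stop("confusion counts must be integers")
  tp <- as.integer(tp); tn <- as.integer(tn)
  fp <- as.integer(fp); fn <- as.integer(fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d tn=%d fp=%d fn=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n))
  invisible(x)
}

#' Derived diagnostic metrics of a confusion-count cell
#'
#' Computes sensitivity, specificity, PPV, NPV and FPR, plus the fraction of
#' the total that each count represents. A ratio with zero denominator is
#' reported as `NA` and listed in the `undefined` field — never silently
#' coerced to 0 — because empty cells are real at extreme cutoffs.
#'
#' @param counts a `confusion_counts` with `n > 0`.
#' @return A `metric_set`: list of the five rates (proportions, not
#'   percentages), `fractions` (per-count share of n), `counts`, and
#'   `undefined` (names of any zero-denominator metrics).
#' @export
derive_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("metrics undefined for n = 0")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(
    sensitivity = rate(counts$tp, counts$tp + counts$fn),
    specificity = rate(counts$tn, counts$tn + counts$fp),
    ppv = rate(counts$tp, counts$tp + counts$fp),
    npv = rate(counts$tn, counts$tn + counts$fn),
    fpr = rate(counts$fp, counts$fp + counts$tn)
  )
  m$fractions <- c(tp = counts$tp, tn = counts$tn,
                   fp = counts$fp, fn = counts$fn) / counts$n
  m$counts <- counts
  m$undefined <- names(which(vapply(m[1:5], is.na, logical(1))))
  structure(m, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("<metric_set> sens=%s spec=%s ppv=%s npv=%s fpr=%s (n=%d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv), fmt(x$fpr), x$counts$n))
  invisible(x)
}

#' Cross-entity average of per-entity confusion counts
#'
#' Two conventions are in use for the "average" column of per-entity
#' evaluation tables, and published tables sometimes mix them:
#' * `"arithmetic"`: the mean of the per-entity metric values;
#' * `"pooled"`: the metric of the element-wise summed counts
#'   (micro-average).
#' Both are computed here so reports can label which one each figure uses.
#' Averaged counts are always arithmetic means.
#'
#' @param counts_list non-empty list of `confusion_counts`.
#' @param method `"arithmetic"` or `"pooled"`.
#' @return A `cross_entity_average`: list with `method`, `metrics` (named
#'   numeric vector of the five rates), and `mean_counts` (arithmetic mean
#'   of tp/tn/fp/fn and n).
#' @export
average_across_entities <- function(counts_list,
                                    method = c("arithmetic", "pooled")) {
  method <- match.arg(method)
  if (length(counts_list) == 0) stop("empty counts list")
  stopifnot(all(vapply(counts_list, inherits, logical(1), "confusion_counts")))
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "fpr")
  mean_counts <- colMeans(do.call(rbind, lapply(counts_list, function(ct)
    c(tp = ct$tp, tn = ct$tn, fp = ct$fp, fn = ct$fn, n = ct$n))))
  if (method == "arithmetic") {
    per_entity <- vapply(counts_list, function(ct) {
      ms <- derive_metrics(ct)
      unlist(ms[metric_names])
    }, numeric(5))
    metrics <- rowMeans(per_entity)
  } else {
    tot <- Reduce(function(a, b) new_confusion_counts(
      a$tp + b$tp, a$tn + b$tn, a$fp + b$fp, a$fn + b$fn), counts_list)
    ms <- derive_metrics(tot)
    metrics <- unlist(ms[metric_names])
  }
  structure(list(method = method, metrics = metrics, mean_counts = mean_counts),
            class = "cross_entity_average")
}

#' @export
print.cross_entity_average <- function(x, ...) {
  cat(sprintf("<cross_entity_average> method=%s\n", x$method))
  print(round(100 * x$metrics, 2))
  invisible(x)
}
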