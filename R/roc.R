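#' Empirical ROC curve
#'
#' Builds the finite-sample ROC of a score against binary gold labels under
#' the global call convention `score >= threshold => positive`. Candidate
#' thresholds are the distinct observed score values plus two sentinels:
#' 0 (everything called positive: sensitivity 1, specificity 0) and `Inf`
#' (nothing called positive: sensitivity 0, specificity 1). No interpolation
#' is performed between operating points.
#'
#' @param scores numeric vector of probabilities in \[0, 1\].
#' @param labels binary vector (0/1) of gold-standard status, same length.
#' @return A `roc_curve`: list with `points` (data.frame of `threshold`,
#'   `sensitivity`, `specificity`, ordered by increasing threshold),
#'   `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: need at least one positive and one negative label")
  }
  thr <- sort(unique(scores))
  if (thr[1] > 0) thr <- c(0, thr)
  thr <- c(thr, Inf)
  # counts with score >= t: findInterval(..., left.open = TRUE) counts
  # elements strictly below t, exactly (thresholds are observed values)
  sp <- sort(scores[labels == 1])
  sn <- sort(scores[labels == 0])
  pos_ge <- n_pos - findInterval(thr, sp, left.open = TRUE)
  neg_ge <- n_neg - findInterval(thr, sn, left.open = TRUE)
  points <- data.frame(
    threshold = thr,
    sensitivity = pos_ge / n_pos,
    specificity = 1 - neg_ge / n_neg
  )
  structure(list(points = points, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, %d pos / %d neg, AUC = %.4f\n",
              nrow(x$points), x$n_pos, x$n_neg, roc_auc(x)))
  invisible(x)
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). For the empirical
#' curve this equals the two-sample rank (Mann-Whitney) statistic with ties
#' counted one half, divided by `n_pos * n_neg`.
#'
#' @param curve a `roc_curve`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$points$specificity
  tpr <- curve$points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' AUC with a DeLong confidence interval
#'
#' Point estimate via the midrank (Mann-Whitney) form; variance via DeLong's
#' placement estimator. When either class has fewer than 10 members the
#' normal-scale interval is replaced by a logit-transformed interval, which
#' respects the \[0, 1\] bounds in small samples. Degenerate variance (e.g.
#' perfect separation) collapses the interval onto the estimate.
#'
#' @param scores,labels as in [empirical_roc()].
#' @param level confidence level (default 0.95).
#' @return An `auc_estimate`: list with `auc`, `ci_low`, `ci_high`, `level`,
#'   `se`, `method`.
#' @export
auc_with_ci <- function(scores, labels, level = 0.95) {
  stopifnot(length(scores) == length(labels), level > 0, level < 1)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("AUC undefined for single-class input")
  all_s <- c(pos, neg)
  rk <- rank(all_s, ties.method = "average")
  rk_pos <- rank(pos, ties.method = "average")
  rk_neg <- rank(neg, ties.method = "average")
  # placements: V10_i = P(pos_i > random neg), V01_j = P(random pos > neg_j)
  v10 <- (rk[seq_len(m)] - rk_pos) / n
  v01 <- 1 - (rk[m + seq_len(n)] - rk_neg) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  small <- (m < 10 || n < 10)
  if (se == 0) {
    lo <- hi <- auc
    method <- "delong (degenerate variance)"
  } else if (small && auc > 0 && auc < 1) {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    lo <- stats::plogis(lg - z * se_lg)
    hi <- stats::plogis(lg + z * se_lg)
    method <- "delong, logit-transformed (small sample)"
  } else {
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
    method <- "delong"
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi, level = level,
                 se = se, method = method),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%%-CI %.3f-%.3f) [%s]\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

threshold_choice <- function(policy, curve, idx, constraint = NA_real_) {
  p <- curve$points[idx, ]
  structure(list(
    policy = policy,
    cutoff = p$threshold,
    sensitivity_at_cutoff = p$sensitivity,
    specificity_at_cutoff = p$specificity,
    youden_j = p$sensitivity + p$specificity - 1,
    constraint = constraint
  ), class = "threshold_choice")
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat(sprintf("<threshold_choice> policy=%s cutoff=%.4f sens=%.3f spec=%.3f J=%.3f\n",
              x$policy, x$cutoff, x$sensitivity_at_cutoff,
              x$specificity_at_cutoff, x$youden_j))
  invisible(x)
}

#' Cutoff maximizing Youden's J
#'
#' Scans every operating point of the curve for the maximum of
#' J = sensitivity + specificity - 1. Ties are broken towards the lowest
#' qualifying threshold, which favours sensitivity — the screening-oriented
#' choice when false negatives carry the greater clinical risk.
#'
#' @param curve a `roc_curve`.
#' @return A `threshold_choice` with `policy = "youden"`.
#' @export
youden_optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  idx <- best[which.min(pts$threshold[best])]
  threshold_choice("youden", curve, idx)
}

#' Sensitivity-constrained cutoff
#'
#' Returns the largest threshold whose sensitivity is at least `min_sens` —
#' equivalently the maximal-specificity operating point subject to the
#' sensitivity floor. Sensitivity 1 is always attainable at threshold 0, so
#' the constraint is always satisfiable.
#'
#' @param curve a `roc_curve`.
#' @param min_sens sensitivity floor in (0, 1\]; default 0.95.
#' @return A `threshold_choice` with `policy = "min_sensitivity"`.
#' @export
sensitivity_constrained_threshold <- function(curve, min_sens = 0.95) {
  stopifnot(inherits(curve, "roc_curve"), min_sens > 0, min_sens <= 1)
  pts <- curve$points
  ok <- which(pts$sensitivity >= min_sens - 1e-12 & is.finite(pts$threshold))
  idx <- ok[which.max(pts$threshold[ok])]
  threshold_choice("min_sensitivity", curve, idx, constraint = min_sens)
}

#' Export a ROC curve's operating points as CSV
#'
#' @param curve a `roc_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_curve <- function(curve, path) {
  utils::write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}
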