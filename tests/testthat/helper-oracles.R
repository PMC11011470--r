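# Brute-force oracles and tiny fixture builders shared across the suite.
# The oracles deliberately use naive enumeration, independent of the
# package's vectorized implementations.

# pairwise Mann-Whitney AUC: (#{pos > neg} + 0.5 #{pos == neg}) / (m * n)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# sensitivity/specificity at one threshold under the score >= t convention
oracle_point <- function(scores, labels, t) {
  calls <- as.integer(scores >= t)
  c(sensitivity = sum(calls == 1 & labels == 1) / sum(labels == 1),
    specificity = sum(calls == 0 & labels == 0) / sum(labels == 0))
}

# exhaustive scan over all distinct-score thresholds (plus sentinels)
oracle_thresholds <- function(scores) {
  thr <- sort(unique(scores))
  if (thr[1] > 0) thr <- c(0, thr)
  c(thr, Inf)
}

oracle_youden <- function(scores, labels) {
  thr <- oracle_thresholds(scores)
  best_j <- -Inf; best_t <- NA
  for (t in thr) {
    pt <- oracle_point(scores, labels, t)
    j <- pt[1] + pt[2] - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}

oracle_constrained <- function(scores, labels, min_sens = 0.95) {
  thr <- oracle_thresholds(scores)
  ok <- thr[is.finite(thr)]
  ok <- ok[vapply(ok, function(t)
    oracle_point(scores, labels, t)[1] >= min_sens - 1e-12, logical(1))]
  max(ok)
}

# naive per-patient re-derivation of the conservative combined category
oracle_patient_category <- function(gold, calls) {
  if (any(gold == 1 & calls == 0)) return("FN_missed")
  if (any(gold == 0 & calls == 1)) return("FP_any")
  if (any(gold == 1)) return("TP_complete")
  "TN_complete"
}

# small random two-class score instance (guaranteed both classes present)
random_instance <- function(n = 8, n_levels = 5) {
  labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
  scores <- sample(seq(0, 1, length.out = n_levels), n, replace = TRUE)
  list(scores = scores, labels = labels)
}

# small fully-valid cohort data.frame built by hand
make_cohort_df <- function(n = 3, seed = 42) {
  set.seed(seed)
  ent <- chest_entities()
  df <- data.frame(
    patient_id = sprintf("pt%02d", seq_len(n)),
    age = sample(18:90, n, replace = TRUE),
    sex = rbinom(n, 1, 0.4),
    foreign_material = rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE
  )
  for (e in ent) {
    df[[paste0("gold_", e)]] <- rbinom(n, 1, 0.3)
    df[[paste0("score_", e)]] <- round(runif(n), 6)
  }
  df
}

# printed-rounding comparison: value (proportion) against a printed
# percentage with `digits` decimals, allowing half-ulp rounding slack
expect_printed_pct <- function(value, printed, digits = 2) {
  expect_false(is.na(value))
  expect_lt(abs(100 * value - printed), 0.51 * 10^(-digits) + 1e-9)
}
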