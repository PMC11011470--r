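#' Evaluate one cutoff policy across all entities
#'
#' For each entity: empirical ROC, AUC with confidence interval, cutoff
#' under the policy, confusion counts and derived metrics at that cutoff.
#'
#' @param cohort a `cohort`.
#' @param policy `"youden"` or `"min_sensitivity"`.
#' @param min_sens sensitivity floor for the constrained policy.
#' @return An `entity_evaluation`: list with `policy`, `per_entity` (named
#'   list of `roc`, `auc`, `choice`, `counts`, `metrics` per entity),
#'   `cutoffs` (named vector), `averages` (list `arithmetic`, `pooled`).
#' @export
evaluate_entities <- function(cohort, policy = c("youden", "min_sensitivity"),
                              min_sens = 0.95) {
  policy <- match.arg(policy)
  df <- as.data.frame(cohort)
  per_entity <- lapply(chest_entities(), function(e) {
    scores <- df[[paste0("score_", e)]]
    gold <- df[[paste0("gold_", e)]]
    curve <- empirical_roc(scores, gold)
    choice <- if (policy == "youden") youden_optimal_threshold(curve)
      else sensitivity_constrained_threshold(curve, min_sens)
    calls <- as.integer(scores >= choice$cutoff)
    counts <- confusion_counts(calls, gold)
    list(roc = curve,
         auc = auc_with_ci(scores, gold),
         choice = choice,
         counts = counts,
         metrics = derive_metrics(counts))
  })
  names(per_entity) <- chest_entities()
  counts_list <- lapply(per_entity, `[[`, "counts")
  structure(list(
    policy = policy,
    min_sens = if (policy == "min_sensitivity") min_sens else NA_real_,
    per_entity = per_entity,
    cutoffs = vapply(per_entity, function(x) x$choice$cutoff, numeric(1)),
    averages = list(
      arithmetic = average_across_entities(counts_list, "arithmetic"),
      pooled = average_across_entities(counts_list, "pooled")
    )
  ), class = "entity_evaluation")
}

#' Run the full evaluation pipeline
#'
#' Chains every stage on one cohort: for each requested policy the
#' per-entity ROC/cutoff/metric table, then the conservative combined
#' patient-level reading with its workload estimate, then the concordance
#' regression on both gold strata. Artifacts are written as CSV when
#' `out_dir` is given.
#'
#' @param cohort a `cohort`, or `NULL` to generate one.
#' @param config `generator_config` used when `cohort` is `NULL`.
#' @param policies character vector among `"youden"`,
#'   `"min_sensitivity"`; must be non-empty.
#' @param min_sens sensitivity floor for the constrained policy, in
#'   (0, 1\].
#' @param out_dir optional output directory for the report CSVs.
#' @param seed seed used when generating the cohort.
#' @return A `triage_report`: list with `cohort`, `entity` (per policy),
#'   `combined` (per policy), `regression` (per stratum), `log`
#'   (character vector of resolved cutoffs and stage notes).
#' @export
run_pipeline <- function(cohort = NULL, config = generator_config(),
                         policies = c("youden", "min_sensitivity"),
                         min_sens = 0.95, out_dir = NULL, seed = 1L) {
  if (length(policies) == 0) stop("at least one policy is required")
  stopifnot(all(policies %in% c("youden", "min_sensitivity")),
            min_sens > 0, min_sens <= 1)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config, seed = seed)
    note("generated cohort: %s", attr(cohort, "provenance"))
  } else {
    note("cohort: %s (%d patients)", attr(cohort, "provenance"), nrow(cohort))
  }
  entity <- list(); combined <- list()
  for (p in policies) {
    ev <- evaluate_entities(cohort, p, min_sens)
    entity[[p]] <- ev
    for (e in chest_entities()) {
      note("policy %s: %s cutoff %.4f (sens %.3f, spec %.3f)", p, e,
           ev$cutoffs[e], ev$per_entity[[e]]$choice$sensitivity_at_cutoff,
           ev$per_entity[[e]]$choice$specificity_at_cutoff)
    }
    combined[[p]] <- combined_reading_report(cohort, ev$cutoffs)
    note("policy %s: combined TN %d/%d (auto-negative %.2f%%), missed %.2f%%",
         p, combined[[p]]$counts$tn, combined[[p]]$counts$n,
         100 * combined[[p]]$workload$auto_negative_fraction,
         100 * combined[[p]]$workload$missed_fraction)
  }
  obs <- build_deviation_table(cohort)
  regression <- list(
    gold_negative = fit_concordance_model(obs, "gold_negative"),
    gold_positive = fit_concordance_model(obs, "gold_positive")
  )
  note("regression: gold-negative R^2 %.4f, gold-positive R^2 %.4f",
       regression$gold_negative$r_squared, regression$gold_positive$r_squared)
  bundle <- structure(list(cohort = cohort, entity = entity,
                           combined = combined, regression = regression,
                           min_sens = min_sens, log = log),
                      class = "triage_report")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("<triage_report> %d patients, policies: %s\n",
              nrow(x$cohort), paste(names(x$entity), collapse = ", ")))
  invisible(x)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "fg", flag = "#"))
}

#' Render a per-entity evaluation as a table
#'
#' One row per entity plus two explicitly labelled average rows
#' (arithmetic and pooled). Columns: cutoff, AUC and its CI, the five
#' rates, and the four confusion counts. Rates are proportions at full
#' precision; percentage rounding is left to the caller.
#'
#' @param evaluation an `entity_evaluation` from [evaluate_entities()].
#' @return data.frame.
#' @export
render_entity_table <- function(evaluation) {
  stopifnot(inherits(evaluation, "entity_evaluation"))
  rows <- lapply(chest_entities(), function(e) {
    pe <- evaluation$per_entity[[e]]
    data.frame(entity = e, cutoff = pe$choice$cutoff,
               auc = pe$auc$auc, ci_low = pe$auc$ci_low,
               ci_high = pe$auc$ci_high,
               sensitivity = pe$metrics$sensitivity,
               specificity = pe$metrics$specificity,
               tp = pe$counts$tp, tn = pe$counts$tn,
               fp = pe$counts$fp, fn = pe$counts$fn,
               ppv = pe$metrics$ppv, npv = pe$metrics$npv,
               fpr = pe$metrics$fpr, stringsAsFactors = FALSE)
  })
  avg_rows <- lapply(c("arithmetic", "pooled"), function(meth) {
    av <- evaluation$averages[[meth]]
    data.frame(entity = paste0("average_", meth), cutoff = NA_real_,
               auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               sensitivity = av$metrics[["sensitivity"]],
               specificity = av$metrics[["specificity"]],
               tp = av$mean_counts[["tp"]], tn = av$mean_counts[["tn"]],
               fp = av$mean_counts[["fp"]], fn = av$mean_counts[["fn"]],
               ppv = av$metrics[["ppv"]], npv = av$metrics[["npv"]],
               fpr = av$metrics[["fpr"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, avg_rows))
  rownames(out) <- NULL
  out
}

#' Render the combined-reading comparison table
#'
#' Rows are metrics (sensitivity, specificity, counts, predictive values,
#' workload fractions), columns the evaluated policies.
#'
#' @param report a `triage_report`.
#' @return data.frame with a `metric` column plus one column per policy.
#' @export
render_combined_table <- function(report) {
  stopifnot(inherits(report, "triage_report"))
  cols <- lapply(report$combined, function(cb) {
    m <- cb$metrics
    c(sensitivity = m$sensitivity, specificity = m$specificity,
      tp = cb$counts$tp, tn = cb$counts$tn, fp = cb$counts$fp,
      fn = cb$counts$fn, ppv = m$ppv, npv = m$npv, fpr = m$fpr,
      auto_negative_fraction = cb$workload$auto_negative_fraction,
      missed_fraction = cb$workload$missed_fraction,
      sensitivity_all_positives = cb$standard$sensitivity_all_positives)
  })
  out <- data.frame(metric = names(cols[[1]]), stringsAsFactors = FALSE)
  for (p in names(cols)) out[[p]] <- unname(cols[[p]])
  out
}

#' Render the regression results table
#'
#' @param report a `triage_report`.
#' @return data.frame: one row per subset x covariate with standardized
#'   beta and p value, plus model rows (R-squared, model p, n).
#' @export
render_regression_table <- function(report) {
  stopifnot(inherits(report, "triage_report"))
  rows <- list()
  for (s in names(report$regression)) {
    f <- report$regression[[s]]
    for (v in names(f$beta)) {
      rows[[length(rows) + 1]] <- data.frame(
        subset = s, term = v, value = unname(f$beta[v]),
        p = unname(f$coefficient_p[v]), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      subset = s, term = "r_squared", value = f$r_squared, p = NA_real_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      subset = s, term = "model", value = NA_real_, p = f$model_p,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      subset = s, term = "n_observations", value = f$n_observations,
      p = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all report tables of a pipeline run as CSV
#'
#' Writes one per-entity table per policy (`entity_<policy>.csv`), the
#' combined-reading table (`combined.csv`), the regression table
#' (`regression.csv`) and the run log (`run_log.txt`).
#'
#' @param report a `triage_report`.
#' @param out_dir output directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "triage_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in names(report$entity)) {
    path <- file.path(out_dir, paste0("entity_", p, ".csv"))
    utils::write.csv(render_entity_table(report$entity[[p]]), path,
                     row.names = FALSE)
    paths <- c(paths, path)
  }
  path <- file.path(out_dir, "combined.csv")
  utils::write.csv(render_combined_table(report), path, row.names = FALSE)
  paths <- c(paths, path)
  path <- file.path(out_dir, "regression.csv")
  utils::write.csv(render_regression_table(report), path, row.names = FALSE)
  paths <- c(paths, path)
  path <- file.path(out_dir, "run_log.txt")
  writeLines(report$log, path)
  paths <- c(paths, path)
  invisible(paths)
}
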