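#' Stacked deviation table for the concordance regression
#'
#' One observation per patient x entity. The dependent variable is the
#' deviation of the AI score from the gold standard: the score itself for a
#' gold-negative observation, `1 - score` for a gold-positive one — i.e.
#' `|gold - score|`, so larger values always mean worse concordance.
#' Patient covariates (sex, age, multimorbidity, foreign material) are
#' copied onto each of the patient's seven observations.
#'
#' @param cohort a `cohort`.
#' @return data.frame with columns `patient_id`, `entity`, `gold`, `score`,
#'   `deviation`, `sex`, `age`, `multimorbidity`, `foreign_material`;
#'   `7 * nrow(cohort)` rows, entity varying fastest within patient.
#' @export
build_deviation_table <- function(cohort) {
  df <- as.data.frame(cohort)
  ent <- chest_entities()
  mm <- multimorbidity(cohort)
  obs <- do.call(rbind, lapply(seq_along(ent), function(j) {
    e <- ent[j]
    g <- df[[paste0("gold_", e)]]
    s <- df[[paste0("score_", e)]]
    data.frame(
      patient_id = df$patient_id,
      entity = e,
      gold = g,
      score = s,
      deviation = abs(g - s),
      sex = df$sex,
      age = df$age,
      multimorbidity = mm,
      foreign_material = df$foreign_material,
      stringsAsFactors = FALSE
    )
  }))
  obs <- obs[order(match(obs$patient_id, df$patient_id),
                   match(obs$entity, ent)), ]
  rownames(obs) <- NULL
  obs
}

default_covariates <- c("sex", "age", "multimorbidity", "foreign_material")

#' Blockwise linear regression of deviation on patient covariates
#'
#' Ordinary least squares of the score-to-gold-standard deviation on
#' standardized covariates, fitted separately for the gold-negative and
#' gold-positive observations. Coefficients are standardized betas (all
#' variables z-scored within the subset), so with a single covariate the
#' beta equals the sample correlation. Covariates that are constant within
#' the subset are dropped with a warning. `blocks` gives covariate groups
#' entered cumulatively; the incremental R-squared of each block is
#' reported. By default all four covariates enter as one block.
#'
#' Observations from the same patient are stacked without a correlation
#' adjustment, matching the usual presentation of such analyses;
#' `cluster_robust = TRUE` replaces the coefficient standard errors with
#' patient-clustered (CR) sandwich estimates, since stacking understates
#' uncertainty.
#'
#' @param observations data.frame from [build_deviation_table()].
#' @param subset `"gold_negative"` or `"gold_positive"`.
#' @param blocks list of character vectors of covariate names; default one
#'   block with all of sex, age, multimorbidity, foreign_material.
#' @param cluster_robust logical; use patient-clustered standard errors.
#' @return A `concordance_fit`: list with `subset`, `beta` (standardized),
#'   `beta_se`, `coefficient_p`, `r_squared`, `model_p` (overall F test),
#'   `n_observations`, `dropped` (constant covariates), `blockwise`
#'   (data.frame of cumulative and incremental R-squared per block, NULL
#'   for a single block), and the underlying `fit`.
#' @export
fit_concordance_model <- function(observations,
                                  subset = c("gold_negative", "gold_positive"),
                                  blocks = NULL,
                                  cluster_robust = FALSE) {
  subset <- match.arg(subset)
  keep <- if (subset == "gold_negative") observations$gold == 0 else observations$gold == 1
  dat <- observations[keep, , drop = FALSE]
  if (nrow(dat) < 10) stop("need at least 10 observations in subset ", subset)
  if (is.null(blocks)) blocks <- list(default_covariates)
  covs <- unique(unlist(blocks))
  stopifnot(all(covs %in% names(dat)))
  constant <- covs[vapply(covs, function(v) stats::sd(dat[[v]]) == 0, logical(1))]
  if (length(constant) > 0) {
    warning("dropping constant covariate(s): ", paste(constant, collapse = ", "))
    blocks <- lapply(blocks, setdiff, constant)
    blocks <- blocks[lengths(blocks) > 0]
    covs <- setdiff(covs, constant)
    if (length(covs) == 0) stop("no non-constant covariates left")
  }
  z <- as.data.frame(lapply(dat[c("deviation", covs)], function(v) {
    as.vector(scale(v))
  }))
  fml <- stats::as.formula(paste("deviation ~", paste(covs, collapse = " + ")))
  fit <- stats::lm(fml, data = z)
  qr_rank <- fit$rank
  if (qr_rank < length(covs) + 1) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear covariate(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  beta <- stats::coef(fit)[covs]
  if (cluster_robust) {
    vc <- sandwich::vcovCL(fit, cluster = dat$patient_id)
    se <- sqrt(diag(vc))[covs]
    tval <- beta / se
    n_cl <- length(unique(dat$patient_id))
    pval <- 2 * stats::pt(-abs(tval), df = n_cl - 1)
  } else {
    se <- sm$coefficients[covs, "Std. Error"]
    pval <- sm$coefficients[covs, "Pr(>|t|)"]
  }
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  blockwise <- NULL
  if (length(blocks) > 1) {
    r2 <- numeric(length(blocks))
    sofar <- character(0)
    for (b in seq_along(blocks)) {
      sofar <- union(sofar, blocks[[b]])
      f_b <- stats::as.formula(paste("deviation ~", paste(sofar, collapse = " + ")))
      r2[b] <- summary(stats::lm(f_b, data = z))$r.squared
    }
    blockwise <- data.frame(
      block = seq_along(blocks),
      covariates = vapply(blocks, paste, character(1), collapse = "+"),
      cumulative_r_squared = r2,
      incremental_r_squared = diff(c(0, r2))
    )
  }
  structure(list(
    subset = subset,
    beta = beta,
    beta_se = se,
    coefficient_p = pval,
    r_squared = sm$r.squared,
    model_p = unname(model_p),
    n_observations = nrow(dat),
    dropped = constant,
    blockwise = blockwise,
    cluster_robust = cluster_robust,
    fit = fit
  ), class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf("<concordance_fit> subset=%s n=%d R^2=%.4f model p=%.4g%s\n",
              x$subset, x$n_observations, x$r_squared, x$model_p,
              if (x$cluster_robust) " (cluster-robust SE)" else ""))
  tab <- data.frame(beta = x$beta, se = x$beta_se, p = x$coefficient_p)
  print(round(tab, 4))
  invisible(x)
}

#' Logistic alternative: covariate effects on call/gold disagreement
#'
#' Companion to [fit_concordance_model()]: instead of the continuous
#' deviation, the outcome is whether the thresholded call disagrees with
#' the gold standard at the supplied per-entity cutoffs. Coefficients are
#' log-odds per standard deviation of each covariate.
#'
#' @param observations data.frame from [build_deviation_table()].
#' @param cutoffs named per-entity cutoff vector covering all seven
#'   entities.
#' @inheritParams fit_concordance_model
#' @return List with `subset`, `beta` (log-odds, standardized covariates),
#'   `coefficient_p`, `n_observations`, `fit` (a `glm`).
#' @export
fit_discordance_logistic <- function(observations, cutoffs,
                                     subset = c("gold_negative", "gold_positive")) {
  subset <- match.arg(subset)
  cutoffs <- unlist(cutoffs)
  if (!all(chest_entities() %in% names(cutoffs))) {
    stop("cutoffs must cover all seven entities")
  }
  keep <- if (subset == "gold_negative") observations$gold == 0 else observations$gold == 1
  dat <- observations[keep, , drop = FALSE]
  call <- as.integer(dat$score >= cutoffs[dat$entity])
  dat$disagree <- as.integer(call != dat$gold)
  covs <- default_covariates
  for (v in covs) dat[[v]] <- as.vector(scale(dat[[v]]))
  fit <- stats::glm(stats::as.formula(
    paste("disagree ~", paste(covs, collapse = " + "))),
    family = stats::binomial(), data = dat)
  sm <- summary(fit)
  list(subset = subset,
       beta = stats::coef(fit)[covs],
       coefficient_p = sm$coefficients[covs, "Pr(>|z|)"],
       n_observations = nrow(dat),
       fit = fit)
}
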