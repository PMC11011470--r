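#' Fit a beta distribution to a median and quartiles
#'
#' Finds shape parameters matching the target median exactly (the second
#' shape is solved by root finding for every candidate first shape) while
#' minimizing the summed squared error of the two quartiles. Used to
#' emulate score distributions published only as median (IQR); the median
#' is the primary calibration target, so it is never traded off against
#' the quartiles. A two-parameter beta cannot always match all three
#' quantiles; when the quartile residual exceeds `tol` a `fit_warning`
#' attribute records it.
#'
#' @param median,q1,q3 target quantiles, `0 < q1 < median < q3 < 1`.
#' @param tol maximum acceptable absolute quartile residual before a
#'   fit-quality warning is attached (default 1e-3).
#' @return Named numeric vector `c(shape1, shape2)`, with attributes
#'   `residual` (max absolute error over the three quantiles) and, if the
#'   quartile residual exceeds `tol`, `fit_warning`.
#' @export
fit_beta_from_quantiles <- function(median, q1, q3, tol = 1e-3) {
  if (!(0 < q1 && q1 < median && median < q3 && q3 < 1)) {
    stop("quantiles must satisfy 0 < q1 < median < q3 < 1")
  }
  med <- median
  # qbeta(0.5, a, b) decreases monotonically in b: solve b | median exact
  # bracketing probes hit extreme shape pairs where qbeta warns about its
  # own accuracy; those probes only need the sign, so the warnings are noise
  b_for <- function(a) {
    exp(stats::uniroot(function(lb)
      suppressWarnings(stats::qbeta(0.5, a, exp(lb))) - med,
      lower = -12, upper = 12, tol = 1e-12)$root)
  }
  obj <- function(la) {
    a <- exp(la)
    b <- b_for(a)
    q <- stats::qbeta(c(0.25, 0.75), a, b)
    sum((q - c(q1, q3))^2)
  }
  opt <- stats::optimize(obj, interval = log(c(1e-3, 1e3)), tol = 1e-10)
  a <- exp(opt$minimum)
  b <- b_for(a)
  resid <- max(abs(stats::qbeta(c(0.25, 0.5, 0.75), a, b) - c(q1, med, q3)))
  out <- stats::setNames(c(a, b), c("shape1", "shape2"))
  attr(out, "residual") <- resid
  if (sqrt(opt$objective) > tol) {
    attr(out, "fit_warning") <-
      sprintf("quartile fit residual %.2g exceeds tolerance %.2g: a beta cannot match this median/IQR shape exactly",
              sqrt(opt$objective), tol)
  }
  out
}

#' Solve truncated-normal parameters for target moments
#'
#' Finds the location and scale of a normal distribution such that, after
#' truncation to \[0, 1\], its mean and standard deviation equal the
#' targets. Published summaries report the moments of the observed
#' (bounded) scores, so sampling from `normal(mean, sd)` truncated
#' afterwards would bias the mean towards the centre; this inversion
#' removes that bias.
#'
#' @param mean,sd target moments of the truncated distribution; `mean` in
#'   (0, 1), `sd > 0` and attainable within \[0, 1\].
#' @return Named numeric vector `c(mu, sigma)` of the untruncated normal.
#' @export
truncnorm01_params <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  moments <- function(mu, s) {
    a <- (0 - mu) / s; b <- (1 - mu) / s
    z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + s * (da - db) / z
    v <- s^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
    c(m, sqrt(v))
  }
  obj <- function(p) {
    mo <- suppressWarnings(moments(p[1], exp(p[2])))
    if (any(!is.finite(mo))) return(1)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  opt <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  if (opt$value > 1e-8) {
    stop(sprintf("no [0,1]-truncated normal attains mean %.4f, sd %.4f",
                 mean, sd))
  }
  c(mu = opt$par[1], sigma = exp(opt$par[2]))
}

#' Synthetic cohort generator configuration
#'
#' Bundles every parameter of the cohort generator. Defaults reproduce the
#' composition of the reference study cohort (see
#' [reference_cohort_composition()] and [reference_score_summaries()]):
#' exact per-entity gold-positive counts and finding-multiplicity
#' histogram, beta-distributed positive scores fitted to the published
#' median/IQR, truncated-normal negative scores with the published
#' mean/SD, and the published covariate mix. For `n != 477` the label
#' marginals are rescaled proportionally (with rounding repair so the
#' histogram still sums to `n` and total findings still match the
#' prevalence sum).
#'
#' @param n cohort size (default 477).
#' @param prevalence named integer vector of gold-positive counts per
#'   entity.
#' @param multiplicity named integer vector, names "0", "1", ...: number
#'   of patients with that many findings. `sum(multiplicity) == n` and
#'   `sum(k * multiplicity[k]) == sum(prevalence)` are required.
#' @param positive_quantiles data.frame (`entity`, `median`, `q1`, `q3`)
#'   for gold-positive score distributions.
#' @param negative_moments data.frame (`entity`, `mean`, `sd`) for
#'   gold-negative score distributions (normal truncated to \[0, 1\]).
#' @param male_fraction,age_mean,age_sd,age_range,foreign_fraction
#'   covariate parameters; ages are drawn normal, shifted for positive
#'   patients, clipped to `age_range` and rounded to integer years.
#' @param positive_age_shift additive years applied to patients with at
#'   least one finding (default 7.2, calibrating the published positive
#'   vs negative mean-age contrast of about 68.6 vs 62.1 years).
#' @param effects optional named numeric vector of injected additive
#'   covariate effects on the score deviation (names among `sex`, `age`,
#'   `multimorbidity`, `foreign_material`), on the standardized-beta
#'   scale; used for regression parameter-recovery experiments.
#' @return A `generator_config` (list), with per-entity beta shapes
#'   pre-fitted in `$beta_shapes`.
#' @export
generator_config <- function(n = 477L,
                             prevalence = NULL,
                             multiplicity = NULL,
                             positive_quantiles = NULL,
                             negative_moments = NULL,
                             male_fraction = 0.5954,
                             age_mean = 61.4,
                             age_sd = 16.73,
                             age_range = c(18, 91),
                             positive_age_shift = 7.2,
                             foreign_fraction = 0.4004,
                             effects = NULL) {
  comp <- reference_cohort_composition()
  summ <- reference_score_summaries()
  n <- as.integer(n)
  if (n < 1) stop("n must be positive")
  if (is.null(prevalence) || is.null(multiplicity)) {
    scaled <- scale_label_marginals(n, comp$prevalence, comp$multiplicity)
    if (is.null(prevalence)) prevalence <- scaled$prevalence
    if (is.null(multiplicity)) multiplicity <- scaled$multiplicity
  }
  if (is.null(positive_quantiles)) positive_quantiles <- summ$positive
  if (is.null(negative_moments)) negative_moments <- summ$negative[, c("entity", "mean", "sd")]
  ent <- chest_entities()
  stopifnot(all(ent %in% names(prevalence)),
            identical(sort(positive_quantiles$entity), ent),
            identical(sort(negative_moments$entity), ent))
  k <- as.integer(names(multiplicity))
  if (sum(multiplicity) != n) stop("multiplicity histogram must sum to n")
  if (sum(k * multiplicity) != sum(prevalence)) {
    stop("total findings in multiplicity histogram (", sum(k * multiplicity),
         ") must equal the prevalence sum (", sum(prevalence), ")")
  }
  if (!is.null(effects)) {
    stopifnot(is.numeric(effects),
              all(names(effects) %in% default_covariates))
  }
  pq <- positive_quantiles[match(ent, positive_quantiles$entity), ]
  shapes <- lapply(seq_along(ent), function(j)
    fit_beta_from_quantiles(pq$median[j], pq$q1[j], pq$q3[j]))
  names(shapes) <- ent
  nm_ord <- negative_moments[match(ent, negative_moments$entity), ]
  neg_params <- lapply(seq_along(ent), function(j)
    truncnorm01_params(nm_ord$mean[j], nm_ord$sd[j]))
  names(neg_params) <- ent
  structure(list(
    n = n,
    prevalence = prevalence[ent],
    multiplicity = multiplicity,
    positive_quantiles = pq,
    negative_moments = nm_ord,
    beta_shapes = shapes,
    neg_params = neg_params,
    male_fraction = male_fraction,
    age_mean = age_mean,
    age_sd = age_sd,
    age_range = age_range,
    positive_age_shift = positive_age_shift,
    foreign_fraction = foreign_fraction,
    effects = effects
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d, %d findings across %d entities%s\n",
              x$n, sum(x$prevalence), length(x$prevalence),
              if (is.null(x$effects)) "" else
                paste0(", injected effects on ",
                       paste(names(x$effects), collapse = "/"))))
  invisible(x)
}

# Proportional rescaling of prevalence counts and multiplicity histogram to
# a new n, with largest-remainder repair so both consistency invariants
# (histogram sums to n; total findings match prevalence sum) hold exactly.
scale_label_marginals <- function(n, prevalence, multiplicity) {
  n0 <- sum(multiplicity)
  k <- as.integer(names(multiplicity))
  pos_k <- k > 0
  mult <- round(multiplicity * n / n0)
  # the zero-findings bin absorbs the patient-count rounding remainder
  mult["0"] <- n - sum(mult[pos_k])
  if (mult["0"] < 0) stop("cannot scale multiplicity histogram to n = ", n)
  total <- sum(k * mult)
  prev <- round(prevalence * total / sum(prevalence))
  # repair the findings total on the most prevalent entities
  delta <- total - sum(prev)
  ord <- order(prev, decreasing = TRUE)
  i <- 1
  while (delta != 0) {
    step <- sign(delta)
    if (prev[ord[i]] + step >= 0) {
      prev[ord[i]] <- prev[ord[i]] + step
      delta <- delta - step
    }
    i <- if (i == length(prev)) 1 else i + 1
  }
  list(prevalence = prev, multiplicity = mult)
}

#' Assign gold labels with exact row and column marginals
#'
#' Builds an n x 7 binary matrix whose row-sum histogram equals the
#' configured finding-multiplicity histogram exactly and whose column sums
#' equal the configured per-entity prevalence counts exactly. A greedy
#' pass (patients in decreasing finding count, each assigned to the
#' entities with the largest remaining demand, ties randomized) produces a
#' feasible matrix whenever one exists; random margin-preserving 2x2 swaps
#' then shuffle away the greedy structure. Consumes the current RNG
#' stream.
#'
#' @param config a `generator_config`.
#' @return Binary integer matrix, `config$n` x 7, canonical entity order.
#' @export
assign_findings <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ent <- chest_entities()
  n <- config$n
  k <- as.integer(names(config$multiplicity))
  row_sums <- rep(k, config$multiplicity)
  row_sums <- sample(row_sums)  # random patient order
  demand <- as.numeric(config$prevalence)
  m <- matrix(0L, nrow = n, ncol = length(ent), dimnames = list(NULL, ent))
  for (i in order(row_sums, decreasing = TRUE)) {
    ki <- row_sums[i]
    if (ki == 0) next
    avail <- which(demand > 0)
    if (length(avail) < ki) stop("infeasible label marginals")
    pick <- avail[order(-demand[avail], stats::runif(length(avail)))][seq_len(ki)]
    m[i, pick] <- 1L
    demand[pick] <- demand[pick] - 1
  }
  if (any(demand != 0)) stop("infeasible label marginals")
  total <- sum(m)
  if (total > 0) {
    n_attempts <- max(2000L, 10L * n)
    rows <- sample.int(n, 2L * n_attempts, replace = TRUE)
    for (t in seq_len(n_attempts)) {
      i1 <- rows[2L * t - 1L]; i2 <- rows[2L * t]
      if (i1 == i2) next
      j1 <- which(m[i1, ] == 1L & m[i2, ] == 0L)
      j2 <- which(m[i1, ] == 0L & m[i2, ] == 1L)
      if (length(j1) == 0 || length(j2) == 0) next
      a <- j1[sample.int(length(j1), 1L)]
      b <- j2[sample.int(length(j2), 1L)]
      m[i1, a] <- 0L; m[i2, a] <- 1L
      m[i1, b] <- 1L; m[i2, b] <- 0L
    }
  }
  m
}

# inverse-CDF sampling from normal(mean, sd) truncated to [0, 1]
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a `generator_config`: exact-marginal gold
#' labels, gold-conditional AI scores (beta for positives, truncated
#' normal for negatives), and covariates (sex, integer age with a
#' positive-patient shift, foreign material). If `config$effects` is set,
#' the score-to-gold deviations are perturbed additively on the
#' standardized covariates (scaled by the within-stratum deviation SD so
#' the injected values are recovered as standardized betas), clipped to
#' \[0, 1\] and mapped back to scores. Deterministic given `seed`.
#'
#' @param config a `generator_config`.
#' @param seed integer seed; all randomness flows from it.
#' @return A `cohort` with provenance recording seed and size.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- config$n
  ent <- chest_entities()
  gold <- assign_findings(config)
  mm <- rowSums(gold)
  sex <- stats::rbinom(n, 1, 1 - config$male_fraction)      # 1 = female
  foreign <- stats::rbinom(n, 1, config$foreign_fraction)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  age <- age + ifelse(mm > 0, config$positive_age_shift, 0)
  age <- as.integer(round(pmin(pmax(age, config$age_range[1]),
                               config$age_range[2])))
  scores <- matrix(NA_real_, n, length(ent), dimnames = list(NULL, ent))
  for (j in seq_along(ent)) {
    pos <- gold[, j] == 1L
    sh <- config$beta_shapes[[j]]
    np <- config$neg_params[[j]]
    if (any(pos)) scores[pos, j] <- stats::rbeta(sum(pos), sh[1], sh[2])
    if (any(!pos)) scores[!pos, j] <- rtruncnorm01(sum(!pos), np["mu"], np["sigma"])
  }
  if (!is.null(config$effects)) {
    scores <- inject_deviation_effects(scores, gold, config$effects,
                                       sex = sex, age = age,
                                       multimorbidity = mm,
                                       foreign_material = foreign)
  }
  df <- data.frame(patient_id = sprintf("P%0*d", nchar(n), seq_len(n)),
                   age = age, sex = sex, foreign_material = foreign,
                   stringsAsFactors = FALSE)
  for (e in ent) {
    df[[paste0("gold_", e)]] <- gold[, e]
    df[[paste0("score_", e)]] <- scores[, e]
  }
  as_cohort(df, provenance = sprintf("generated(seed=%d, n=%d)", seed, n))
}

# Additive covariate effects on the deviation scale. Within each gold
# stratum the covariates are z-scored over the stacked patient-x-entity
# observations and the perturbation is scaled by that stratum's deviation
# SD, so each injected coefficient is (approximately) recovered as the
# standardized beta of the stacked regression.
inject_deviation_effects <- function(scores, gold, effects, sex, age,
                                     multimorbidity, foreign_material) {
  dev <- abs(gold - scores)
  covs <- cbind(sex = sex, age = age, multimorbidity = multimorbidity,
                foreign_material = foreign_material)
  for (g in c(0L, 1L)) {
    mask <- gold == g
    if (sum(mask) < 2) next
    s_g <- stats::sd(dev[mask])
    delta <- matrix(0, nrow(scores), ncol(scores))
    for (v in names(effects)) {
      x <- covs[, v]
      xm <- matrix(x, nrow(scores), ncol(scores))
      mu <- mean(xm[mask]); sdv <- stats::sd(xm[mask])
      if (sdv == 0) next
      delta <- delta + effects[[v]] * (xm - mu) / sdv * s_g
    }
    dev[mask] <- pmin(pmax(dev[mask] + delta[mask], 0), 1)
  }
  ifelse(gold == 1L, 1 - dev, dev)
}

#' Read a generator configuration from a YAML file
#'
#' Flat keys mirror the arguments of [generator_config()]; `prevalence`,
#' `multiplicity` and `effects` are YAML maps, `positive_quantiles` and
#' `negative_moments` lists of per-entity maps. Omitted keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  # keep y/n/yes/no as strings: YAML 1.1 would otherwise turn the key "n"
  # into a boolean
  keep <- function(x) x
  raw <- yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                         handlers = list("bool#yes" = keep, "bool#no" = keep))
  args <- list()
  for (key in c("n", "male_fraction", "age_mean", "age_sd",
                "positive_age_shift", "foreign_fraction")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$age_range)) args$age_range <- unlist(raw$age_range)
  for (key in c("prevalence", "multiplicity", "effects")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  for (key in c("positive_quantiles", "negative_moments")) {
    if (!is.null(raw[[key]])) {
      args[[key]] <- do.call(rbind, lapply(raw[[key]], as.data.frame))
    }
  }
  do.call(generator_config, args)
}
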