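test_that("beta quantile fit recovers known shapes and reference targets", {
  # uniform: median 0.5, quartiles 0.25/0.75 correspond to shape (1, 1)
  sh <- fit_beta_from_quantiles(0.5, 0.25, 0.75)
  expect_equal(unname(sh[1]), 1, tolerance = 1e-2)
  expect_equal(unname(sh[2]), 1, tolerance = 1e-2)
  # round trip from a known pair
  q <- qbeta(c(0.25, 0.5, 0.75), 2, 5)
  sh2 <- fit_beta_from_quantiles(q[2], q[1], q[3])
  expect_equal(as.vector(sh2), c(2, 5), tolerance = 1e-2)
  # published pneumonia positive-score quantiles: the median is matched
  # exactly; no two-parameter beta can also hit both quartiles (global
  # search bottoms out near 7e-3), so the quartile misfit is bounded and
  # flagged
  sh3 <- fit_beta_from_quantiles(0.6953, 0.5705, 0.8207)
  fitted_q <- qbeta(c(0.25, 0.5, 0.75), sh3[1], sh3[2])
  expect_lt(abs(fitted_q[2] - 0.6953), 1e-6)
  expect_lt(max(abs(fitted_q[c(1, 3)] - c(0.5705, 0.8207))), 0.02)
  expect_type(attr(sh3, "fit_warning"), "character")
  expect_error(fit_beta_from_quantiles(0.5, 0.6, 0.7), "quantiles")
})

test_that("every default per-entity beta fit matches its median with bounded IQR misfit", {
  cfg <- generator_config()
  pq <- cfg$positive_quantiles
  for (e in chest_entities()) {
    sh <- cfg$beta_shapes[[e]]
    fitted_q <- qbeta(c(0.25, 0.5, 0.75), sh[1], sh[2])
    i <- match(e, pq$entity)
    expect_lt(abs(fitted_q[2] - pq$median[i]), 1e-6)
    expect_lt(max(abs(fitted_q[c(1, 3)] - c(pq$q1[i], pq$q3[i]))), 0.05)
  }
})

test_that("truncated-normal parameters reproduce the target moments after truncation", {
  for (tgt in list(c(0.1581, 0.1411), c(0.4668, 0.1311), c(0.2358, 0.1858))) {
    p <- truncnorm01_params(tgt[1], tgt[2])
    x <- qnorm(seq(1e-6, 1 - 1e-6, length.out = 2e5), p["mu"], p["sigma"])
    x <- x[x >= 0 & x <= 1]  # dense grid restricted to the support
    expect_equal(mean(x), tgt[1], tolerance = 1e-3)
    expect_equal(sd(x), tgt[2], tolerance = 1e-3)
  }
  expect_error(truncnorm01_params(0.5, 0.9), "attains")
})

test_that("gold assignment preserves both marginals exactly", {
  cfg <- generator_config()
  set.seed(31)
  m <- assign_findings(cfg)
  expect_equal(colSums(m), cfg$prevalence, ignore_attr = TRUE)
  expect_equal(as.vector(table(factor(rowSums(m), levels = 0:4))),
               unname(cfg$multiplicity))
  # two seeds: different matrices, identical marginals
  set.seed(32); m2 <- assign_findings(cfg)
  expect_false(identical(m, m2))
  expect_equal(colSums(m2), colSums(m))
  expect_equal(sort(rowSums(m2)), sort(rowSums(m)))
})

test_that("degenerate and infeasible marginals are handled", {
  cfg <- generator_config()
  cfg$multiplicity <- stats::setNames(c(10L), "0")
  cfg$prevalence[] <- 0L
  cfg$n <- 10L
  set.seed(1)
  expect_equal(sum(assign_findings(cfg)), 0)
  # demand one entity eight times among patients with one finding each:
  # infeasible when that entity's demand exceeds patients available
  bad <- generator_config()
  bad$n <- 3L
  bad$multiplicity <- stats::setNames(c(0L, 1L, 1L, 1L), c("0", "1", "2", "7"))
  bad$prevalence[] <- 0L
  bad$prevalence["tumor"] <- 10L
  set.seed(1)
  expect_error(assign_findings(bad), "infeasible")
})

test_that("generation is deterministic given the seed, down to CSV bytes", {
  cfg <- generator_config(n = 60)
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(score_matrix(c1), score_matrix(c3)))
})

test_that("marginal rescaling to other cohort sizes keeps the invariants", {
  for (n in c(100, 1000, 10000)) {
    cfg <- generator_config(n = n)
    expect_equal(sum(cfg$multiplicity), n)
    k <- as.integer(names(cfg$multiplicity))
    expect_equal(sum(k * cfg$multiplicity), sum(cfg$prevalence))
  }
})

test_that("large-cohort score distributions match their calibration targets", {
  cfg <- generator_config(n = 10000)
  co <- generate_cohort(cfg, seed = 77)
  g <- gold_matrix(co); s <- score_matrix(co)
  summ <- reference_score_summaries()
  for (e in chest_entities()) {
    i <- match(e, summ$positive$entity)
    pos_med <- median(s[g[, e] == 1, e])
    # tolerance from the sampling error of a median: 4 x 1/(2 f(q50) sqrt(n))
    sh <- cfg$beta_shapes[[e]]
    se_med <- 0.5 / (dbeta(qbeta(0.5, sh[1], sh[2]), sh[1], sh[2]) *
                       sqrt(sum(g[, e])))
    expect_lt(abs(pos_med - summ$positive$median[i]), 4 * se_med)
    # negative means: 4 x sd/sqrt(n) is ~0.01 at this size
    neg_mean <- mean(s[g[, e] == 0, e])
    expect_lt(abs(neg_mean - summ$negative$mean[i]), 0.01)
    neg_sd <- sd(s[g[, e] == 0, e])
    expect_lt(abs(neg_sd - summ$negative$sd[i]), 0.01)
  }
  # binomial SE at n = 10,000 is ~0.0049; allow 3 SEs
  expect_lt(abs(mean(co$sex == 0) - 0.5954), 0.015)
  expect_lt(abs(mean(co$foreign_material) - 0.4004), 0.015)
  expect_true(all(co$age >= 18 & co$age <= 91))
  # positive patients older by construction
  mm <- multimorbidity(co)
  expect_gt(mean(co$age[mm > 0]), mean(co$age[mm == 0]) + 4)
})

test_that("default-config pipeline yields informative scores (AUC > 0.5 everywhere)", {
  co <- generate_cohort(generator_config(), seed = 2)
  for (e in chest_entities()) {
    curve <- empirical_roc(score_matrix(co)[, e], gold_matrix(co)[, e])
    expect_gt(roc_auc(curve), 0.5)
  }
})

test_that("generator config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n: 50",
    "male_fraction: 0.5",
    "foreign_fraction: 0.25",
    "effects:",
    "  age: 0.1",
    "  sex: -0.05"
  ), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n, 50L)
  expect_equal(cfg$male_fraction, 0.5)
  expect_equal(cfg$effects, c(age = 0.1, sex = -0.05))
  expect_equal(sum(cfg$multiplicity), 50)
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(co), 50)
})
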