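test_that("IQR outlier filter drops extremes by the quartile rule", {
  out <- iqr_outlier_filter(c(1:9, 100), k = 1.5)
  expect_equal(as.numeric(out), 1:9)   # Q1=3.25, Q3=7.75 -> upper 14.5
  expect_equal(attr(out, "removed"), 10L)

  same <- iqr_outlier_filter(rep(5, 6))
  expect_equal(as.numeric(same), rep(5, 6))

  all_kept <- iqr_outlier_filter(c(1:9, 100), k = Inf)
  expect_equal(length(all_kept), 10)
  expect_error(iqr_outlier_filter(1:3), "at least 4")
})

test_that("sequential elimination drops the worst collinear offender first", {
  set.seed(10)
  n <- 200
  base <- rnorm(n)
  # x1 and x2 correlated ~0.9; x3 nearly independent
  feats <- data.frame(ct = base + rnorm(n, 0, 0.45),
                      nt = base + rnorm(n, 0, 0.45),
                      ri = rnorm(n))
  cm <- abs(cor(feats))
  expect_gt(cm["ct", "nt"], 0.5)
  outcomes <- data.frame(y = rnorm(n))
  sel <- correlation_select(feats, outcomes,
                            domains = c(ct = "time", nt = "time", ri = "time"),
                            per_domain = 2, covariates = character(0))
  # one of the 0.9 pair must go; survivors are pairwise below threshold
  expect_length(sel, 2)
  expect_true("ri" %in% sel)
  expect_lt(abs(cor(feats[sel])[1, 2]), 0.5)
})

test_that("below-threshold features are ranked, not eliminated", {
  set.seed(11)
  n <- 150
  y <- rnorm(n)
  feats <- data.frame(a1 = y * 0.45 + rnorm(n),   # most outcome-relevant
                      a2 = y * 0.30 + rnorm(n),
                      a3 = rnorm(n))
  expect_true(max(abs(cor(feats)[upper.tri(diag(3))])) < 0.5)
  sel <- correlation_select(feats, data.frame(y = y),
                            domains = c(a1 = "time", a2 = "time", a3 = "time"),
                            per_domain = 2, covariates = character(0))
  expect_setequal(sel, c("a1", "a2"))
})

test_that("three domains plus SBP yield seven selected features", {
  co <- generate_cohort(cohort_params(n_participants = 40L,
                                      samples_per_participant = 4L,
                                      seed = 21L))$cohort
  feat_cols <- intersect(names(feature_domains()), names(co))
  sel <- correlation_select(co[feat_cols], co[psych_outcomes])
  expect_length(sel, 7)
  expect_true("sbp" %in% sel)
  doms <- feature_domains()[setdiff(sel, "sbp")]
  expect_equal(unname(table(doms)[c("time", "curvature", "frequency")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("univariate regression recovers exact linear relationships", {
  cohort <- data.frame(participant_id = sprintf("P%02d", 1:30),
                       x = seq(-1, 1, length.out = 30))
  cohort$y <- 2 * cohort$x + 1
  fit <- univariate_regression(cohort, "x", "y", mode = "aggregated_ols")
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-10)
  fitc <- univariate_regression(cohort, "x", "y", mode = "cluster_robust")
  expect_equal(fitc$slope, 2, tolerance = 1e-10)

  # duplicating rows k times leaves the aggregated fit unchanged
  dup <- cohort[rep(1:30, each = 3), ]
  fitd <- univariate_regression(dup, "x", "y", mode = "aggregated_ols")
  expect_equal(fitd[c("slope", "se", "t", "p")], fit[c("slope", "se", "t", "p")])

  const <- cohort
  const$x <- 1
  expect_error(univariate_regression(const, "x", "y"), "zero variance")
})

test_that("cluster-robust SE reduces to HC1 with one observation per cluster", {
  set.seed(30)
  d <- data.frame(participant_id = sprintf("P%02d", 1:40),
                  x = rnorm(40))
  d$y <- 0.5 * d$x + rnorm(40)
  fit <- lm(y ~ x, data = d)
  se_hc1 <- sqrt(sandwich::vcovHC(fit, type = "HC1")["x", "x"])
  res <- univariate_regression(d, "x", "y", mode = "cluster_robust")
  expect_equal(res$se, se_hc1, tolerance = 1e-10)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("grouped CV keeps each participant in exactly one test fold", {
  co <- generate_cohort(cohort_params(n_participants = 15L,
                                      samples_per_participant = 3L,
                                      seed = 31L))$cohort
  res <- rf_grouped_cv(co, c("ppt", "ri", "ct"), "phq9", folds = 5, seed = 3)
  all_parts <- unique(co$participant_id)
  seen <- unlist(res$fold_participants)
  expect_setequal(seen, all_parts)
  expect_equal(anyDuplicated(seen), 0L)
  # every row predicted exactly once, out of fold
  expect_equal(nrow(res$predictions), nrow(co))
  for (k in seq_along(res$fold_participants)) {
    test_ids <- res$fold_participants[[k]]
    train_ids <- setdiff(all_parts, test_ids)
    expect_length(intersect(test_ids, train_ids), 0)
  }
  expect_error(rf_grouped_cv(co, "ppt", "phq9", folds = 20, seed = 1),
               "folds")
})

test_that("constant outcomes give zero error and undefined correlation", {
  co <- generate_cohort(cohort_params(n_participants = 10L, seed = 32L))$cohort
  co$constant_y <- 7
  res <- rf_grouped_cv(co, c("ppt", "ri"), "constant_y", folds = 5, seed = 1)
  expect_lt(res$mae, 1e-9)
  expect_true(is.na(res$pearson_r))
})

test_that("random forests detect programmed feature-outcome links", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(cohort_params(
      n_participants = 100L, samples_per_participant = 3L,
      effect_map = c("phq9:f_a" = 4, "phq9:ct" = 3), noise_sd = 2,
      seed = 500L + s))$cohort
    res <- rf_grouped_cv(co, c("f_a", "ct", "ri", "ppt"), "phq9",
                         folds = 5, seed = s)
    if (!is.na(res$p) && res$pearson_r > 0 && res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("Bland-Altman agreement matches its closed forms", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  off <- bland_altman(x + 3, x)
  expect_equal(off$bias, 3)
  expect_equal(off$loa_high - off$loa_low, 0)
  expect_equal(off$pearson_r, 1)

  set.seed(33)
  a <- rnorm(1000)
  b <- rnorm(1000)
  ba <- bland_altman(a, b)
  expect_lt(abs(ba$bias), 0.1)
  half_width <- (ba$loa_high - ba$loa_low) / 2
  expect_equal(half_width, 1.96 * sqrt(2), tolerance = 0.05)
  expect_error(bland_altman(1:5, 1:4), "paired")
})

test_that("aggregated slopes are unbiased on generated cohorts", {
  slopes <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_params(
      n_participants = 60L, samples_per_participant = 3L,
      effect_map = c("phq9:f_a" = 5), noise_sd = 0.5, seed = 700L + s))$cohort
    agg <- aggregate(co[c("f_a", "phq9")],
                     by = list(participant_id = co$participant_id), median)
    fit <- univariate_regression(co, "f_a", "phq9", mode = "aggregated_ols")
    # convert the raw-scale slope back to the standardized programmed one
    fit$slope * sd(agg$f_a)
  }, numeric(1))
  expect_equal(mean(slopes), 5, tolerance = 0.05)
})
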