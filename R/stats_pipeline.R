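#' IQR outlier filter
#'
#' Drops values outside `[Q1 - k*IQR, Q3 + k*IQR]`, quartiles by linear
#' interpolation (type 7). With constant input the bounds collapse onto the
#' value and nothing is removed.
#'
#' @param values numeric vector, length >= 4.
#' @param k IQR multiplier (1.5 by convention).
#' @return The retained values; attribute `"removed"` holds the indices of
#'   dropped elements.
#' @export
iqr_outlier_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - k * iqr
  hi <- q[2L] + k * iqr
  keep <- is.na(values) | (values >= lo & values <= hi)
  out <- values[keep]
  attr(out, "removed") <- which(!keep)
  out
}

#' Mask per-feature outliers in a cohort table
#'
#' Applies [iqr_outlier_filter()] column-wise across samples, setting flagged
#' entries to `NA` so row alignment with identifiers is preserved.
#'
#' @param data data.frame.
#' @param cols columns to filter (default: all numeric).
#' @param k IQR multiplier.
#' @return `data` with outlying entries set to `NA`.
#' @export
iqr_mask_outliers <- function(data, cols = NULL, k = 1.5) {
  if (is.null(cols))
    cols <- names(data)[vapply(data, is.numeric, logical(1L))]
  for (col in cols) {
    v <- data[[col]]
    if (sum(is.finite(v)) < 4L) next
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
    iqr <- q[2L] - q[1L]
    out <- !is.na(v) & (v < q[1L] - k * iqr | v > q[2L] + k * iqr)
    v[out] <- NA_real_
    data[[col]] <- v
  }
  data
}

#' Correlation-based feature selection with per-domain retention
#'
#' Within each feature domain, pairs with absolute Pearson correlation above
#' `threshold` are treated as collinear and resolved by sequential
#' elimination: the worst-offending pair is found, and its member with the
#' larger mean absolute correlation to all remaining features is dropped;
#' this repeats until no pair exceeds the threshold. The surviving features
#' are then ranked by mean absolute correlation with the outcome block and
#' the top `per_domain` are retained. Covariate columns pass through
#' unconditionally. Ties break by column order (earlier kept).
#'
#' @param features data.frame of candidate feature columns (samples x
#'   features).
#' @param domains named character vector mapping feature names to domains;
#'   defaults to [feature_domains()]. Names absent from the map are ignored.
#' @param outcomes data.frame of outcome columns aligned to `features`, used
#'   for the "top" ranking.
#' @param threshold collinearity threshold on `|r|`.
#' @param per_domain features retained per domain.
#' @param covariates column names passed through unchanged.
#' @return Character vector of selected feature names (per-domain picks in
#'   domain order, then covariates).
#' @export
correlation_select <- function(features, outcomes, domains = feature_domains(),
                               threshold = 0.5, per_domain = 2L,
                               covariates = intersect("sbp", names(features))) {
  stopifnot(is.data.frame(features))
  cand <- setdiff(names(features), covariates)
  cand <- cand[cand %in% names(domains)]
  cand <- cand[domains[cand] != "covariate"]
  usable <- vapply(features[cand], function(v)
    sum(is.finite(v)) >= 3 && stats::sd(v, na.rm = TRUE) > 0, logical(1L))
  cand <- cand[usable]
  selected <- character(0L)
  for (dom in c("time", "curvature", "frequency")) {
    cols <- cand[domains[cand] == dom]
    if (length(cols) == 0L) next
    survivors <- .eliminate_collinear(features[cols], threshold)
    if (length(survivors) < per_domain)
      warning(sprintf("domain '%s': only %d features survive elimination",
                      dom, length(survivors)))
    ranked <- .rank_by_outcome_relevance(features[survivors], outcomes)
    selected <- c(selected, ranked[seq_len(min(per_domain, length(ranked)))])
  }
  c(selected, covariates)
}

# Sequential elimination: repeatedly locate the pair with the largest |r| >
# threshold and drop the member with the larger mean |r| to the remaining
# features (ties: the later column).
.eliminate_collinear <- function(df, threshold) {
  cols <- names(df)
  repeat {
    if (length(cols) < 2L) break
    cm <- abs(stats::cor(df[cols], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    idx <- which(cm == worst, arr.ind = TRUE)[1L, ]
    i <- cols[idx[1L]]
    j <- cols[idx[2L]]
    mean_i <- mean(cm[i, setdiff(cols, i)])
    mean_j <- mean(cm[j, setdiff(cols, j)])
    drop <- if (mean_i > mean_j) i
            else if (mean_j > mean_i) j
            else cols[max(match(c(i, j), cols))]
    cols <- setdiff(cols, drop)
  }
  cols
}

# Mean |r| of each feature with the outcome block; descending, ties by
# column order.
.rank_by_outcome_relevance <- function(df, outcomes) {
  rel <- vapply(df, function(v) {
    r <- vapply(outcomes, function(y)
      suppressWarnings(abs(stats::cor(v, y, use = "pairwise.complete.obs"))),
      numeric(1L))
    mean(r, na.rm = TRUE)
  }, numeric(1L))
  rel[is.na(rel)] <- -Inf
  names(df)[order(-rel)]
}

#' Univariate regression of a psychological outcome on one waveform feature
#'
#' Two modes address the nested structure (repeated samples within
#' participants, scores measured once per participant):
#' \describe{
#'   \item{aggregated_ols}{each participant contributes their median feature
#'     value; ordinary least squares at the participant level.}
#'   \item{cluster_robust}{OLS on all rows with CR1 small-sample-corrected
#'     cluster-robust standard errors clustered on participant; two-sided p
#'     from a t reference with (clusters - 2) degrees of freedom.}
#' }
#'
#' @param cohort data.frame with `participant_id`, the feature and outcome
#'   columns.
#' @param feature,outcome column names.
#' @param mode `"aggregated_ols"` or `"cluster_robust"`.
#' @param alpha,m optional significance level and number of comparisons; when
#'   given, the Bonferroni significance flag is filled.
#' @return A one-row data.frame: `feature`, `outcome`, `slope`, `se`, `t`,
#'   `p`, `method`, `n`, `n_clusters`, `significant_at_bonferroni`.
#' @export
univariate_regression <- function(cohort, feature, outcome,
                                  mode = c("aggregated_ols", "cluster_robust"),
                                  alpha = 0.05, m = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("participant_id", feature, outcome) %in% names(cohort)))
  dat <- cohort[stats::complete.cases(cohort[c(feature, outcome)]), ]
  clusters <- unique(dat$participant_id)
  if (length(clusters) < 3L) stop("need at least 3 participants")
  if (mode == "aggregated_ols") {
    agg <- stats::aggregate(dat[c(feature, outcome)],
                            by = list(participant_id = dat$participant_id),
                            FUN = stats::median)
    if (stats::sd(agg[[feature]]) == 0) stop("feature has zero variance")
    fit <- stats::lm(stats::reformulate(feature, outcome), data = agg)
    sm <- summary(fit)$coefficients
    slope <- sm[feature, "Estimate"]
    se <- sm[feature, "Std. Error"]
    tval <- sm[feature, "t value"]
    p <- sm[feature, "Pr(>|t|)"]
    n <- nrow(agg)
  } else {
    if (stats::sd(dat[[feature]]) == 0) stop("feature has zero variance")
    fit <- stats::lm(stats::reformulate(feature, outcome), data = dat)
    vc <- sandwich::vcovCL(fit, cluster = dat$participant_id, type = "HC1")
    slope <- stats::coef(fit)[[feature]]
    se <- sqrt(vc[feature, feature])
    tval <- slope / se
    df <- length(clusters) - 2L
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    n <- nrow(dat)
  }
  sig <- if (!is.null(m)) p < bonferroni_threshold(alpha, m) else NA
  data.frame(feature = feature, outcome = outcome, slope = slope, se = se,
             t = tval, p = p, method = mode, n = n,
             n_clusters = length(clusters),
             significant_at_bonferroni = sig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return `alpha / m` (summaries print it to 4 decimals).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  if (!is.finite(m) || m < 1) stop("`m` must be >= 1")
  alpha / m
}

# Participant-exclusive fold assignment: shuffle participants, deal them
# round-robin into folds.
.grouped_folds <- function(participants, folds) {
  participants <- unique(participants)
  if (folds > length(participants))
    stop("more folds than participants")
  shuffled <- sample(participants)
  split(shuffled, rep_len(seq_len(folds), length(shuffled)))
}

#' Random-forest regression under participant-grouped cross-validation
#'
#' All observations from a participant land in exactly one test fold, so no
#' within-person information leaks from training to evaluation. The forest
#' uses 100 trees, variance (MSE) splitting, trees grown to full depth
#' (terminal node size 1), all features considered at each split, and
#' bootstrap resampling. Out-of-fold predictions are pooled; performance is
#' reported as pooled and fold-averaged mean absolute error and Pearson
#' correlation between predicted and observed values, with
#' mean-decrease-in-impurity importances averaged over folds.
#'
#' @param cohort data.frame with `participant_id`, features and outcome.
#' @param features character vector of feature column names.
#' @param outcome outcome column name.
#' @param folds number of folds (5).
#' @param seed master seed; per-fold seeds are derived from it.
#' @param ntree trees per forest.
#' @return A list of class `cv_result`: `mae`, `pearson_r`, `p` (pooled),
#'   `mae_per_fold`, `r_per_fold`, `importances`, `predictions` (data.frame
#'   with `participant_id`, `fold`, `observed`, `predicted`), `fold_participants`.
#' @export
rf_grouped_cv <- function(cohort, features, outcome, folds = 5L, seed = 1L,
                          ntree = 100L) {
  stopifnot(all(c("participant_id", features, outcome) %in% names(cohort)))
  dat <- cohort[stats::complete.cases(cohort[c(features, outcome)]), ]
  participants <- unique(dat$participant_id)
  if (folds > length(participants)) stop("more folds than participants")
  set.seed(seed)
  assignment <- .grouped_folds(dat$participant_id, folds)
  fold_seeds <- sample.int(.Machine$integer.max %/% 2L, folds)
  preds <- vector("list", folds)
  imps <- matrix(0, nrow = length(features), ncol = folds,
                 dimnames = list(features, NULL))
  for (k in seq_len(folds)) {
    test_ids <- assignment[[k]]
    tr <- dat[!dat$participant_id %in% test_ids, ]
    te <- dat[dat$participant_id %in% test_ids, ]
    set.seed(fold_seeds[k])
    rf <- randomForest::randomForest(
      x = tr[features], y = tr[[outcome]],
      ntree = ntree, mtry = length(features), nodesize = 1L,
      replace = TRUE, importance = FALSE)
    imps[, k] <- rf$importance[features, "IncNodePurity"]
    preds[[k]] <- data.frame(participant_id = te$participant_id, fold = k,
                             observed = te[[outcome]],
                             predicted = stats::predict(rf, te[features]),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  pd <- do.call(rbind, preds)
  mae_fold <- vapply(preds, function(p) mean(abs(p$observed - p$predicted)),
                     numeric(1L))
  r_fold <- vapply(preds, function(p) {
    if (stats::sd(p$observed) == 0 || stats::sd(p$predicted) == 0)
      return(NA_real_)
    stats::cor(p$observed, p$predicted)
  }, numeric(1L))
  if (stats::sd(pd$observed) > 0 && stats::sd(pd$predicted) > 0) {
    ct <- stats::cor.test(pd$observed, pd$predicted)
    r_pool <- unname(ct$estimate)
    p_pool <- ct$p.value
  } else {
    r_pool <- NA_real_
    p_pool <- NA_real_
  }
  structure(list(mae = mean(abs(pd$observed - pd$predicted)),
                 pearson_r = r_pool, p = p_pool,
                 mae_per_fold = mae_fold, r_per_fold = r_fold,
                 importances = rowMeans(imps),
                 predictions = pd,
                 fold_participants = assignment),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> pooled MAE %.3f, r = %s (p = %s), %d folds\n",
              x$mae,
              format(x$pearson_r, digits = 3),
              format(x$p, digits = 3),
              length(x$mae_per_fold)))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies absolute agreement between two paired measurement series:
#' bias = mean difference, 95% limits of agreement = bias +/- 1.96 * SD of
#' the differences (sample SD), plus the Pearson correlation for association
#' strength.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return A one-row data.frame: `bias`, `loa_low`, `loa_high`, `pearson_r`,
#'   `p`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired (equal length)")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    r <- NA_real_
    p <- NA_real_
  }
  data.frame(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
             pearson_r = r, p = p, n = length(x))
}

#' Run the full univariate analysis grid
#'
#' Regresses every outcome on every selected feature in both inference modes
#' and flags Bonferroni-corrected significance at `alpha / length(features)`.
#'
#' @param cohort cohort data.frame.
#' @param features selected feature names.
#' @param outcomes outcome column names.
#' @param modes inference modes to run.
#' @param alpha family-wise error rate.
#' @return data.frame stacking [univariate_regression()] rows.
#' @export
univariate_grid <- function(cohort, features, outcomes,
                            modes = c("aggregated_ols", "cluster_robust"),
                            alpha = 0.05) {
  m <- length(features)
  rows <- list()
  for (mode in modes)
    for (f in features)
      for (o in outcomes)
        rows[[length(rows) + 1L]] <- tryCatch(
          univariate_regression(cohort, f, o, mode = mode, alpha = alpha,
                                m = m),
          error = function(e) NULL)
  do.call(rbind, rows)
}
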