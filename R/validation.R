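#' Screen device-versus-stopwatch speed pairs and correlate
#'
#' Applies the two exclusion rules used when validating device gait speed
#' against a hand stopwatch: (i) pairs whose stopwatch speed exceeds
#' `max_stopwatch` m/s are dropped outright (faster than plausible walking;
#' almost certainly a stopwatch misread), then (ii) pairs whose
#' device-minus-stopwatch difference lies more than `sd_cut` SDs from the
#' mean difference of the remaining pairs are dropped. Pearson correlation
#' is computed on the survivors.
#'
#' @param data Data frame with device and stopwatch speed columns.
#' @param device,stopwatch Column names (tidy-eval) of the two speeds.
#' @param max_stopwatch Absolute stopwatch plausibility bound, m/s.
#' @param sd_cut Difference-distribution cut, SDs.
#' @return List of class `speed_validation`: `kept` (tibble with the
#'   surviving pairs), `excluded` (tibble with `reason`), `r`, `p`,
#'   `median_abs_diff`, `n`.
#' @export
exclude_speed_outliers <- function(data, device = "device_speed",
                                   stopwatch = "stopwatch_speed",
                                   max_stopwatch = 2.5, sd_cut = 2.5) {
  d <- tibble(device = data[[device]], stopwatch = data[[stopwatch]])
  stopifnot(nrow(d) > 0, !anyNA(d))
  absurd <- d$stopwatch > max_stopwatch
  rest <- d[!absurd, ]
  diffs <- rest$device - rest$stopwatch
  far <- abs(diffs - mean(diffs)) > sd_cut * sd(diffs)
  kept <- rest[!far, ]
  if (nrow(kept) < 3) abort("fewer than 3 pairs remain after exclusion")
  ct <- cor.test(kept$device, kept$stopwatch)
  excluded <- dplyr::bind_rows(
    dplyr::mutate(d[absurd, ], reason = "stopwatch_over_max"),
    dplyr::mutate(rest[far, ], reason = "difference_outlier")
  )
  structure(
    list(kept = kept, excluded = excluded,
         r = unname(ct$estimate), p = ct$p.value,
         median_abs_diff = median(abs(kept$device - kept$stopwatch)),
         n = nrow(kept)),
    class = "speed_validation"
  )
}

#' @export
print.speed_validation <- function(x, ...) {
  cat(sprintf(
    "<speed_validation> r = %.3f (p = %.3g) on %d pairs; %d excluded; median |diff| = %.3f m/s\n",
    x$r, x$p, x$n, nrow(x$excluded), x$median_abs_diff))
  invisible(x)
}

#' Leave-one-out cross-validated single-feature logistic prediction
#'
#' For each subject in turn, a logistic model of the binary outcome on the
#' single feature is fitted to all other subjects and used to predict the
#' held-out one. Accuracy is the fraction of correct held-out predictions
#' at probability 0.5; AUC is computed from the held-out probabilities by
#' the rank (Mann-Whitney) statistic with ties averaged. Folds whose
#' training data lose a class entirely are flagged and skipped.
#'
#' @param data Data frame.
#' @param feature Name of the numeric predictor column.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @return Object of class `loocv_result`: `accuracy`, `auc`,
#'   `predictions` (tibble: `feature`, `truth`, `prob`, `predicted`),
#'   `roc` (tibble of ROC points), `n_skipped`. Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
loocv_logistic <- function(data, feature, outcome) {
  x <- data[[feature]]
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(y)
  if (n < 10) abort("need at least 10 subjects")
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  prob <- rep(NA_real_, n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    if (length(unique(yt)) < 2) {
      skipped[i] <- TRUE
      next
    }
    fit <- suppressWarnings(glm(yt ~ x[-i], family = binomial()))
    eta <- coef(fit)[1] + coef(fit)[2] * x[i]
    prob[i] <- stats::plogis(unname(eta))
  }
  ok <- !skipped
  if (any(skipped)) {
    warn(sprintf("%d folds skipped: a class was absent from training data",
                 sum(skipped)))
  }
  pred <- as.integer(prob[ok] >= 0.5)
  acc <- mean(pred == y[ok])
  auc <- rank_auc(prob[ok], y[ok])
  thr <- sort(unique(c(-Inf, prob[ok], Inf)))
  roc <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(th) mean(prob[ok][y[ok] == 1] >= th), numeric(1)),
    fpr = vapply(thr, function(th) mean(prob[ok][y[ok] == 0] >= th), numeric(1))
  )
  structure(
    list(accuracy = acc, auc = auc,
         predictions = tibble(feature = x[ok], truth = y[ok],
                              prob = prob[ok], predicted = pred),
         roc = roc, n_skipped = sum(skipped)),
    class = "loocv_result"
  )
}

# Mann-Whitney AUC from scores, ties averaged
rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> accuracy = %.1f%%, AUC = %.1f%% (%d held-out predictions)\n",
              100 * x$accuracy, 100 * x$auc, nrow(x$predictions)))
  invisible(x)
}

#' Two-sample tests and correlations for group comparisons
#'
#' Thin tidy wrapper over the standard two-sided tests used for cohort
#' comparisons: Mann-Whitney (Wilcoxon rank-sum), Kolmogorov-Smirnov,
#' Welch t, and Pearson correlation (for `test = "pearson"`, `group` is the
#' second numeric variable rather than a label).
#'
#' @param data Data frame.
#' @param values Name of the numeric column.
#' @param group Name of the two-level grouping column (or the second numeric
#'   column for Pearson).
#' @param test One of `"mann_whitney"`, `"ks"`, `"t"`, `"pearson"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n1`, `n2`.
#' @export
group_tests <- function(data, values, group,
                        test = c("mann_whitney", "ks", "t", "pearson")) {
  test <- match.arg(test)
  v <- data[[values]]
  g <- data[[group]]
  if (test == "pearson") {
    ht <- cor.test(v, g)
    return(tibble(test = test, statistic = unname(ht$estimate),
                  p_value = ht$p.value, n1 = length(v), n2 = length(v)))
  }
  lv <- unique(g[!is.na(g)])
  if (length(lv) != 2) abort("group column must have exactly 2 levels")
  a <- v[g == lv[1]]; b <- v[g == lv[2]]
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  ht <- switch(test,
               mann_whitney = suppressWarnings(wilcox.test(a, b)),
               ks = suppressWarnings(ks.test(a, b)),
               t = t.test(a, b))
  tibble(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
         n1 = length(a), n2 = length(b))
}

#' Fried frailty phenotype grouping
#'
#' Maps Fried Frailty Index scores (0-5) to the standard phenotype groups:
#' 0 is robust, 1-2 prefrail, above 2 frail.
#'
#' @param fried Integer vector of Fried scores in 0-5.
#' @return Factor with levels `robust`, `prefrail`, `frail`.
#' @export
frailty_groups <- function(fried) {
  if (any(!is.na(fried) & (fried < 0 | fried > 5))) {
    abort("Fried scores must lie in 0-5")
  }
  factor(ifelse(fried == 0, "robust", ifelse(fried <= 2, "prefrail", "frail")),
         levels = c("robust", "prefrail", "frail"))
}

#' Binarize Quality of Recovery-15 scores
#'
#' Scores strictly above the validated cutoff (121 by default) indicate
#' good recovery; scores at or below it indicate poor recovery.
#'
#' @param qor15 Integer vector of QoR-15 scores in 0-150.
#' @param cutoff Good-recovery cutoff.
#' @return Factor with levels `poor`, `good`.
#' @export
qor_binarize <- function(qor15, cutoff = 121) {
  if (any(!is.na(qor15) & (qor15 < 0 | qor15 > 150))) {
    abort("QoR-15 scores must lie in 0-150")
  }
  factor(ifelse(qor15 > cutoff, "good", "poor"), levels = c("poor", "good"))
}

#' Speed-by-cadence interaction model for recovery outcomes
#'
#' Logistic regression of a binary recovery outcome on gait speed, cadence,
#' and their interaction; the quantity of interest is the interaction-term
#' odds ratio with its Wald 95% confidence interval. The model can be run
#' for any combination of devices supplying the speed and cadence columns.
#' Complete separation (non-convergence or exploding coefficients) is
#' flagged rather than silently reported.
#'
#' @param data Data frame.
#' @param speed,cadence,outcome Column names; the outcome must be binary
#'   (logical, 0/1, or a two-level factor whose second level is the event).
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `qor_interaction`: the `fit`, `interaction_or`,
#'   `conf_low`, `conf_high`, `p`, `separation_flag`, `n`. Supports
#'   [tidy()] and [glance()].
#' @export
qor_interaction_model <- function(data, speed = "speed", cadence = "cadence",
                                  outcome = "outcome", conf_level = 0.95) {
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1))
  if (length(y) < 20) abort("need at least 20 subjects")
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  df <- tibble(y = y, s = data[[speed]], c = data[[cadence]])
  fit <- suppressWarnings(glm(y ~ s * c, family = binomial(), data = df))
  cf <- summary(fit)$coefficients
  beta <- cf["s:c", "Estimate"]
  se <- cf["s:c", "Std. Error"]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  sep <- !fit$converged || abs(beta) > 15 || se > 1e3
  if (sep) {
    warn("possible separation: consider a penalized (e.g. ridge) refit")
  }
  structure(
    list(fit = fit, interaction_or = exp(beta),
         conf_low = exp(beta - zq * se), conf_high = exp(beta + zq * se),
         p = cf["s:c", "Pr(>|z|)"], separation_flag = sep, n = length(y)),
    class = "qor_interaction"
  )
}

#' @export
print.qor_interaction <- function(x, ...) {
  cat(sprintf("<qor_interaction> interaction OR = %.3f [%.3f, %.3f], p = %.3g, n = %d%s\n",
              x$interaction_or, x$conf_low, x$conf_high, x$p, x$n,
              if (x$separation_flag) " [separation]" else ""))
  invisible(x)
}
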