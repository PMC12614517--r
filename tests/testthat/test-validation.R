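test_that("concordant speed pairs survive screening with r = 1", {
  d <- tibble::tibble(device_speed = seq(0.8, 1.8, by = 0.1),
                      stopwatch_speed = seq(0.8, 1.8, by = 0.1))
  v <- exclude_speed_outliers(d)
  expect_equal(nrow(v$excluded), 0L)
  expect_equal(v$r, 1)
  expect_equal(v$median_abs_diff, 0)
})

test_that("implausible stopwatch speeds are excluded by the absolute rule", {
  set.seed(51)
  d <- tibble::tibble(device_speed = c(rnorm(20, 1.2, 0.2), 1.1),
                      stopwatch_speed = c(rnorm(20, 1.2, 0.2), 3.0))
  v <- exclude_speed_outliers(d)
  expect_equal(v$excluded$reason, "stopwatch_over_max")
  expect_equal(v$excluded$stopwatch, 3.0)
})

test_that("a planted difference outlier is the only pair excluded", {
  set.seed(52)
  n <- 50
  sw <- runif(n, 0.8, 1.8)
  diffs <- rnorm(n, mean = 0.05, sd = 0.04)
  diffs[17] <- 0.05 + 5 * 0.04  # 5 SDs from the mean difference
  d <- tibble::tibble(device_speed = sw + diffs, stopwatch_speed = sw)
  v <- exclude_speed_outliers(d)
  expect_equal(nrow(v$excluded), 1L)
  expect_equal(v$excluded$reason, "difference_outlier")
  expect_equal(v$excluded$device, d$device_speed[17])
  expect_gt(v$r, 0.99)
})

test_that("LOOCV separates a clean feature and is null on an independent one", {
  d <- tibble::tibble(x = c(rnorm(20, 0), rnorm(20, 10)),
                      y = rep(0:1, each = 20))
  r <- loocv_logistic(d, "x", "y")
  expect_equal(r$auc, 1)
  expect_gt(r$accuracy, 0.95)

  set.seed(53)
  d0 <- tibble::tibble(x = rnorm(200), y = rep(0:1, 100))
  expect_lt(abs(loocv_logistic(d0, "x", "y")$auc - 0.5), 0.1)
})

test_that("LOOCV predictions equal a brute-force per-fold refit oracle", {
  set.seed(54)
  d <- tibble::tibble(x = rnorm(20), y = rbinom(20, 1, plogis(rnorm(20) + 0.8)))
  if (length(unique(d$y)) < 2) d$y[1:2] <- 0:1
  r <- loocv_logistic(d, "x", "y")
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    fit <- suppressWarnings(glm(y ~ x, binomial(), data = d[-i, ]))
    unname(predict(fit, newdata = d[i, ], type = "response"))
  }, numeric(1))
  expect_equal(r$predictions$prob, oracle, tolerance = 1e-12)
})

test_that("group tests match closed forms and an exact permutation oracle", {
  d_same <- tibble::tibble(v = rep(c(1, 2, 3), 2),
                           g = rep(c("a", "b"), each = 3))
  expect_equal(group_tests(d_same, "v", "g", "ks")$statistic, 0)

  d_sep <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                          g = rep(c("a", "b"), each = 3))
  expect_equal(group_tests(d_sep, "v", "g", "mann_whitney")$statistic, 0)

  # exact permutation oracle for the rank-sum p on 3 + 3 values
  v <- c(1.3, 2.1, 0.7, 3.9, 2.8, 4.4)
  d <- tibble::tibble(v = v, g = rep(c("a", "b"), each = 3))
  obs <- abs(sum(rank(v)[1:3]) - 3 * 7 / 2)
  perms <- combn(6, 3)
  null_stats <- apply(perms, 2, function(ix) abs(sum(rank(v)[ix]) - 3 * 7 / 2))
  p_exact <- mean(null_stats >= obs)
  expect_equal(group_tests(d, "v", "g", "mann_whitney")$p_value, p_exact,
               tolerance = 1e-10)

  d_num <- tibble::tibble(v = 1:20 + rnorm(20, sd = 0.1), w = 1:20)
  expect_gt(group_tests(d_num, "v", "w", "pearson")$statistic, 0.99)
})

test_that("frailty grouping follows the standard phenotype cuts", {
  expect_equal(as.character(frailty_groups(c(0, 1, 2, 3, 5))),
               c("robust", "prefrail", "prefrail", "frail", "frail"))
  expect_error(frailty_groups(6), "0-5")
})

test_that("QoR-15 binarization uses a strict cutoff at 121", {
  expect_equal(as.character(qor_binarize(c(122, 121, 0))),
               c("good", "poor", "poor"))
  expect_error(qor_binarize(151), "0-150")
})

test_that("interaction odds ratio is invariant to dataset duplication", {
  set.seed(55)
  n <- 100
  s <- rnorm(n, 1.2, 0.27); cad <- rnorm(n, 111, 11)
  y <- rbinom(n, 1, plogis(scale(s) * scale(cad) * 0.8))
  d <- tibble::tibble(speed = s, cadence = cad, outcome = y)
  m1 <- qor_interaction_model(d)
  m2 <- qor_interaction_model(dplyr::bind_rows(d, d))
  expect_equal(m2$interaction_or, m1$interaction_or, tolerance = 1e-6)
})

test_that("a generated positive interaction is recovered with the right sign", {
  hits <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 150
    sp <- rnorm(n, 1.2, 0.27); cad <- rnorm(n, 111, 11)
    inter <- as.numeric(scale(sp)) * as.numeric(scale(cad))
    y <- rbinom(n, 1, plogis(0.2 + 0.8 * inter))
    qor_interaction_model(tibble::tibble(speed = sp, cadence = cad,
                                         outcome = y))$interaction_or > 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null interaction confidence intervals cover OR = 1", {
  cover <- vapply(1:60, function(s) {
    set.seed(900 + s)
    n <- 250
    sp <- rnorm(n); cad <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    m <- qor_interaction_model(tibble::tibble(speed = sp, cadence = cad,
                                              outcome = y))
    m$conf_low <= 1 && m$conf_high >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})
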