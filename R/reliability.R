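#' Intraclass correlation for test-retest reliability
#'
#' Single-measure ICC from the ANOVA mean squares of an n-subjects by
#' k-trials table. Three variance-component forms are offered:
#' `"oneway"` (one-way random effects, ICC(1) — the default, matching the
#' default of the commonly used reliability packages), `"twoway_consistency"`
#' (two-way, ICC(C,1)) and `"twoway_agreement"` (two-way, ICC(A,1)).
#' P-values are the F tests of McGraw & Wong (1996), testing ICC = 0.
#'
#' @param pairs Data frame with one trial column per repeat (e.g. `trial1`,
#'   `trial2`), one row per subject; or a numeric matrix.
#' @param form ICC form; see Details.
#' @return Object of class `icc_result`: `icc`, `p`, `f`, `df1`, `df2`,
#'   `form`, `n`, `k`, the mean squares, and the input `data`. Supports
#'   [tidy()], [glance()] and `autoplot()`.
#' @export
icc <- function(pairs, form = c("oneway", "twoway_consistency",
                                "twoway_agreement")) {
  form <- match.arg(form)
  x <- as.matrix(as.data.frame(pairs))
  if (anyNA(x)) abort("all trials must be present for every included subject")
  if (nrow(x) < 3) abort("need at least 3 subjects")
  if (ncol(x) < 2) abort("need at least 2 trials per subject")
  res <- icc_from_matrix(x, form)
  res$data <- as_tibble(as.data.frame(x))
  class(res) <- "icc_result"
  res
}

# lean core shared with the permutation loop
icc_from_matrix <- function(x, form) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssb <- k * sum((rm_ - grand)^2)         # between subjects
  ssc <- n * sum((cm - grand)^2)          # between trials (columns)
  sst <- sum((x - grand)^2)
  msb <- ssb / (n - 1)
  if (form == "oneway") {
    ssw <- sst - ssb
    msw <- ssw / (n * (k - 1))
    if (msb + (k - 1) * msw <= 0) abort("zero total variance")
    val <- (msb - msw) / (msb + (k - 1) * msw)
    f <- msb / msw
    df1 <- n - 1; df2 <- n * (k - 1)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  } else {
    sse <- sst - ssb - ssc
    mse <- sse / ((n - 1) * (k - 1))
    msc <- ssc / (k - 1)
    if (form == "twoway_consistency") {
      val <- (msb - mse) / (msb + (k - 1) * mse)
      f <- msb / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      p <- pf(f, df1, df2, lower.tail = FALSE)
    } else {
      val <- (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msc - mse))
      # McGraw & Wong approximate F test for ICC(A,1) = 0
      a <- (k * val) / (n * (1 - val))
      b <- 1 + (k * val * (n - 1)) / (n * (1 - val))
      f <- msb / (a * msc + b * mse)
      v_num <- (a * msc + b * mse)^2
      v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
      df1 <- n - 1; df2 <- v_num / v_den
      p <- pf(f, df1, df2, lower.tail = FALSE)
    }
    return(list(icc = val, p = p, f = f, df1 = df1, df2 = df2, form = form,
                n = n, k = k, msb = msb, msc = msc, mse = mse))
  }
  list(icc = val, p = p, f = f, df1 = df1, df2 = df2, form = form,
       n = n, k = k, msb = msb, msw = msw)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s), F(%g, %.3g) = %.2f, p = %.3g, n = %d\n",
              x$icc, x$form, x$df1, x$df2, x$f, x$p, x$n))
  invisible(x)
}

#' Permutation test for the ICC
#'
#' Shuffles the second-trial values across subjects `n_perm` times —
#' breaking the pairing while preserving both marginals — and recomputes
#' the ICC each time. `Q` is the fraction of permuted ICCs at least as
#' large as the observed one, reported with the (b + 1) / (n_perm + 1)
#' correction so it is never exactly zero.
#'
#' @param pairs As in [icc()] (two trial columns).
#' @param n_perm Number of permutations (10,000 by default).
#' @param seed Integer seed for the shuffles.
#' @param form ICC form, as in [icc()].
#' @return List of class `icc_permutation`: `q`, `observed` (the
#'   `icc_result`), `null_icc` (permuted values) and `n_perm`.
#' @export
icc_permutation <- function(pairs, n_perm = 10000, seed = NULL,
                            form = "oneway") {
  if (!is.null(seed)) set.seed(seed)
  obs <- icc(pairs, form = form)
  x <- as.matrix(as.data.frame(pairs))
  n <- nrow(x)
  null_icc <- vapply(seq_len(n_perm), function(b) {
    xb <- cbind(x[, 1], x[sample.int(n), 2])
    icc_from_matrix(xb, form)$icc
  }, numeric(1))
  structure(
    list(q = (sum(null_icc >= obs$icc) + 1) / (n_perm + 1),
         observed = obs, null_icc = null_icc, n_perm = n_perm),
    class = "icc_permutation"
  )
}

#' @export
print.icc_permutation <- function(x, ...) {
  cat(sprintf("<icc_permutation> observed ICC = %.3f, Q = %.4g (%d shuffles)\n",
              x$observed$icc, x$q, x$n_perm))
  invisible(x)
}
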