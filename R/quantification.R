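# quantification: exposed-vs-control comparison of peak heights with the
# tiered normality -> variance -> test decision rules

# Lilliefors-corrected Kolmogorov-Smirnov normality test: the KS statistic
# with estimated mean/sd is compared against a Monte-Carlo null distribution
# (plain KS with estimated parameters is anticonservative). Null tables are
# simulated once per sample size (seeded deterministically) and cached.
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Lilliefors (Monte-Carlo) normality test
#'
#' @param x numeric sample (n >= 4, nonzero variance).
#' @param n_sim Monte-Carlo replicates for the null table (cached per sample
#'   size; the simulation seed is fixed and independent of the caller's RNG).
#' @return list with `statistic` and `p_value`.
#' @export
lilliefors_test <- function(x, n_sim = 10000) {
  n <- length(x)
  if (n < 3) abort("lilliefors_test needs n >= 3", "insufficient_data_error")
  if (stats::sd(x) == 0) abort("zero-variance sample", "degenerate_input_error")
  key <- sprintf("n%d_%d", n, n_sim)
  if (is.null(.lilliefors_cache[[key]])) {
    .lilliefors_cache[[key]] <- with_seed(20231100 + n, {
      vapply(seq_len(n_sim),
             function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
    })
  }
  null <- .lilliefors_cache[[key]]
  d <- lilliefors_statistic(x)
  list(statistic = d, p_value = (1 + sum(null >= d)) / (length(null) + 1))
}

#' Levene's test for equality of variances (classic, mean-centred)
#'
#' One-way ANOVA on the absolute deviations from each group's mean.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (F), `df`, and `p_value`.
#' @export
levene_test <- function(x, y) {
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  z <- c(zx, zy)
  g <- rep(1:2, c(length(x), length(y)))
  k <- 2; n <- length(z)
  means <- tapply(z, g, mean)
  ssb <- sum(tapply(z, g, length) * (means - mean(z))^2)
  ssw <- sum((z - means[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# decide and run the tiered two-group test; returns a one-row data.frame
tiered_group_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    abort("both groups need n >= 3", "insufficient_data_error")
  }
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    # constant heights carry no distributional information; fall through to
    # the rank-based path, which tolerates ties
    sw_p <- 0; ks_p <- 0
  } else {
    sw_p <- min(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
    ks_p <- min(lilliefors_test(x)$p_value, lilliefors_test(y)$p_value)
  }
  if (sw_p < alpha || ks_p < alpha) {
    kw <- stats::kruskal.test(list(x, y))
    return(data.frame(test_used = "kruskal_wallis", levene_p = NA_real_,
                      normality_p_ks = ks_p, normality_p_sw = sw_p,
                      test_p = kw$p.value))
  }
  lv <- levene_test(x, y)
  if (lv$p_value < alpha) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(test_used = "welch_t", levene_p = lv$p_value,
               normality_p_ks = ks_p, normality_p_sw = sw_p,
               test_p = tt$p.value)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(test_used = "student_t", levene_p = lv$p_value,
               normality_p_ks = ks_p, normality_p_sw = sw_p,
               test_p = tt$p.value)
  }
}

#' Compare exposed and control cohorts per peak
#'
#' For every selected peak: both normality tests (Shapiro-Wilk and
#' Lilliefors-corrected Kolmogorov-Smirnov) are run on each group; if any
#' rejects at `alpha` the nonparametric Kruskal-Wallis test is used,
#' otherwise Levene's test routes to the Student (equal variances) or Welch
#' (unequal) two-tailed t-test. The relative lignin change is the ratio of
#' group-mean peak heights, `100 * (mean_exposed / mean_control - 1)`.
#' No multiple-testing correction is applied across peaks by default
#' (per-peak 95 percent significance); set `bonferroni = TRUE` to adjust.
#'
#' @param heights a peak-height table from [compute_peak_heights()], with
#'   groups `"exposed"` and `"control"`.
#' @param alpha significance level.
#' @param bonferroni adjust test p-values by the number of peaks.
#' @return a `lignin_change_estimate`: list with `per_peak` (one row per
#'   peak: means, relative change, test used, p-values, significance, and
#'   two dispersion summaries for the change - the sd of per-sample
#'   exposed/control-mean ratios and the group-sd propagated form),
#'   `significant_peaks` (their centers) and `summary_range` (min/max
#'   percent change over significant peaks).
#' @export
compare_groups <- function(heights, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(all(c("peak_center", "group", "height") %in% names(heights)))
  res <- lapply(split(heights, heights$peak_center), function(d) {
    x <- d$height[d$group == "exposed"]
    y <- d$height[d$group == "control"]
    tst <- tiered_group_test(x, y, alpha)
    me <- mean(x); mc <- mean(y)
    rel <- if (mc > 0) 100 * (me / mc - 1) else NA_real_
    cbind(data.frame(
      peak_center = d$peak_center[1],
      n_exposed = length(x), n_control = length(y),
      mean_exposed = me, mean_control = mc,
      relative_change_percent = rel,
      change_sd_ratio = if (mc > 0) 100 * stats::sd(x / mc) else NA_real_,
      change_sd_propagated = if (mc > 0 && me > 0) {
        100 * (me / mc) * sqrt(stats::var(x) / me^2 + stats::var(y) / mc^2)
      } else NA_real_
    ), tst)
  })
  per_peak <- do.call(rbind, res)
  rownames(per_peak) <- NULL
  if (bonferroni) {
    per_peak$test_p <- pmin(1, per_peak$test_p * nrow(per_peak))
  }
  per_peak$significant <- !is.na(per_peak$test_p) & per_peak$test_p < alpha
  sig <- per_peak[per_peak$significant, , drop = FALSE]
  structure(list(
    per_peak = per_peak,
    significant_peaks = sig$peak_center,
    summary_range = if (nrow(sig)) range(sig$relative_change_percent) else c(NA_real_, NA_real_),
    alpha = alpha
  ), class = "lignin_change_estimate")
}

#' @export
print.lignin_change_estimate <- function(x, ...) {
  cat(sprintf("<lignin_change_estimate> %d peaks, %d significant at alpha = %g\n",
              nrow(x$per_peak), length(x$significant_peaks), x$alpha))
  print(x$per_peak[, c("peak_center", "relative_change_percent", "test_used",
                       "test_p", "significant")], row.names = FALSE, digits = 4)
  if (length(x$significant_peaks)) {
    cat(sprintf("significant relative change range: %.1f to %.1f %%\n",
                x$summary_range[1], x$summary_range[2]))
  }
  invisible(x)
}

#' Write the quantification results CSV and run summary
#'
#' @param estimate a `lignin_change_estimate`.
#' @param csv_path results CSV path (one row per peak, mirroring the
#'   relative-change figure of a typical report).
#' @param summary_path optional path for a flat key/value run summary.
#' @return `csv_path`, invisibly.
#' @export
write_quantification_results <- function(estimate, csv_path,
                                         summary_path = NULL) {
  utils::write.csv(estimate$per_peak, csv_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    write_kv(list(
      n_peaks = nrow(estimate$per_peak),
      n_significant = length(estimate$significant_peaks),
      significant_peaks = estimate$significant_peaks,
      summary_range_percent = estimate$summary_range,
      alpha = estimate$alpha
    ), summary_path)
  }
  invisible(csv_path)
}
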