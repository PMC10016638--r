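#' Diagnostic-accuracy statistics from a 2x2 table
#'
#' Sensitivity, specificity, predictive values, accuracy and likelihood
#' ratios, kept at full precision internally (rendering rounds half-up
#' only at print time). Any statistic whose denominator is zero is
#' undefined (`NA`), never silently 0 or 1. Wilson 95% intervals are
#' attached for the proportions and log-method intervals for the
#' likelihood ratios; the source study reports none, so these are an
#' extension.
#'
#' @param table a [contingency_table()].
#' @param conf_level confidence level for the intervals.
#' @return A `diagnostic_stats` list: `sens`, `spec`, `ppv`, `npv`,
#'   `accuracy` (proportions), `lr_pos`, `lr_neg`, `n_total`, and `ci`,
#'   a data frame of intervals.
#' @export
diagnostic_stats <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty contingency table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  accuracy <- (tp + tn) / n
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 1) {
    sens / (1 - spec)
  } else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0) {
    (1 - sens) / spec
  } else NA_real_
  wilson <- function(x, m) {
    if (m == 0) return(c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - conf_level) / 2)
    p <- x / m
    den <- 1 + z^2 / m
    ctr <- (p + z^2 / (2 * m)) / den
    hw <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / den
    c(ctr - hw, ctr + hw)
  }
  lr_ci <- function(lr, a, b, c_, d) {
    # log-method interval for a ratio of two proportions a/b over c/d
    if (is.na(lr) || lr <= 0 || a == 0 || c_ == 0) return(c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a - 1 / b + 1 / c_ - 1 / d)
    exp(log(lr) + c(-1, 1) * z * se)
  }
  ci <- rbind(
    data.frame(stat = "sens", t(wilson(tp, tp + fn))),
    data.frame(stat = "spec", t(wilson(tn, tn + fp))),
    data.frame(stat = "ppv", t(wilson(tp, tp + fp))),
    data.frame(stat = "npv", t(wilson(tn, tn + fn))),
    data.frame(stat = "accuracy", t(wilson(tp + tn, n))),
    data.frame(stat = "lr_pos", t(lr_ci(lr_pos, tp, tp + fn, fp, fp + tn))),
    data.frame(stat = "lr_neg", t(lr_ci(lr_neg, fn, tp + fn, tn, fp + tn)))
  )
  names(ci) <- c("stat", "lower", "upper")
  structure(
    list(sens = sens, spec = spec, ppv = ppv, npv = npv,
         accuracy = accuracy, lr_pos = lr_pos, lr_neg = lr_neg,
         n_total = n, ci = ci),
    class = "diagnostic_stats"
  )
}

#' @export
print.diagnostic_stats <- function(x, digits = 1, ...) {
  pc <- function(v) {
    if (is.na(v)) "undefined" else paste0(round_half_up(100 * v, digits), "%")
  }
  nm <- function(v) if (is.na(v)) "undefined" else round_half_up(v, 2)
  cat(sprintf("Sens %s | Esp %s | VP+ %s | VP- %s | Accuracy %s | RV+ %s | RV- %s (n = %d)\n",
              pc(x$sens), pc(x$spec), pc(x$ppv), pc(x$npv), pc(x$accuracy),
              nm(x$lr_pos), nm(x$lr_neg), x$n_total))
  invisible(x)
}

#' Compare a quantitative variable between two groups
#'
#' Normality is screened per group with the Shapiro-Wilk test at
#' `normality_alpha` (on a fixed-seed subsample above the test's 5000
#' observation limit); both groups normal selects the two-sample t-test
#' (Welch), otherwise the Mann-Whitney (Wilcoxon rank-sum) test. The
#' chosen test is recorded.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param normality_alpha significance level of the normality screen.
#' @return A `group_test` list: `test_name` (`"t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`. Degenerate identical zero-variance samples
#'   give an undefined-flagged result.
#' @export
compare_quantitative <- function(x, y, normality_alpha = 0.05) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  if (psd(c(x, y)) == 0) {
    out <- list(test_name = NA_character_, statistic = NA_real_,
                p_value = NA_real_)
    attr(out, "undefined") <- TRUE
    class(out) <- "group_test"
    return(out)
  }
  sub <- function(v) if (length(v) > 5000L) v[seq(1L, length(v),
                                                  length.out = 5000L)] else v
  norm_p <- function(v) {
    if (psd(v) == 0) return(0) # constant group: not normal
    shapiro.test(sub(v))$p.value
  }
  normal <- norm_p(x) > normality_alpha && norm_p(y) > normality_alpha
  res <- if (normal) {
    h <- t.test(x, y)
    list(test_name = "t", statistic = unname(h$statistic),
         p_value = h$p.value)
  } else {
    h <- suppressWarnings(wilcox.test(x, y))
    list(test_name = "mann_whitney", statistic = unname(h$statistic),
         p_value = h$p.value)
  }
  class(res) <- "group_test"
  res
}

#' Compare a qualitative (2x2) variable between two groups
#'
#' Fisher's exact test when any expected cell count is below 5,
#' otherwise the chi-squared test with continuity correction; the choice
#' is recorded.
#'
#' @param table a 2x2 matrix of counts.
#' @return A `group_test` list: `test_name` (`"fisher"` or `"chi2"`),
#'   `statistic` (chi-squared statistic, or the odds-ratio estimate for
#'   Fisher), `p_value`. An all-zero table is undefined-flagged.
#' @export
compare_qualitative <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (sum(table) == 0) {
    out <- list(test_name = NA_character_, statistic = NA_real_,
                p_value = NA_real_)
    attr(out, "undefined") <- TRUE
    class(out) <- "group_test"
    return(out)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  res <- if (any(expected < 5)) {
    h <- fisher.test(table)
    list(test_name = "fisher", statistic = unname(h$estimate),
         p_value = h$p.value)
  } else {
    h <- chisq.test(table, correct = TRUE)
    list(test_name = "chi2", statistic = unname(h$statistic),
         p_value = h$p.value)
  }
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  if (is_flagged_undefined(x)) {
    cat("<group_test> undefined (degenerate input)\n")
  } else {
    cat(sprintf("<group_test> %s: statistic %.4g, p = %.4g\n",
                x$test_name, x$statistic, x$p_value))
  }
  invisible(x)
}
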