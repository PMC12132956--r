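## Inter-rater agreement and group comparison statistics. The ICC mean
## squares are computed from the closed-form balanced two-way decomposition
## (subjects x raters, one observation per cell); the test suite checks them
## against stats::aov independently.

#' Ratings matrix constructor
#'
#' Arranges one metric measured by k raters on n subjects into the complete
#' n x k matrix required by [icc_2_1()]. Cells must be complete; remove
#' subjects with missing measurements upstream (listwise).
#'
#' @param values Numeric matrix (subjects x raters), or a vector to be
#'   shaped with `n` rows.
#' @param subjects,raters Optional dimension labels.
#' @return A numeric matrix of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values, subjects = NULL, raters = NULL) {
  m <- as.matrix(values)
  if (!is.numeric(m) || anyNA(m)) {
    stop_validation("ratings must be numeric and complete (no missing cells)")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_validation("ratings need at least 2 subjects and 2 raters")
  }
  if (!is.null(subjects)) rownames(m) <- subjects
  if (!is.null(raters)) colnames(m) <- raters
  class(m) <- c("ratings_matrix", class(m))
  m
}

icc_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure ICC(A,1) under the two-way random-effects model with
#' absolute agreement,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, rater and
#' residual mean squares of the balanced two-way layout. The confidence
#' interval uses the McGraw-Wong F approximation. Because reliability
#' studies report either the single-measure or the average-measure form,
#' the average-measure ICC(A,k) is returned alongside, with its interval
#' obtained through the Spearman-Brown transform of the single-measure
#' limits.
#'
#' @param m A [ratings_matrix()] (n subjects x k raters) or plain matrix.
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`
#'   (single measure); `icc_avg`, `ci_avg_low`, `ci_avg_high` (average
#'   measure); the mean squares; `n`, `k`, `ci_level`.
#' @export
icc_2_1 <- function(m, ci_level = 0.95) {
  if (!inherits(m, "ratings_matrix")) m <- ratings_matrix(m)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop_validation("ci_level must be in (0, 1)")
  }
  ms <- icc_mean_squares(m)
  n <- ms$n; k <- ms$k
  if (ms$msr == 0 && ms$mse == 0 && ms$msc == 0) {
    stop_validation("undefined ICC: all cells are identical (zero variance)")
  }
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  icc <- (ms$msr - ms$mse) / denom
  denom_k <- ms$msr + (ms$msc - ms$mse) / n
  icc_k <- (ms$msr - ms$mse) / denom_k
  alpha <- 1 - ci_level
  if (ms$mse == 0 && ms$msc == 0) {
    ## perfect agreement: degenerate F interval
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
    ci <- c(lower, upper)
  }
  sb <- function(r) (k * r) / (1 + (k - 1) * r)
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         icc_avg = icc_k, ci_avg_low = sb(ci[1]), ci_avg_high = sb(ci[2]),
         ms = ms, n = n, k = k, ci_level = ci_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  lvl <- round(100 * x$ci_level)
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI %.3f to %.3f)\n",
              x$icc, lvl, x$ci_low, x$ci_high))
  cat(sprintf("ICC(A,%d) = %.3f (%d%% CI %.3f to %.3f)\n",
              x$k, x$icc_avg, lvl, x$ci_avg_low, x$ci_avg_high))
  cat(sprintf("n = %d subjects, k = %d raters\n", x$n, x$k))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurement series: bias is the
#' mean of `x - y`, and the limits of agreement are bias +/- 1.96 times the
#' sample standard deviation of the differences (the conventional normal
#' multiplier). The per-pair means and differences are kept for plotting.
#'
#' @param x,y Numeric vectors of equal length (>= 2): the same quantity
#'   measured by two raters or methods.
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `means`, `diffs`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stop_validation("x and y must be numeric without NAs")
  }
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 2L) stop_validation("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         means = (x + y) / 2, diffs = d, n = length(x)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, SD %.3f, limits [%.3f, %.3f] (n = %d)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Two-group t test
#'
#' Compares two independent groups, defaulting to Welch's unequal-variance
#' form (with Welch-Satterthwaite degrees of freedom); set
#' `var_equal = TRUE` for the classical pooled-variance Student t.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Assume equal variances (pooled t) instead of Welch.
#' @return A list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  for (g in list(a, b)) {
    if (!is.numeric(g) || length(g) < 2L || anyNA(g) || !all(is.finite(g))) {
      stop_validation("each group needs >= 2 finite numeric values")
    }
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop_validation("degenerate groups: zero variance in both groups")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohort summary table with two-group comparison
#'
#' Summarizes each metric as mean +/- SD overall and within the two sex
#' groups, with the two-group p-value from [welch_t()] -- the layout of a
#' demographic/contour summary table.
#'
#' @param metrics A `data.frame` of per-eye metrics (e.g. from
#'   [metrics_table()]); all numeric columns are summarized.
#' @param sex Character/factor vector with one entry per row of `metrics`,
#'   containing exactly the two levels being compared (e.g. `"F"`, `"M"`).
#' @param var_equal Passed to [welch_t()].
#' @return A `data.frame` with one row per metric: `metric`, `total_mean`,
#'   `total_sd`, `<level1>_mean`, `<level1>_sd`, `<level2>_mean`,
#'   `<level2>_sd`, `p_value`.
#' @export
summarize_cohort <- function(metrics, sex, var_equal = FALSE) {
  if (!is.data.frame(metrics) || !nrow(metrics)) {
    stop_validation("metrics must be a non-empty data.frame")
  }
  sex <- as.character(sex)
  if (length(sex) != nrow(metrics)) {
    stop_validation("sex must have one label per metrics row")
  }
  lev <- sort(unique(sex))
  if (length(lev) != 2L) {
    stop_validation("sex must contain exactly two groups")
  }
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (!length(num)) stop_validation("metrics has no numeric columns")
  rows <- lapply(num, function(col) {
    v <- metrics[[col]]
    g1 <- v[sex == lev[1]]
    g2 <- v[sex == lev[2]]
    p <- if (sum(!is.na(g1)) >= 2 && sum(!is.na(g2)) >= 2 &&
             (stats::var(g1, na.rm = TRUE) > 0 || stats::var(g2, na.rm = TRUE) > 0)) {
      welch_t(g1[!is.na(g1)], g2[!is.na(g2)], var_equal = var_equal)$p
    } else if (isTRUE(all.equal(mean(g1, na.rm = TRUE), mean(g2, na.rm = TRUE)))) {
      1
    } else {
      NA_real_
    }
    out <- data.frame(
      metric = col,
      total_mean = mean(v, na.rm = TRUE), total_sd = stats::sd(v, na.rm = TRUE),
      m1 = mean(g1, na.rm = TRUE), s1 = stats::sd(g1, na.rm = TRUE),
      m2 = mean(g2, na.rm = TRUE), s2 = stats::sd(g2, na.rm = TRUE),
      p_value = p, stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  names(out)[4:7] <- c(paste0(lev[1], c("_mean", "_sd")),
                       paste0(lev[2], c("_mean", "_sd")))
  out
}
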