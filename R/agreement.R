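# Paired-method agreement and group-comparison statistics.

#' Pearson correlation with p-value
#'
#' @param x,y Paired numeric vectors, n >= 3, finite, non-constant.
#' @return List with `r` and two-sided `p` (t transform).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman paired-difference statistics
#'
#' Bias (mean of x - y), SD of the differences, and 95% limits of agreement
#' (bias +/- 1.96 SD) between two methods measuring the same quantity.
#'
#' @param x,y Paired numeric vectors, n >= 2.
#' @return List with `bias`, `sd_diff`, `loa` (length-2), `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s, loa = bias + c(-1, 1) * 1.96 * s,
       n = length(d))
}

#' Bland-Altman plot
#'
#' Difference against mean of each pair, with bias and limits of agreement.
#'
#' @param x,y Paired numeric vectors.
#' @param main Plot title.
#' @param xlab,ylab Axis labels.
#' @return The [bland_altman()] statistics, invisibly.
#' @export
bland_altman_plot <- function(x, y, main = "Bland-Altman",
                              xlab = "Mean of methods",
                              ylab = "Difference (x - y)") {
  ba <- bland_altman(x, y)
  graphics::plot((x + y) / 2, x - y, main = main, xlab = xlab, ylab = ylab,
                 pch = 19, col = "grey30")
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement measure penalizing both scatter and location/scale shift:
#' `2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with biased (1/n)
#' moments. Equals 1 only for perfect agreement (`y = x`); satisfies
#' `|ccc| <= |r|`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return Scalar in [-1, 1].
#' @export
concordance_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) stop("both variances zero")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects, single-rater, absolute-agreement intraclass
#' correlation (McGraw & Wong's ICC(A,1)) for an inter-rater reliability
#' table, with the F-based 95% confidence interval.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns,
#'   complete (no NA), >= 5 subjects and >= 2 raters.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `icc`, `ci` (length-2), `n_subjects`, `n_raters`.
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings table must be complete")
  n <- nrow(ratings)  # subjects
  k <- ncol(ratings)  # raters
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 subjects")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # raters
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI (McGraw & Wong 1996)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  fj <- msc / mse
  v <- (a * fj + b)^2 /
    ((a * fj)^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower, upper), n_subjects = n, n_raters = k)
}

#' Contiguous-score comparisons with Holm adjustment
#'
#' Compares the means of adjacent ordinal-score groups (0-1, 1-2, ...) with
#' two-sample pooled-variance t-tests, applies the Holm step-down adjustment
#' at family level `alpha`, and computes post-hoc power per pair from the
#' observed effect size via the noncentral t distribution.
#'
#' @param groups Named list of numeric vectors, ordered by score; each group
#'   needs n >= 2.
#' @param alpha Family-wise significance level, default 0.05.
#' @param var_equal Use the pooled-variance Student t-test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @param power Also compute post-hoc power (default `TRUE`).
#' @return Data frame of class `score_comparison`: one row per adjacent pair
#'   with `pair`, `t`, `df`, `p_raw`, `p_adjusted`, `significant`,
#'   `post_hoc_power`.
#' @export
contiguous_score_tests <- function(groups, alpha = 0.05, var_equal = TRUE,
                                   power = TRUE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L))
    stop("group(s) with n < 2: ", paste(names(groups)[ns < 2L], collapse = ", "))
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups) - 1L)
  m <- length(groups) - 1L
  rows <- lapply(seq_len(m), function(i) {
    a <- groups[[i]]; b <- groups[[i + 1L]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    pw <- NA_real_
    if (power) {
      n1 <- length(a); n2 <- length(b)
      sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                   (n1 + n2 - 2))
      d <- if (sp > 0) abs(mean(a) - mean(b)) / sp else Inf
      ncp <- d * sqrt(n1 * n2 / (n1 + n2))
      dfree <- n1 + n2 - 2
      tc <- stats::qt(1 - alpha / 2, dfree)
      pw <- stats::pt(tc, dfree, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-tc, dfree, ncp = ncp)
    }
    data.frame(pair = paste0(labs[i], "-", labs[i + 1L]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, post_hoc_power = pw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_adjusted < alpha
  out <- out[, c("pair", "t", "df", "p_raw", "p_adjusted", "significant",
                 "post_hoc_power")]
  class(out) <- c("score_comparison", "data.frame")
  out
}

#' Per-metric method-agreement table
#'
#' Pairs two metrics tables (e.g. phone channel vs laboratory channel) by
#' `trial_id` and `axis`, and computes r, p, bias, SD of differences and
#' Lin's CCC per metric and task, optionally restricted to trials whose
#' reference-channel RMS passes the amplitude threshold. Cells with fewer
#' than 3 surviving pairs are flagged insufficient (statistics NA) rather
#' than fabricated.
#'
#' @param test_metrics,ref_metrics `tremor_metrics` data frames sharing
#'   `trial_id`s; `ref_metrics` is the reference channel used for
#'   thresholding.
#' @param metrics Which metric columns to compare (default all eight).
#' @param by_task Split by task (default `TRUE`); `FALSE` pools all trials.
#' @param threshold_mm Amplitude threshold in mm applied to the reference
#'   RMS, or `NULL` for no threshold.
#' @return Data frame with one row per metric x task: `metric`, `task`,
#'   `n`, `r`, `p`, `bias`, `sd`, `ccc`, `insufficient`.
#' @export
agreement_table <- function(test_metrics, ref_metrics,
                            metrics = METRIC_COLUMNS, by_task = TRUE,
                            threshold_mm = NULL) {
  key <- function(m) paste(m$trial_id, m$axis, sep = "::")
  a <- as.data.frame(test_metrics); b <- as.data.frame(ref_metrics)
  a$.key <- key(a); b$.key <- key(b)
  common <- intersect(a$.key, b$.key)
  if (length(common) == 0L) stop("no shared (trial_id, axis) pairs")
  a <- a[match(common, a$.key), ]
  b <- b[match(common, b$.key), ]
  tasks <- if (by_task) sort(unique(b$task)) else "all"
  if (!is.null(threshold_mm)) {
    keep <- passes_amplitude_threshold(b$rms, threshold_mm)
    a <- a[keep, ]; b <- b[keep, ]
  }
  rows <- list()
  for (tk in tasks) {
    sel <- if (by_task) b$task == tk else rep(TRUE, nrow(b))
    for (mt in metrics) {
      x <- a[[mt]][sel]; y <- b[[mt]][sel]
      n <- length(x)
      if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mt, task = tk, n = n, r = NA_real_, p = NA_real_,
          bias = NA_real_, sd = NA_real_, ccc = NA_real_,
          insufficient = TRUE, stringsAsFactors = FALSE)
        next
      }
      pr <- pearson(x, y)
      ba <- bland_altman(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mt, task = tk, n = n, r = pr$r, p = pr$p,
        bias = ba$bias, sd = ba$sd_diff, ccc = concordance_ccc(x, y),
        insufficient = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' Write an agreement table as CSV
#' @param tab Result of [agreement_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
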