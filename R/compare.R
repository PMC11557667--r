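# Cohort-level statistics and the end-to-end method-comparison report.
#
# The elementary statistics (paired t, Pearson r with its t test, one-way
# repeated-measures ANOVA) are implemented from their defining formulas so
# the pipeline is self-contained; the test suite cross-checks each against
# the corresponding stats:: routine.

#' Container for a test statistic
#'
#' @param statistic Test statistic value (t, F, or r).
#' @param df Degrees of freedom (length 1 for t/r, length 2 for F).
#' @param p_value Two-sided p value.
#' @param effect_size Effect size value.
#' @param effect_label Label of the effect size ("cohen_d", "eta_squared",
#'   "r").
#' @param method Short description of the test.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, df, p_value, effect_size = NA_real_,
                        effect_label = NA_character_, method = "") {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         effect_size = effect_size, effect_label = effect_label,
         method = method),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g", x$method,
              x$statistic, dfs, x$p_value))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", %s = %.3f", x$effect_label, x$effect_size))
  }
  cat("\n")
  invisible(x)
}

#' Paired t test
#'
#' Two-sided paired t test with `df = n - 1` and Cohen's d for paired
#' contrasts computed as `mean(diff) / sd(diff)`.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2, no missing
#'   values).
#' @return A [stat_result()] with the t statistic.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pairing error: missing pairs are not allowed", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) {
    stop("insufficient data: paired t needs >= 2 pairs", call. = FALSE)
  }
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  cohen_d <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / sd_d
  }
  stat_result(t_stat, n - 1, p, cohen_d, "cohen_d", "paired t test")
}

#' Pearson correlation with its t test
#'
#' `r` with the t statistic `r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with non-zero
#'   variance.
#' @return A [stat_result()] whose `statistic` is the t value and whose
#'   `effect_size` is r.
#' @export
pearson_r_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) {
    stop("insufficient data: correlation needs >= 3 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  stat_result(t_stat, n - 2, p, r, "r", "Pearson correlation t test")
}

#' One-way repeated-measures ANOVA on section slopes
#'
#' Standard within-subject sums-of-squares decomposition for a complete
#' observers x conditions matrix: `F = MS_condition / MS_error` with degrees
#' of freedom `(k - 1, (k - 1)(n - 1))`, and
#' `eta^2 = SS_condition / (SS_condition + SS_error)`.
#'
#' @param slopes Numeric matrix or data.frame, rows = observers, columns =
#'   conditions (e.g. regression sections); complete, >= 2 rows, >= 2
#'   columns.
#' @return A [stat_result()] with the F statistic and partial eta squared.
#' @export
rm_anova_slopes <- function(slopes) {
  m <- as.matrix(slopes)
  if (anyNA(m)) {
    stop("incomplete design: missing cells in the slope matrix", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) {
    stop("insufficient data: need >= 2 observers and >= 2 conditions",
         call. = FALSE)
  }
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  f_stat <- if (ms_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / df1) / ms_err
  }
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  eta_sq <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)
  stat_result(f_stat, c(df1, df2), p, eta_sq, "eta_squared",
              "repeated-measures ANOVA")
}

#' Compare constant-stimuli and adjustment thresholds across a cohort
#'
#' Joins per-observer thresholds from the two dyadic methods, applies the
#' triadic segment correction to each, and reports means, the
#' adjustment-to-constant-stimuli threshold ratio, paired t tests, and
#' between-method correlations, uncorrected and corrected.
#'
#' @param fits_cs Data.frame with `observer_id` and `threshold_deg`
#'   (constant-stimuli fits, e.g. from [fit_cohort_psychometric()]).
#' @param adj_summaries Data.frame with `observer_id` and
#'   `overall_threshold` (from [summarize_adjustment_cohort()]).
#' @param triadic_fits Either the list returned by [fit_cohort_triadic()],
#'   a named list of `piecewise_fit` objects keyed by observer id, or a
#'   segment table as accepted by [piecewise_from_segments()].  `NULL`
#'   skips the corrected block.
#' @return An object of class `comparison_report`: a list with
#'   `per_observer` (data.frame), `uncorrected` and (when triadic fits are
#'   supplied) `corrected` blocks, each holding `mean_cs`, `mean_adj`,
#'   `sd_cs`, `sd_adj`, `ratio`, `t` and `correlation` [stat_result()]s.
#' @export
compare_methods <- function(fits_cs, adj_summaries, triadic_fits = NULL) {
  if (!all(c("observer_id", "threshold_deg") %in% names(fits_cs))) {
    stop("data error: `fits_cs` needs observer_id and threshold_deg",
         call. = FALSE)
  }
  if (!all(c("observer_id", "overall_threshold") %in% names(adj_summaries))) {
    stop("data error: `adj_summaries` needs observer_id and overall_threshold",
         call. = FALSE)
  }
  ids_cs <- fits_cs$observer_id
  ids_adj <- adj_summaries$observer_id
  mismatched <- c(setdiff(ids_cs, ids_adj), setdiff(ids_adj, ids_cs))
  if (length(mismatched)) {
    stop("join error: observer ids do not align across inputs: ",
         paste(sort(unique(mismatched)), collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(ids_cs))
  per <- data.frame(
    observer_id = ids,
    threshold_cs = fits_cs$threshold_deg[match(ids, ids_cs)],
    threshold_adj = adj_summaries$overall_threshold[match(ids, ids_adj)]
  )

  fits <- NULL
  if (!is.null(triadic_fits)) {
    fits <- if (is.list(triadic_fits) && !is.null(triadic_fits$fits)) {
      triadic_fits$fits
    } else if (is.data.frame(triadic_fits)) {
      piecewise_from_segments(triadic_fits)
    } else {
      triadic_fits
    }
    missing_ids <- setdiff(as.character(ids), names(fits))
    if (length(missing_ids)) {
      stop("join error: no triadic fit for observer(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    corr_cs <- vapply(seq_along(ids), function(i) {
      correct_threshold(per$threshold_cs[i],
                        fits[[as.character(ids[i])]])$corrected_threshold
    }, numeric(1))
    corr_adj <- vapply(seq_along(ids), function(i) {
      correct_threshold(per$threshold_adj[i],
                        fits[[as.character(ids[i])]])$corrected_threshold
    }, numeric(1))
    per$corrected_cs <- corr_cs
    per$corrected_adj <- corr_adj
    per$bias_cs <- ifelse(per$threshold_cs > 0,
                          per$corrected_cs / per$threshold_cs, NA_real_)
    per$bias_adj <- ifelse(per$threshold_adj > 0,
                           per$corrected_adj / per$threshold_adj, NA_real_)
  }

  block <- function(cs, adj) {
    corr <- if (stats::sd(cs) > 0 && stats::sd(adj) > 0) {
      pearson_r_test(cs, adj)
    } else NULL
    list(mean_cs = mean(cs), mean_adj = mean(adj),
         sd_cs = stats::sd(cs), sd_adj = stats::sd(adj),
         ratio = mean(adj) / mean(cs),
         t = paired_t(adj, cs), correlation = corr)
  }
  report <- list(
    per_observer = per,
    uncorrected = block(per$threshold_cs, per$threshold_adj),
    corrected = if (!is.null(fits)) {
      block(per$corrected_cs, per$corrected_adj)
    } else NULL
  )
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  fmt <- function(b, label) {
    cat(sprintf("%s thresholds: constant stimuli %.2f deg (SD %.2f), adjustment %.2f deg (SD %.2f), ratio %.2f\n",
                label, b$mean_cs, b$sd_cs, b$mean_adj, b$sd_adj, b$ratio))
    cat(sprintf("  paired t(%d) = %.2f, p = %.3f, d = %.2f\n",
                b$t$df, b$t$statistic, b$t$p_value, b$t$effect_size))
    if (!is.null(b$correlation)) {
      cat(sprintf("  correlation r = %.2f, t(%d) = %.2f, p = %.3f\n",
                  b$correlation$effect_size, b$correlation$df,
                  b$correlation$statistic, b$correlation$p_value))
    }
  }
  cat(sprintf("Method comparison over %d observers\n", nrow(x$per_observer)))
  fmt(x$uncorrected, "Uncorrected")
  if (!is.null(x$corrected)) fmt(x$corrected, "Corrected")
  invisible(x)
}
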