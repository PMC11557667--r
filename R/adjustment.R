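# Summaries of method-of-adjustment sessions: per-observer thresholds from
# unweighted (series x side) cell means, and the cohort-level hysteresis
# contrast between descending and ascending series.

#' Summarize one observer's adjustment trials
#'
#' Cell means are computed per series (and per side for two-sided data) and
#' combined unweighted.  For two-sided data the left-side cell means are
#' folded by sign (their magnitudes taken) before entering the overall
#' threshold, so a symmetric cone yields the same threshold on either side;
#' signed per-side means are reported alongside.  The within-observer SD is
#' taken over all stop magnitudes.
#'
#' @param trials Data.frame with columns `series` ("ascending"/"descending"),
#'   `stop_deg`, and for two-sided data `side` ("left"/"right").
#' @param sides `"one"` or `"two"`.
#' @return An object of class `adjustment_summary`: a one-row data.frame with
#'   `mean_ascending`, `mean_descending` (folded magnitudes), `mean_left`,
#'   `mean_right` (signed; `NA` for one-sided data), `overall_threshold`,
#'   `within_sd`, `n_trials`.
#' @export
summarize_adjustment <- function(trials, sides = c("one", "two")) {
  sides <- match.arg(sides)
  if (!all(c("series", "stop_deg") %in% names(trials))) {
    stop("data error: trials need columns `series` and `stop_deg`",
         call. = FALSE)
  }
  bad <- setdiff(unique(trials$series), c("ascending", "descending"))
  if (length(bad)) {
    stop("data error: unknown series label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sides == "two" && !"side" %in% names(trials)) {
    stop("data error: two-sided summaries need a `side` column", call. = FALSE)
  }
  side_labels <- if (sides == "one") "right" else c("left", "right")
  cells <- expand.grid(series = c("ascending", "descending"),
                       side = side_labels, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$mean <- NA_real_
  cells$n <- 0L
  for (k in seq_len(nrow(cells))) {
    sel <- trials$series == cells$series[k]
    if (sides == "two") sel <- sel & trials$side == cells$side[k]
    if (!any(sel)) {
      stop(sprintf("missing cell: no trials for (%s, %s)",
                   cells$series[k], cells$side[k]), call. = FALSE)
    }
    cells$mean[k] <- mean(trials$stop_deg[sel])
    cells$n[k] <- sum(sel)
  }
  folded <- abs(cells$mean)   # fold left-side magnitudes for pooled measures
  asc <- cells$series == "ascending"
  summary <- data.frame(
    mean_ascending = mean(folded[asc]),
    mean_descending = mean(folded[!asc]),
    mean_left = if (sides == "two") {
      mean(cells$mean[cells$side == "left"])
    } else NA_real_,
    mean_right = mean(cells$mean[cells$side == "right"]),
    overall_threshold = mean(folded),
    within_sd = stats::sd(abs(trials$stop_deg)),
    n_trials = nrow(trials)
  )
  attr(summary, "cells") <- cells
  class(summary) <- c("adjustment_summary", "data.frame")
  summary
}

#' Summarize adjustment trials for every observer in a cohort
#'
#' @param trials Trial table with an `observer_id` column; see
#'   [summarize_adjustment()].
#' @param sides `"one"` or `"two"`.
#' @return Data.frame with one row per observer (column `observer_id` plus
#'   the [summarize_adjustment()] fields).
#' @export
summarize_adjustment_cohort <- function(trials, sides = c("one", "two")) {
  sides <- match.arg(sides)
  ids <- sort(unique(trials$observer_id))
  rows <- lapply(ids, function(id) {
    s <- summarize_adjustment(trials[trials$observer_id == id, , drop = FALSE],
                              sides = sides)
    cbind(observer_id = id, as.data.frame(s))
  })
  do.call(rbind, rows)
}

#' Hysteresis contrast between descending and ascending series
#'
#' Paired t test on per-observer (descending - ascending) mean stop
#' magnitudes, with Cohen's d and the Pearson correlation between the two
#' series across observers.
#'
#' @param summaries Cohort summary table from [summarize_adjustment_cohort()]
#'   (needs `mean_ascending` and `mean_descending`).
#' @return A list with `contrast_mean` (mean descending - ascending in
#'   degrees), `t` (a `stat_result` from [paired_t()]), and `correlation`
#'   (a `stat_result` from [pearson_r_test()], `NULL` if either series is
#'   constant).
#' @export
hysteresis_contrast <- function(summaries) {
  need <- c("mean_ascending", "mean_descending")
  if (!all(need %in% names(summaries))) {
    stop("data error: summaries need mean_ascending and mean_descending",
         call. = FALSE)
  }
  if (nrow(summaries) < 2) {
    stop("insufficient data: need >= 2 observers with both series",
         call. = FALSE)
  }
  asc <- summaries$mean_ascending
  desc <- summaries$mean_descending
  corr <- if (stats::sd(asc) > 0 && stats::sd(desc) > 0) {
    pearson_r_test(asc, desc)
  } else NULL
  list(
    contrast_mean = mean(desc - asc),
    t = paired_t(desc, asc),
    correlation = corr
  )
}
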