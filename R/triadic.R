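# Regression of triadic gaze-direction reports: global linear fit, fixed-
# breakpoint four-piece linear regression, segment selection, and the
# segment-based threshold correction.
#
# Reports are collected in cm on the response scale; they are converted to
# degrees through the viewing geometry before any regression, so that the
# correction formula composes directly with degree-valued thresholds.

default_breakpoints <- c(0, 0.9, 2.2, 5.4, 13.9)

#' Convert triadic cm reports to perceived gaze angles
#'
#' @param trials Data.frame with `true_deg` and `reported_cm`.
#' @param geom A [gaze_geometry()] whose distance is the looker-to-scale
#'   distance.
#' @return The input with an added `perceived_deg` column.
#' @export
triadic_to_degrees <- function(trials, geom) {
  if (!all(c("true_deg", "reported_cm") %in% names(trials))) {
    stop("data error: trials need columns `true_deg` and `reported_cm`",
         call. = FALSE)
  }
  trials$perceived_deg <- offset_to_angle(trials$reported_cm, geom)
  trials
}

#' Ordinary least-squares fit of perceived on true gaze direction
#'
#' The slope is the overestimation factor: slope > 1 means perceived
#' eccentricity exceeds true eccentricity.
#'
#' @param true_deg True gaze directions (>= 2 distinct values).
#' @param perceived_deg Perceived directions, same length.
#' @return A list of class `linear_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_linear <- function(true_deg, perceived_deg) {
  if (length(true_deg) != length(perceived_deg)) {
    stop("data error: predictor and response lengths differ", call. = FALSE)
  }
  if (length(unique(true_deg)) < 2) {
    stop("singular fit: need >= 2 distinct gaze directions", call. = FALSE)
  }
  fit <- stats::lm(perceived_deg ~ true_deg)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((perceived_deg - mean(perceived_deg))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_points = length(true_deg)),
    class = "linear_fit"
  )
}

#' Four-piece linear regression with fixed breakpoints
#'
#' An independent OLS line is fitted within each section
#' `[b[k], b[k+1]]` of the (absolute) gaze-direction axis; the section
#' boundaries are the measured gaze directions.  Sections are closed
#' intervals, so a point on an interior boundary enters both adjacent fits;
#' discontinuities between sections are permitted.
#'
#' @param true_deg True gaze-direction magnitudes.
#' @param perceived_deg Perceived directions, same length.
#' @param breakpoints Strictly increasing section boundaries
#'   (default `c(0, 0.9, 2.2, 5.4, 13.9)`).
#' @return A list of class `piecewise_fit`: `breakpoints` and `segments`, a
#'   data.frame with `segment`, `lower`, `upper`, `slope`, `intercept`,
#'   `n_points`.
#' @export
fit_piecewise <- function(true_deg, perceived_deg,
                          breakpoints = default_breakpoints) {
  if (length(true_deg) != length(perceived_deg)) {
    stop("data error: predictor and response lengths differ", call. = FALSE)
  }
  if (length(breakpoints) < 2 || any(diff(breakpoints) <= 0)) {
    stop("design error: breakpoints must be strictly increasing",
         call. = FALSE)
  }
  n_seg <- length(breakpoints) - 1
  segments <- data.frame(segment = seq_len(n_seg),
                         lower = breakpoints[-length(breakpoints)],
                         upper = breakpoints[-1],
                         slope = NA_real_, intercept = NA_real_,
                         n_points = NA_integer_)
  for (k in seq_len(n_seg)) {
    sel <- true_deg >= segments$lower[k] & true_deg <= segments$upper[k]
    if (length(unique(true_deg[sel])) < 2) {
      stop(sprintf(
        "segment error: section %d [%g, %g] needs >= 2 distinct gaze directions",
        k, segments$lower[k], segments$upper[k]), call. = FALSE)
    }
    f <- fit_linear(true_deg[sel], perceived_deg[sel])
    segments$slope[k] <- f$slope
    segments$intercept[k] <- f$intercept
    segments$n_points[k] <- sum(sel)
  }
  structure(list(breakpoints = breakpoints, segments = segments),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piece-wise linear fit:\n")
  s <- x$segments
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  section %d [%g, %g] deg: slope %.3f, intercept %.3f (n = %d)\n",
                s$segment[k], s$lower[k], s$upper[k], s$slope[k],
                s$intercept[k], s$n_points[k]))
  }
  invisible(x)
}

#' Select the regression section containing a threshold
#'
#' Returns the section `k` with `b[k] <= T <= b[k+1]`.  A threshold on an
#' interior boundary is assigned to the higher section; a threshold above the
#' last breakpoint extrapolates with the last section.
#'
#' @param threshold_deg Threshold of direct gaze (>= 0).
#' @param fit A [fit_piecewise()] result.
#' @return Section index (integer in 1..number of sections).
#' @export
select_segment <- function(threshold_deg, fit) {
  if (!inherits(fit, "piecewise_fit")) {
    stop("data error: expected a `piecewise_fit` object", call. = FALSE)
  }
  if (!is.numeric(threshold_deg) || length(threshold_deg) != 1 ||
      !is.finite(threshold_deg) || threshold_deg < 0) {
    stop("domain error: threshold must be a single non-negative number",
         call. = FALSE)
  }
  b <- fit$breakpoints
  interior <- b[-c(1, length(b))]
  k <- findInterval(threshold_deg, interior) + 1L
  min(k, length(b) - 1L)
}

#' Correct a dyadic threshold with the triadic overestimation regression
#'
#' Evaluates the regression line of the section containing the threshold:
#' `corrected = slope_k * T + intercept_k`.  The estimation bias is the ratio
#' corrected / raw (undefined at T = 0, reported as `NA`).
#'
#' @param threshold_deg Raw threshold of direct gaze in degrees (>= 0).
#' @param fit A [fit_piecewise()] result for the same observer.
#' @return A list of class `correction_result`: `raw_threshold`,
#'   `segment_index`, `corrected_threshold`, `estimation_bias`.
#' @export
correct_threshold <- function(threshold_deg, fit) {
  k <- select_segment(threshold_deg, fit)
  seg <- fit$segments[k, ]
  corrected <- seg$slope * threshold_deg + seg$intercept
  structure(
    list(raw_threshold = threshold_deg,
         segment_index = k,
         corrected_threshold = corrected,
         estimation_bias = if (threshold_deg > 0) {
           corrected / threshold_deg
         } else NA_real_),
    class = "correction_result"
  )
}

#' Fit the triadic regressions for every observer in a cohort
#'
#' Converts cm reports to degrees, then fits both the global linear and the
#' four-piece regression per observer.
#'
#' @param trials Triadic trial table with `observer_id`, `true_deg`,
#'   `reported_cm`.
#' @param geom A [gaze_geometry()] (looker-to-scale distance).
#' @param breakpoints Section boundaries for [fit_piecewise()].
#' @return A list with `linear` (data.frame: `observer_id`, `slope`,
#'   `intercept`, `r_squared`), `segments` (data.frame: `observer_id`,
#'   `segment`, `lower`, `upper`, `slope`, `intercept`, `n_points`), and
#'   `fits` (named list of `piecewise_fit` objects keyed by observer id).
#' @export
fit_cohort_triadic <- function(trials, geom, breakpoints = default_breakpoints) {
  trials <- triadic_to_degrees(trials, geom)
  ids <- sort(unique(trials$observer_id))
  linear <- list(); segs <- list(); fits <- list()
  for (id in ids) {
    d <- trials[trials$observer_id == id, , drop = FALSE]
    lf <- fit_linear(d$true_deg, d$perceived_deg)
    pf <- fit_piecewise(d$true_deg, d$perceived_deg, breakpoints)
    linear[[as.character(id)]] <- data.frame(
      observer_id = id, slope = lf$slope, intercept = lf$intercept,
      r_squared = lf$r_squared)
    segs[[as.character(id)]] <- cbind(observer_id = id, pf$segments)
    fits[[as.character(id)]] <- pf
  }
  list(linear = do.call(rbind, linear), segments = do.call(rbind, segs),
       fits = fits)
}

#' Rebuild per-observer piecewise fits from a segment table
#'
#' Inverse of the `segments` component of [fit_cohort_triadic()]; useful when
#' segment coefficients were round-tripped through CSV.
#'
#' @param segments Data.frame with `observer_id`, `segment`, `lower`,
#'   `upper`, `slope`, `intercept`.
#' @return Named list of `piecewise_fit` objects keyed by observer id.
#' @export
piecewise_from_segments <- function(segments) {
  need <- c("observer_id", "segment", "lower", "upper", "slope", "intercept")
  if (!all(need %in% names(segments))) {
    stop("data error: segment table is missing columns: ",
         paste(setdiff(need, names(segments)), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in sort(unique(segments$observer_id))) {
    s <- segments[segments$observer_id == id, , drop = FALSE]
    s <- s[order(s$segment), , drop = FALSE]
    out[[as.character(id)]] <- structure(
      list(breakpoints = c(s$lower, s$upper[nrow(s)]),
           segments = data.frame(segment = s$segment, lower = s$lower,
                                 upper = s$upper, slope = s$slope,
                                 intercept = s$intercept,
                                 n_points = if ("n_points" %in% names(s)) {
                                   s$n_points
                                 } else NA_integer_)),
      class = "piecewise_fit")
  }
  out
}
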