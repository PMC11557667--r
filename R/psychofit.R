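# Maximum-likelihood psychometric fitting.
#
# Two models, matching the two threshold definitions used for dyadic data:
#   * one-sided data: cumulative Gaussian on P(averted | theta); the 50%
#     point is the threshold of direct gaze;
#   * two-sided data: Gaussian bell on P(direct | theta); the SD of the bell
#     is the threshold, the center is the cone's center shift.
#
# Both use the binomial log-likelihood directly (0% and 100% cells need no
# transform), bounded quasi-Newton optimization with deterministic multi-
# start, and are verifiable against an exhaustive grid oracle.

#' Aggregate dyadic trials into per-direction proportions
#'
#' @param trials Data.frame with columns `gaze_deg` and `response`
#'   (1 = "looked at").
#' @return Data.frame with columns `gaze_deg`, `n_trials`, `n_direct`,
#'   sorted by direction.
#' @export
aggregate_dyadic <- function(trials) {
  if (!all(c("gaze_deg", "response") %in% names(trials))) {
    stop("data error: trials need columns `gaze_deg` and `response`",
         call. = FALSE)
  }
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, nrow(trials)), n_direct = trials$response),
    by = list(gaze_deg = trials$gaze_deg), FUN = sum
  )
  agg[order(agg$gaze_deg), , drop = FALSE]
}

check_proportions <- function(props, min_angles) {
  need <- c("gaze_deg", "n_trials", "n_direct")
  if (!all(need %in% names(props))) {
    stop("data error: proportions need columns gaze_deg, n_trials, n_direct",
         call. = FALSE)
  }
  if (any(props$n_direct < 0) || any(props$n_direct > props$n_trials)) {
    stop("data error: need 0 <= n_direct <= n_trials", call. = FALSE)
  }
  if (length(unique(props$gaze_deg)) < min_angles) {
    stop(sprintf("data error: need >= %d distinct gaze directions", min_angles),
         call. = FALSE)
  }
  invisible(props)
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Binomial log-likelihood of averted counts under the cumulative Gaussian:
# P(averted | theta) = (1 - lapse) * Phi((theta - T) / sigma) + lapse / 2.
loglik_cumulative <- function(threshold, sigma, lapse, props) {
  p_avert <- clamp_prob((1 - lapse) *
                          stats::pnorm((props$gaze_deg - threshold) / sigma) +
                          lapse / 2)
  sum(stats::dbinom(props$n_trials - props$n_direct, props$n_trials, p_avert,
                    log = TRUE))
}

# Binomial log-likelihood of direct counts under the Gaussian bell:
# P(direct | theta) = amplitude * exp(-(theta - center)^2 / (2 width^2)).
loglik_bell <- function(center, width, amplitude, props) {
  p_dir <- clamp_prob(amplitude *
                        exp(-(props$gaze_deg - center)^2 / (2 * width^2)))
  sum(stats::dbinom(props$n_direct, props$n_trials, p_dir, log = TRUE))
}

multistart_optim <- function(starts, fn, lower, upper) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 1000)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("fit error: all optimization starts failed", call. = FALSE)
  }
  best
}

#' Fit a cumulative-Gaussian psychometric function (one-sided threshold)
#'
#' Maximum-likelihood fit of
#' `P(averted | theta) = (1 - lapse) * Phi((theta - T) / sigma) + lapse / 2`
#' to aggregated yes/no data ("looked at" judgements inverted so the function
#' rises with eccentricity).  The 50% point `T` is the threshold of direct
#' gaze.  The lapse rate is fixed at 0 by default; `lapse = "free"` estimates
#' it within \[0, 0.05\], which stabilizes fits with 0%/100% cells.
#'
#' @param props Aggregated data from [aggregate_dyadic()] (>= 3 distinct
#'   directions, >= 10 trials in total).
#' @param lapse `"fixed"` (at `lapse_value`, default 0) or `"free"`.
#' @param lapse_value Fixed lapse value when `lapse = "fixed"`.
#' @return An object of class `psychometric_fit` with fields `threshold`,
#'   `sigma`, `lapse`, `loglik`, `converged`.
#' @export
fit_cumulative_gaussian <- function(props, lapse = c("fixed", "free"),
                                    lapse_value = 0) {
  lapse <- match.arg(lapse)
  check_proportions(props, min_angles = 3)
  if (sum(props$n_trials) < 10) {
    stop("data error: need >= 10 trials in total", call. = FALSE)
  }
  if (sum(props$n_direct) == 0 || sum(props$n_direct) == sum(props$n_trials)) {
    stop(paste("non-identifiable: all responses identical across all gaze",
               "directions; the threshold is unbounded"), call. = FALSE)
  }
  th <- props$gaze_deg
  span <- diff(range(th))
  lower_t <- min(th) - 1
  upper_t <- max(th) + 1
  # deterministic multi-start: thresholds at direction quantiles, two widths
  t_starts <- stats::quantile(th, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  starts <- cbind(threshold = t_starts,
                  sigma = rep(c(span / 4, span / 10), length.out = 5))
  if (lapse == "free") {
    fn <- function(par) -loglik_cumulative(par[1], par[2], par[3], props)
    best <- multistart_optim(cbind(starts, lapse = 0.01), fn,
                             lower = c(lower_t, 1e-3, 0),
                             upper = c(upper_t, 2 * span + 1, 0.05))
    fitted_lapse <- best$par[3]
  } else {
    fn <- function(par) -loglik_cumulative(par[1], par[2], lapse_value, props)
    best <- multistart_optim(starts, fn,
                             lower = c(lower_t, 1e-3),
                             upper = c(upper_t, 2 * span + 1))
    fitted_lapse <- lapse_value
  }
  converged <- best$convergence == 0
  if (!converged) {
    warning("psychometric fit did not formally converge; returning best point",
            call. = FALSE)
  }
  structure(
    list(threshold = best$par[1], sigma = best$par[2], lapse = fitted_lapse,
         loglik = -best$value, converged = converged, model = "cumulative"),
    class = "psychometric_fit"
  )
}

#' Fit a Gaussian bell to two-sided "looked at" proportions
#'
#' Maximum-likelihood fit of
#' `P(direct | theta) = a * exp(-(theta - c)^2 / (2 w^2))`.  The SD `w` is
#' the threshold of direct gaze; `c` is the center of the gaze cone (positive
#' = shifted toward the observer's right).
#'
#' @param props Aggregated data (>= 5 distinct directions spanning both
#'   signs).
#' @param fix_amplitude If `TRUE`, fixes `a = 1`; default leaves `a` free in
#'   (0, 1\].
#' @return An object of class `psychometric_fit` with fields `center`,
#'   `width`, `amplitude`, `loglik`, `converged`; `threshold` aliases
#'   `width`.
#' @export
fit_gaussian_bell <- function(props, fix_amplitude = FALSE) {
  check_proportions(props, min_angles = 5)
  if (all(props$gaze_deg >= 0) || all(props$gaze_deg <= 0)) {
    stop("data error: two-sided fit needs directions of both signs",
         call. = FALSE)
  }
  prop <- props$n_direct / props$n_trials
  if (diff(range(prop)) < .Machine$double.eps^0.5) {
    stop("non-identifiable: proportions are flat across gaze directions",
         call. = FALSE)
  }
  th <- props$gaze_deg
  span <- diff(range(th))
  c_starts <- stats::quantile(th, c(0.25, 0.5, 0.5, 0.75, 0.5), names = FALSE)
  starts <- cbind(center = c_starts,
                  width = rep(c(span / 6, span / 3), length.out = 5))
  if (fix_amplitude) {
    fn <- function(par) -loglik_bell(par[1], par[2], 1, props)
    best <- multistart_optim(starts, fn,
                             lower = c(min(th), 1e-3),
                             upper = c(max(th), 2 * span))
    amp <- 1
  } else {
    fn <- function(par) -loglik_bell(par[1], par[2], par[3], props)
    best <- multistart_optim(cbind(starts, amplitude = 0.95), fn,
                             lower = c(min(th), 1e-3, 1e-3),
                             upper = c(max(th), 2 * span, 1))
    amp <- best$par[3]
  }
  converged <- best$convergence == 0
  if (!converged) {
    warning("bell fit did not formally converge; returning best point",
            call. = FALSE)
  }
  structure(
    list(center = best$par[1], width = best$par[2], threshold = best$par[2],
         amplitude = amp, loglik = -best$value, converged = converged,
         model = "bell"),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$model == "cumulative") {
    cat(sprintf("Cumulative-Gaussian fit: threshold %.2f deg, sigma %.2f deg, lapse %.3f (loglik %.2f)\n",
                x$threshold, x$sigma, x$lapse, x$loglik))
  } else {
    cat(sprintf("Gaussian-bell fit: width (threshold) %.2f deg, center %.2f deg, amplitude %.2f (loglik %.2f)\n",
                x$width, x$center, x$amplitude, x$loglik))
  }
  invisible(x)
}

#' Exhaustive grid-search oracle for the psychometric likelihoods
#'
#' Evaluates the binomial log-likelihood on every point of a finite parameter
#' grid and returns the maximizing point together with the full surface.
#' Intended as an independent verification of the quasi-Newton fits.
#'
#' @param props Aggregated proportions.
#' @param grid A named list of parameter value vectors: for
#'   `model = "cumulative"`, `threshold`, `sigma` and optionally `lapse`
#'   (default 0); for `model = "bell"`, `center`, `width` and optionally
#'   `amplitude` (default 1).
#' @param model `"cumulative"` or `"bell"`.
#' @return A list with `best` (named parameter vector), `loglik`, and
#'   `surface` (data.frame of all grid points and log-likelihoods).
#' @export
grid_fit_oracle <- function(props, grid, model = c("cumulative", "bell")) {
  model <- match.arg(model)
  if (length(grid) == 0 || any(vapply(grid, length, 1L) == 0)) {
    stop("grid error: empty parameter grid", call. = FALSE)
  }
  if (model == "cumulative") {
    if (is.null(grid$lapse)) grid$lapse <- 0
    surface <- expand.grid(threshold = grid$threshold, sigma = grid$sigma,
                           lapse = grid$lapse, KEEP.OUT.ATTRS = FALSE)
    surface$loglik <- mapply(loglik_cumulative, surface$threshold,
                             surface$sigma, surface$lapse,
                             MoreArgs = list(props = props))
  } else {
    if (is.null(grid$amplitude)) grid$amplitude <- 1
    surface <- expand.grid(center = grid$center, width = grid$width,
                           amplitude = grid$amplitude, KEEP.OUT.ATTRS = FALSE)
    surface$loglik <- mapply(loglik_bell, surface$center, surface$width,
                             surface$amplitude,
                             MoreArgs = list(props = props))
  }
  k <- which.max(surface$loglik)
  best <- unlist(surface[k, setdiff(names(surface), "loglik")])
  list(best = best, loglik = surface$loglik[k], surface = surface)
}

#' Fit psychometric functions for every observer in a cohort
#'
#' @param trials Dyadic trial table with `observer_id`, `gaze_deg`,
#'   `response`.
#' @param style `"one_sided"` (cumulative Gaussian) or `"two_sided"`
#'   (Gaussian bell).
#' @param ... Passed to the underlying fitting function.
#' @return Data.frame with one row per observer: `observer_id`,
#'   `threshold_deg`, `sigma_or_width_deg`, `center_deg`, `lapse`, `loglik`,
#'   `converged`.
#' @export
fit_cohort_psychometric <- function(trials, style = c("one_sided", "two_sided"),
                                    ...) {
  style <- match.arg(style)
  ids <- sort(unique(trials$observer_id))
  rows <- lapply(ids, function(id) {
    props <- aggregate_dyadic(trials[trials$observer_id == id, , drop = FALSE])
    if (style == "one_sided") {
      f <- fit_cumulative_gaussian(props, ...)
      data.frame(observer_id = id, threshold_deg = f$threshold,
                 sigma_or_width_deg = f$sigma, center_deg = NA_real_,
                 lapse = f$lapse, loglik = f$loglik, converged = f$converged)
    } else {
      f <- fit_gaussian_bell(props, ...)
      data.frame(observer_id = id, threshold_deg = f$width,
                 sigma_or_width_deg = f$width, center_deg = f$center,
                 lapse = NA_real_, loglik = f$loglik, converged = f$converged)
    }
  })
  do.call(rbind, rows)
}
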