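# Generative observer model and trial-level simulators for the three tasks.
#
# The simulator maps one observed phenomenon to one parameter:
#   * dyadic yes/no responses: cumulative-Gaussian psychometric rule around
#     the criterion, with a symmetric lapse;
#   * adjustment stop-points: criterion +/- half the hysteresis depending on
#     series direction, plus Gaussian settling noise, quantized to the
#     adjustment step;
#   * triadic reports: a two-slope (shallow near straight gaze, steep in the
#     periphery) perceived-direction gain, converted to cm on the response
#     scale, plus report noise, rounded to whole centimetres.
#
# Every simulator takes an explicit seed and is deterministic given
# (parameters, design, seed).

#' Generative parameters of one virtual observer
#'
#' @param criterion Threshold of direct gaze T in degrees (> 0) governing the
#'   dyadic task and, unless overridden, the adjustment task.
#' @param psycho_width SD (degrees) of the generative cumulative-Gaussian
#'   psychometric function (> 0).
#' @param lapse Stimulus-independent error probability in \[0, 0.1\].
#' @param center_shift Center c of the gaze cone in degrees (two-sided
#'   observers; 0 for symmetric observers).
#' @param adjust_criterion Criterion used in the method-of-adjustment task.
#'   Defaults to `criterion`; set it higher to emulate the empirically larger
#'   adjustment thresholds (the two tasks need not share a criterion).
#' @param hysteresis Expected descending-minus-ascending stop difference h in
#'   degrees; stops sit at criterion -/+ h/2 for ascending/descending series.
#' @param adjust_noise_sd SD of adjustment stop-points in degrees (>= 0).
#' @param triadic_near_gain Slope of perceived vs true gaze below the knot.
#' @param triadic_far_gain Slope above the knot.
#' @param triadic_knot Knot position in degrees (>= 0).
#' @param triadic_noise_sd SD of triadic report noise in cm (>= 0).
#' @param seed Integer seed for this observer's trial streams.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(criterion = 3.3,
                            psycho_width = 1.5,
                            lapse = 0.02,
                            center_shift = 0,
                            adjust_criterion = NULL,
                            hysteresis = 0.37,
                            adjust_noise_sd = 1.05,
                            triadic_near_gain = 0.18,
                            triadic_far_gain = 1.8,
                            triadic_knot = 0.9,
                            triadic_noise_sd = 2.0,
                            seed = 1L) {
  if (is.null(adjust_criterion)) adjust_criterion <- criterion
  p <- list(
    criterion = criterion, psycho_width = psycho_width, lapse = lapse,
    center_shift = center_shift, adjust_criterion = adjust_criterion,
    hysteresis = hysteresis, adjust_noise_sd = adjust_noise_sd,
    triadic_near_gain = triadic_near_gain, triadic_far_gain = triadic_far_gain,
    triadic_knot = triadic_knot, triadic_noise_sd = triadic_noise_sd,
    seed = as.integer(seed)
  )
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("observer error: all parameters must be single finite numbers (",
         paste(names(p)[!num], collapse = ", "), ")", call. = FALSE)
  }
  if (p$criterion <= 0 || p$adjust_criterion <= 0) {
    stop("observer error: criteria must be positive", call. = FALSE)
  }
  if (p$psycho_width <= 0) {
    stop("observer error: `psycho_width` must be positive", call. = FALSE)
  }
  if (p$lapse < 0 || p$lapse > 0.1) {
    stop("observer error: `lapse` must lie in [0, 0.1]", call. = FALSE)
  }
  if (p$adjust_noise_sd < 0 || p$triadic_noise_sd < 0) {
    stop("observer error: noise SDs must be non-negative", call. = FALSE)
  }
  if (p$triadic_knot < 0) {
    stop("observer error: `triadic_knot` must be non-negative", call. = FALSE)
  }
  structure(p, class = "observer_params")
}

#' Probability of a "looked at" response at a gaze direction
#'
#' `P(direct | theta) = (1 - lapse) * Phi((T - |theta - c|) / sigma) + lapse / 2`.
#' One-sided designs use the gaze magnitude and ignore the center shift.
#'
#' @param theta_deg Gaze direction(s) in degrees.
#' @param obs An [observer_params()] object.
#' @param sides `"one"` or `"two"`.
#' @return Probabilities in \[0, 1\].
#' @export
p_direct <- function(theta_deg, obs, sides = c("one", "two")) {
  sides <- match.arg(sides)
  ecc <- if (sides == "one") abs(theta_deg) else abs(theta_deg - obs$center_shift)
  (1 - obs$lapse) * stats::pnorm((obs$criterion - ecc) / obs$psycho_width) +
    obs$lapse / 2
}

#' Simulate a constant-stimuli (dyadic yes/no) session
#'
#' One Bernoulli response per design trial under the observer's psychometric
#' rule, with trial order randomized by the seed.
#'
#' @param obs An [observer_params()] object.
#' @param design A [stimulus_design()].
#' @param seed Integer seed; defaults to the observer's own seed.
#' @return A data.frame with columns `trial`, `gaze_deg`, `response`
#'   (1 = "looked at", 0 = "not looked at").
#' @export
simulate_dyadic_constant <- function(obs, design, seed = obs$seed) {
  if (!inherits(design, "stimulus_design")) {
    stop("design error: expected a `stimulus_design` object", call. = FALSE)
  }
  set.seed(seed)
  gaze <- sample(rep(design$directions_deg, each = design$repetitions))
  p <- p_direct(gaze, obs, sides = design$sides)
  data.frame(
    trial = seq_along(gaze),
    gaze_deg = gaze,
    response = as.integer(stats::runif(length(gaze)) < p)
  )
}

#' Series plan for a method-of-adjustment session
#'
#' @param sides `"one"` or `"two"`; two-sided plans run each series on the
#'   left and right separately.
#' @param reps_per_cell Trials per (series x side) cell.
#' @param range_max_deg Largest adjustable gaze magnitude in degrees (> 0).
#' @param step_deg Adjustment granularity in degrees; stop-points are
#'   quantized to this step (e.g. 0.05 for a fine mouse-wheel mapping, 1 for
#'   a coarse one).
#' @return An object of class `adjustment_plan`.
#' @export
adjustment_plan <- function(sides = c("one", "two"), reps_per_cell = 6,
                            range_max_deg = 13.9, step_deg = 0.05) {
  sides <- match.arg(sides)
  if (range_max_deg <= 0) {
    stop("design error: `range_max_deg` must be positive", call. = FALSE)
  }
  if (reps_per_cell < 1) {
    stop("design error: `reps_per_cell` must be >= 1", call. = FALSE)
  }
  if (step_deg < 0) {
    stop("design error: `step_deg` must be non-negative", call. = FALSE)
  }
  side_labels <- if (sides == "one") "right" else c("left", "right")
  n <- 2L * length(side_labels) * as.integer(reps_per_cell)
  structure(
    list(sides = sides, reps_per_cell = as.integer(reps_per_cell),
         range_max_deg = range_max_deg, step_deg = step_deg,
         side_labels = side_labels, n_trials = n),
    class = "adjustment_plan"
  )
}

#' Simulate a method-of-adjustment session
#'
#' Ascending series stop at `criterion - h/2 + noise`, descending series at
#' `criterion + h/2 + noise` (magnitudes, then signed by side), clipped to
#' the adjustable range and quantized to the plan's step.
#'
#' @param obs An [observer_params()] object.
#' @param plan An [adjustment_plan()].
#' @param seed Integer seed; defaults to the observer's own seed.
#' @return A data.frame with columns `trial`, `series` ("ascending" /
#'   "descending"), `side` ("left" / "right"), `stop_deg` (signed).
#' @export
simulate_adjustment <- function(obs, plan, seed = obs$seed) {
  if (!inherits(plan, "adjustment_plan")) {
    stop("design error: expected an `adjustment_plan` object", call. = FALSE)
  }
  set.seed(seed)
  cells <- expand.grid(
    series = c("ascending", "descending"), side = plan$side_labels,
    rep = seq_len(plan$reps_per_cell),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells <- cells[sample(nrow(cells)), , drop = FALSE]
  offset <- ifelse(cells$series == "ascending",
                   -obs$hysteresis / 2, obs$hysteresis / 2)
  mag <- obs$adjust_criterion + offset +
    stats::rnorm(nrow(cells), 0, obs$adjust_noise_sd)
  mag <- pmin(pmax(mag, 0), plan$range_max_deg)
  if (plan$step_deg > 0) mag <- round(mag / plan$step_deg) * plan$step_deg
  sign_side <- ifelse(cells$side == "left", -1, 1)
  data.frame(
    trial = seq_len(nrow(cells)),
    series = cells$series,
    side = cells$side,
    stop_deg = sign_side * mag
  )
}

#' Perceived gaze direction under the two-slope triadic gain
#'
#' `g(theta) = sign(theta) * (near * min(|theta|, knot) + far * max(0, |theta| - knot))`
#' in degrees: an odd, piecewise-linear, continuous mapping that is shallow
#' below the knot and steep above it.
#'
#' @param theta_deg True gaze direction(s) in degrees.
#' @param obs An [observer_params()] object.
#' @return Perceived direction(s) in degrees.
#' @export
perceived_direction <- function(theta_deg, obs) {
  a <- abs(theta_deg)
  sign(theta_deg) * (obs$triadic_near_gain * pmin(a, obs$triadic_knot) +
                       obs$triadic_far_gain * pmax(0, a - obs$triadic_knot))
}

#' Simulate a triadic gaze-direction estimation session
#'
#' For each true fixation direction the observer's perceived direction is
#' mapped to a position on the response scale (cm at the fixation plane),
#' perturbed by report noise, and rounded to the nearest whole centimetre,
#' emulating reading a cm value off a meterstick.
#'
#' @param obs An [observer_params()] object.
#' @param positions_deg True fixation directions in degrees (each repeated
#'   `repetitions` times).
#' @param geom A [gaze_geometry()] whose distance is the looker-to-scale
#'   distance.
#' @param repetitions Trials per position.
#' @param scale_max_cm Half-length of the response scale in cm; true
#'   positions beyond it raise a range error.
#' @param round_to_cm Quantize reports to whole centimetres (the meterstick
#'   reading rule). Set `FALSE` for an unquantized response scale, e.g. in
#'   noiseless parameter-recovery checks where sub-centimetre perceived
#'   offsets near straight gaze would otherwise all collapse to zero.
#' @param seed Integer seed; defaults to the observer's own seed.
#' @return A data.frame with columns `trial`, `true_deg`, `reported_cm`
#'   (integer when `round_to_cm` is `TRUE`).
#' @export
simulate_triadic <- function(obs, positions_deg, geom, repetitions = 10,
                             scale_max_cm = 100, round_to_cm = TRUE,
                             seed = obs$seed) {
  assert_geometry(geom)
  true_cm <- angle_to_offset(positions_deg, geom)
  if (any(abs(true_cm) > scale_max_cm)) {
    stop("range error: fixation position beyond the response scale",
         call. = FALSE)
  }
  set.seed(seed)
  gaze <- sample(rep(positions_deg, each = repetitions))
  perceived_cm <- angle_to_offset(perceived_direction(gaze, obs), geom) +
    stats::rnorm(length(gaze), 0, obs$triadic_noise_sd)
  data.frame(
    trial = seq_along(gaze),
    true_deg = gaze,
    reported_cm = if (round_to_cm) as.integer(round(perceived_cm)) else perceived_cm
  )
}

# -- cohort simulation --------------------------------------------------------

# Deterministic per-observer seed derivation: a fixed multiplicative counter
# scheme keeps observer streams reproducible and distinct, and stays within
# the 32-bit integer range R's RNG seeding accepts.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(index)) %%
               2147483647)
}

draw_param <- function(spec, n, lower = -Inf, upper = Inf) {
  if (length(spec) == 1) return(rep(spec, n))
  if (length(spec) != 2) {
    stop("config error: parameter spec must be a single value or c(mean, sd)",
         call. = FALSE)
  }
  pmin(pmax(stats::rnorm(n, spec[1], spec[2]), lower), upper)
}

#' Configuration for a simulated cohort of observers
#'
#' Each observer-level parameter is either a fixed value (length 1) or a
#' `c(mean, sd)` pair sampled from a Normal distribution truncated to the
#' parameter's valid range.  Per-observer seeds are derived deterministically
#' from `master_seed` by a fixed counter scheme, so a cohort is fully
#' reproducible from its configuration.
#'
#' @param n_observers Number of virtual observers (>= 1).
#' @param criterion,psycho_width,lapse,center_shift,adjust_criterion,hysteresis,adjust_noise_sd,triadic_near_gain,triadic_far_gain,triadic_knot,triadic_noise_sd
#'   Fixed value or `c(mean, sd)`; see [observer_params()] for meanings.
#'   `adjust_criterion = NULL` reuses each observer's `criterion`.
#' @param dyadic_design A [stimulus_design()] for the constant-stimuli task.
#' @param adjustment A [adjustment_plan()].
#' @param triadic_positions_deg True fixation directions for the triadic task.
#' @param triadic_repetitions Trials per triadic position.
#' @param geom A [gaze_geometry()].
#' @param master_seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_observers = 18,
                          criterion = c(3.3, 1.0),
                          psycho_width = c(1.5, 0.3),
                          lapse = 0.02,
                          center_shift = 0,
                          adjust_criterion = NULL,
                          hysteresis = 0.37,
                          adjust_noise_sd = 1.05,
                          triadic_near_gain = c(0.18, 0.1),
                          triadic_far_gain = c(1.8, 0.4),
                          triadic_knot = 0.9,
                          triadic_noise_sd = 2.0,
                          dyadic_design = NULL,
                          adjustment = adjustment_plan("one"),
                          triadic_positions_deg = NULL,
                          triadic_repetitions = 10,
                          geom = gaze_geometry(165),
                          master_seed = 1L) {
  if (n_observers < 1) {
    stop("config error: `n_observers` must be >= 1", call. = FALSE)
  }
  if (is.null(dyadic_design)) {
    dyadic_design <- exponential_stimulus_design(2.5, 4, geom, repetitions = 25)
  }
  if (is.null(triadic_positions_deg)) {
    triadic_positions_deg <- dyadic_design$directions_deg
  }
  structure(
    list(n_observers = as.integer(n_observers),
         params = list(criterion = criterion, psycho_width = psycho_width,
                       lapse = lapse, center_shift = center_shift,
                       adjust_criterion = adjust_criterion,
                       hysteresis = hysteresis,
                       adjust_noise_sd = adjust_noise_sd,
                       triadic_near_gain = triadic_near_gain,
                       triadic_far_gain = triadic_far_gain,
                       triadic_knot = triadic_knot,
                       triadic_noise_sd = triadic_noise_sd),
         dyadic_design = dyadic_design, adjustment = adjustment,
         triadic_positions_deg = triadic_positions_deg,
         triadic_repetitions = triadic_repetitions,
         geom = geom, master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' Simulate a full cohort across all three tasks
#'
#' Draws per-observer generative parameters from the cohort configuration,
#' then simulates a constant-stimuli, an adjustment, and a triadic session
#' for every observer.  The drawn parameters are returned as the `truth`
#' table, the ground truth for parameter-recovery checks.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `gaze_cohort` with data.frames `truth`, `dyadic`,
#'   `adjustment`, `triadic` (trial tables carry an `observer_id` column).
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) {
    stop("config error: expected a `cohort_config` object", call. = FALSE)
  }
  n <- cfg$n_observers
  set.seed(cfg$master_seed)
  pp <- cfg$params
  truth <- data.frame(
    observer_id = seq_len(n),
    criterion = draw_param(pp$criterion, n, lower = 0.1),
    psycho_width = draw_param(pp$psycho_width, n, lower = 0.05),
    lapse = draw_param(pp$lapse, n, lower = 0, upper = 0.1),
    center_shift = draw_param(pp$center_shift, n),
    hysteresis = draw_param(pp$hysteresis, n),
    adjust_noise_sd = draw_param(pp$adjust_noise_sd, n, lower = 0),
    triadic_near_gain = draw_param(pp$triadic_near_gain, n, lower = 0),
    triadic_far_gain = draw_param(pp$triadic_far_gain, n, lower = 0),
    triadic_knot = draw_param(pp$triadic_knot, n, lower = 0),
    triadic_noise_sd = draw_param(pp$triadic_noise_sd, n, lower = 0)
  )
  truth$adjust_criterion <- if (is.null(pp$adjust_criterion)) {
    truth$criterion
  } else {
    draw_param(pp$adjust_criterion, n, lower = 0.1)
  }
  truth$seed <- derive_seed(cfg$master_seed, seq_len(n))

  one_observer <- function(i) {
    row <- truth[i, ]
    observer_params(
      criterion = row$criterion, psycho_width = row$psycho_width,
      lapse = row$lapse, center_shift = row$center_shift,
      adjust_criterion = row$adjust_criterion, hysteresis = row$hysteresis,
      adjust_noise_sd = row$adjust_noise_sd,
      triadic_near_gain = row$triadic_near_gain,
      triadic_far_gain = row$triadic_far_gain,
      triadic_knot = row$triadic_knot,
      triadic_noise_sd = row$triadic_noise_sd, seed = row$seed
    )
  }
  with_id <- function(df, i) cbind(observer_id = i, df)
  dyadic <- do.call(rbind, lapply(seq_len(n), function(i) {
    with_id(simulate_dyadic_constant(one_observer(i), cfg$dyadic_design), i)
  }))
  adjustment <- do.call(rbind, lapply(seq_len(n), function(i) {
    obs <- one_observer(i)
    with_id(simulate_adjustment(obs, cfg$adjustment,
                                seed = derive_seed(obs$seed, 1L)), i)
  }))
  triadic <- do.call(rbind, lapply(seq_len(n), function(i) {
    obs <- one_observer(i)
    with_id(simulate_triadic(obs, cfg$triadic_positions_deg, cfg$geom,
                             repetitions = cfg$triadic_repetitions,
                             seed = derive_seed(obs$seed, 2L)), i)
  }))
  structure(
    list(truth = truth, dyadic = dyadic, adjustment = adjustment,
         triadic = triadic, config = cfg),
    class = "gaze_cohort"
  )
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("Simulated gaze cohort: %d observers\n", nrow(x$truth)))
  cat(sprintf("  dyadic trials: %d, adjustment trials: %d, triadic trials: %d\n",
              nrow(x$dyadic), nrow(x$adjustment), nrow(x$triadic)))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `dyadic_trials.csv`, `adjustment_trials.csv`, `triadic_trials.csv`
#' and `truth.csv` (RFC-4180, header row, '.' decimal separator) into `dir`.
#'
#' @param cohort A `gaze_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "gaze_cohort")) {
    stop("config error: expected a `gaze_cohort` object", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dyadic = file.path(dir, "dyadic_trials.csv"),
    adjustment = file.path(dir, "adjustment_trials.csv"),
    triadic = file.path(dir, "triadic_trials.csv"),
    truth = file.path(dir, "truth.csv")
  )
  utils::write.csv(cohort$dyadic, paths[["dyadic"]], row.names = FALSE)
  utils::write.csv(cohort$adjustment, paths[["adjustment"]], row.names = FALSE)
  utils::write.csv(cohort$triadic, paths[["triadic"]], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
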