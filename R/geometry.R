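# Viewing geometry: conversions between on-screen fixation offsets and
# looker eye rotations, stimulus-set construction, cone-width bookkeeping.
#
# Sign convention throughout the package: angles are in degrees, gaze to the
# observer's left is negative, right is positive.  One-sided designs store
# non-negative magnitudes together with a `sides = "one"` flag.

#' Viewing geometry of a gaze-perception setup
#'
#' Bundles the looker--observer viewing distance and the looker's
#' interpupillary distance (IPD).  All angle conversions in the package go
#' through this object; angles are exact (`atan`), no small-angle
#' approximation is used.
#'
#' @param viewing_distance_cm Looker--observer distance in cm (> 0).
#' @param ipd_cm Interpupillary distance in cm (>= 0). Default 6.5 cm.
#' @return An object of class `gaze_geometry`.
#' @examples
#' geom <- gaze_geometry(165)
#' offset_to_angle(2, geom) # ~0.69 degrees
#' @export
gaze_geometry <- function(viewing_distance_cm, ipd_cm = 6.5) {
  if (!is.numeric(viewing_distance_cm) || length(viewing_distance_cm) != 1 ||
      !is.finite(viewing_distance_cm) || viewing_distance_cm <= 0) {
    stop("invalid geometry: `viewing_distance_cm` must be a single finite positive number",
         call. = FALSE)
  }
  if (!is.numeric(ipd_cm) || length(ipd_cm) != 1 ||
      !is.finite(ipd_cm) || ipd_cm < 0) {
    stop("invalid geometry: `ipd_cm` must be a single finite non-negative number",
         call. = FALSE)
  }
  structure(
    list(viewing_distance_cm = viewing_distance_cm, ipd_cm = ipd_cm),
    class = "gaze_geometry"
  )
}

#' @export
print.gaze_geometry <- function(x, ...) {
  cat(sprintf("Gaze geometry: viewing distance %.1f cm, IPD %.2f cm\n",
              x$viewing_distance_cm, x$ipd_cm))
  invisible(x)
}

assert_geometry <- function(geom) {
  if (!inherits(geom, "gaze_geometry")) {
    stop("invalid geometry: expected a `gaze_geometry` object", call. = FALSE)
  }
  invisible(geom)
}

#' Convert an on-screen offset to a gaze rotation
#'
#' A fixation point `offset_cm` centimetres from the observer's midline, at
#' the geometry's viewing distance, corresponds to an eye rotation of
#' `atan(offset / distance)` degrees.  The sign of the output equals the sign
#' of the offset (left negative).
#'
#' @param offset_cm Offset(s) on the fixation plane, in cm. Vectorized.
#' @param geom A [gaze_geometry()] object.
#' @return Gaze angle(s) in degrees.
#' @export
offset_to_angle <- function(offset_cm, geom) {
  assert_geometry(geom)
  if (!is.numeric(offset_cm) || any(!is.finite(offset_cm))) {
    stop("invalid geometry: `offset_cm` must be finite", call. = FALSE)
  }
  atan(offset_cm / geom$viewing_distance_cm) * 180 / pi
}

#' Convert a gaze rotation to an on-screen offset
#'
#' Exact inverse of [offset_to_angle()]: `offset = distance * tan(angle)`.
#'
#' @param angle_deg Gaze angle(s) in degrees, |angle| < 90. Vectorized.
#' @param geom A [gaze_geometry()] object.
#' @return Offset(s) in cm on the fixation plane.
#' @export
angle_to_offset <- function(angle_deg, geom) {
  assert_geometry(geom)
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)) ||
      any(abs(angle_deg) >= 90)) {
    stop("invalid angle: |angle_deg| must be finite and < 90", call. = FALSE)
  }
  geom$viewing_distance_cm * tan(angle_deg * pi / 180)
}

#' Per-eye vergence rotation for a fixated observer
#'
#' Inward rotation each eye needs to fixate the observer at the viewing
#' distance: `atan((IPD / 2) / distance)` degrees per eye.
#'
#' @param geom A [gaze_geometry()] object.
#' @return Vergence angle per eye in degrees (non-negative).
#' @export
vergence_per_eye <- function(geom) {
  assert_geometry(geom)
  atan((geom$ipd_cm / 2) / geom$viewing_distance_cm) * 180 / pi
}

#' Stimulus design for a constant-stimuli or adjustment task
#'
#' @param directions_deg Ordered gaze directions in degrees. One-sided designs
#'   must contain only non-negative magnitudes.
#' @param repetitions Trials per direction (positive integer).
#' @param sides `"one"` (magnitudes only) or `"two"` (signed directions).
#' @return An object of class `stimulus_design` with fields `directions_deg`,
#'   `repetitions`, `sides`, and `n_trials = length(directions) * repetitions`.
#' @export
stimulus_design <- function(directions_deg, repetitions, sides = c("one", "two")) {
  sides <- match.arg(sides)
  if (!is.numeric(directions_deg) || length(directions_deg) < 1 ||
      any(!is.finite(directions_deg))) {
    stop("design error: `directions_deg` must be a non-empty finite vector",
         call. = FALSE)
  }
  if (anyDuplicated(directions_deg)) {
    stop("design error: gaze directions must be distinct", call. = FALSE)
  }
  if (sides == "one" && any(directions_deg < 0)) {
    stop("design error: one-sided designs contain only non-negative magnitudes",
         call. = FALSE)
  }
  if (!is.numeric(repetitions) || length(repetitions) != 1 ||
      repetitions < 1 || repetitions != round(repetitions)) {
    stop("design error: `repetitions` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      directions_deg = as.numeric(directions_deg),
      repetitions = as.integer(repetitions),
      sides = sides,
      n_trials = length(directions_deg) * as.integer(repetitions)
    ),
    class = "stimulus_design"
  )
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf("Stimulus design (%s-sided): %d directions x %d repetitions = %d trials\n",
              x$sides, length(x$directions_deg), x$repetitions, x$n_trials))
  cat("  directions (deg):", paste(round(x$directions_deg, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Exponentially spaced one-sided stimulus design
#'
#' Fixation offsets at 0 and at successive powers of the base step
#' (`base_cm^1 ... base_cm^n_steps` cm), converted to gaze angles through the
#' geometry.  With the 2.5 cm base and 165 cm distance this yields the
#' direction set 0, 0.9, 2.2, 5.4, 13.3 degrees.
#'
#' @param base_cm Base of the exponential offset series in cm (> 0, != 1).
#' @param n_steps Number of non-zero steps (>= 1).
#' @param geom A [gaze_geometry()] object.
#' @param repetitions Trials per direction.
#' @return A one-sided [stimulus_design()] with an extra field `offsets_cm`.
#' @export
exponential_stimulus_design <- function(base_cm = 2.5, n_steps = 4, geom,
                                        repetitions = 25) {
  assert_geometry(geom)
  if (!is.numeric(base_cm) || length(base_cm) != 1 || base_cm <= 0) {
    stop("design error: `base_cm` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("design error: `n_steps` must be >= 1", call. = FALSE)
  }
  offsets_cm <- c(0, base_cm ^ seq_len(n_steps))
  if (anyDuplicated(offsets_cm)) {
    stop("design error: exponential offsets are not distinct (degenerate base)",
         call. = FALSE)
  }
  design <- stimulus_design(offset_to_angle(offsets_cm, geom),
                            repetitions = repetitions, sides = "one")
  design$offsets_cm <- offsets_cm
  design
}

#' Linearly spaced two-sided stimulus design
#'
#' Signed gaze directions from `-max_deg` to `max_deg` in steps of
#' `step_deg` (e.g. 11 directions for 15 degrees in steps of 3).
#'
#' @param step_deg Angular step in degrees (> 0).
#' @param max_deg Largest magnitude in degrees (>= step).
#' @param repetitions Trials per direction.
#' @return A two-sided [stimulus_design()].
#' @export
linear_stimulus_design <- function(step_deg = 3, max_deg = 15, repetitions = 35) {
  if (step_deg <= 0 || max_deg < step_deg) {
    stop("design error: need 0 < step_deg <= max_deg", call. = FALSE)
  }
  stimulus_design(seq(-max_deg, max_deg, by = step_deg),
                  repetitions = repetitions, sides = "two")
}

#' Gaze-cone width from a threshold of direct gaze
#'
#' The threshold of direct gaze is the half width of the gaze cone; the full
#' (two-sided) cone width is exactly twice the half width.
#'
#' @param half_width_deg Threshold of direct gaze in degrees (>= 0).
#' @return A list with `half_width_deg` and `full_width_deg = 2 * half`.
#' @export
cone_width <- function(half_width_deg) {
  if (!is.numeric(half_width_deg) || any(!is.finite(half_width_deg)) ||
      any(half_width_deg < 0)) {
    stop("domain error: half width must be non-negative", call. = FALSE)
  }
  list(half_width_deg = half_width_deg, full_width_deg = 2 * half_width_deg)
}
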