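#' Arena geometry specification
#'
#' Describes the recording arena: a rectangular cropped frame containing a
#' circular culture dish with a static food (artificial diet) blob. The
#' default matches the standard assay setup: a 520 x 400 px crop of a 100 mm
#' dish filmed at one frame every 3 s.
#'
#' Coordinates use image convention: `x` is the column and `y` the row, the
#' origin is the top-left corner, `y` increases downward, and pixel centres
#' lie at integer coordinates.
#'
#' @param width_px,height_px Frame dimensions in pixels.
#' @param dish_center Numeric `(x, y)`, centre of the dish in pixels.
#' @param dish_radius_px Dish radius in pixels; the dish circle must fit
#'   inside the frame.
#' @param food_center Numeric `(x, y)`, centre of the diet blob; must lie
#'   inside the dish.
#' @param food_radius_px Radius of the diet blob in pixels (may be 0).
#' @param frame_interval_s Nominal inter-frame interval in seconds.
#' @return An object of class `arena_spec`.
#' @examples
#' arena <- arena_spec()
#' arena
#' @export
arena_spec <- function(width_px = 520L, height_px = 400L,
                       dish_center = c(260, 200), dish_radius_px = 190,
                       food_center = c(260, 200), food_radius_px = 30,
                       frame_interval_s = 3) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  stop_unless(length(dish_center) == 2 && all(is.finite(dish_center)),
              "dish_center must be a finite (x, y) pair")
  stop_unless(length(food_center) == 2 && all(is.finite(food_center)),
              "food_center must be a finite (x, y) pair")
  stop_unless(is.finite(dish_radius_px) && dish_radius_px > 0,
              "dish_radius_px must be positive")
  stop_unless(is.finite(food_radius_px) && food_radius_px >= 0,
              "food_radius_px must be non-negative")
  stop_unless(is.finite(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be positive")
  stop_unless(dish_center[1] - dish_radius_px >= 0 &&
              dish_center[1] + dish_radius_px <= width_px &&
              dish_center[2] - dish_radius_px >= 0 &&
              dish_center[2] + dish_radius_px <= height_px,
              "dish circle must fit inside the frame rectangle")
  stop_unless(sqrt(sum((food_center - dish_center)^2)) + food_radius_px <=
              dish_radius_px,
              "food circle must lie inside the dish")
  structure(list(width_px = width_px, height_px = height_px,
                 dish_center = as.numeric(dish_center),
                 dish_radius_px = as.numeric(dish_radius_px),
                 food_center = as.numeric(food_center),
                 food_radius_px = as.numeric(food_radius_px),
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("Arena: %d x %d px, dish r = %.0f px at (%.0f, %.0f),",
              x$width_px, x$height_px, x$dish_radius_px,
              x$dish_center[1], x$dish_center[2]))
  cat(sprintf(" food r = %.0f px at (%.0f, %.0f), %.3g s/frame\n",
              x$food_radius_px, x$food_center[1], x$food_center[2],
              x$frame_interval_s))
  invisible(x)
}

#' Behavioural parameters of the two-state larva model
#'
#' The simulator alternates stationary phases (exponentially distributed
#' duration with rate `bout_rate_per_h`) and movement bouts
#' (gamma-distributed duration). During a bout the larva performs a
#' correlated random walk: per-interval step lengths are lognormal with mean
#' `step_mean_px`, and the heading turns by a normal angle whose spread
#' shrinks as `heading_persistence` approaches 1. Stationary phases get
#' sub-threshold centroid jitter (net step at most 0.3 px) so the 0.5 px
#' movement classifier is exercised near its boundary, as real centroids
#' fluctuate.
#'
#' Spatial mode: `"food_centered"` larvae drift back toward the diet blob and
#' reflect off the dish wall; `"edge_following"` larvae drift outward and
#' then travel tangentially along the wall. `mode_switch_h` flips the mode at
#' a fixed time after recording start (e.g. late-infection onset of
#' edge-following).
#'
#' @param bout_rate_per_h Expected movement-bout initiations per hour
#'   (rate of the exponential stationary-phase duration). Zero means the
#'   larva never moves.
#' @param bout_duration_shape,bout_duration_mean_s Gamma shape and mean (s)
#'   of movement-bout durations.
#' @param step_mean_px Mean per-interval displacement (px) while moving.
#' @param step_dispersion Lognormal sdlog of moving step lengths.
#' @param heading_persistence Directional correlation in `[0, 1]`; 1 keeps
#'   the heading, 0 randomizes it each interval.
#' @param mode Initial spatial mode, `"food_centered"` or `"edge_following"`.
#' @param mode_switch_h Hours after start at which the mode flips to the
#'   other one; `NA` (default) means never.
#' @return An object of class `behavior_params`.
#' @seealso [mock_params()], [infected_params()], [simulate_trajectory()]
#' @export
behavior_params <- function(bout_rate_per_h = 2,
                            bout_duration_shape = 2,
                            bout_duration_mean_s = 120,
                            step_mean_px = 2,
                            step_dispersion = 0.5,
                            heading_persistence = 0.7,
                            mode = c("food_centered", "edge_following"),
                            mode_switch_h = NA_real_) {
  mode <- match.arg(mode)
  stop_unless(is.finite(bout_rate_per_h) && bout_rate_per_h >= 0,
              "bout_rate_per_h must be non-negative")
  stop_unless(is.finite(bout_duration_shape) && bout_duration_shape > 0,
              "bout_duration_shape must be strictly positive")
  stop_unless(is.finite(bout_duration_mean_s) && bout_duration_mean_s > 0,
              "bout_duration_mean_s must be strictly positive")
  stop_unless(is.finite(step_mean_px) && step_mean_px > 0,
              "step_mean_px must be strictly positive")
  stop_unless(is.finite(step_dispersion) && step_dispersion > 0,
              "step_dispersion must be strictly positive")
  stop_unless(is.finite(heading_persistence) &&
              heading_persistence >= 0 && heading_persistence <= 1,
              "heading_persistence must lie in [0, 1]")
  stop_unless(is.na(mode_switch_h) ||
              (mode_switch_h >= 0 && mode_switch_h <= 24),
              "mode_switch_h must lie in [0, 24] when given")
  structure(list(bout_rate_per_h = bout_rate_per_h,
                 bout_duration_shape = bout_duration_shape,
                 bout_duration_mean_s = bout_duration_mean_s,
                 step_mean_px = step_mean_px,
                 step_dispersion = step_dispersion,
                 heading_persistence = heading_persistence,
                 mode = mode, mode_switch_h = as.numeric(mode_switch_h)),
            class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat(sprintf(
    "Two-state larva: %.3g bouts/h, gamma(%.3g) mean %.3g s; steps lognormal mean %.3g px (sdlog %.3g), persistence %.2f\n",
    x$bout_rate_per_h, x$bout_duration_shape, x$bout_duration_mean_s,
    x$step_mean_px, x$step_dispersion, x$heading_persistence))
  cat(sprintf("mode: %s%s\n", x$mode,
              if (is.na(x$mode_switch_h)) "" else
                sprintf(" (switches at %.3g h)", x$mode_switch_h)))
  invisible(x)
}

#' Default behavioural regimes for mock- and virus-infected larvae
#'
#' `mock_params()` is the healthy control regime: modest speed, short bouts,
#' food-centred locomotion throughout. `infected_params()` encodes the
#' infection phenotype: doubled step length and doubled bout duration at an
#' unchanged bout rate, with a switch from food-centred to edge-following
#' locomotion 9 h into the recording (the late-stage dysregulation of the
#' spatial pattern).
#'
#' @param ... Overrides forwarded to [behavior_params()].
#' @return A `behavior_params` object.
#' @export
mock_params <- function(...) {
  args <- utils::modifyList(
    list(bout_rate_per_h = 2, bout_duration_shape = 2,
         bout_duration_mean_s = 120, step_mean_px = 2,
         step_dispersion = 0.5, heading_persistence = 0.7,
         mode = "food_centered", mode_switch_h = NA_real_),
    list(...))
  do.call(behavior_params, args)
}

#' @rdname mock_params
#' @export
infected_params <- function(...) {
  args <- utils::modifyList(
    list(bout_rate_per_h = 2, bout_duration_shape = 2,
         bout_duration_mean_s = 240, step_mean_px = 4,
         step_dispersion = 0.5, heading_persistence = 0.7,
         mode = "food_centered", mode_switch_h = 9),
    list(...))
  do.call(behavior_params, args)
}

#' Rendering parameters for synthetic frames
#'
#' Controls how a ground-truth trajectory is rasterized into 8-bit greyscale
#' frames. The larva is an anti-aliased ellipse oriented along its heading,
#' brighter than the background by default (the dish bottom is lined with
#' black paper in the assay, so the pale larva is the bright object).
#'
#' @param larva_axis_px Numeric `(major, minor)` half-axes of the larva
#'   ellipse in pixels.
#' @param larva_intensity,background_intensity,food_intensity Grey levels in
#'   `[0, 255]`.
#' @param noise_sd Standard deviation of per-pixel Gaussian noise.
#' @param dropout_prob Probability that a frame omits the larva entirely
#'   (exercises downstream gap filling).
#' @param clutter_prob Probability that a frame contains a spurious second
#'   blob (exercises multi-detection averaging).
#' @return An object of class `render_params`.
#' @export
render_params <- function(larva_axis_px = c(6, 3),
                          larva_intensity = 140,
                          background_intensity = 30,
                          food_intensity = 90,
                          noise_sd = 2,
                          dropout_prob = 0,
                          clutter_prob = 0) {
  stop_unless(length(larva_axis_px) == 2 && all(larva_axis_px > 0),
              "larva_axis_px must be two positive half-axes")
  ints <- c(larva_intensity, background_intensity, food_intensity)
  stop_unless(all(is.finite(ints)) && all(ints >= 0) && all(ints <= 255),
              "intensities must lie in [0, 255]")
  stop_unless(is.finite(noise_sd) && noise_sd >= 0,
              "noise_sd must be non-negative")
  probs <- c(dropout_prob, clutter_prob)
  stop_unless(all(probs >= 0) && all(probs <= 1),
              "probabilities must lie in [0, 1]")
  structure(list(larva_axis_px = as.numeric(larva_axis_px),
                 larva_intensity = as.numeric(larva_intensity),
                 background_intensity = as.numeric(background_intensity),
                 food_intensity = as.numeric(food_intensity),
                 noise_sd = as.numeric(noise_sd),
                 dropout_prob = as.numeric(dropout_prob),
                 clutter_prob = as.numeric(clutter_prob)),
            class = "render_params")
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
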