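#' Construct a frame stack
#'
#' @param frames List of equal-sized integer matrices with grey levels in
#'   `[0, 255]`; matrix rows are image rows (y), columns are x.
#' @param frame_interval_s Nominal inter-frame interval in seconds.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval_s = 3) {
  stop_unless(is.list(frames) && length(frames) >= 1,
              "frames must be a non-empty list of matrices")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  stop_unless(all(ok), "all frames must be matrices of identical dimensions")
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  stop_unless(rng[1] >= 0 && rng[2] <= 255, "grey levels must lie in [0, 255]")
  stop_unless(is.finite(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be positive")
  structure(list(frames = frames,
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %d x %d px, %.3g s/frame\n",
              length(x$frames), d[2], d[1], x$frame_interval_s))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Render a simulated trajectory into greyscale frames
#'
#' Rasterizes each ground-truth position as an anti-aliased ellipse oriented
#' along the current heading, over a uniform background with a static diet
#' blob, then adds per-pixel Gaussian noise, rounds and clamps to 8-bit grey
#' levels. Per-frame dropout (larva omitted) and clutter (a spurious second
#' blob at a random in-dish location) are drawn from seeded Bernoulli trials
#' so downstream gap filling and multi-detection averaging can be exercised.
#'
#' A warning is issued when the larva/background contrast does not exceed
#' twice the noise standard deviation, since the larva is then effectively
#' invisible to thresholding.
#'
#' @param truth A `larva_truth` from [simulate_trajectory()].
#' @param arena The [arena_spec()] the truth was generated under.
#' @param rp A [render_params()].
#' @param seed Integer seed for noise, dropout and clutter.
#' @return A `frame_stack` with attributes `truth_table` (data frame
#'   `frame,time_s,x,y,state,bout_index`, the interval columns describing the
#'   interval ending at each frame) and `dropout` (logical per frame).
#' @export
render_frames <- function(truth, arena, rp = render_params(), seed = 1) {
  stop_unless(inherits(truth, "larva_truth"), "truth must be a larva_truth")
  stop_unless(inherits(rp, "render_params"), "rp must be render_params")
  pos <- truth$positions
  stop_unless(all(pos$x >= 1) && all(pos$x <= arena$width_px) &&
              all(pos$y >= 1) && all(pos$y <= arena$height_px),
              "truth positions must lie inside the arena frame")
  if (abs(rp$larva_intensity - rp$background_intensity) <= 2 * rp$noise_sd)
    warning("larva/background contrast <= 2 * noise_sd: larva may be undetectable",
            call. = FALSE)

  h <- arena$height_px
  w <- arena$width_px
  base <- matrix(rp$background_intensity, h, w)
  base <- draw_disc(base, arena$food_center, arena$food_radius_px,
                    rp$food_intensity)

  # heading per frame from consecutive displacements (carried while still)
  dx <- diff(pos$x)
  dy <- diff(pos$y)
  ang <- atan2(dy, dx)
  still <- sqrt(dx^2 + dy^2) < 1e-6
  ang[still] <- NA
  ang <- c(ang[1], ang)               # frame i uses the incoming heading
  last <- 0
  for (i in seq_along(ang)) {
    if (is.na(ang[i])) ang[i] <- last else last <- ang[i]
  }

  n <- nrow(pos)
  frames <- vector("list", n)
  with_seed(seed, {
    drop_frame <- stats::runif(n) < rp$dropout_prob
    clutter_frame <- stats::runif(n) < rp$clutter_prob
    for (i in seq_len(n)) {
      f <- base
      if (!drop_frame[i])
        f <- draw_ellipse(f, c(pos$x[i], pos$y[i]), rp$larva_axis_px, ang[i],
                          rp$larva_intensity)
      if (clutter_frame[i]) {
        rr <- (arena$dish_radius_px - 10) * sqrt(stats::runif(1))
        aa <- stats::runif(1, 0, 2 * pi)
        f <- draw_disc(f, arena$dish_center + rr * c(cos(aa), sin(aa)),
                       4, rp$larva_intensity)
      }
      if (rp$noise_sd > 0)
        f <- f + matrix(stats::rnorm(h * w, 0, rp$noise_sd), h, w)
      frames[[i]] <- matrix(as.integer(pmin(255, pmax(0, round(f)))), h, w)
    }
    drop_frame
  }) -> drop_frame

  stk <- frame_stack(frames, arena$frame_interval_s)
  attr(stk, "truth_table") <- truth_table(truth)
  attr(stk, "dropout") <- drop_frame
  stk
}

# Paint an anti-aliased filled ellipse (half-axes `axes`, rotated by `theta`)
# onto matrix m; alpha falls off linearly over ~1 px at the boundary.
draw_ellipse <- function(m, center, axes, theta, intensity) {
  a <- axes[1]
  b <- axes[2]
  h <- nrow(m)
  w <- ncol(m)
  r <- max(a, b) + 1
  xs <- max(1L, floor(center[1] - r)):min(w, ceiling(center[1] + r))
  ys <- max(1L, floor(center[2] - r)):min(h, ceiling(center[2] + r))
  if (!length(xs) || !length(ys)) return(m)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - center[1]
  gy <- matrix(ys, length(ys), length(xs)) - center[2]
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  q <- sqrt((u / a)^2 + (v / b)^2)
  alpha <- pmin(1, pmax(0, 0.5 - (q - 1) * min(a, b)))
  m[ys, xs] <- m[ys, xs] * (1 - alpha) + intensity * alpha
  m
}

draw_disc <- function(m, center, radius, intensity) {
  if (radius <= 0) return(m)
  h <- nrow(m)
  w <- ncol(m)
  xs <- max(1L, floor(center[1] - radius - 1)):min(w, ceiling(center[1] + radius + 1))
  ys <- max(1L, floor(center[2] - radius - 1)):min(h, ceiling(center[2] + radius + 1))
  if (!length(xs) || !length(ys)) return(m)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - center[1]
  gy <- matrix(ys, length(ys), length(xs)) - center[2]
  d <- sqrt(gx^2 + gy^2)
  alpha <- pmin(1, pmax(0, radius + 0.5 - d))
  m[ys, xs] <- m[ys, xs] * (1 - alpha) + intensity * alpha
  m
}

#' Ground-truth table of a simulated trajectory
#'
#' One row per frame with the interval labels attached to the frame that
#' ends the interval (frame 0 has no incoming interval).
#'
#' @param truth A `larva_truth`.
#' @return Data frame `frame,time_s,x,y,state,bout_index`.
#' @export
truth_table <- function(truth) {
  stop_unless(inherits(truth, "larva_truth"), "need a larva_truth")
  pos <- truth$positions
  data.frame(pos,
             state = c(NA_character_, truth$intervals$state),
             bout_index = c(NA_integer_, truth$intervals$bout_index))
}
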