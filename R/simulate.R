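#' Simulate a ground-truthed larval trajectory
#'
#' Generates a per-frame position series from the two-state (semi-Markov)
#' behavioural model described in [behavior_params()]: stationary phases with
#' sub-threshold centroid jitter alternate with movement bouts in which the
#' larva performs a correlated random walk confined to the dish. Every
#' inter-frame interval is labelled `"moving"` or `"stationary"` and moving
#' intervals carry the index of the bout they belong to, so downstream
#' tracking, classification and bout segmentation can all be checked against
#' ground truth.
#'
#' The walk is confined to a circle 1 px inside the dish wall. In
#' food-centred mode a step crossing the wall is specularly reflected; in
#' edge-following mode it is projected back onto the wall circle and the
#' heading is rotated to the tangent, which produces wall-hugging paths.
#'
#' @param arena An [arena_spec()].
#' @param params A [behavior_params()].
#' @param duration_h Recording duration in hours (> 0). 24 h at the default
#'   3 s interval gives 28 801 frames / 28 800 intervals.
#' @param seed Integer seed; fixes all randomness, so identical arguments
#'   reproduce bit-identical output.
#' @return An object of class `larva_truth`: a list with `positions`
#'   (data frame `frame` (0-based), `time_s`, `x`, `y`), `intervals`
#'   (data frame `interval` (1-based, interval i joins frames i-1 and i),
#'   `state`, `bout_index`), and the generating `arena`, `params`,
#'   `duration_h`, `seed`.
#' @examples
#' truth <- simulate_trajectory(arena_spec(), mock_params(), duration_h = 0.5,
#'                              seed = 1)
#' truth
#' table(truth$intervals$state)
#' @export
simulate_trajectory <- function(arena, params, duration_h, seed) {
  stop_unless(inherits(arena, "arena_spec"), "arena must be an arena_spec")
  stop_unless(inherits(params, "behavior_params"),
              "params must be a behavior_params")
  stop_unless(is.finite(duration_h) && duration_h > 0,
              "duration_h must be strictly positive")
  dt <- arena$frame_interval_s
  n_int <- as.integer(round(duration_h * 3600 / dt))
  stop_unless(n_int >= 1, "duration must cover at least one frame interval")

  with_seed(seed, {
    sched <- phase_schedule(params, n_int, dt)
    walk_phases(arena, params, sched, n_int, dt)
  }) -> res

  res$arena <- arena
  res$params <- params
  res$duration_h <- duration_h
  res$seed <- seed
  class(res) <- "larva_truth"
  res
}

# Alternating stationary/moving phase lengths (in intervals) covering n_int.
# Stationary durations are exponential with rate bout_rate_per_h; bout
# durations gamma(shape, mean). Records start in a stationary phase.
phase_schedule <- function(params, n_int, dt) {
  state <- character(0)
  len <- integer(0)
  tot <- 0L
  cur <- "stationary"
  repeat {
    if (cur == "stationary") {
      if (params$bout_rate_per_h <= 0) {
        d_int <- n_int - tot
        if (d_int < 1L) d_int <- 1L
      } else {
        d_s <- stats::rexp(1, rate = params$bout_rate_per_h / 3600)
        d_int <- max(1L, as.integer(round(d_s / dt)))
      }
    } else {
      d_s <- stats::rgamma(1, shape = params$bout_duration_shape,
                           scale = params$bout_duration_mean_s /
                             params$bout_duration_shape)
      d_int <- max(1L, as.integer(round(d_s / dt)))
    }
    d_int <- min(d_int, n_int - tot)
    if (d_int > 0L) {
      state <- c(state, cur)
      len <- c(len, d_int)
      tot <- tot + d_int
    }
    if (tot >= n_int) break
    cur <- if (cur == "stationary") "moving" else "stationary"
  }
  list(state = state, len = len)
}

walk_phases <- function(arena, params, sched, n_int, dt) {
  r_eff <- arena$dish_radius_px - 1   # confinement circle, 1 px off the wall
  cx <- arena$dish_center[1]
  cy <- arena$dish_center[2]
  turn_sd <- pi * (1 - params$heading_persistence)
  sdlog <- params$step_dispersion
  meanlog <- log(params$step_mean_px) - sdlog^2 / 2
  switch_int <- if (is.na(params$mode_switch_h)) Inf else
    params$mode_switch_h * 3600 / dt
  other_mode <- if (params$mode == "food_centered") "edge_following" else
    "food_centered"

  x <- numeric(n_int + 1)
  y <- numeric(n_int + 1)
  state <- character(n_int)
  bout_index <- rep(NA_integer_, n_int)

  # start near the diet blob (larvae are placed on/next to the food)
  r0 <- max(arena$food_radius_px, 5) * sqrt(stats::runif(1))
  a0 <- stats::runif(1, 0, 2 * pi)
  x[1] <- arena$food_center[1] + r0 * cos(a0)
  y[1] <- arena$food_center[2] + r0 * sin(a0)
  heading <- stats::runif(1, -pi, pi)
  rot_dir <- sample(c(-1, 1), 1)     # persistent wall-following direction

  pos <- c(x[1], y[1])
  i <- 1L      # next interval to fill
  bout <- 0L
  for (ph in seq_along(sched$state)) {
    L <- sched$len[ph]
    idx <- i:(i + L - 1L)
    if (sched$state[ph] == "stationary") {
      # uniform jitter in a 0.15 px disc about the anchor: net step <= 0.3 px
      rr <- 0.15 * sqrt(stats::runif(L))
      aa <- stats::runif(L, 0, 2 * pi)
      x[idx + 1L] <- pos[1] + rr * cos(aa)
      y[idx + 1L] <- pos[2] + rr * sin(aa)
      state[idx] <- "stationary"
      pos <- c(x[i + L], y[i + L])
    } else {
      bout <- bout + 1L
      turns <- stats::rnorm(L, 0, turn_sd)
      steps <- stats::rlnorm(L, meanlog, sdlog)
      for (k in seq_len(L)) {
        j <- idx[k]
        mode <- if (j - 1L >= switch_int) other_mode else params$mode
        heading <- heading + turns[k]
        # spatial drift: blend the heading toward a target direction
        if (mode == "food_centered") {
          vfx <- arena$food_center[1] - pos[1]
          vfy <- arena$food_center[2] - pos[2]
          if (sqrt(vfx^2 + vfy^2) > arena$food_radius_px)
            heading <- blend_heading(heading, atan2(vfy, vfx), 0.25)
        } else {
          rx <- pos[1] - cx
          ry <- pos[2] - cy
          rad <- sqrt(rx^2 + ry^2)
          out_ang <- atan2(ry, rx)
          if (rad < 0.85 * r_eff) {
            heading <- blend_heading(heading, out_ang, 0.3)
          } else {
            heading <- blend_heading(heading, out_ang + rot_dir * pi / 2, 0.5)
          }
        }
        px <- pos[1] + steps[k] * cos(heading)
        py <- pos[2] + steps[k] * sin(heading)
        dx <- px - cx
        dy <- py - cy
        d <- sqrt(dx^2 + dy^2)
        if (d > r_eff) {
          if (mode == "food_centered") {
            # specular (radial mirror) reflection off the wall circle
            scl <- (2 * r_eff - d) / d
            px <- cx + dx * scl
            py <- cy + dy * scl
            heading <- atan2(py - pos[2], px - pos[1])
          } else {
            # slide along the wall: project onto the circle, go tangential
            px <- cx + dx * r_eff / d
            py <- cy + dy * r_eff / d
            heading <- atan2(dy, dx) + rot_dir * pi / 2
          }
        }
        pos <- c(px, py)
        x[j + 1L] <- px
        y[j + 1L] <- py
      }
      state[idx] <- "moving"
      bout_index[idx] <- bout
    }
    i <- i + L
  }

  list(positions = data.frame(frame = 0:n_int,
                              time_s = (0:n_int) * dt,
                              x = x, y = y),
       intervals = data.frame(interval = seq_len(n_int),
                              state = state,
                              bout_index = bout_index))
}

# circular blend of two angles by weight w on the target
blend_heading <- function(h, target, w) {
  vx <- (1 - w) * cos(h) + w * cos(target)
  vy <- (1 - w) * sin(h) + w * sin(target)
  atan2(vy, vx)
}

#' @export
print.larva_truth <- function(x, ...) {
  n_int <- nrow(x$intervals)
  cat(sprintf("Simulated larva: %d frames (%.3g h at %.3g s/frame), seed %d\n",
              nrow(x$positions), x$duration_h, x$arena$frame_interval_s,
              x$seed))
  nb <- length(unique(stats::na.omit(x$intervals$bout_index)))
  cat(sprintf("  %d moving / %d stationary intervals in %d bouts\n",
              sum(x$intervals$state == "moving"),
              sum(x$intervals$state == "stationary"), nb))
  invisible(x)
}

#' Per-interval displacements of a simulated trajectory
#'
#' @param truth A `larva_truth` object.
#' @return Numeric vector of Euclidean inter-frame distances (px), length
#'   one less than the number of frames.
#' @export
truth_steps <- function(truth) {
  stop_unless(inherits(truth, "larva_truth"), "need a larva_truth")
  with(truth$positions, sqrt(diff(x)^2 + diff(y)^2))
}

#' Simulate a labelled two-group cohort
#'
#' Produces `n_per_group` mock and `n_per_group` infected trajectories under
#' a common arena, with per-larva seeds derived deterministically from the
#' master seed (see [child_seed()]), so cohorts of any size are reproducible
#' and per-larva streams are disjoint.
#'
#' @param arena An [arena_spec()].
#' @param mock,infected [behavior_params()] for the two groups.
#' @param n_per_group Larvae per group (>= 1).
#' @param seed Master integer seed.
#' @param duration_h Recording duration per larva in hours (default 24).
#' @return An object of class `larva_cohort`: a list of entries with
#'   `larva_id`, `group` (`"mock"`/`"infected"`), `seed` and `truth`.
#' @examples
#' coh <- make_cohort(arena_spec(), mock_params(), infected_params(),
#'                    n_per_group = 2, seed = 7, duration_h = 0.25)
#' sapply(coh, function(l) l$group)
#' @export
make_cohort <- function(arena, mock, infected, n_per_group, seed,
                        duration_h = 24) {
  stop_unless(is.finite(n_per_group) && n_per_group >= 1,
              "n_per_group must be >= 1")
  n_per_group <- as.integer(n_per_group)
  groups <- rep(c("mock", "infected"), each = n_per_group)
  params <- list(mock = mock, infected = infected)
  coh <- vector("list", 2L * n_per_group)
  for (i in seq_along(coh)) {
    s <- child_seed(seed, i)
    coh[[i]] <- list(
      larva_id = sprintf("%s_%02d", groups[i],
                         ((i - 1L) %% n_per_group) + 1L),
      group = groups[i], seed = s,
      truth = simulate_trajectory(arena, params[[groups[i]]], duration_h, s))
  }
  structure(coh, class = "larva_cohort", master_seed = seed)
}

#' Derive a per-larva seed from a master seed
#'
#' Splittable counter scheme: child i is `(master + 1000003 * i) mod
#' (2^31 - 1)`, giving disjoint, reproducible streams for any cohort size.
#'
#' @param master Master integer seed.
#' @param i Child index (1-based).
#' @return An integer seed.
#' @export
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' @export
print.larva_cohort <- function(x, ...) {
  g <- table(vapply(x, function(l) l$group, ""))
  cat(sprintf("Cohort of %d larvae (%s), master seed %d\n", length(x),
              paste(sprintf("%s n=%d", names(g), g), collapse = ", "),
              attr(x, "master_seed")))
  invisible(x)
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}
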