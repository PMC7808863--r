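#' Remove detections outside the dish
#'
#' Detections farther than `dish_radius_px + tolerance_px` from the dish
#' centre are physically impossible larval positions (reflections, rim
#' artefacts) and are dropped. The tolerance absorbs centroid jitter at the
#' wall.
#'
#' @param detections Data frame with columns `frame`, `x`, `y` (e.g. from
#'   [track_stack()]).
#' @param arena An [arena_spec()].
#' @param tolerance_px Allowed overshoot beyond the dish radius (default 2).
#' @return The detections data frame without out-of-dish rows; the number
#'   removed is in attribute `n_removed`.
#' @export
filter_out_of_arena <- function(detections, arena, tolerance_px = 2) {
  stop_unless(all(c("frame", "x", "y") %in% names(detections)),
              "detections need frame, x, y columns")
  d <- sqrt((detections$x - arena$dish_center[1])^2 +
            (detections$y - arena$dish_center[2])^2)
  keep <- d <= arena$dish_radius_px + tolerance_px
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Consolidate multiple detections per frame
#'
#' When binarization splits the larva into several particles, a single frame
#' carries several detections; the larval position is taken as the
#' unweighted average of their coordinates. Frames with one detection pass
#' through; frames with none emit nothing (they are handled by
#' [fill_missing()]).
#'
#' @param detections Data frame with `frame`, `x`, `y`.
#' @return Data frame `frame,x,y,n_points` with at most one row per frame,
#'   ordered by frame.
#' @export
consolidate <- function(detections) {
  stop_unless(all(c("frame", "x", "y") %in% names(detections)),
              "detections need frame, x, y columns")
  if (!nrow(detections))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      n_points = integer(0)))
  f <- factor(detections$frame)
  out <- data.frame(frame = as.integer(levels(f)),
                    x = as.numeric(tapply(detections$x, f, mean)),
                    y = as.numeric(tapply(detections$y, f, mean)),
                    n_points = as.integer(table(f)))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fill missing frames by carry-forward
#'
#' Frames without a detected position take the position of the most recent
#' earlier frame. Frames before the first detection are back-filled from it
#' (the alternative, dropping them, would break the fixed frame grid that
#' the 30 s windowing relies on). Provenance records how each frame's
#' position was obtained.
#'
#' @param points Data frame `frame,x,y` (0-based frames) with optional
#'   `n_points` column from [consolidate()]; at most one row per frame.
#' @param n_frames Total number of frames in the record.
#' @return An object of class `clean_trajectory`: data frame
#'   `frame,x,y,provenance` with exactly one row per frame, provenance one
#'   of `detected`, `averaged`, `carried_forward`, `back_filled`.
#' @export
fill_missing <- function(points, n_frames) {
  stop_unless(all(c("frame", "x", "y") %in% names(points)),
              "points need frame, x, y columns")
  stop_unless(nrow(points) > 0,
              "no detections in any frame: cannot reconstruct a trajectory")
  stop_unless(!anyDuplicated(points$frame), "at most one point per frame")
  stop_unless(n_frames >= max(points$frame) + 1,
              "n_frames smaller than the largest detected frame index")
  x <- rep(NA_real_, n_frames)
  y <- rep(NA_real_, n_frames)
  prov <- rep(NA_character_, n_frames)
  i <- points$frame + 1L
  x[i] <- points$x
  y[i] <- points$y
  prov[i] <- if ("n_points" %in% names(points))
    ifelse(points$n_points > 1, "averaged", "detected") else "detected"
  first <- min(i)
  if (first > 1L) {
    lead <- seq_len(first - 1L)
    x[lead] <- x[first]
    y[lead] <- y[first]
    prov[lead] <- "back_filled"
  }
  for (k in seq(first + 1L, length.out = max(0L, n_frames - first))) {
    if (is.na(x[k])) {
      x[k] <- x[k - 1L]
      y[k] <- y[k - 1L]
      prov[k] <- "carried_forward"
    }
  }
  structure(data.frame(frame = 0:(n_frames - 1L), x = x, y = y,
                       provenance = prov),
            class = c("clean_trajectory", "data.frame"))
}

#' Per-interval step distances
#'
#' Euclidean travel distance in pixels between each pair of adjacent frames.
#' A carried-forward frame yields a zero-length interval; the following
#' interval absorbs the accumulated displacement.
#'
#' @param traj A `clean_trajectory` or any data frame with `x`, `y` ordered
#'   by frame.
#' @return Numeric vector of length `nrow(traj) - 1`.
#' @export
step_distances <- function(traj) {
  stop_unless(nrow(traj) >= 2, "need at least two frames")
  sqrt(diff(traj$x)^2 + diff(traj$y)^2)
}

#' Clean raw detections into one position per frame
#'
#' Applies the full quality-control chain: out-of-dish filtering,
#' multi-detection averaging, and carry-forward gap filling.
#'
#' @inheritParams filter_out_of_arena
#' @param n_frames Total frames in the recording; defaults to
#'   `max(detections$frame) + 1`.
#' @return A `clean_trajectory` (see [fill_missing()]); frames whose only
#'   detections were removed by the arena filter get provenance
#'   `removed_then_filled`.
#' @export
clean_detections <- function(detections, arena, tolerance_px = 2,
                             n_frames = NULL) {
  if (is.null(n_frames)) {
    stop_unless(nrow(detections) > 0, "no detections and no n_frames given")
    n_frames <- max(detections$frame) + 1L
  }
  had_rows <- unique(detections$frame)
  kept <- filter_out_of_arena(detections, arena, tolerance_px)
  pts <- consolidate(kept)
  traj <- fill_missing(pts, n_frames)
  removed_frames <- setdiff(had_rows, pts$frame)
  sel <- traj$frame %in% removed_frames
  traj$provenance[sel] <- "removed_then_filled"
  traj
}

#' @export
print.clean_trajectory <- function(x, ...) {
  cat(sprintf("Clean trajectory: %d frames\n", nrow(x)))
  print(table(x$provenance))
  invisible(x)
}

#' Flag a larva for exclusion on tracking quality
#'
#' Background modelling fails for nearly immobile larvae (their body is
#' averaged into the background), producing long undetected stretches. A
#' larva is flagged when the fraction of frames without a genuine detection
#' (provenance not `detected`/`averaged`) exceeds `max_missing_frac`. This
#' operationalizes, as a reproducible rule, the manual practice of dropping
#' animals whose plotted positions fail visual inspection.
#'
#' @param traj A `clean_trajectory`.
#' @param max_missing_frac Maximum tolerated missing-frame fraction
#'   (default 0.2).
#' @return Logical: `TRUE` if the larva should be excluded, with the
#'   missing fraction in attribute `missing_frac`.
#' @export
qc_exclusion_flag <- function(traj, max_missing_frac = 0.2) {
  miss <- mean(!traj$provenance %in% c("detected", "averaged"))
  structure(miss > max_missing_frac, missing_frac = miss)
}
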