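#' Score intervals as movement or stationary behaviour
#'
#' An inter-frame interval counts as movement when its displacement strictly
#' exceeds `threshold_px` (default 0.5 px per 3 s interval); a displacement
#' of exactly the threshold is stationary.
#'
#' @param steps Numeric vector of per-interval distances (px), e.g. from
#'   [step_distances()].
#' @param threshold_px Movement threshold in pixels (> 0).
#' @return Logical vector, `TRUE` for moving intervals.
#' @export
score_movement <- function(steps, threshold_px = 0.5) {
  stop_unless(length(steps) >= 1, "empty step series")
  stop_unless(is.finite(threshold_px) && threshold_px > 0,
              "threshold_px must be positive")
  steps > threshold_px
}

#' Mean step distance per fixed window
#'
#' Partitions the interval series into consecutive non-overlapping windows
#' of `window_len` intervals anchored at the first interval (10 intervals =
#' 30 s at 3 s resolution) and averages the distances within each. A
#' trailing partial window is averaged over its actual members and flagged,
#' so no part of the record is discarded.
#'
#' @param steps Numeric vector of per-interval distances.
#' @param window_len Window length in intervals (>= 1, default 10).
#' @return Data frame `window` (0-based), `mean_step`, `n_intervals`,
#'   `partial`.
#' @export
window_means <- function(steps, window_len = 10) {
  stop_unless(length(steps) >= 1, "empty step series")
  stop_unless(window_len >= 1, "window_len must be >= 1")
  window_len <- as.integer(window_len)
  w <- (seq_along(steps) - 1L) %/% window_len
  f <- factor(w, levels = 0:max(w))
  n <- as.integer(table(f))
  data.frame(window = 0:max(w),
             mean_step = as.numeric(tapply(steps, f, mean)),
             n_intervals = n,
             partial = n < window_len)
}

#' Segment continuous locomotion bouts
#'
#' A window qualifies as "kept moving" when its mean per-interval distance
#' strictly exceeds `threshold_px`; a maximal run of consecutive qualifying
#' windows is one continuous locomotion event (bout).
#'
#' @param windows Data frame from [window_means()], or a numeric vector of
#'   window means.
#' @param threshold_px Qualification threshold, same 0.5 px default as
#'   [score_movement()].
#' @return Data frame `bout` (1-based), `start_window` (0-based),
#'   `n_windows`; zero rows when no window qualifies.
#' @export
segment_bouts <- function(windows, threshold_px = 0.5) {
  m <- if (is.data.frame(windows)) windows$mean_step else as.numeric(windows)
  q <- m > threshold_px
  if (!length(q) || !any(q))
    return(data.frame(bout = integer(0), start_window = integer(0),
                      n_windows = integer(0)))
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(bout = seq_along(sel),
             start_window = starts[sel] - 1L,
             n_windows = r$lengths[sel])
}

#' Summary locomotion metrics for one larva
#'
#' The four per-larva outcome measures of the assay:
#' \describe{
#'   \item{total_distance_px}{sum of all inter-frame distances over the
#'     record;}
#'   \item{median_speed_px_per_interval}{median displacement over moving
#'     intervals only (`NA` when the larva never moves);}
#'   \item{median_bout_duration_windows}{median number of 30 s windows per
#'     continuous locomotion event (`NA` when there are no bouts);}
#'   \item{bout_count}{number of continuous locomotion events.}
#' }
#'
#' @param steps Per-interval distances.
#' @param flags Logical movement flags from [score_movement()].
#' @param bouts Bout table from [segment_bouts()].
#' @param larva_id,group,experiment Labels carried into the record.
#' @return One-row data frame (a `MetricsRecord`).
#' @export
summarize_locomotion <- function(steps, flags, bouts,
                                 larva_id = NA_character_,
                                 group = NA_character_,
                                 experiment = NA_character_) {
  stop_unless(length(steps) == length(flags),
              "steps and flags lengths differ")
  data.frame(larva_id = larva_id, group = group, experiment = experiment,
             total_distance_px = sum(steps),
             median_speed_px_per_interval =
               if (any(flags)) stats::median(steps[flags]) else NA_real_,
             median_bout_duration_windows =
               if (nrow(bouts)) stats::median(bouts$n_windows) else NA_real_,
             bout_count = nrow(bouts))
}

#' Full locomotion quantification of one trajectory
#'
#' Convenience wrapper chaining [step_distances()], [score_movement()],
#' [window_means()], [segment_bouts()] and [summarize_locomotion()].
#'
#' @param traj A `clean_trajectory`, a `larva_truth`, or a data frame with
#'   `x`, `y` ordered by frame.
#' @param interval_s Inter-frame interval in seconds (default 3).
#' @param window_s Window length in seconds (default 30).
#' @param threshold_px Movement threshold (default 0.5).
#' @param larva_id,group,experiment Labels for the output record.
#' @return One-row metrics data frame with the per-larva bout table in
#'   attribute `bouts`. Speed is reported in px per interval (the native
#'   resolution of the recording); `median_speed_px_per_s` adds the px/s
#'   equivalent.
#' @export
locomotion_metrics <- function(traj, interval_s = 3, window_s = 30,
                               threshold_px = 0.5,
                               larva_id = NA_character_,
                               group = NA_character_,
                               experiment = NA_character_) {
  if (inherits(traj, "larva_truth")) {
    interval_s <- traj$arena$frame_interval_s
    traj <- traj$positions
  }
  steps <- step_distances(traj)
  flags <- score_movement(steps, threshold_px)
  wins <- window_means(steps, max(1L, as.integer(round(window_s / interval_s))))
  bouts <- segment_bouts(wins, threshold_px)
  rec <- summarize_locomotion(steps, flags, bouts, larva_id, group, experiment)
  rec$median_speed_px_per_s <- rec$median_speed_px_per_interval / interval_s
  attr(rec, "bouts") <- bouts
  rec
}

#' Locomotion metrics for a whole cohort
#'
#' @param cohort A `larva_cohort` from [make_cohort()], or a list of entries
#'   with `truth`, `larva_id`, `group` fields.
#' @param experiment Experiment label applied to all rows.
#' @param ... Passed to [locomotion_metrics()].
#' @return Metrics data frame, one row per larva.
#' @export
cohort_metrics <- function(cohort, experiment = "1", ...) {
  do.call(rbind, lapply(cohort, function(l)
    locomotion_metrics(l$truth, larva_id = l$larva_id, group = l$group,
                       experiment = experiment, ...)))
}
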