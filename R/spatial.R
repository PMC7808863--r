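#' Split a trajectory into equal time segments
#'
#' Partitions the frame axis into `n_segments` contiguous equal blocks (a
#' 24 h record into eight 3 h segments by default); when the frame count is
#' not divisible the remainder goes to the last segment.
#'
#' @param traj Data frame with one row per frame (`x`, `y`, optionally
#'   `frame`).
#' @param n_segments Number of segments (default 8).
#' @return The trajectory data frame with an added integer `segment` column
#'   (1-based).
#' @export
segment_time <- function(traj, n_segments = 8) {
  n <- nrow(traj)
  stop_unless(n_segments >= 1, "n_segments must be >= 1")
  stop_unless(n_segments <= n, "more segments than frames")
  size <- n %/% n_segments
  seg <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_segments)
  out <- traj
  out$segment <- as.integer(seg)
  out
}

#' Spatial occupancy summary of a position set
#'
#' Quantifies where the larva spent its time, as proxies for the qualitative
#' contrast between food-centred and edge-following occupancy:
#' `median_radial_fraction` is the median distance from the dish centre in
#' units of the dish radius; `food_fraction` the fraction of positions
#' within `food_radius + food_margin_px` of the food centre; and
#' `edge_fraction` the fraction with radial fraction above `edge_cutoff`.
#'
#' @param positions Data frame with `x`, `y` (non-empty).
#' @param arena An [arena_spec()].
#' @param edge_cutoff Radial fraction above which a position counts as "at
#'   the edge" (default 0.8).
#' @param food_margin_px Margin added to the food radius (default 10).
#' @return One-row data frame `median_radial_fraction,food_fraction,
#'   edge_fraction,n_positions`.
#' @export
occupancy <- function(positions, arena, edge_cutoff = 0.8,
                      food_margin_px = 10) {
  stop_unless(nrow(positions) > 0, "empty position set")
  r <- sqrt((positions$x - arena$dish_center[1])^2 +
            (positions$y - arena$dish_center[2])^2) / arena$dish_radius_px
  df <- sqrt((positions$x - arena$food_center[1])^2 +
             (positions$y - arena$food_center[2])^2)
  data.frame(median_radial_fraction = stats::median(r),
             food_fraction = mean(df <= arena$food_radius_px + food_margin_px),
             edge_fraction = mean(r > edge_cutoff),
             n_positions = nrow(positions))
}

#' Per-segment occupancy summaries
#'
#' @param traj Data frame of per-frame positions.
#' @param arena An [arena_spec()].
#' @param n_segments Number of equal time segments (default 8).
#' @param ... Passed to [occupancy()].
#' @return Data frame with one row per segment, `segment` column first.
#' @export
occupancy_by_segment <- function(traj, arena, n_segments = 8, ...) {
  seg <- segment_time(traj, n_segments)
  out <- do.call(rbind, lapply(split(seg, seg$segment), occupancy,
                               arena = arena, ...))
  cbind(data.frame(segment = sort(unique(seg$segment))), out,
        row.names = NULL)
}

#' Plot position distributions, whole-record and per-segment
#'
#' Scatter plots of every per-frame position (the occupancy footprint of
#' the larva), either as a single panel or one panel per time segment, with
#' dish and food outlines. Writes a PNG and a CSV of the plotted points so
#' the figure is verifiable.
#'
#' @param traj Data frame of per-frame positions (`x`, `y`).
#' @param arena An [arena_spec()].
#' @param n_segments 1 for a whole-record panel; 8 reproduces the 3 h
#'   segmentation of a 24 h record.
#' @param out_png,out_csv Output paths; `NULL` skips the file (the plot is
#'   still drawn on the active device when `out_png` is `NULL`).
#' @param col Point colour.
#' @return Invisibly, the plotted data frame (with `segment` column).
#' @export
export_distribution_plot <- function(traj, arena, n_segments = 1,
                                     out_png = NULL, out_csv = NULL,
                                     col = "#00000040") {
  seg <- segment_time(traj, n_segments)
  if (!is.null(out_csv))
    utils::write.csv(seg[, c(intersect("frame", names(seg)), "x", "y",
                             "segment")],
                     out_csv, row.names = FALSE)
  if (!is.null(out_png)) {
    grDevices::png(out_png, width = 280 * min(n_segments, 4),
                   height = 240 * ceiling(n_segments / 4))
    on.exit(grDevices::dev.off())
  }
  nr <- ceiling(n_segments / 4)
  graphics::par(mfrow = c(nr, min(n_segments, 4)), mar = c(1, 1, 2, 1))
  th <- seq(0, 2 * pi, length.out = 200)
  for (s in sort(unique(seg$segment))) {
    p <- seg[seg$segment == s, ]
    graphics::plot(NA, xlim = c(0, arena$width_px),
                   ylim = c(arena$height_px, 0), asp = 1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = if (n_segments > 1) sprintf("segment %d", s) else
                     "24 h distribution")
    graphics::lines(arena$dish_center[1] + arena$dish_radius_px * cos(th),
                    arena$dish_center[2] + arena$dish_radius_px * sin(th))
    if (arena$food_radius_px > 0)
      graphics::lines(arena$food_center[1] + arena$food_radius_px * cos(th),
                      arena$food_center[2] + arena$food_radius_px * sin(th),
                      lty = 2)
    graphics::points(p$x, p$y, pch = 16, cex = 0.3, col = col)
  }
  invisible(seg)
}
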