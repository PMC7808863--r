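#' Convert an RGB frame to greyscale
#'
#' Unweighted channel mean, rounded half-up to the nearest integer grey
#' level. Single-channel input passes through unchanged.
#'
#' @param frame A `height x width` matrix (returned unchanged) or a
#'   `height x width x 3` array of 8-bit values.
#' @return Integer matrix of grey levels.
#' @export
to_greyscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stop_unless(is.array(frame) && length(dim(frame)) == 3 &&
              dim(frame)[3] == 3,
              "frame must have 1 or 3 channels")
  g <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  matrix(as.integer(floor(g + 0.5)), nrow(g), ncol(g))
}

#' Average-intensity background model
#'
#' The background image is the per-pixel arithmetic mean over every frame in
#' the stack. A (mostly) moving larva contributes little to any one pixel's
#' mean, so subtracting the background isolates it; static scene elements
#' (dish, diet blob) cancel. This is also why a larva that never moves
#' defeats the method: its own body becomes part of the background.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @return Real-valued matrix, same dimensions as the frames.
#' @export
build_background <- function(stack) {
  stop_unless(inherits(stack, "frame_stack"), "stack must be a frame_stack")
  stop_unless(length(stack$frames) >= 2, "need at least 2 frames")
  Reduce(`+`, stack$frames) / length(stack$frames)
}

#' Otsu threshold of an 8-bit image
#'
#' Maximizes between-class variance over the 256-bin grey-level histogram.
#' Returns the threshold t such that foreground is `value > t`.
#'
#' @param img Numeric matrix; values are rounded and clamped to 0..255 for
#'   the histogram.
#' @return Integer threshold in 0..254.
#' @export
otsu_threshold <- function(img) {
  v <- pmin(255L, pmax(0L, as.integer(round(img))))
  counts <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * lev)
  total <- sum0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - sum0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv <- bcv[1:255]                    # thresholds 0..254
  which.max(bcv) - 1L
}

#' Background subtraction and binarization
#'
#' Computes the absolute difference `|frame - background|` and thresholds
#' it. Absolute difference makes the pipeline agnostic to whether the larva
#' is lighter or darker than the background. With `method = "otsu"` the
#' threshold is data-driven but floored at `min_fg_level`: on frames with
#' little or no real foreground Otsu latches onto the sensor-noise
#' distribution (thresholds of 1-3 grey levels), and the floor keeps such
#' frames from masking half the image. A frame whose difference image never
#' exceeds the floor therefore yields an empty mask.
#'
#' @param frame Grey-level matrix.
#' @param bg Background matrix from [build_background()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (required when `method = "fixed"`);
#'   foreground is `difference > threshold`.
#' @param min_fg_level Floor on the Otsu threshold (default 10).
#' @return Logical matrix mask.
#' @export
subtract_and_binarize <- function(frame, bg, method = c("otsu", "fixed"),
                                  threshold = NULL, min_fg_level = 10) {
  method <- match.arg(method)
  stop_unless(identical(dim(frame), dim(bg)),
              "frame and background dimensions differ")
  d <- abs(frame - bg)
  if (method == "fixed") {
    stop_unless(is.numeric(threshold) && length(threshold) == 1,
                "fixed method needs a threshold")
    thr <- threshold
  } else {
    thr <- max(otsu_threshold(d), min_fg_level)
  }
  d > thr
}

# 8-connected component labeling by union-find over foreground pixels.
# Returns an integer matrix of labels (0 = background), labels arbitrary
# but distinct per component.
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- which(mask)                    # column-major linear indices
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  parent <- seq_along(fg)

  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }

  row <- ((fg - 1L) %% h) + 1L
  col <- ((fg - 1L) %/% h) + 1L
  # half the 8-neighbourhood (E, SE, S, SW); the rest follows by symmetry
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (o in offs) {
    nr <- row + o[1]
    nc <- col + o[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    if (!any(ok)) next
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    here <- id[fg[ok]]
    there <- id[nidx]
    both <- there > 0L
    a <- here[both]
    b <- there[both]
    for (e in seq_along(a)) {
      ra <- find(a[e])
      rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(fg), find, integer(1))
  lab[fg] <- match(roots, unique(roots))
  lab
}

#' Detect particles in a binary mask
#'
#' Finds 8-connected foreground components of at least `min_area` pixels and
#' reports each component's unweighted centroid (the "centre of mass" of a
#' binarized particle) and area. Output is sorted by area descending; ties
#' break by the component's top-left pixel (first in row-major order).
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component size in pixels (default 10, suppressing
#'   noise speckle).
#' @return Data frame `x,y,area` (possibly 0 rows); `x` is the column and
#'   `y` the row of the centroid, pixel centres at integers.
#' @export
detect_particles <- function(mask, min_area = 10) {
  stop_unless(is.matrix(mask) && is.logical(mask), "mask must be logical")
  lab <- label_components(mask)
  fg <- which(lab > 0L)
  if (!length(fg))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  h <- nrow(mask)
  row <- ((fg - 1L) %% h) + 1L
  col <- ((fg - 1L) %/% h) + 1L
  comp <- lab[fg]
  area <- tabulate(comp)
  compf <- factor(comp, levels = seq_along(area))  # keep numeric order
  cx <- tapply(col, compf, mean)
  cy <- tapply(row, compf, mean)
  # top-left pixel = first member in row-major order, for the tie-break
  rm_order <- (row - 1L) * ncol(mask) + (col - 1L)
  first_rm <- tapply(rm_order, compf, min)
  keep <- which(area >= min_area)
  if (!length(keep))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  ord <- keep[order(-area[keep], first_rm[keep])]
  data.frame(x = as.numeric(cx[ord]), y = as.numeric(cy[ord]),
             area = as.integer(area[ord]), row.names = NULL)
}

#' Track a full frame stack
#'
#' Runs the complete detection pipeline: builds the average-intensity
#' background once, then subtracts, binarizes and detects particles in every
#' frame. Frames may yield zero or several detections; resolving those into
#' one position per frame is the trajectory module's job
#' ([clean_detections()]).
#'
#' @param stack A [frame_stack()].
#' @inheritParams subtract_and_binarize
#' @inheritParams detect_particles
#' @return Data frame `frame` (0-based), `x`, `y`, `area`,
#'   `n_detections_in_frame` (one row per detection; undetected frames have
#'   no rows), with the per-frame detection counts in attribute `counts`.
#' @export
track_stack <- function(stack, method = c("otsu", "fixed"), threshold = NULL,
                        min_area = 10, min_fg_level = 10) {
  method <- match.arg(method)
  bg <- build_background(stack)
  out <- vector("list", length(stack$frames))
  counts <- integer(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    mask <- subtract_and_binarize(stack$frames[[i]], bg, method, threshold,
                                  min_fg_level)
    det <- detect_particles(mask, min_area)
    counts[i] <- nrow(det)
    if (nrow(det))
      out[[i]] <- data.frame(frame = i - 1L, det)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0))
  res$n_detections_in_frame <- counts[res$frame + 1L]
  attr(res, "counts") <- counts
  res
}
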