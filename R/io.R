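#' Write a frame stack to disk
#'
#' Frames are written either as zero-padded numbered 8-bit greyscale PNG
#' files in a directory, or as a single multi-page TIFF (chosen from the
#' `path` extension: a path ending in `.tif`/`.tiff` gets one TIFF,
#' anything else is treated as a directory).
#'
#' @param stack A [frame_stack()].
#' @param path Output directory or `.tiff` path.
#' @return Invisibly, the file path(s) written.
#' @export
write_frames <- function(stack, path) {
  stop_unless(inherits(stack, "frame_stack"), "stack must be a frame_stack")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(lapply(stack$frames, function(f) f / 255), path,
                    bits.per.sample = 8L)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, sprintf("frame_%06d.png",
                                   seq_along(stack$frames) - 1L))
  for (i in seq_along(files))
    png::writePNG(stack$frames[[i]] / 255, files[i])
  invisible(files)
}

#' Read a frame stack from disk
#'
#' Accepts a directory of PNG frames (sorted by file name) or a multi-page
#' TIFF. RGB images are converted to greyscale with [to_greyscale()].
#'
#' @param path Frame directory or `.tiff` path.
#' @param frame_interval_s Nominal inter-frame interval in seconds.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, frame_interval_s = 3) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    stop_unless(length(files) >= 1, paste("no PNG frames in", path))
    frames <- lapply(files, function(f) img_to_grey(png::readPNG(f)))
  } else {
    stop_unless(file.exists(path), paste("no such file:", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(pages, img_to_grey)
  }
  frame_stack(frames, frame_interval_s)
}

# [0,1]-scaled array from png/tiff -> integer grey matrix 0..255
img_to_grey <- function(img) {
  img <- img * 255
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) img <- img[, , 1:3] else img <- img[, , 1]
  }
  to_greyscale(if (length(dim(img)) == 3) img else
    matrix(as.integer(round(img)), nrow(img), ncol(img)))
}

#' Write / read a trajectory or ground-truth CSV
#'
#' Column layout `frame,time_s,x,y,state,bout_index` for ground truth
#' (frames 0-based; interval labels attached to the frame ending the
#' interval) and `frame,x,y,provenance` for clean trajectories; plain
#' `frame,x,y` CSVs are accepted on input.
#'
#' @param x A `larva_truth`, `clean_trajectory`, or data frame.
#' @param path CSV path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a data frame.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- if (inherits(x, "larva_truth")) truth_table(x) else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  stop_unless(all(c("frame", "x", "y") %in% names(df)),
              "trajectory CSV needs frame, x, y columns")
  df
}

#' Read a simulation configuration file
#'
#' A single declarative YAML file holds the arena geometry, one behavioural
#' parameter block per group, rendering parameters and seeds. See
#' `system.file("extdata", "example_config.yaml", package = "larvatrack")`.
#'
#' @param path YAML path.
#' @return List with `arena` ([arena_spec()]), `groups` (named list of
#'   [behavior_params()]), `render` ([render_params()] or `NULL`), `seed`,
#'   and `duration_h`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  arena <- do.call(arena_spec, cfg$arena)
  groups <- lapply(cfg$groups, function(g) do.call(behavior_params, g))
  render <- if (!is.null(cfg$render)) do.call(render_params, cfg$render)
  list(arena = arena, groups = groups, render = render,
       seed = cfg$seed %||% 1L, duration_h = cfg$duration_h %||% 24)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
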