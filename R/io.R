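#' Frame streams and session I/O
#'
#' A frame stream is a lazy sequence of color frames with a fixed frame rate:
#' a list with `n_frames`, `fps`, `dims` (c(width, height)) and a
#' `get_frame(i)` closure returning the i-th frame as an H x W x 3 array in
#' [0, 1]. Streams are how recorded frame directories and synthetic scenes
#' enter the pipeline.
#'
#' @name frame-streams
NULL

#' Construct a frame stream
#'
#' @param get_frame function(i) returning frame i (H x W x 3 array in [0,1]).
#' @param n_frames number of frames.
#' @param fps frames per second.
#' @param dims c(width, height) in px.
#' @export
frame_stream <- function(get_frame, n_frames, fps, dims) {
  stopifnot(is.function(get_frame), n_frames >= 1, fps > 0, length(dims) == 2)
  structure(list(get_frame = get_frame, n_frames = as.integer(n_frames),
                 fps = fps, dims = as.integer(dims)),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("Frame stream: %d frames, %g fps, %d x %d px (%.1f s)\n",
              x$n_frames, x$fps, x$dims[1], x$dims[2], x$n_frames / x$fps))
  invisible(x)
}

#' Timestamps of a stream's frames
#' @param stream a `frame_stream`.
#' @return numeric vector, `(i - 1) / fps` seconds.
#' @export
frame_times <- function(stream) (seq_len(stream$n_frames) - 1) / stream$fps

as_rgb_array <- function(img) {
  if (length(dim(img)) == 2) {
    array(rep(img, 3), c(dim(img), 3))
  } else if (dim(img)[3] >= 3) {
    img[, , 1:3, drop = FALSE]
  } else {
    array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  }
}

#' Open a recording as a frame stream
#'
#' Reads a directory of numbered frame images (PNG or TIFF), sorted by file
#' name, as a lazy frame stream. Video containers must be exported to frames
#' upstream (e.g. with ffmpeg); the frame rate of a directory is supplied via
#' `fps`.
#'
#' @param path directory containing the frames.
#' @param fps frame rate to attach (default 30, the standard recording rate).
#' @return a [frame_stream()].
#' @export
read_video <- function(path, fps = 30) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("'", path, "' is a file; decode video containers to a frame ",
           "directory first (e.g. ffmpeg -i in.mp4 dir/%06d.png), then ",
           "read_video(dir, fps)")
    }
    stop("no such directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) {
    stop("no frame images (*.png, *.tif) found in ", path)
  }
  read1 <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      as_rgb_array(png::readPNG(f))
    } else {
      as_rgb_array(tiff::readTIFF(f))
    }
  }
  probe <- read1(files[1])
  frame_stream(function(i) read1(files[i]),
               n_frames = length(files), fps = fps,
               dims = c(dim(probe)[2], dim(probe)[1]))
}

#' Write a frame stream to a directory of PNGs
#'
#' @param stream a `frame_stream`.
#' @param dir output directory (created if needed).
#' @param indices which frames to write (default: all).
#' @export
write_frames <- function(stream, dir, indices = seq_len(stream$n_frames)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in indices) {
    png::writePNG(stream$get_frame(i),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

# -- trial CSV ----------------------------------------------------------------

trial_schema <- "laser-trial-v1"
trial_columns <- c("participant", "hand", "draw_direction",
                   "anatomical_direction", "trial", "start_frame", "end_frame",
                   "duration_s", "acuity_pct", "speed_arc_mm_s",
                   "speed_nominal_mm_s", "n_frames_total", "n_frames_detected",
                   "n_frames_on_line", "path_length_mm")

#' Write / read the per-trial results table
#'
#' One row per scored trial, fixed versioned column set, schema tag in a
#' comment line so files are self-describing. A JSON manifest is written next
#' to the CSV with the record count, the expected count (when given) and an
#' md5 of the table for provenance.
#'
#' @param records data frame with (a superset of) the trial columns.
#' @param path output CSV path.
#' @param expected_trials optionally, how many trials the session should have
#'   contained; noted in the manifest when records are missing.
#' @param config optional `run_config` echoed into the manifest.
#' @export
write_trial_csv <- function(records, path, expected_trials = NULL,
                            config = NULL) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(trial_columns, names(records))
  for (m in missing_cols) records[[m]] <- rep(NA, nrow(records))
  records <- records[, trial_columns, drop = FALSE]
  con <- file(path, "w")
  writeLines(paste0("# schema: ", trial_schema), con)
  utils::write.csv(records, con, row.names = FALSE)
  close(con)
  manifest <- list(
    schema = trial_schema,
    n_records = nrow(records),
    expected_trials = expected_trials,
    complete = if (is.null(expected_trials)) NA else
      nrow(records) == expected_trials,
    csv_md5 = unname(tools::md5sum(path)),
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(trial_schema, first, fixed = TRUE)) {
    stop("not a ", trial_schema, " file: ", path)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
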