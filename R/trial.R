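#' Trial scoring: segmentation, acuity, speed
#'
#' A scored trial is represented as a data frame of per-frame observations
#' (`frame`, `time_s`, `detected`, `x_px`, `y_px`, `x_mm`, `y_mm`, `area_px`,
#' `on_line`) plus the derived `trial_result`.
#'
#' @name trial-scoring
NULL

# first run of >= dwell consecutive TRUE values in `within`, restricted to
# positions > after; returns c(first_idx, last_idx) of the run or NULL
first_dwell_run <- function(within, dwell, after = 0) {
  if (after > 0) within[seq_len(min(after, length(within)))] <- FALSE
  r <- rle(within)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= dwell)
  if (length(ok) == 0) return(NULL)
  c(starts[ok[1]], ends[ok[1]])
}

#' Detect trial start and end frames
#'
#' The trial is delimited by the dot dwelling near the two trace termini: the
#' start frame is the last frame of the first run of at least `dwell_frames`
#' consecutive frames with the dot within `radius_mm` of the start corner
#' (i.e. the moment of departure); the end frame is the first frame of the
#' first subsequent such run at the end corner (the moment of arrival).
#'
#' @param observations per-frame observation data frame (see
#'   [analyze_trial()]); needs `frame`, `detected`, `x_mm`, `y_mm`.
#' @param start_corner_mm,end_corner_mm length-2 mm positions of the trace
#'   termini.
#' @param radius_mm dwell radius around each terminus.
#' @param dwell_frames minimum run length that counts as dwelling.
#' @return list with `start_frame` and `end_frame` (values of
#'   `observations$frame`).
#' @export
segment_trial <- function(observations, start_corner_mm, end_corner_mm,
                          radius_mm = 10, dwell_frames = 5) {
  o <- observations
  dist_to <- function(p) sqrt((o$x_mm - p[1])^2 + (o$y_mm - p[2])^2)
  within_start <- !is.na(o$x_mm) & o$detected & dist_to(start_corner_mm) <= radius_mm
  run_s <- first_dwell_run(within_start, dwell_frames)
  if (is.null(run_s)) {
    stop("TrialNotSegmentable: the dot never dwells within ", radius_mm,
         " mm of the start corner for ", dwell_frames, " frames",
         call. = FALSE)
  }
  within_end <- !is.na(o$x_mm) & o$detected & dist_to(end_corner_mm) <= radius_mm
  run_e <- first_dwell_run(within_end, dwell_frames, after = run_s[2])
  if (is.null(run_e)) {
    stop("TrialNotSegmentable: the dot never dwells within ", radius_mm,
         " mm of the end corner after leaving the start", call. = FALSE)
  }
  list(start_frame = o$frame[run_s[2]], end_frame = o$frame[run_e[1]])
}

#' Movement acuity of a trial
#'
#' Percentage of the trial time that the laser dot was on the black target
#' line. With `denominator = "all"` (the default) every frame of the trial
#' window counts and frames without a detected dot score as off-line, since
#' acuity is defined over trial time; `"detected"` restricts the denominator
#' to frames with a detection.
#'
#' @inheritParams segment_trial
#' @param start_frame,end_frame trial window (inclusive), from
#'   [segment_trial()].
#' @param denominator `"all"` or `"detected"`.
#' @return acuity in percent, in [0, 100].
#' @export
compute_acuity <- function(observations, start_frame, end_frame,
                           denominator = c("all", "detected")) {
  denominator <- match.arg(denominator)
  w <- observations[observations$frame >= start_frame &
                      observations$frame <= end_frame, ]
  if (nrow(w) == 0) stop("empty trial window")
  den <- if (denominator == "all") nrow(w) else sum(w$detected)
  if (den == 0) stop("no detected frames in trial window")
  100 * sum(w$on_line %in% TRUE) / den
}

#' Average movement speed of a trial
#'
#' `mode = "arc"` (default): arc length of the centroid trajectory in mm,
#' after a centered moving-average smoothing over `smooth_window` frames,
#' divided by the trial duration. Gaps from undetected frames are bridged by
#' the straight segment between the neighbouring detections. `mode =
#' "nominal"`: the pattern's trace length divided by the duration (assumes the
#' trace was followed once end to end).
#'
#' @inheritParams compute_acuity
#' @param fps frame rate of the recording.
#' @param mode `"arc"` or `"nominal"`.
#' @param trace_length_mm needed for `"nominal"`.
#' @param smooth_window moving-average window in frames (default 1 = none;
#'   smoothing clips genuine lateral wiggle and shortens the measured path).
#' @return speed in mm/s, with attributes `path_length_mm` and `duration_s`.
#' @export
compute_speed <- function(observations, start_frame, end_frame, fps,
                          mode = c("arc", "nominal"), trace_length_mm = NULL,
                          smooth_window = 1) {
  mode <- match.arg(mode)
  duration <- (end_frame - start_frame) / fps
  if (duration <= 0) stop("empty trial window")
  if (mode == "nominal") {
    if (is.null(trace_length_mm)) stop("nominal mode needs trace_length_mm")
    v <- trace_length_mm / duration
    attr(v, "path_length_mm") <- trace_length_mm
    attr(v, "duration_s") <- duration
    return(v)
  }
  w <- observations[observations$frame >= start_frame &
                      observations$frame <= end_frame &
                      observations$detected & !is.na(observations$x_mm), ]
  if (nrow(w) < 2) stop("fewer than 2 detected frames in trial window")
  xy <- cbind(smooth_ma(w$x_mm, smooth_window), smooth_ma(w$y_mm, smooth_window))
  path <- sum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                              xy[-nrow(xy), , drop = FALSE])^2)))
  v <- path / duration
  attr(v, "path_length_mm") <- path
  attr(v, "duration_s") <- duration
  v
}

# centered moving average; window is clipped near the ends (partial windows)
smooth_ma <- function(x, window) {
  if (window <= 1 || length(x) < 3) return(x)
  half <- floor(window / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Anatomical movement direction from hand and drawing direction
#'
#' Clockwise means the trace is drawn left-to-right, anticlockwise
#' right-to-left. For the left hand a clockwise draw is a palmar-direction
#' wrist movement and an anticlockwise draw dorsal; for the right hand the
#' mapping is reversed.
#'
#' @param hand `"left"` or `"right"` (vectorized).
#' @param draw_direction `"clockwise"` (or `"lr"`) / `"anticlockwise"` (or
#'   `"rl"`).
#' @return `"palmar"` or `"dorsal"`.
#' @export
label_direction <- function(hand, draw_direction) {
  hand <- match_enum(hand, c("left", "right"))
  dd <- normalize_draw_direction(draw_direction)
  ifelse(dd == "clockwise",
         ifelse(hand == "left", "palmar", "dorsal"),
         ifelse(hand == "left", "dorsal", "palmar"))
}

match_enum <- function(x, choices) {
  x <- as.character(x)
  if (!all(x %in% choices)) {
    stop("values must be one of: ", paste(choices, collapse = ", "))
  }
  x
}

normalize_draw_direction <- function(x) {
  x <- as.character(x)
  x[x == "lr"] <- "clockwise"
  x[x == "rl"] <- "anticlockwise"
  match_enum(x, c("clockwise", "anticlockwise"))
}

#' Aggregate trials to condition means
#'
#' Mean acuity and speed over the (up to three) trials of each participant x
#' hand x anatomical-direction condition, with the number of contributing
#' trials. Missing trials are simply averaged over what is available; a
#' warning lists participants with conditions that have no trials at all.
#'
#' @param records trial table (see [write_trial_csv()] for the schema);
#'   `anatomical_direction` is derived from `hand` and `draw_direction` when
#'   absent.
#' @param expected_conditions number of conditions a complete session has.
#' @return data frame with one row per participant x hand x direction.
#' @export
aggregate_conditions <- function(records, expected_conditions = 4) {
  r <- as.data.frame(records)
  if (is.null(r$anatomical_direction) || anyNA(r$anatomical_direction)) {
    r$anatomical_direction <- label_direction(r$hand, r$draw_direction)
  }
  key <- interaction(r$participant, r$hand, r$anatomical_direction, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) tapply(as.character(v), key, `[`, 1)
  out <- data.frame(
    participant = unname(first(r$participant)),
    hand = unname(first(r$hand)),
    anatomical_direction = unname(first(r$anatomical_direction)),
    n_trials = agg(r$acuity_pct, function(v) sum(!is.na(v))),
    acuity_pct = agg(r$acuity_pct, function(v) mean(v, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  speed_col <- intersect(c("speed_arc_mm_s", "speed_mm_s"), names(r))[1]
  if (!is.na(speed_col)) {
    out$speed_mm_s <- agg(r[[speed_col]], function(v) mean(v, na.rm = TRUE))
  }
  n_cond <- table(out$participant)
  short <- names(n_cond)[n_cond < expected_conditions]
  if (length(short)) {
    warning("participant(s) with missing conditions omitted from those cells: ",
            paste(short, collapse = ", "))
  }
  out[order(out$participant, out$hand, out$anatomical_direction), ]
}

#' Score one trial video end to end
#'
#' Runs the full per-trial pipeline on a frame stream: corner detection and
#' calibration (once, unless a calibration is supplied), line-mask
#' rasterization, per-frame dot detection and on-line classification, trial
#' segmentation, and the acuity/speed outcome variables.
#'
#' @param stream a [frame_stream()] (recorded via [read_video()] or synthetic
#'   via [generate_trial()]).
#' @param pattern the `zigzag_pattern` on the wall.
#' @param hand `"left"` or `"right"`.
#' @param draw_direction `"clockwise"`/`"lr"` or `"anticlockwise"`/`"rl"`;
#'   decides which terminus is the start corner.
#' @param config a [run_config()].
#' @param calibration optional precomputed `laser_calibration` (reused across
#'   the trials of a session).
#' @param participant,trial identifiers carried into the result row.
#' @return an object of class `trial_result`; see Details.
#' @details The result contains `start_frame`, `end_frame`, `duration_s`,
#'   `acuity_pct`, `speed_arc_mm_s`, `speed_nominal_mm_s`, `path_length_mm`,
#'   the quality counters `n_frames_total`, `n_frames_detected`,
#'   `n_frames_on_line` (within the trial window), the per-frame
#'   `observations` data frame, and the `calibration` used.
#' @export
analyze_trial <- function(stream, pattern, hand = "right",
                          draw_direction = "clockwise",
                          config = run_config(), calibration = NULL,
                          participant = NA, trial = NA) {
  stopifnot(inherits(stream, "frame_stream"))
  draw_direction <- normalize_draw_direction(draw_direction)
  if (is.null(calibration)) {
    corners <- detect_corners_stream(stream,
                                     dark_threshold = config$dark_threshold)
    calibration <- calibrate(corners, pattern)
    if (config$refine_calibration) {
      calibration <- refine_calibration(stream$get_frame(1), pattern,
                                        calibration,
                                        dark_threshold = config$dark_threshold)
    }
  }
  tol <- config$on_line_tol_mm
  if (is.null(tol)) {
    # auto: an eighth of the pixel pitch at the board center; offsets the
    # area contact lost by sampling both the dot and the line at pixel
    # centers (about a quarter pixel in total, shared between the two masks)
    ctr <- mm_to_px(calibration, pattern$center_cross_mm)
    step <- px_to_mm(calibration, ctr + c(1, 0)) - px_to_mm(calibration, ctr)
    tol <- 0.125 * sqrt(sum(step^2))
  }
  mask <- line_mask(pattern, calibration, stream$dims, tol_mm = tol)
  n <- stream$n_frames
  times <- frame_times(stream)
  obs <- data.frame(frame = seq_len(n), time_s = times, detected = FALSE,
                    x_px = NA_real_, y_px = NA_real_, x_mm = NA_real_,
                    y_mm = NA_real_, area_px = NA_real_, on_line = NA)
  t0 <- proc.time()[3]
  for (i in seq_len(n)) {
    dot <- detect_dot(stream$get_frame(i), t_abs = config$t_abs,
                      t_margin = config$t_margin,
                      white_core = config$white_core,
                      min_dot_area = config$min_dot_area,
                      max_dot_area = config$max_dot_area,
                      opening_size = config$opening_size,
                      frame_index = i, time_s = times[i])
    if (dot$detected) {
      mm <- px_to_mm(calibration, dot$centroid_px)
      obs$detected[i] <- TRUE
      obs$x_px[i] <- dot$centroid_px[1]; obs$y_px[i] <- dot$centroid_px[2]
      obs$x_mm[i] <- mm[1]; obs$y_mm[i] <- mm[2]
      obs$area_px[i] <- dot$area_px
      obs$on_line[i] <- classify_on_line(dot, mask, config$min_overlap_px)
    }
  }
  detect_s <- (proc.time()[3] - t0) / n
  n_interp <- 0
  if (config$interpolate_gaps > 0) {
    obs <- interpolate_gaps(obs, config$interpolate_gaps)
    n_interp <- sum(obs$interpolated %in% TRUE)
  }
  term <- pattern_termini(pattern)
  start_mm <- if (draw_direction == "clockwise") term$left else term$right
  end_mm <- if (draw_direction == "clockwise") term$right else term$left
  seg <- segment_trial(obs, start_mm, end_mm,
                       radius_mm = config$radius_mm,
                       dwell_frames = config$dwell_frames)
  acuity <- compute_acuity(obs, seg$start_frame, seg$end_frame,
                           denominator = config$acuity_denominator)
  sp_arc <- compute_speed(obs, seg$start_frame, seg$end_frame, stream$fps,
                          mode = "arc", smooth_window = config$smooth_window)
  sp_nom <- compute_speed(obs, seg$start_frame, seg$end_frame, stream$fps,
                          mode = "nominal",
                          trace_length_mm = pattern$trace_length_mm)
  w <- obs[obs$frame >= seg$start_frame & obs$frame <= seg$end_frame, ]
  structure(list(
    participant = participant, trial = trial, hand = hand,
    draw_direction = draw_direction,
    anatomical_direction = label_direction(hand, draw_direction),
    start_frame = seg$start_frame, end_frame = seg$end_frame,
    duration_s = attr(sp_arc, "duration_s"),
    acuity_pct = acuity,
    speed_arc_mm_s = as.numeric(sp_arc),
    speed_nominal_mm_s = as.numeric(sp_nom),
    speed_mm_s = if (config$speed_mode == "arc") as.numeric(sp_arc)
                 else as.numeric(sp_nom),
    path_length_mm = attr(sp_arc, "path_length_mm"),
    n_frames_total = nrow(w),
    n_frames_detected = sum(w$detected),
    n_frames_on_line = sum(w$on_line %in% TRUE),
    n_frames_interpolated = n_interp,
    mean_detect_s = unname(detect_s),
    observations = obs, calibration = calibration
  ), class = "trial_result")
}

# linear interpolation of centroids across undetected runs of <= k frames;
# interpolated frames keep detected = FALSE and get interpolated = TRUE,
# on_line stays NA (they still count in the "all"-frames acuity denominator)
interpolate_gaps <- function(obs, k) {
  obs$interpolated <- FALSE
  det <- which(obs$detected)
  if (length(det) < 2) return(obs)
  for (j in seq_len(length(det) - 1)) {
    a <- det[j]; b <- det[j + 1]
    gap <- b - a - 1
    if (gap >= 1 && gap <= k) {
      t <- seq_len(gap) / (gap + 1)
      idx <- (a + 1):(b - 1)
      obs$x_mm[idx] <- obs$x_mm[a] + t * (obs$x_mm[b] - obs$x_mm[a])
      obs$y_mm[idx] <- obs$y_mm[a] + t * (obs$y_mm[b] - obs$y_mm[a])
      obs$x_px[idx] <- obs$x_px[a] + t * (obs$x_px[b] - obs$x_px[a])
      obs$y_px[idx] <- obs$y_px[a] + t * (obs$y_px[b] - obs$y_px[a])
      obs$interpolated[idx] <- TRUE
    }
  }
  obs
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Scored trial\n")
  cat(sprintf("  %s hand, %s draw (%s direction)\n",
              x$hand, x$draw_direction, x$anatomical_direction))
  cat(sprintf("  frames %d..%d (%.2f s), %d/%d detected\n",
              x$start_frame, x$end_frame, x$duration_s,
              x$n_frames_detected, x$n_frames_total))
  cat(sprintf("  Acuity: %.1f %%   Speed: %.1f mm/s (arc), %.1f mm/s (nominal)\n",
              x$acuity_pct, x$speed_arc_mm_s, x$speed_nominal_mm_s))
  invisible(x)
}

#' @export
as.data.frame.trial_result <- function(x, ...) {
  data.frame(participant = x$participant, hand = x$hand,
             draw_direction = x$draw_direction,
             anatomical_direction = x$anatomical_direction, trial = x$trial,
             start_frame = x$start_frame, end_frame = x$end_frame,
             duration_s = x$duration_s, acuity_pct = x$acuity_pct,
             speed_arc_mm_s = x$speed_arc_mm_s,
             speed_nominal_mm_s = x$speed_nominal_mm_s,
             n_frames_total = x$n_frames_total,
             n_frames_detected = x$n_frames_detected,
             n_frames_on_line = x$n_frames_on_line,
             path_length_mm = x$path_length_mm,
             stringsAsFactors = FALSE)
}

#' @export
plot.trial_result <- function(x, ...) {
  o <- x$observations[x$observations$detected, ]
  plot(o$x_mm, o$y_mm, type = "n", asp = 1, ylim = rev(range(o$y_mm)),
       xlab = "x (mm)", ylab = "y (mm)",
       main = sprintf("Dot path (Acuity %.1f%%)", x$acuity_pct), ...)
  lines(o$x_mm, o$y_mm, col = "grey70")
  points(o$x_mm, o$y_mm, pch = 16, cex = 0.4,
         col = ifelse(o$on_line %in% TRUE, "forestgreen", "firebrick"))
  abline(v = c(x$start_frame, x$end_frame), col = NA)
  invisible(x)
}
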