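#' Synthetic trial scenes with analytic ground truth
#'
#' The generator emulates the physical test setup — a green A3 board with the
#' black zig-zag line, viewed with mild perspective, and a red laser dot
#' advancing along the trace with a noisy speed profile and an AR(1) lateral
#' error — and returns, alongside the rendered frames, the exact per-frame dot
#' position and on-line state. Every pipeline stage can therefore be validated
#' against analytic truth without real recordings.
#'
#' @name synthetic-scenes
NULL

#' Camera homography (mm plane to pixels)
#'
#' Composes an isotropic scale, optional rotation, a translation centering the
#' board in the image, and a mild projective (perspective) term, giving the mm
#' to px homography the renderer and the calibration tests use.
#'
#' @param px_per_mm nominal scale at the board center.
#' @param rotation_deg in-plane rotation.
#' @param persp length-2 projective coefficients (per mm); order 1e-5..1e-4
#'   gives the gentle keystone of a tripod camera slightly off-axis.
#' @param image_dims c(width, height) px.
#' @param board_dims c(width, height) mm.
#' @return 3 x 3 homography, mm -> px.
#' @export
make_camera_warp <- function(px_per_mm = 2.2, rotation_deg = 0,
                             persp = c(4e-5, -3e-5),
                             image_dims = c(1280, 720),
                             board_dims = c(420, 297)) {
  th <- rotation_deg * pi / 180
  A <- px_per_mm * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                          byrow = TRUE)
  cmm <- board_dims / 2
  cpx <- image_dims / 2
  w <- persp[1] * cmm[1] + persp[2] * cmm[2] + 1
  t <- cpx * w - as.vector(A %*% cmm)
  rbind(cbind(A, t), c(persp, 1))
}

#' Scene configuration
#'
#' Defaults reproduce the standard recording conditions: 1280 x 720 px at
#' 30 fps, the A3 zig-zag target, a red laser dot with a saturated core, and a
#' self-paced tracing speed at the fast end of the 15-45 s per-trial range
#' observed in practice.
#'
#' @param pattern a [zigzag_pattern()].
#' @param image_width,image_height frame size in px.
#' @param fps frame rate.
#' @param camera_warp mm to px homography (see [make_camera_warp()]).
#' @param dot_radius_mm laser dot radius on the board.
#' @param dot_color RGB of the dot's outer disk.
#' @param core_frac radius fraction rendered as saturated white core.
#' @param speed_mean_mm_s,speed_jitter_sd mean tangential speed and its
#'   per-frame white jitter SD.
#' @param lateral_sd_mm,lateral_rho stationary SD and lag-1 correlation of
#'   the AR(1) lateral error (tremor and corrective drift are strongly
#'   autocorrelated at 30 fps).
#' @param dwell_s dwell time at each terminus before/after the traverse.
#' @param seg_radius_mm,seg_dwell_frames start/stop rule used to define the
#'   ground-truth trial window (same defaults as [run_config()]).
#' @param pixel_noise_sd additive Gaussian sensor noise SD (intensity units).
#' @param board_color,bg_color,line_color scene colors.
#' @param seed RNG seed; the whole scene (trajectory and per-frame noise) is
#'   reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pattern = zigzag_pattern(),
                       image_width = 1280, image_height = 720, fps = 30,
                       camera_warp = make_camera_warp(
                         image_dims = c(image_width, image_height),
                         board_dims = c(pattern$board_width_mm,
                                        pattern$board_height_mm)),
                       dot_radius_mm = 2.5,
                       dot_color = c(1, 0.15, 0.12), core_frac = 0.45,
                       speed_mean_mm_s = 67, speed_jitter_sd = 8,
                       lateral_sd_mm = 2, lateral_rho = 0.9,
                       dwell_s = 1, seg_radius_mm = 10, seg_dwell_frames = 5,
                       pixel_noise_sd = 0.008,
                       board_color = c(0.10, 0.60, 0.12),
                       bg_color = c(0.85, 0.85, 0.85),
                       line_color = c(0.02, 0.02, 0.02),
                       seed = 1) {
  stopifnot(fps > 0, dot_radius_mm > 0, speed_mean_mm_s > 0,
            lateral_rho >= 0, lateral_rho < 1, dwell_s >= 0,
            pixel_noise_sd >= 0, inherits(pattern, "zigzag_pattern"))
  structure(list(pattern = pattern, image_width = image_width,
                 image_height = image_height, fps = fps,
                 camera_warp = camera_warp, dot_radius_mm = dot_radius_mm,
                 dot_color = dot_color, core_frac = core_frac,
                 speed_mean_mm_s = speed_mean_mm_s,
                 speed_jitter_sd = speed_jitter_sd,
                 lateral_sd_mm = lateral_sd_mm, lateral_rho = lateral_rho,
                 dwell_s = dwell_s, seg_radius_mm = seg_radius_mm,
                 seg_dwell_frames = seg_dwell_frames,
                 pixel_noise_sd = pixel_noise_sd, board_color = board_color,
                 bg_color = bg_color, line_color = line_color, seed = seed),
            class = "sim_config")
}

# Static scene (board + anti-aliased line) rendered once per configuration.
# Coverage blending over the pixel footprint mimics a camera integrating over
# each sensor pixel; a binary center-in-band rasterization would shrink drawn
# marks by about half a pixel and bias edge-overlap statistics.
render_background <- function(config) {
  W <- config$image_width; H <- config$image_height
  p <- config$pattern
  Hinv <- solve(config$camera_warp)  # px -> mm
  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), times = W)
  w <- Hinv[3, 1] * xs + Hinv[3, 2] * ys + Hinv[3, 3]
  xmm <- (Hinv[1, 1] * xs + Hinv[1, 2] * ys + Hinv[1, 3]) / w
  ymm <- (Hinv[2, 1] * xs + Hinv[2, 2] * ys + Hinv[2, 3]) / w
  on_board <- xmm >= 0 & xmm <= p$board_width_mm &
    ymm >= 0 & ymm <= p$board_height_mm
  bg <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- ifelse(on_board, config$board_color[ch], config$bg_color[ch])
    bg[, , ch] <- plane
  }
  # line: coverage-blended band around the polyline, restricted to its bbox
  pitch <- 1 / local_px_per_mm(config$camera_warp, p$center_cross_mm)
  half <- p$line_width_mm / 2
  a <- p$apex_points_mm
  pad <- half + 2 * pitch
  cand <- which(xmm >= min(a[, 1]) - pad & xmm <= max(a[, 1]) + pad &
                  ymm >= min(a[, 2]) - pad & ymm <= max(a[, 2]) + pad)
  if (length(cand)) {
    d <- dist_to_polyline(cbind(xmm[cand], ymm[cand]), a)
    cov <- pmin(pmax(0.5 + (half - d) / pitch, 0), 1)
    hit <- which(cov > 0)
    if (length(hit)) {
      ci <- cand[hit]; cv <- cov[hit]
      for (ch in 1:3) {
        idx <- (ch - 1L) * H * W + ci
        bg[idx] <- cv * config$line_color[ch] + (1 - cv) * bg[idx]
      }
    }
  }
  bg
}

# local px-per-mm scale of the warp around a mm point
local_px_per_mm <- function(Hmm2px, at_mm) {
  p0 <- apply_homography(Hmm2px, at_mm)
  px <- apply_homography(Hmm2px, at_mm + c(1, 0))
  py <- apply_homography(Hmm2px, at_mm + c(0, 1))
  max(sqrt(sum((px - p0)^2)), sqrt(sum((py - p0)^2)))
}

#' Generate one synthetic trial
#'
#' Simulates the dot trajectory (dwell at the start terminus, traverse with a
#' jittered speed profile and AR(1) lateral error, dwell at the end terminus),
#' derives the analytic ground truth, and wraps a lazy renderer of the frames
#' as a [frame_stream()]. Rendering cost is paid only for frames actually
#' requested, so truth-only studies are cheap.
#'
#' @param config a [sim_config()].
#' @param direction `"lr"` (left terminus to right; the clockwise draw) or
#'   `"rl"`.
#' @return list of class `sim_trial` with `stream` (a `frame_stream`),
#'   `truth` (see Details) and `config`.
#' @details `truth` contains the per-frame table `frames` (`s_mm` arc
#'   position, `x_mm`, `y_mm`, `x_px`, `y_px`, `lateral_mm`, `on_line`) and
#'   the scalars `start_frame`, `end_frame` (the segmentation rule of
#'   `seg_radius_mm`/`seg_dwell_frames` applied to the true positions),
#'   `arc_length_mm`, `duration_s`, `speed_mm_s`, `acuity_pct` (percentage of
#'   window frames with `|lateral| <= dot_radius + line_width/2`).
#' @export
generate_trial <- function(config, direction = c("lr", "rl")) {
  direction <- match.arg(direction)
  p <- config$pattern
  L <- p$trace_length_mm
  force(config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n_dwell <- round(config$dwell_s * config$fps)
  # speed profile: white-jittered tangential speed, floored at 1 mm/s
  v <- numeric(0)
  s_end <- 0
  while (s_end < L) {
    v <- c(v, pmax(stats::rnorm(256, config$speed_mean_mm_s,
                                config$speed_jitter_sd), 1))
    s_end <- sum(v) / config$fps
  }
  s_move <- cumsum(v / config$fps)
  s_move <- s_move[seq_len(which(s_move >= L)[1])]
  s_move[length(s_move)] <- L
  s <- c(rep(0, n_dwell), s_move, rep(L, n_dwell))
  n <- length(s)
  # AR(1) lateral error, stationary start
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, config$lateral_sd_mm)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0,
                          config$lateral_sd_mm * sqrt(1 - config$lateral_rho^2))
    for (i in 2:n) e[i] <- config$lateral_rho * e[i - 1] + innov[i - 1]
  }
  if (config$lateral_sd_mm == 0) e[] <- 0
  frame_seeds <- sample.int(2147483646L, n)
  s_along <- if (direction == "lr") s else L - s
  base <- point_at_arc(p$apex_points_mm, s_along)
  nrm <- normal_at_arc(p$apex_points_mm, s_along)
  pos <- base + nrm * e
  px <- apply_homography(config$camera_warp, pos)
  on <- abs(e) <= config$dot_radius_mm + p$line_width_mm / 2
  term <- pattern_termini(p)
  start_mm <- if (direction == "lr") term$left else term$right
  end_mm <- if (direction == "lr") term$right else term$left
  d_start <- sqrt((pos[, 1] - start_mm[1])^2 + (pos[, 2] - start_mm[2])^2)
  d_end <- sqrt((pos[, 1] - end_mm[1])^2 + (pos[, 2] - end_mm[2])^2)
  run_s <- first_dwell_run(d_start <= config$seg_radius_mm,
                           config$seg_dwell_frames)
  run_e <- first_dwell_run(d_end <= config$seg_radius_mm,
                           config$seg_dwell_frames,
                           after = if (is.null(run_s)) 0 else run_s[2])
  start_f <- if (is.null(run_s)) NA_integer_ else run_s[2]
  end_f <- if (is.null(run_e)) NA_integer_ else run_e[1]
  truth <- list(
    frames = data.frame(frame = seq_len(n), s_mm = s_along,
                        x_mm = pos[, 1], y_mm = pos[, 2],
                        x_px = px[, 1], y_px = px[, 2],
                        lateral_mm = e, on_line = on),
    start_frame = start_f, end_frame = end_f
  )
  if (!is.na(start_f) && !is.na(end_f)) {
    win <- start_f:end_f
    steps <- sqrt(rowSums((pos[win[-1], , drop = FALSE] -
                             pos[win[-length(win)], , drop = FALSE])^2))
    truth$arc_length_mm <- sum(steps)
    truth$duration_s <- (end_f - start_f) / config$fps
    truth$speed_mm_s <- truth$arc_length_mm / truth$duration_s
    truth$acuity_pct <- 100 * mean(on[win])
  }
  env <- new.env()
  stream <- frame_stream(
    get_frame = function(i) {
      if (is.null(env$bg)) env$bg <- render_background(config)
      render_dot_frame(config, env$bg, pos[i, ], frame_seeds[i])
    },
    n_frames = n, fps = config$fps,
    dims = c(config$image_width, config$image_height)
  )
  structure(list(stream = stream, truth = truth, config = config,
                 direction = direction),
            class = "sim_trial")
}

# paint the anti-aliased dot patch onto the background and add sensor noise
render_dot_frame <- function(config, bg, center_mm, frame_seed) {
  H <- config$image_height; W <- config$image_width
  cpx <- apply_homography(config$camera_warp, center_mm)
  sc <- local_px_per_mm(config$camera_warp, center_mm)
  pitch <- 1 / sc
  r_px <- config$dot_radius_mm * sc + 2
  xs <- max(1L, floor(cpx[1] - r_px)):min(W, ceiling(cpx[1] + r_px))
  ys <- max(1L, floor(cpx[2] - r_px)):min(H, ceiling(cpx[2] + r_px))
  idx <- integer(0); val <- numeric(0)
  if (length(xs) && length(ys)) {
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    Hinv <- solve(config$camera_warp)
    mm <- apply_homography(Hinv, cbind(gx, gy))
    d <- sqrt((mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2)
    cov <- pmin(pmax(0.5 + (config$dot_radius_mm - d) / pitch, 0), 1)
    core <- pmin(pmax(0.5 + (config$core_frac * config$dot_radius_mm - d) /
                        pitch, 0), 1)
    hit <- which(cov > 0)
    if (length(hit)) {
      lin <- (gx[hit] - 1L) * H + gy[hit]
      for (ch in 1:3) {
        dotc <- config$dot_color[ch] * (1 - core[hit]) + 1 * core[hit]
        under <- bg[(ch - 1L) * H * W + lin]
        idx <- c(idx, (ch - 1L) * H * W + lin)
        val <- c(val, cov[hit] * dotc + (1 - cov[hit]) * under)
      }
    }
  }
  set.seed(frame_seed)
  render_frame_cpp(bg, as.integer(idx), val, config$pixel_noise_sd)
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Synthetic trial\n")
  print(x$stream)
  if (!is.null(x$truth$acuity_pct)) {
    cat(sprintf("  truth: frames %d..%d, acuity %.1f %%, speed %.1f mm/s\n",
                x$truth$start_frame, x$truth$end_frame, x$truth$acuity_pct,
                x$truth$speed_mm_s))
  }
  invisible(x)
}

#' Simulate a subjects x trials outcome matrix
#'
#' Additive two-way model `y_ij = mu + b_i + d_j + e_ij` with subject effects
#' `b_i ~ N(0, sd_subject^2)`, fixed per-trial shifts `d_j` (e.g. a learning
#' effect) and residual noise `e_ij ~ N(0, sd_error^2)`. Under this model the
#' consistency ICC is `sd_subject^2 / (sd_subject^2 + sd_error^2)` and the SEM
#' is `sd_error`, which makes the matrix generator the reference for
#' parameter-recovery checks of [icc()] and [sem_from_differences()].
#'
#' @param n subjects; @param k trials.
#' @param mu grand mean.
#' @param sd_subject,sd_error between-subject and residual SDs.
#' @param trial_effect scalar per-trial increment (trial j gets
#'   `(j-1) * trial_effect`) or length-k vector of shifts.
#' @export
simulate_trial_matrix <- function(n, k, mu = 70, sd_subject = 8,
                                  sd_error = 5.5, trial_effect = 0) {
  d <- if (length(trial_effect) == k) trial_effect else
    (seq_len(k) - 1) * trial_effect
  b <- stats::rnorm(n, 0, sd_subject)
  mu + outer(b, d, `+`) + matrix(stats::rnorm(n * k, 0, sd_error), n, k)
}

#' Simulate a study-shaped cohort of scored trials
#'
#' Draws a cohort performing the full session (left and right hand, both draw
#' directions, three trials each: 12 trials per subject) directly at the
#' outcome level, without rendering video. Subject-level acuity and preferred
#' speed are correlated (faster tracers are less accurate), which induces the
#' expected negative speed-accuracy correlation; optional effects add a
#' dominant-hand acuity gain, an acuity deficit for subjects with hand pain,
#' and a per-trial learning shift.
#'
#' @param n_subjects cohort size.
#' @param dominant_gain acuity points added to the dominant hand.
#' @param pain_deficit acuity points subtracted for subjects with pain in the
#'   tested hand.
#' @param learning_per_trial acuity points added per trial number (0-based).
#' @param acuity_mean grand mean acuity; values are clipped to [0, 100].
#' @param subject_sd,condition_sd,trial_sd SD of the subject, subject x
#'   condition, and residual (trial) effects on acuity.
#' @param speed_mean,speed_subject_sd,speed_trial_sd tracing speed components
#'   (mm/s).
#' @param speed_acuity_slope acuity points lost per mm/s of (subject) speed
#'   above the mean.
#' @param right_handed_prop,pain_prevalence cohort composition.
#' @param seed RNG seed.
#' @return list with `records` (trial table in the standard schema plus
#'   `dominant` and `pain` flags) and `subjects` (the generating per-subject
#'   parameters).
#' @export
generate_cohort <- function(n_subjects = 50, dominant_gain = 0,
                            pain_deficit = 0, learning_per_trial = 0,
                            acuity_mean = 70, subject_sd = 8,
                            condition_sd = 4, trial_sd = 5.5,
                            speed_mean = 40, speed_subject_sd = 10,
                            speed_trial_sd = 4, speed_acuity_slope = 0.4,
                            right_handed_prop = 0.9, pain_prevalence = 0.25,
                            seed = 1) {
  stopifnot(n_subjects >= 1)
  # force the seed argument before snapshotting the RNG state, so a caller
  # passing a freshly drawn seed keeps its own RNG advance
  force(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subjects <- data.frame(
    participant = sprintf("S%03d", seq_len(n_subjects)),
    dominant_hand = ifelse(stats::runif(n_subjects) < right_handed_prop,
                           "right", "left"),
    base_acuity = stats::rnorm(n_subjects, acuity_mean, subject_sd),
    pref_speed = pmax(stats::rnorm(n_subjects, speed_mean, speed_subject_sd),
                      5),
    pain_left = stats::runif(n_subjects) < pain_prevalence / 2,
    pain_right = stats::runif(n_subjects) < pain_prevalence / 2,
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(trial = 1:3,
                      draw_direction = c("clockwise", "anticlockwise"),
                      hand = c("left", "right"),
                      participant = subjects$participant,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("participant", "hand", "draw_direction", "trial")]
  su <- subjects[match(grid$participant, subjects$participant), ]
  cond_key <- interaction(grid$participant, grid$hand, grid$draw_direction,
                          drop = TRUE)
  cond_eff <- stats::rnorm(nlevels(cond_key), 0, condition_sd)[cond_key]
  dominant <- grid$hand == su$dominant_hand
  pain <- ifelse(grid$hand == "left", su$pain_left, su$pain_right)
  acuity <- su$base_acuity + cond_eff +
    dominant_gain * dominant - pain_deficit * pain +
    learning_per_trial * (grid$trial - 1) -
    speed_acuity_slope * (su$pref_speed - speed_mean) +
    stats::rnorm(nrow(grid), 0, trial_sd)
  speed <- pmax(su$pref_speed + stats::rnorm(nrow(grid), 0, speed_trial_sd), 2)
  records <- data.frame(
    grid,
    anatomical_direction = label_direction(grid$hand, grid$draw_direction),
    acuity_pct = pmin(pmax(acuity, 0), 100),
    speed_arc_mm_s = speed,
    dominant = dominant, pain = pain,
    stringsAsFactors = FALSE
  )
  list(records = records, subjects = subjects)
}
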