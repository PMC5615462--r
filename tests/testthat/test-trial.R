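make_obs <- function(x_mm, y_mm = 0, detected = TRUE, on_line = TRUE,
                     fps = 30) {
  n <- length(x_mm)
  data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fps,
             detected = rep_len(detected, n),
             x_px = x_mm, y_px = y_mm, x_mm = x_mm,
             y_mm = rep_len(y_mm, n), area_px = 50,
             on_line = rep_len(on_line, n))
}

test_that("segmentation finds the analytic radius crossings", {
  # monotone traverse 0..100 mm in 2 mm steps; radius 10 mm, dwell 1 frame:
  # the dot leaves the 10 mm start disk after x = 10 (frame 6) and enters the
  # 10 mm end disk at x = 90 (frame 46)
  o <- make_obs(seq(0, 100, by = 2))
  seg <- segment_trial(o, c(0, 0), c(100, 0), radius_mm = 10,
                       dwell_frames = 1)
  expect_equal(seg$start_frame, 6)
  expect_equal(seg$end_frame, 46)
})

test_that("dwell requirement suppresses flicker at the terminus", {
  x <- c(0, 0, 0, 12, 0, 0, 0, 0, seq(2, 100, by = 2))
  o <- make_obs(x)
  # dwell of 4: the first 3-frame visit flickers out and is too short; the
  # real dwell is the following run, which stays within the 10 mm radius
  # until x = 10 at frame 13 - the moment of departure
  seg <- segment_trial(o, c(0, 0), c(100, 0), radius_mm = 10,
                       dwell_frames = 4)
  expect_equal(seg$start_frame, 13)
})

test_that("trials that never reach a terminus are not segmentable", {
  o <- make_obs(seq(30, 70, by = 2))
  expect_error(segment_trial(o, c(0, 0), c(100, 0), 10, 1),
               "start corner")
  o2 <- make_obs(seq(0, 50, by = 2))
  expect_error(segment_trial(o2, c(0, 0), c(100, 0), 10, 1),
               "end corner")
})

test_that("acuity is the on-line share of trial time", {
  o <- make_obs(rep(1, 600), on_line = c(rep(TRUE, 450), rep(FALSE, 150)))
  expect_equal(compute_acuity(o, 1, 600), 75)
  expect_equal(compute_acuity(o, 1, 450), 100)
  # undetected frames count against acuity in the default denominator
  o2 <- make_obs(rep(1, 100), detected = c(rep(TRUE, 80), rep(FALSE, 20)),
                 on_line = c(rep(TRUE, 80), rep(NA, 20)))
  expect_equal(compute_acuity(o2, 1, 100), 80)
  expect_equal(compute_acuity(o2, 1, 100, denominator = "detected"), 100)
  expect_error(compute_acuity(o, 700, 800), "empty")
})

test_that("speed is path length over duration", {
  fps <- 30
  o <- make_obs(seq(0, 1000, length.out = 601), fps = fps)  # 20 s traverse
  v <- compute_speed(o, 1, 601, fps = fps)
  expect_equal(as.numeric(v), 50, tolerance = 1e-9)
  expect_equal(attr(v, "path_length_mm") / attr(v, "duration_s"),
               as.numeric(v), tolerance = 1e-12)
  vn <- compute_speed(o, 1, 601, fps = fps, mode = "nominal",
                      trace_length_mm = 1000)
  expect_equal(as.numeric(vn), 50)
  still <- make_obs(rep(5, 100), fps = fps)
  expect_equal(as.numeric(compute_speed(still, 1, 100, fps = fps)), 0)
  sparse <- make_obs(c(0, 1), detected = c(TRUE, FALSE))
  expect_error(compute_speed(sparse, 1, 2, fps = fps), "2 detected")
})

test_that("hand and draw direction map to anatomical direction", {
  expect_equal(label_direction("left", "clockwise"), "palmar")
  expect_equal(label_direction("right", "clockwise"), "dorsal")
  expect_equal(label_direction("left", "anticlockwise"), "dorsal")
  expect_equal(label_direction("right", "anticlockwise"), "palmar")
  # lr/rl synonyms
  expect_equal(label_direction("left", "lr"), "palmar")
  expect_equal(label_direction(c("left", "right"), c("rl", "rl")),
               c("dorsal", "palmar"))
  expect_error(label_direction("left", "up"), "one of")
})

test_that("condition aggregation averages available trials", {
  rec <- expand.grid(trial = 1:3,
                     draw_direction = c("clockwise", "anticlockwise"),
                     hand = c("left", "right"),
                     participant = c("P1", "P2"),
                     stringsAsFactors = FALSE)
  rec$acuity_pct <- 70
  rec$speed_arc_mm_s <- 40
  rec$acuity_pct[rec$participant == "P1" & rec$hand == "left" &
                   rec$draw_direction == "clockwise"] <- c(70, 75, 80)
  agg <- aggregate_conditions(rec)
  expect_equal(nrow(agg), 8)
  p1lp <- agg[agg$participant == "P1" & agg$hand == "left" &
                agg$anatomical_direction == "palmar", ]
  expect_equal(p1lp$acuity_pct, 75)
  expect_equal(p1lp$n_trials, 3)
  # one missing trial: mean over the remaining two, flagged by n_trials
  rec2 <- rec[!(rec$participant == "P1" & rec$hand == "left" &
                  rec$draw_direction == "clockwise" & rec$trial == 2), ]
  agg2 <- aggregate_conditions(rec2)
  p1lp2 <- agg2[agg2$participant == "P1" & agg2$hand == "left" &
                  agg2$anatomical_direction == "palmar", ]
  expect_equal(p1lp2$acuity_pct, 75)
  expect_equal(p1lp2$n_trials, 2)
  # a condition with no trials at all is omitted with a warning
  rec3 <- rec[!(rec$participant == "P2" & rec$hand == "right" &
                  rec$draw_direction == "clockwise"), ]
  expect_warning(agg3 <- aggregate_conditions(rec3), "P2")
  expect_equal(nrow(agg3), 7)
})

test_that("gap interpolation bridges short undetected runs only", {
  o <- make_obs(seq(0, 20, by = 1))
  o$detected[c(5, 6, 12)] <- FALSE
  o$x_mm[c(5, 6, 12)] <- NA; o$x_px[c(5, 6, 12)] <- NA
  out <- lasertrace:::interpolate_gaps(o, k = 1)
  expect_true(out$interpolated[12])
  expect_equal(out$x_mm[12], 11)
  expect_false(any(out$interpolated[c(5, 6)]))   # gap of 2 > k
  expect_false(out$detected[12])                 # never promoted to detected
  out2 <- lasertrace:::interpolate_gaps(o, k = 2)
  expect_equal(out2$x_mm[c(5, 6)], c(4, 5))
})

test_that("identical synthetic input yields identical trial results", {
  cfg <- test_scene_config(seed = 21)
  r1 <- analyze_trial(generate_trial(cfg)$stream, cfg$pattern)
  r2 <- analyze_trial(generate_trial(cfg)$stream, cfg$pattern)
  expect_identical(r1$acuity_pct, r2$acuity_pct)
  expect_identical(r1$speed_arc_mm_s, r2$speed_arc_mm_s)
  expect_identical(r1$observations, r2$observations)
})
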