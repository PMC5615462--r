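test_that("the generator is fully reproducible from its seed", {
  cfg <- test_scene_config(seed = 99)
  s1 <- generate_trial(cfg); s2 <- generate_trial(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$stream$get_frame(10), s2$stream$get_frame(10))
  expect_identical(s1$stream$get_frame(1), s2$stream$get_frame(1))
  # frames are identical regardless of access order
  a20 <- s1$stream$get_frame(20)
  invisible(s2$stream$get_frame(3))
  expect_identical(s2$stream$get_frame(20), a20)
  # a different seed changes the scene
  s3 <- generate_trial(test_scene_config(seed = 100))
  expect_false(identical(s3$truth$frames$lateral_mm,
                         s1$truth$frames$lateral_mm))
})

test_that("frame accounting matches the configured timing", {
  cfg <- test_scene_config(seed = 2)
  sim <- generate_trial(cfg)
  n <- sim$stream$n_frames
  expect_equal(nrow(sim$truth$frames), n)
  dwell_n <- round(cfg$dwell_s * cfg$fps)
  expect_true(all(sim$truth$frames$s_mm[1:dwell_n] == 0))
  expect_true(all(sim$truth$frames$s_mm[(n - dwell_n + 1):n] ==
                    cfg$pattern$trace_length_mm))
  tms <- frame_times(sim$stream)
  expect_equal(tms[1], 0)
  expect_equal(tms[n], (n - 1) / cfg$fps)
})

test_that("ground truth honours the lateral-error contact rule", {
  cfg <- test_scene_config(seed = 3, lateral_sd_mm = 3)
  sim <- generate_trial(cfg)
  tr <- sim$truth$frames
  thr <- cfg$dot_radius_mm + cfg$pattern$line_width_mm / 2
  expect_identical(tr$on_line, abs(tr$lateral_mm) <= thr)
  # arc length equals the summed frame displacements inside the window
  win <- sim$truth$start_frame:sim$truth$end_frame
  d <- sqrt(diff(tr$x_mm[win])^2 + diff(tr$y_mm[win])^2)
  expect_equal(sim$truth$arc_length_mm, sum(d), tolerance = 1e-9)
  expect_equal(sim$truth$speed_mm_s,
               sum(d) / ((max(win) - min(win)) / cfg$fps), tolerance = 1e-9)
})

test_that("zero lateral error keeps the dot on the line throughout", {
  cfg <- test_scene_config(seed = 4, lateral_sd_mm = 0)
  sim <- generate_trial(cfg)
  expect_equal(sim$truth$acuity_pct, 100)
})

test_that("true on-line fraction falls as lateral error grows", {
  frac <- sapply(c(0.5, 1, 2, 4), function(sdl) {
    mean(sapply(1:3, function(s) {
      generate_trial(test_scene_config(seed = 40 + s, lateral_sd_mm = sdl,
                                       dot_radius_mm = 1))$truth$acuity_pct
    }))
  })
  expect_true(all(diff(frac) < 0))
})

test_that("the scripted dwell drives the ground-truth trial window", {
  cfg <- test_scene_config(seed = 6)
  sim <- generate_trial(cfg)
  dwell_n <- round(cfg$dwell_s * cfg$fps)
  # the dot leaves the start terminus right after the scripted dwell; the
  # start frame is within a few frames of it (the dot must clear the radius)
  expect_gte(sim$truth$start_frame, dwell_n)
  expect_lte(sim$truth$start_frame, dwell_n + 3)
  expect_lt(sim$truth$end_frame, sim$stream$n_frames - dwell_n + 2)
})

test_that("cohort simulation has the study's session structure", {
  coh <- generate_cohort(8, seed = 5)
  expect_equal(nrow(coh$records), 8 * 12)
  expect_equal(as.integer(table(coh$records$participant)), rep(12L, 8))
  per <- table(coh$records$participant, coh$records$hand,
               coh$records$anatomical_direction)
  expect_true(all(per == 3))
  expect_true(all(coh$records$acuity_pct >= 0 &
                    coh$records$acuity_pct <= 100))
  expect_identical(coh$records$anatomical_direction,
                   label_direction(coh$records$hand,
                                   coh$records$draw_direction))
})

test_that("built-in effects are visible to the analysis layer", {
  # dominant-hand gain: paired comparison on condition means
  coh <- generate_cohort(50, dominant_gain = 8, seed = 31)
  agg <- aggregate_conditions(coh$records)
  dom_hand <- coh$subjects$dominant_hand[match(agg$participant,
                                               coh$subjects$participant)]
  dom <- tapply(agg$acuity_pct[agg$hand == dom_hand],
                agg$participant[agg$hand == dom_hand], mean)
  nondom <- tapply(agg$acuity_pct[agg$hand != dom_hand],
                   agg$participant[agg$hand != dom_hand], mean)
  r <- compare_groups(dom[names(nondom)], nondom, paired = TRUE)
  expect_gt(r$estimate, 0)
  expect_lt(r$p, 0.01)
  # learning effect: repeated-measures ANOVA flags the trial factor
  coh2 <- generate_cohort(50, learning_per_trial = 2, seed = 32)
  m <- condition_matrix(coh2$records, "acuity_pct", "right", "dorsal")
  expect_lt(rm_anova(m)$p, 0.05)
  expect_gt(mean(colMeans(m)[3] - colMeans(m)[1]), 1)
  # speed-accuracy trade-off: negative rank correlation across subjects
  agg2 <- aggregate_conditions(coh$records)
  r2 <- speed_accuracy_correlation(agg2$acuity_pct, agg2$speed_mm_s)
  expect_lt(r2$rho, 0)
  expect_lt(r2$p, 0.01)
})
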