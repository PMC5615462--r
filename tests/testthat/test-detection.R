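test_that("corners are found within 2 px on rendered patterns", {
  for (seed in 1:5) {
    set.seed(seed)
    W <- make_camera_warp(px_per_mm = runif(1, 1.9, 2.3),
                          persp = runif(2, -8e-5, 8e-5))
    cfg <- sim_config(camera_warp = W, seed = seed)
    bg <- lasertrace:::render_background(cfg)
    det <- detect_corners(bg)
    ref <- t(sapply(pattern_corners(cfg$pattern),
                    function(p) apply_homography(W, p)))
    expect_lt(max(sqrt(rowSums((det$points - ref)^2))), 2)
  }
})

test_that("images without a pattern raise NoPatternFound", {
  expect_error(detect_corners(flat_frame(80, 120, c(1, 1, 1))),
               "NoPatternFound")
})

test_that("a single dark point gives a degenerate corner set", {
  f <- flat_frame(80, 120, c(0.9, 0.9, 0.9))
  f[40, 60, ] <- 0
  expect_error(detect_corners(f), "degenerate")
})

test_that("the laser dot centroid is recovered to subpixel accuracy", {
  f <- flat_frame(200, 300, c(0.1, 0.6, 0.12))
  f <- paint_disk(f, 151.3, 92.6, 8, c(1, 0.15, 0.12))
  dot <- detect_dot(f)
  expect_true(dot$detected)
  expect_lt(abs(dot$centroid_px[1] - 151.3), 0.5)
  expect_lt(abs(dot$centroid_px[2] - 92.6), 0.5)
  expect_gt(dot$area_px, pi * 7^2)
})

test_that("a saturated white core stays part of the dot", {
  f <- flat_frame(200, 300, c(0.1, 0.6, 0.12))
  f <- paint_disk(f, 150, 90, 9, c(1, 0.15, 0.12))
  f <- paint_disk(f, 150, 90, 4, c(1, 1, 1))       # blown-out laser core
  dot <- detect_dot(f)
  expect_true(dot$detected)
  expect_lt(abs(dot$centroid_px[1] - 150), 0.5)
  expect_lt(abs(dot$centroid_px[2] - 90), 0.5)
})

test_that("absence of the dot is an observation, not an error", {
  dot <- detect_dot(flat_frame(100, 100, c(0.1, 0.6, 0.12)))
  expect_false(dot$detected)
  expect_true(is.na(dot$centroid_px[1]))
  expect_true(is.na(dot$area_px))
  expect_true(is.na(dot$on_line))
})

test_that("small speckles are cleared while the dot is kept", {
  f <- flat_frame(200, 300, c(0.1, 0.6, 0.12))
  f <- paint_disk(f, 100, 100, 8, c(1, 0.15, 0.12))   # ~200 px dot
  f[30, 40, ] <- c(1, 0, 0); f[30, 41, ] <- c(1, 0, 0)
  f[31, 40, ] <- c(1, 0, 0)                            # 3 px speckle
  dot <- detect_dot(f, min_dot_area = 10)
  expect_true(dot$detected)
  expect_lt(abs(dot$centroid_px[1] - 100), 0.5)
  expect_lt(abs(dot$centroid_px[2] - 100), 0.5)
})

test_that("detection is translation-equivariant", {
  base <- flat_frame(200, 300, c(0.1, 0.6, 0.12))
  d0 <- detect_dot(paint_disk(base, 80.4, 120.7, 7, c(1, 0.1, 0.1)))
  d1 <- detect_dot(paint_disk(base, 80.4 + 37, 120.7 + 21, 7, c(1, 0.1, 0.1)))
  expect_lt(abs((d1$centroid_px[1] - d0$centroid_px[1]) - 37), 0.5)
  expect_lt(abs((d1$centroid_px[2] - d0$centroid_px[2]) - 21), 0.5)
})

test_that("the exclusion mask removes candidate pixels", {
  f <- paint_disk(flat_frame(100, 100, c(0.1, 0.6, 0.12)), 50, 50, 7,
                  c(1, 0.1, 0.1))
  excl <- matrix(FALSE, 100, 100); excl[40:60, 40:60] <- TRUE
  expect_false(detect_dot(f, exclusion = excl)$detected)
})

test_that("corner detection ignores the dot in the board interior", {
  cfg <- test_scene_config(seed = 5)
  bg <- lasertrace:::render_background(cfg)
  c0 <- detect_corners(bg)
  # paint the dot mid-board, far from every extreme corner
  mid <- apply_homography(cfg$camera_warp, cfg$pattern$center_cross_mm)
  withdot <- paint_disk(bg, mid[1], mid[2] + 10, 5, c(1, 0.15, 0.12))
  c1 <- detect_corners(withdot)
  expect_equal(c1$points, c0$points)
})

test_that("multi-frame corner detection survives occlusion of a terminus", {
  cfg <- test_scene_config(seed = 8)
  sim <- generate_trial(cfg)
  det <- detect_corners_stream(sim$stream)
  ref <- t(sapply(pattern_corners(cfg$pattern),
                  function(p) apply_homography(cfg$camera_warp, p)))
  expect_lt(max(sqrt(rowSums((det$points - ref)^2))), 2.5)
  # frame 1 alone is contaminated: the dot dwells on the start terminus,
  # which is the up-left extreme of the drawn line
  c1 <- detect_corners(sim$stream$get_frame(1))
  d1 <- sqrt(sum((c1$points["up_left", ] - ref["up_left", ])^2))
  expect_gt(d1, sqrt(sum((det$points["up_left", ] - ref["up_left", ])^2)))
})

test_that("on-line classification follows the shared-pixel rule", {
  mask <- matrix(FALSE, 60, 200)
  mask[30, ] <- TRUE                      # one-pixel-high horizontal line
  on <- dot_observation(TRUE, centroid_px = c(100, 30), area_px = 21,
                        pixels = cbind(x = rep(96:104, 3),
                                       y = rep(29:31, each = 9)))
  expect_true(classify_on_line(on, mask))
  off <- dot_observation(TRUE, centroid_px = c(100, 45), area_px = 9,
                         pixels = cbind(x = rep(99:101, 3),
                                        y = rep(44:46, each = 3)))
  expect_false(classify_on_line(off, mask))
  # tangent: exactly one shared pixel row
  tangent <- dot_observation(TRUE, centroid_px = c(100, 32), area_px = 9,
                             pixels = cbind(x = rep(99:101, 3),
                                            y = rep(30:32, each = 3)))
  expect_true(classify_on_line(tangent, mask))
  expect_false(classify_on_line(tangent, mask, min_overlap_px = 5))
  undetected <- dot_observation(FALSE)
  expect_true(is.na(classify_on_line(undetected, mask)))
})
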