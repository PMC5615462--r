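# Shared fixtures: a reduced-size scene for unit tests (full-resolution scenes
# are exercised in test-acceptance.R) and small raster constructors.

test_scene_config <- function(seed = 1, ...) {
  dims <- c(640, 360)
  defaults <- list(image_width = dims[1], image_height = dims[2], fps = 10,
                   camera_warp = make_camera_warp(px_per_mm = 1.15,
                                                  image_dims = dims),
                   dot_radius_mm = 3, speed_mean_mm_s = 150,
                   speed_jitter_sd = 10, dwell_s = 0.8, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# uniform color image (H x W x 3)
flat_frame <- function(h, w, rgb = c(1, 1, 1)) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

# paint a filled disk centered at (cx, cy) px
paint_disk <- function(frame, cx, cy, radius, rgb) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  xs <- pmax(1, floor(cx - radius)):pmin(w, ceiling(cx + radius))
  ys <- pmax(1, floor(cy - radius)):pmin(h, ceiling(cy + radius))
  for (x in xs) for (y in ys) {
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) frame[y, x, ] <- rgb
  }
  frame
}

# brute-force two-way sums of squares by explicit loops (independent oracle
# for the ICC / RM-ANOVA decomposition)
ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); mu <- mean(m)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - mu)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - mu)^2
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - mu)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}
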