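#' Debug overlays
#'
#' Renders detection results into a copy of the frame for visual inspection:
#' the line mask tinted blue, detected corners as red squares, the dot's
#' component colored green when touching the line and orange otherwise.
#'
#' @param frame H x W x 3 array in [0, 1].
#' @param corners optional `corner_set`.
#' @param dot optional `dot_observation`.
#' @param mask optional logical line mask.
#' @param on_line optional logical overriding the dot color choice.
#' @return annotated frame array.
#' @export
draw_overlay <- function(frame, corners = NULL, dot = NULL, mask = NULL,
                         on_line = NA) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  out <- frame
  if (!is.null(mask)) {
    idx <- which(mask)
    out[idx + 2L * H * W] <- pmin(out[idx + 2L * H * W] + 0.5, 1)
  }
  if (!is.null(dot) && isTRUE(dot$detected)) {
    p <- dot$pixels
    lin <- (p[, 1] - 1L) * H + p[, 2]
    col <- if (isTRUE(on_line)) c(0.1, 0.9, 0.1) else c(1, 0.6, 0.1)
    for (ch in 1:3) out[lin + (ch - 1L) * H * W] <- col[ch]
  }
  if (!is.null(corners)) {
    for (i in seq_len(nrow(corners$points))) {
      cx <- round(corners$points[i, 1]); cy <- round(corners$points[i, 2])
      xs <- max(1, cx - 4):min(W, cx + 4)
      ys <- max(1, cy - 4):min(H, cy + 4)
      out[ys, xs, 1] <- 1; out[ys, xs, 2] <- 0; out[ys, xs, 3] <- 0
    }
  }
  out
}

#' Write a debug overlay PNG
#'
#' @inheritParams draw_overlay
#' @param path output PNG path.
#' @export
write_overlay_png <- function(path, frame, corners = NULL, dot = NULL,
                              mask = NULL, on_line = NA) {
  png::writePNG(draw_overlay(frame, corners, dot, mask, on_line), path)
  invisible(path)
}

#' End-to-end self test
#'
#' Generates one synthetic trial with the default scene, scores it with the
#' default configuration, and reports the recovered against the true acuity
#' and speed. Intended as a quick installation check.
#'
#' @param seed RNG seed for the scene.
#' @param ... overrides passed to [sim_config()].
#' @return invisibly, a list with the `trial_result` and the ground truth.
#' @export
selftest <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- generate_trial(cfg)
  res <- analyze_trial(sim$stream, cfg$pattern)
  cat(sprintf("Acuity: recovered %.1f %% vs true %.1f %% (err %.2f pp)\n",
              res$acuity_pct, sim$truth$acuity_pct,
              res$acuity_pct - sim$truth$acuity_pct))
  cat(sprintf("Speed:  recovered %.1f mm/s vs true %.1f mm/s (err %.2f %%)\n",
              res$speed_arc_mm_s, sim$truth$speed_mm_s,
              100 * (res$speed_arc_mm_s / sim$truth$speed_mm_s - 1)))
  cat(sprintf("Window: frames %d..%d vs true %d..%d\n",
              res$start_frame, res$end_frame,
              sim$truth$start_frame, sim$truth$end_frame))
  invisible(list(result = res, truth = sim$truth))
}
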