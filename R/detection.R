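#' Corner and laser-dot detection
#'
#' Frames are numeric arrays of dim c(height, width, 3) with values in [0, 1]
#' (as returned by [png::readPNG()]); `frame[y, x, ]` is the RGB of pixel
#' (x, y).
#'
#' @name detection
NULL

luma <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

otsu_threshold <- function(values) {
  v <- pmin(pmax(values, 0), 1)
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = c(0, 1))
}

# Fill, per image row, the span between the first and last TRUE pixel.
# Turns the (green) board-surface mask into a solid board region that also
# covers the black line and the dot.
fill_rows <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (y in seq_len(nrow(mask))) {
    w <- which(mask[y, ])
    if (length(w) >= 2) out[y, w[1]:w[length(w)]] <- TRUE
    else if (length(w) == 1) out[y, w] <- TRUE
  }
  out
}

#' Detect the four corners of the target pattern
#'
#' Locates the drawn zig-zag line and returns its four L1-extreme on-pixels:
#' up-left = argmin(x+y), up-right = argmax(x-y), down-left = argmax(y-x),
#' down-right = argmax(x+y). The image is converted to grayscale (luma
#' weights) and dark pixels are thresholded within the board region; the board
#' region is found as the row-filled hull of green-dominant pixels, so that
#' dark clutter outside the board cannot masquerade as line pixels. When no
#' green board is visible the threshold is applied globally. The threshold
#' defaults to Otsu's method on the region and can be overridden.
#'
#' Corner detection is done once per recording session (the board is fixed to
#' the wall), so this routine favours robustness over speed.
#'
#' @param frame color frame array, dim c(H, W, 3), values in [0, 1].
#' @param dark_threshold optional fixed grayscale threshold in [0, 1];
#'   `NULL` = Otsu.
#' @param green_margin minimum G - max(R, B) for a pixel to count as board
#'   surface.
#' @return a [corner_set()].
#' @export
detect_corners <- function(frame, dark_threshold = NULL, green_margin = 0.1) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  g <- luma(frame)
  green <- frame[, , 2] - pmax(frame[, , 1], frame[, , 3]) >= green_margin
  if (sum(green) >= 100) {
    region <- fill_rows(green)
  } else {
    region <- matrix(TRUE, nrow(g), ncol(g))
  }
  vals <- g[region]
  if (length(vals) == 0 || stats::sd(vals) < 1e-6) {
    stop("NoPatternFound: image has no contrast within the search region",
         call. = FALSE)
  }
  thr <- if (is.null(dark_threshold)) otsu_threshold(vals) else dark_threshold
  dark <- region & (g < thr)
  idx <- which(dark)
  if (length(idx) == 0) {
    stop("NoPatternFound: no dark line pixels below threshold ",
         signif(thr, 3), call. = FALSE)
  }
  y <- (idx - 1L) %% nrow(g) + 1L
  x <- (idx - 1L) %/% nrow(g) + 1L
  # subpixel tip estimate: among the on-pixels within one pixel of the
  # extreme along the criterion diagonal, average the transverse coordinate;
  # the tip sits at the extreme level plus ~1/3 px of cap coverage lost to
  # center sampling
  pick <- function(ux, uy) {
    sc <- x * ux + y * uy
    sel <- sc >= max(sc) - 1 / sqrt(2)
    vc <- mean(-x[sel] * uy + y[sel] * ux)
    uc <- max(sc) + 0.3
    c(uc * ux - vc * uy, uc * uy + vc * ux)
  }
  s2 <- 1 / sqrt(2)
  corner_set(
    up_left    = pick(-s2, -s2),
    up_right   = pick(s2, -s2),
    down_left  = pick(-s2, s2),
    down_right = pick(s2, s2)
  )
}

#' Detect pattern corners from several frames of a session
#'
#' The laser dot can occlude the line wherever it currently sits — including,
#' at the trial start, the terminus apex that *is* one of the four extreme
#' corners — which would pull a single-frame corner estimate inward. Since
#' occlusion can only shrink the dark line (the red dot is never counted as
#' dark), sampling a handful of frames across the recording and keeping, for
#' each corner, the candidate most extreme under its own L1 criterion
#' recovers the uncontaminated corner set. Corners are still estimated once
#' per session.
#'
#' @param stream a [frame_stream()].
#' @param n_sample number of frames sampled evenly across the stream.
#' @param ... passed to [detect_corners()].
#' @return a [corner_set()].
#' @export
detect_corners_stream <- function(stream, n_sample = 5, ...) {
  idx <- unique(round(seq(1, stream$n_frames, length.out = n_sample)))
  sets <- lapply(idx, function(i) {
    tryCatch(detect_corners(stream$get_frame(i), ...), error = function(e) NULL)
  })
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0) {
    stop("NoPatternFound: corner detection failed in every sampled frame",
         call. = FALSE)
  }
  crit <- list(up_left = c(-1, -1), up_right = c(1, -1),
               down_left = c(-1, 1), down_right = c(1, 1))
  best <- lapply(names(crit), function(nm) {
    cand <- t(vapply(sets, function(s) s$points[nm, ], numeric(2)))
    cand[which.max(cand %*% crit[[nm]]), ]
  })
  corner_set(best[[1]], best[[2]], best[[3]], best[[4]])
}

#' Dot observation
#'
#' Result of laser-dot detection in one frame. When `detected` is `FALSE`
#' the geometric fields are `NA` (absent), never zero-filled.
#'
#' @param detected logical flag.
#' @param centroid_px length-2 (x, y) pixel centroid or `NA`.
#' @param area_px component area in pixels or `NA`.
#' @param pixels n x 2 (x, y) matrix of the component's pixels or `NULL`.
#' @param frame_index,time_s frame bookkeeping.
#' @export
dot_observation <- function(detected, centroid_px = c(NA_real_, NA_real_),
                            area_px = NA_integer_, pixels = NULL,
                            frame_index = NA_integer_, time_s = NA_real_) {
  structure(list(frame_index = frame_index, time_s = time_s,
                 detected = detected, centroid_px = centroid_px,
                 centroid_mm = c(NA_real_, NA_real_),
                 area_px = area_px, pixels = pixels, on_line = NA),
            class = "dot_observation")
}

#' @export
print.dot_observation <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("Laser dot at px (%.2f, %.2f), area %d px, frame %s\n",
                x$centroid_px[1], x$centroid_px[2], x$area_px,
                format(x$frame_index)))
  } else {
    cat("Laser dot not detected\n")
  }
  invisible(x)
}

#' Detect the laser dot in one frame
#'
#' Red-dominance binarization (`R >= t_abs` and `R - max(G, B) >= t_margin`,
#' plus near-saturated pixels `R >= white_core` to keep the blown-out laser
#' core), followed by artifact clearing: a 3x3 morphological opening, an area
#' band-pass `[min_dot_area, max_dot_area]`, and keep-largest among surviving
#' connected components. Absence of the dot (occlusion by hair/shoulder,
#' off-board pointing) is a valid observation, not an error.
#'
#' The candidate scan runs in compiled code over the full frame; morphology
#' and labelling then run on the candidates' bounding patch only.
#'
#' @param frame color frame array, dim c(H, W, 3), values in [0, 1].
#' @param t_abs absolute red threshold.
#' @param t_margin red-dominance margin over max(G, B).
#' @param white_core near-max red level accepted regardless of margin.
#' @param min_dot_area,max_dot_area component area band-pass in px.
#' @param exclusion optional logical H x W matrix of pixels to ignore.
#' @param opening_size structuring-element width for the opening (0 = skip).
#' @param frame_index,time_s bookkeeping copied into the observation.
#' @return a [dot_observation()].
#' @export
detect_dot <- function(frame, t_abs = 0.5, t_margin = 0.2, white_core = 0.97,
                       min_dot_area = 10, max_dot_area = 5000,
                       exclusion = NULL, opening_size = 3,
                       frame_index = NA_integer_, time_s = NA_real_) {
  d <- dim(frame)
  H <- d[1]; W <- d[2]
  none <- dot_observation(FALSE, frame_index = frame_index, time_s = time_s)
  cand <- red_candidates_cpp(frame, H * W, t_abs, t_margin, white_core)
  if (!is.null(exclusion)) cand <- cand[!exclusion[cand]]
  if (length(cand) == 0) return(none)
  cy <- (cand - 1L) %% H + 1L
  cx <- (cand - 1L) %/% H + 1L
  pad <- max(2L, opening_size)
  y0 <- max(1L, min(cy) - pad); y1 <- min(H, max(cy) + pad)
  x0 <- max(1L, min(cx) - pad); x1 <- min(W, max(cx) + pad)
  raw <- matrix(0, y1 - y0 + 1L, x1 - x0 + 1L)
  raw[cbind(cy - y0 + 1L, cx - x0 + 1L)] <- 1
  patch <- if (opening_size > 0) {
    EBImage::opening(raw, EBImage::makeBrush(opening_size, shape = "box"))
  } else raw
  lab <- EBImage::bwlabel(patch)
  nlab <- max(lab)
  if (nlab == 0) return(none)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= min_dot_area & areas <= max_dot_area)
  if (length(keep) == 0) return(none)
  best <- keep[which.max(areas[keep])]
  # opening-by-reconstruction: the opening selects the component and clears
  # speckles, but erodes the rim; recover the full candidate component the
  # surviving pixels belong to, so centroid and line-contact use the true
  # extent
  lab_raw <- EBImage::bwlabel(raw)
  raw_id <- lab_raw[which(lab == best)[1]]
  pix <- which(lab_raw == raw_id)
  py <- (pix - 1L) %% nrow(patch) + y0
  px <- (pix - 1L) %/% nrow(patch) + x0
  dot_observation(TRUE,
                  centroid_px = c(mean(px), mean(py)),
                  area_px = length(pix),
                  pixels = cbind(x = px, y = py),
                  frame_index = frame_index, time_s = time_s)
}

#' Is the dot touching the target line?
#'
#' `TRUE` when the detected dot's pixel set shares at least `min_overlap_px`
#' pixels with the rasterized line mask (default: one shared pixel).
#'
#' @param dot a [dot_observation()].
#' @param mask logical line mask from [line_mask()], same frame dimensions.
#' @param min_overlap_px minimum number of shared pixels.
#' @return logical, or `NA` when the dot was not detected.
#' @export
classify_on_line <- function(dot, mask, min_overlap_px = 1) {
  if (!isTRUE(dot$detected)) return(NA)
  p <- dot$pixels
  sum(mask[cbind(p[, 2], p[, 1])]) >= min_overlap_px
}
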