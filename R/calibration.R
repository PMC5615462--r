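#' Plane homography utilities and pixel-to-mm calibration
#'
#' The camera views the board at an angle, so the pixel-to-board-plane mapping
#' is a projective homography, estimated exactly from the four detected
#' pattern corners. Pixel convention everywhere: origin at the top-left, x
#' rightward, y downward, pixel centers at integer coordinates starting at
#' (1, 1).
#'
#' @name calibration
NULL

#' Fit a homography from four (or more) point pairs
#'
#' Direct linear transform: solves for the 3x3 matrix `H` (with `H[3,3] = 1`)
#' mapping `src` to `dst` homogeneous plane coordinates. With exactly four
#' pairs the fit is exact.
#'
#' @param src,dst n x 2 matrices (n >= 4) of corresponding points.
#' @return 3 x 3 homography matrix.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) >= 4, nrow(src) == nrow(dst))
  n <- nrow(src)
  A <- matrix(0, 2 * n, 8)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(
    if (n == 4) solve(A, b) else qr.solve(A, b),
    error = function(e) stop("degenerate point configuration: ",
                             conditionMessage(e), call. = FALSE)
  )
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param p n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, p) {
  p <- matrix(as.numeric(p), ncol = 2)
  w <- H[3, 1] * p[, 1] + H[3, 2] * p[, 2] + H[3, 3]
  cbind(x = (H[1, 1] * p[, 1] + H[1, 2] * p[, 2] + H[1, 3]) / w,
        y = (H[2, 1] * p[, 1] + H[2, 2] * p[, 2] + H[2, 3]) / w)
}

#' Corner set
#'
#' Container for the four detected pattern corners in pixel coordinates.
#' @param up_left,up_right,down_left,down_right length-2 pixel points (x, y).
#' @export
corner_set <- function(up_left, up_right, down_left, down_right) {
  pts <- rbind(up_left = up_left, up_right = up_right,
               down_left = down_left, down_right = down_right)
  stopifnot(ncol(pts) == 2)
  colnames(pts) <- c("x", "y")
  if (anyDuplicated(pts) > 0) {
    stop("degenerate corner set: corners are not pairwise distinct")
  }
  # shoelace area of the quadrilateral UL, UR, DR, DL
  q <- pts[c(1, 2, 4, 3), ]
  area <- abs(sum(q[, 1] * q[c(2, 3, 4, 1), 2] - q[c(2, 3, 4, 1), 1] * q[, 2])) / 2
  if (area < 1) {
    stop("degenerate corner set: quadrilateral is (near-)collinear, area ",
         signif(area, 3), " px^2")
  }
  structure(list(points = pts, area_px2 = area), class = "corner_set")
}

#' @export
print.corner_set <- function(x, ...) {
  cat("Detected pattern corners (px):\n")
  print(round(x$points, 2))
  invisible(x)
}

#' Calibrate the pixel-to-mm mapping from detected corners
#'
#' Fits the exact homography taking the four detected corner pixels onto the
#' pattern's reference corner positions in mm (see [pattern_corners()]). The
#' RMS reprojection error of the corners (in px, via the inverse map) is
#' stored for sanity checking; it is numerically zero for a four-point exact
#' fit.
#'
#' @param corners a `corner_set` from [detect_corners()].
#' @param pattern the `zigzag_pattern` being viewed.
#' @return an object of class `laser_calibration` with fields `homography`
#'   (px to mm), `inverse` (mm to px) and `rms_reprojection_px`.
#' @export
calibrate <- function(corners, pattern) {
  stopifnot(inherits(corners, "corner_set"), inherits(pattern, "zigzag_pattern"))
  ref <- pattern_corners(pattern)
  dst <- rbind(ref$up_left, ref$up_right, ref$down_left, ref$down_right)
  src <- corners$points
  H <- fit_homography(src, dst)
  if (abs(det(H)) < 1e-12) stop("calibration failed: singular homography")
  Hinv <- solve(H)
  back <- apply_homography(Hinv, dst)
  rms <- sqrt(mean(rowSums((back - src)^2)))
  structure(list(homography = H, inverse = Hinv,
                 rms_reprojection_px = rms,
                 corners_px = src, corners_mm = dst),
            class = "laser_calibration")
}

#' @export
print.laser_calibration <- function(x, ...) {
  cat("Pixel-to-mm plane calibration (4-corner homography)\n")
  cat(sprintf("  rms corner reprojection: %.4g px\n", x$rms_reprojection_px))
  invisible(x)
}

#' Convert pixel points to mm (and back)
#'
#' @param calibration a `laser_calibration`.
#' @param p n x 2 points.
#' @export
px_to_mm <- function(calibration, p) apply_homography(calibration$homography, p)

#' @rdname px_to_mm
#' @export
mm_to_px <- function(calibration, p) apply_homography(calibration$inverse, p)

#' Refine a calibration by registering the drawn line to the model
#'
#' The four-corner fit is exact at the corners but inherits their one-pixel
#' quantization, which displaces the interior mapping by a few tenths of a mm
#' at 720p. This refinement performs a fine registration: dark line pixels
#' are extracted from a frame (same thresholding as [detect_corners()]),
#' mapped to mm, and the eight homography parameters are optimized to
#' minimize the mean squared distance of those pixels to the model polyline,
#' with the corner correspondences kept as a weak anchor. The dark band is
#' symmetric about the printed line, so the least-squares optimum centers the
#' band on the polyline; the anchor removes the residual scale freedom at
#' negligible cost (its gradient balance sits at micrometre shrinkage).
#' Occlusion of parts of the line (by the dot or the hand) only removes dark
#' pixels symmetrically and therefore does not bias the registration.
#'
#' @param frame a frame of the session (any frame showing the pattern).
#' @param pattern the `zigzag_pattern`.
#' @param calibration initial `laser_calibration` from [calibrate()].
#' @param n_sample maximum number of dark pixels used.
#' @param anchor_weight weight of the squared corner-residual term (mm^2)
#'   relative to the mean squared pixel-to-line distance.
#' @param dark_threshold optional fixed threshold, as in [detect_corners()].
#' @return a refined `laser_calibration` (same structure; `refined = TRUE`).
#' @export
refine_calibration <- function(frame, pattern, calibration, n_sample = 3000,
                               anchor_weight = 0.05, dark_threshold = NULL) {
  g <- luma(frame)
  green <- frame[, , 2] - pmax(frame[, , 1], frame[, , 3]) >= 0.1
  region <- if (sum(green) >= 100) fill_rows(green) else
    matrix(TRUE, nrow(g), ncol(g))
  thr <- if (is.null(dark_threshold)) otsu_threshold(g[region]) else
    dark_threshold
  idx <- which(region & g < thr)
  if (length(idx) < 50) return(calibration)
  if (length(idx) > n_sample) {
    idx <- idx[round(seq(1, length(idx), length.out = n_sample))]
  }
  p <- cbind((idx - 1L) %/% nrow(g) + 1L, (idx - 1L) %% nrow(g) + 1L)
  apex <- pattern$apex_points_mm
  src <- calibration$corners_px
  ref <- calibration$corners_mm
  loss <- function(h) {
    H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
    mm <- apply_homography(H, p)
    d <- dist_to_polyline(mm, apex)
    cr <- apply_homography(H, src) - ref
    mean(d^2) + anchor_weight * mean(rowSums(cr^2))
  }
  h0 <- as.vector(t(calibration$homography))[1:8]
  # parameters live on very different scales; optimize on relative scale
  sc <- ifelse(abs(h0) > 1e-8, abs(h0), 1e-6)
  opt <- stats::optim(h0 / sc, function(z) loss(z * sc),
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  H <- matrix(c(opt$par * sc, 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12) return(calibration)
  Hinv <- solve(H)
  back <- apply_homography(Hinv, ref)
  structure(list(homography = H, inverse = Hinv,
                 rms_reprojection_px = sqrt(mean(rowSums((back - src)^2))),
                 corners_px = src, corners_mm = ref, refined = TRUE),
            class = "laser_calibration")
}

#' Rasterized mask of the target line in pixel space
#'
#' Marks every pixel whose center maps, through the calibration, to a board
#' position within `line_width_mm / 2 + tol_mm` of the center polyline. Used
#' by the on-line classifier ("touching the black line").
#'
#' @param pattern a `zigzag_pattern`.
#' @param calibration a `laser_calibration`.
#' @param image_dims c(width, height) of the frames in px.
#' @param tol_mm extra tolerance added to the line half-width (default 0).
#' @return logical matrix of dim c(height, width); `mask[y, x]` indexes pixel
#'   (x, y).
#' @export
line_mask <- function(pattern, calibration, image_dims, tol_mm = 0) {
  W <- image_dims[1]; H <- image_dims[2]
  half <- pattern$line_width_mm / 2 + tol_mm
  mask <- matrix(FALSE, H, W)
  if (half <= 0) return(mask)
  # candidate pixel window: project the polyline bbox (padded) into px space
  a <- pattern$apex_points_mm
  pad <- half + 2
  box <- cbind(c(min(a[, 1]) - pad, max(a[, 1]) + pad, min(a[, 1]) - pad,
                 max(a[, 1]) + pad),
               c(min(a[, 2]) - pad, min(a[, 2]) - pad, max(a[, 2]) + pad,
                 max(a[, 2]) + pad))
  bpx <- apply_homography(calibration$inverse, box)
  xs <- max(1L, floor(min(bpx[, 1]))):min(W, ceiling(max(bpx[, 1])))
  ys <- max(1L, floor(min(bpx[, 2]))):min(H, ceiling(max(bpx[, 2])))
  if (!length(xs) || !length(ys)) return(mask)
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  mm <- apply_homography(calibration$homography, grid)
  d <- dist_to_polyline(mm, a)
  hit <- d <= half
  mask[cbind(grid[hit, 2], grid[hit, 1])] <- TRUE
  mask
}
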