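#' Zig-zag target pattern
#'
#' Physical model of the printed tracing target: a thin black zig-zag center
#' line on a green board. All coordinates are in millimetres in the board
#' plane, origin at the top-left corner of the board, x rightward, y downward
#' (matching the raster convention used for pixels). The defaults describe the
#' standard test target: an A3 landscape board (420 x 297 mm) carrying a 1 mm
#' thick center line whose total trace length is 1 m.
#'
#' The apex layout is parameterized by the number of straight segments and the
#' horizontal span; the segment amplitude is solved from the trace-length
#' constraint. For `n` equal-length segments of horizontal run `span/n`, each
#' segment must have length `trace/n`, so the vertical rise is
#' `sqrt((trace/n)^2 - (span/n)^2)`; the layout is infeasible when that is not
#' a positive real, or when it does not fit on the board.
#'
#' @param n_segments number of straight segments (>= 2).
#' @param board_width_mm,board_height_mm board dimensions in mm.
#' @param trace_length_mm total arc length of the center polyline in mm.
#' @param span_mm horizontal extent of the polyline in mm (default: board
#'   width minus a 10 mm margin on each side).
#' @param line_width_mm thickness of the printed line in mm.
#' @param start_at top or bottom: vertical position of the first (leftmost)
#'   apex.
#' @return an object of class `zigzag_pattern` with fields
#'   `apex_points_mm` (ordered (n_segments+1) x 2 matrix), `line_width_mm`,
#'   `trace_length_mm`, `board_width_mm`, `board_height_mm`,
#'   `center_cross_mm` (point at half arc length).
#' @examples
#' p <- zigzag_pattern()
#' polyline_length(p$apex_points_mm)  # 1000
#' @export
zigzag_pattern <- function(n_segments = 5,
                           board_width_mm = 420,
                           board_height_mm = 297,
                           trace_length_mm = 1000,
                           span_mm = board_width_mm - 20,
                           line_width_mm = 1,
                           start_at = c("top", "bottom")) {
  start_at <- match.arg(start_at)
  if (n_segments < 2) {
    stop("n_segments must be >= 2 (a single segment is a straight line, ",
         "not a zig-zag)")
  }
  stopifnot(line_width_mm > 0, trace_length_mm > 0,
            span_mm > 0, span_mm <= board_width_mm)
  seg_len <- trace_length_mm / n_segments
  run <- span_mm / n_segments
  amp2 <- seg_len^2 - run^2
  if (amp2 <= 0) {
    stop("infeasible geometry: trace length ", trace_length_mm,
         " mm cannot be reached with ", n_segments,
         " segments over a ", span_mm, " mm span (segments would be straight)")
  }
  amp <- sqrt(amp2)
  if (amp + line_width_mm > board_height_mm) {
    stop("infeasible geometry: required amplitude ", round(amp, 2),
         " mm exceeds the board height (", board_height_mm, " mm)")
  }
  x0 <- (board_width_mm - span_mm) / 2
  yc <- board_height_mm / 2
  i <- 0:n_segments
  ys <- yc + ifelse(i %% 2 == 0, -amp / 2, amp / 2)
  if (start_at == "bottom") ys <- 2 * yc - ys
  apex <- cbind(x = x0 + i * run, y = ys)
  obj <- new_zigzag_pattern(apex, line_width_mm, trace_length_mm,
                            board_width_mm, board_height_mm)
  obj
}

#' Low-level pattern constructor
#'
#' Builds a `zigzag_pattern` from an explicit apex list, validating the
#' geometric invariants (arc length matches the declared trace length, all
#' apexes on the board, positive line width). Useful for non-standard targets
#' such as a single straight calibration line.
#'
#' @param apex_points_mm ordered m x 2 matrix of apex coordinates in mm.
#' @param line_width_mm,trace_length_mm,board_width_mm,board_height_mm see
#'   [zigzag_pattern()].
#' @export
new_zigzag_pattern <- function(apex_points_mm, line_width_mm,
                               trace_length_mm = polyline_length(apex_points_mm),
                               board_width_mm = 420, board_height_mm = 297) {
  apex_points_mm <- as.matrix(apex_points_mm)
  stopifnot(ncol(apex_points_mm) == 2, nrow(apex_points_mm) >= 2,
            line_width_mm > 0)
  colnames(apex_points_mm) <- c("x", "y")
  len <- polyline_length(apex_points_mm)
  if (abs(len - trace_length_mm) > 1e-6 * max(1, trace_length_mm)) {
    stop("polyline arc length (", len, " mm) does not match trace_length_mm (",
         trace_length_mm, " mm)")
  }
  if (any(apex_points_mm[, 1] < 0) || any(apex_points_mm[, 1] > board_width_mm) ||
      any(apex_points_mm[, 2] < 0) || any(apex_points_mm[, 2] > board_height_mm)) {
    stop("apex points must lie inside the board rectangle")
  }
  structure(list(
    apex_points_mm = apex_points_mm,
    line_width_mm = line_width_mm,
    trace_length_mm = trace_length_mm,
    board_width_mm = board_width_mm,
    board_height_mm = board_height_mm,
    center_cross_mm = as.numeric(point_at_arc(apex_points_mm,
                                              trace_length_mm / 2))
  ), class = "zigzag_pattern")
}

#' @export
print.zigzag_pattern <- function(x, ...) {
  cat("Zig-zag target pattern\n")
  cat(sprintf("  board: %g x %g mm, line width %g mm\n",
              x$board_width_mm, x$board_height_mm, x$line_width_mm))
  cat(sprintf("  %d segments, trace length %g mm\n",
              nrow(x$apex_points_mm) - 1, x$trace_length_mm))
  cat(sprintf("  center cross at (%.1f, %.1f) mm\n",
              x$center_cross_mm[1], x$center_cross_mm[2]))
  invisible(x)
}

#' @export
plot.zigzag_pattern <- function(x, ...) {
  plot(NA, xlim = c(0, x$board_width_mm), ylim = c(x$board_height_mm, 0),
       asp = 1, xlab = "x (mm)", ylab = "y (mm)", main = "Zig-zag target", ...)
  rect(0, x$board_height_mm, x$board_width_mm, 0, col = "#c8e6c9", border = NA)
  lines(x$apex_points_mm, lwd = 2)
  pc <- pattern_corners(x)
  pts <- do.call(rbind, pc)
  points(pts, pch = 0, col = "red", cex = 1.5)
  points(x$center_cross_mm[1], x$center_cross_mm[2], pch = 3)
  invisible(x)
}

# -- polyline helpers (mm plane) ---------------------------------------------

#' Arc length of a polyline
#' @param pts m x 2 matrix of vertices.
#' @export
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Point(s) on a polyline at given arc length(s)
#'
#' @param pts m x 2 matrix of vertices.
#' @param s arc length(s) from the first vertex; clamped to `[0, total]`.
#' @return length(s) x 2 matrix of coordinates.
#' @export
point_at_arc <- function(pts, s) {
  pts <- as.matrix(pts)
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lens))
  t <- (s - cum[i]) / lens[i]
  cbind(x = pts[i, 1] + t * seg[i, 1], y = pts[i, 2] + t * seg[i, 2])
}

#' Unit normal of the polyline segment at given arc length(s)
#'
#' Left-hand normal of the segment containing arc position `s`; used to apply
#' lateral offsets to a point travelling along the line.
#' @inheritParams point_at_arc
#' @export
normal_at_arc <- function(pts, s) {
  pts <- as.matrix(pts)
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lens))
  cbind(x = -seg[i, 2] / lens[i], y = seg[i, 1] / lens[i])
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to the polyline.
#' @param p n x 2 matrix of query points.
#' @param pts m x 2 matrix of polyline vertices.
#' @export
dist_to_polyline <- function(p, pts) {
  p <- matrix(as.numeric(p), ncol = 2)
  pts <- as.matrix(pts)
  d2 <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]
    ab <- pts[i + 1, ] - a
    l2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / l2
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Reference corner positions of the drawn pattern
#'
#' The four extreme points of the drawn (inked) line under the L1 criteria
#' used by the corner detector: up-left = argmin(x+y), up-right = argmax(x-y),
#' down-left = argmax(y-x), down-right = argmax(x+y), each pushed outward by
#' half the line width along the criterion's diagonal. For a zig-zag these sit
#' on the extreme apexes (not, in general, on the bounding-box corners).
#'
#' @param pattern a `zigzag_pattern`.
#' @param step_mm densification step along the polyline.
#' @return list with elements `up_left`, `up_right`, `down_left`,
#'   `down_right`, each a length-2 mm coordinate.
#' @export
pattern_corners <- function(pattern, step_mm = 0.5) {
  s <- seq(0, pattern$trace_length_mm, by = step_mm)
  pts <- point_at_arc(pattern$apex_points_mm, s)
  h <- pattern$line_width_mm / 2 / sqrt(2)
  list(
    up_left    = pts[which.min(pts[, 1] + pts[, 2]), ] + c(-h, -h),
    up_right   = pts[which.max(pts[, 1] - pts[, 2]), ] + c(h, -h),
    down_left  = pts[which.max(pts[, 2] - pts[, 1]), ] + c(-h, h),
    down_right = pts[which.max(pts[, 1] + pts[, 2]), ] + c(h, h)
  )
}

#' Trace termini of the pattern
#'
#' Start and end of the center polyline as drawn left-to-right. The trial
#' start terminus depends on the drawing direction: clockwise (left-to-right)
#' starts at the left terminus.
#' @param pattern a `zigzag_pattern`.
#' @return list with `left` and `right` mm points.
#' @export
pattern_termini <- function(pattern) {
  a <- pattern$apex_points_mm
  if (a[1, 1] <= a[nrow(a), 1]) {
    list(left = a[1, ], right = a[nrow(a), ])
  } else {
    list(left = a[nrow(a), ], right = a[1, ])
  }
}

# -- JSON (de)serialization --------------------------------------------------

#' Write / read a pattern definition as JSON
#'
#' @param pattern a `zigzag_pattern`.
#' @param path file path.
#' @export
write_pattern_json <- function(pattern, path) {
  x <- list(
    apex_points_mm = unclass(pattern$apex_points_mm),
    line_width_mm = pattern$line_width_mm,
    trace_length_mm = pattern$trace_length_mm,
    board_width_mm = pattern$board_width_mm,
    board_height_mm = pattern$board_height_mm
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pattern_json
#' @export
read_pattern_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_zigzag_pattern(x$apex_points_mm, x$line_width_mm, x$trace_length_mm,
                     x$board_width_mm, x$board_height_mm)
}
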