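#' Run configuration
#'
#' All tunable parameters of the scoring pipeline with their defaults. Every
#' field is documented here once; unknown fields in a config file are
#' rejected.
#'
#' @param t_abs,t_margin,white_core laser-dot binarization thresholds
#'   (intensities in [0, 1]); see [detect_dot()].
#' @param min_dot_area,max_dot_area dot component area band-pass in px.
#' @param opening_size structuring-element width of the artifact-clearing
#'   opening (px).
#' @param dark_threshold fixed grayscale threshold for corner detection, or
#'   `NULL` for Otsu.
#' @param radius_mm start/stop corner radius used by trial segmentation (mm).
#' @param refine_calibration register the drawn line to the model after the
#'   four-corner fit (see [refine_calibration()]); recommended.
#' @param dwell_frames frames the dot must stay within `radius_mm` for the
#'   dwell to count.
#' @param acuity_denominator `"all"` (every frame in the trial window counts,
#'   undetected frames score off-line; the default, since acuity is defined
#'   over trial time) or `"detected"`.
#' @param on_line_tol_mm extra mm tolerance added to the line half-width when
#'   building the on-line mask. The default `NULL` means auto: an eighth of
#'   the pixel pitch at the board center, which compensates the area contact
#'   lost when both the dot and the line are sampled at pixel centers.
#' @param min_overlap_px shared pixels needed to call the dot "touching".
#' @param speed_mode `"arc"` (arc length of the centroid trajectory per unit
#'   time) or `"nominal"` (trace length / duration).
#' @param smooth_window moving-average window (frames) applied to the
#'   centroid trajectory before arc-length integration. Default 1 (off):
#'   centroid noise is far smaller than genuine frame-to-frame lateral
#'   motion, which smoothing would clip, shortening the measured path.
#' @param interpolate_gaps bridge undetected runs of up to this many frames by
#'   linear interpolation of the centroid (0 = never; interpolated frames stay
#'   `detected = FALSE` and are logged).
#' @param icc_form which ICC form the report headlines: `"consistency"` or
#'   `"agreement"` (both are always computed).
#' @param holm apply Holm correction across conditions in reliability
#'   reports.
#' @param seed seed for any randomized step.
#' @return an object of class `run_config` (a validated named list).
#' @export
run_config <- function(t_abs = 0.5, t_margin = 0.2, white_core = 0.97,
                       min_dot_area = 10, max_dot_area = 5000,
                       opening_size = 3, dark_threshold = NULL,
                       radius_mm = 10, dwell_frames = 5, refine_calibration = TRUE,
                       acuity_denominator = c("all", "detected"),
                       on_line_tol_mm = NULL, min_overlap_px = 1,
                       speed_mode = c("arc", "nominal"), smooth_window = 1,
                       interpolate_gaps = 0,
                       icc_form = c("consistency", "agreement"),
                       holm = FALSE, seed = 1) {
  cfg <- list(
    t_abs = t_abs, t_margin = t_margin, white_core = white_core,
    min_dot_area = min_dot_area, max_dot_area = max_dot_area,
    opening_size = opening_size, dark_threshold = dark_threshold,
    radius_mm = radius_mm, dwell_frames = dwell_frames,
    refine_calibration = refine_calibration,
    acuity_denominator = match.arg(acuity_denominator),
    on_line_tol_mm = on_line_tol_mm, min_overlap_px = min_overlap_px,
    speed_mode = match.arg(speed_mode), smooth_window = smooth_window,
    interpolate_gaps = interpolate_gaps,
    icc_form = match.arg(icc_form), holm = holm, seed = seed
  )
  stopifnot(cfg$radius_mm > 0, cfg$dwell_frames >= 1,
            cfg$min_dot_area >= 1, cfg$max_dot_area >= cfg$min_dot_area,
            cfg$smooth_window >= 1, cfg$interpolate_gaps >= 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields not in [run_config()] are rejected with an error naming them.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, x)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Scoring run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(x[[nm]])) "auto" else format(x[[nm]])))
  }
  invisible(x)
}
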