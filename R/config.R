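#' Analysis configuration
#'
#' Per-image segmentation and extraction parameters.  `K` is the number of
#' intensity clusters, `j` the 1-based index (by ascending cluster mean
#' intensity) of the cluster containing the vertebrae, `d` the diameter in
#' pixels of the disk structuring element used to erode the cluster
#' complement, and `delta` the proximity threshold in pixels for accepting a
#' cluster boundary point as part of the spinolaminar line.  Clinical
#' radiographs in this workflow typically use `K` in 4..7, `j` in
#' `{K - 1, K - 2}`, `d` around 13-68 px and `delta` around 18-82 px,
#' scaling with image resolution.
#'
#' @param K cluster count, 2..12.
#' @param j selected cluster index, 1..K.
#' @param d disk structuring-element diameter in pixels, >= 1.
#' @param delta proximity threshold in pixels, >= 0.
#' @param roi optional region of interest `c(row_min, row_max, col_min,
#'   col_max)`, 0-based inclusive pixel coordinates.
#' @param plate_length_L optional plate length in pixels, used to express
#'   curvature in nondimensional 1/L units.
#' @param fit_axis `"auto"`, `"x"` (column as the ordered coordinate) or
#'   `"y"` (row).
#' @param seed integer seed forwarded to every stochastic stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(K, j, d, delta, roi = NULL, plate_length_L = NULL,
                            fit_axis = c("auto", "x", "y"), seed = 0L) {
  fit_axis <- match.arg(fit_axis)
  if (!is_count(K, 2L) || K > 12L)
    stop_spinocurve("K must be an integer in 2..12", "validation_error")
  if (!is_count(j, 1L) || j > K)
    stop_spinocurve("j must be an integer in 1..K", "validation_error")
  if (!is_count(d, 1L))
    stop_spinocurve("d must be a positive integer", "validation_error")
  if (length(delta) != 1L || !is.numeric(delta) || is.na(delta) || delta < 0)
    stop_spinocurve("delta must be a nonnegative number", "validation_error")
  if (!is.null(roi)) {
    roi <- as.numeric(roi)
    if (length(roi) != 4L || anyNA(roi) || roi[1] > roi[2] || roi[3] > roi[4] ||
        any(roi < 0) || any(roi != floor(roi)))
      stop_spinocurve(
        "roi must be c(row_min, row_max, col_min, col_max), 0-based, ordered",
        "validation_error")
  }
  if (!is.null(plate_length_L) &&
      (!is.numeric(plate_length_L) || length(plate_length_L) != 1L ||
       plate_length_L <= 0))
    stop_spinocurve("plate_length_L must be a positive number", "validation_error")
  if (!is_count(seed, 0L) && !is_count(-seed, 0L))
    stop_spinocurve("seed must be an integer", "validation_error")
  structure(
    list(K = as.integer(K), j = as.integer(j), d = as.integer(d),
         delta = as.numeric(delta), roi = roi,
         plate_length_L = plate_length_L, fit_axis = fit_axis,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> K=%d j=%d d=%d delta=%g fit_axis=%s seed=%d\n",
              x$K, x$j, x$d, x$delta, x$fit_axis, x$seed))
  if (!is.null(x$roi))
    cat(sprintf("  roi: rows %d..%d, cols %d..%d\n",
                x$roi[1], x$roi[2], x$roi[3], x$roi[4]))
  if (!is.null(x$plate_length_L))
    cat(sprintf("  plate_length_L: %g px\n", x$plate_length_L))
  invisible(x)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Accepted keys are exactly `K, j, d, delta, roi, plate_length_L, fit_axis,
#' seed`; missing optional keys get defaults (`fit_axis = "auto"`,
#' `seed = 0`).  All invariants of [analysis_config()] are validated.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param image optional [gray_image()]; when given, the ROI is checked to
#'   lie inside the image.
#' @return An [analysis_config()].
#' @export
load_config <- function(path, image = NULL) {
  if (!file.exists(path))
    stop_spinocurve(sprintf("config not found: %s", path), "validation_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_spinocurve(sprintf("unsupported config format: .%s", ext),
                    "validation_error")
  )
  known <- c("K", "j", "d", "delta", "roi", "plate_length_L", "fit_axis", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_spinocurve(paste0("unknown config keys: ", paste(extra, collapse = ", ")),
                    "validation_error")
  for (key in c("K", "j", "d", "delta"))
    if (is.null(raw[[key]]))
      stop_spinocurve(sprintf("config key `%s` is required", key),
                      "validation_error")
  cfg <- analysis_config(
    K = raw$K, j = raw$j, d = raw$d, delta = raw$delta,
    roi = raw$roi, plate_length_L = raw$plate_length_L,
    fit_axis = if (is.null(raw$fit_axis)) "auto" else raw$fit_axis,
    seed = if (is.null(raw$seed)) 0L else raw$seed
  )
  if (!is.null(image) && !is.null(cfg$roi)) check_roi(cfg$roi, image)
  cfg
}

check_roi <- function(roi, img) {
  if (roi[2] >= img$height || roi[4] >= img$width)
    stop_spinocurve("roi extends outside the image", "validation_error")
  invisible(roi)
}

#' Write an analysis configuration to YAML
#'
#' @param cfg an [analysis_config()].
#' @param path output path (`.yaml`).
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  lst <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(lapply(unclass(lst), function(v)
    if (is.numeric(v)) as.vector(v) else v), path)
  invisible(path)
}
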