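#' Spinolaminar point set
#'
#' Ordered collection of candidate landmark points in 0-based (row, col)
#' pixel coordinates, with provenance and an ROI flag.
#'
#' @param points two-column matrix or data frame of (row, col) coordinates.
#' @param source provenance tag (image id, config summary).
#' @param roi_applied logical flag.
#' @return An object of class `sl_point_set`.
#' @export
sl_point_set <- function(points, source = NA_character_, roi_applied = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop_spinocurve("points must have two columns (row, col)", "validation_error")
  colnames(points) <- c("row", "col")
  points <- unique(points)
  structure(list(points = points, source = source, roi_applied = roi_applied),
            class = "sl_point_set")
}

#' @export
print.sl_point_set <- function(x, ...) {
  cat(sprintf("<sl_point_set> %d point(s)%s\n", nrow(x$points),
              if (x$roi_applied) " (ROI applied)" else ""))
  invisible(x)
}

#' Select landmark points by proximity to the reference boundary
#'
#' A boundary point `p` of the selected cluster is kept iff its minimum
#' Euclidean distance to the reference-region boundary `sigma_1` is at most
#' `delta`.  Selection is per point by default; `whole_loop = TRUE` keeps
#' or drops entire loops by whether any of their points qualifies.
#'
#' @param cluster_boundaries a `contour_set` of the selected cluster mask
#'   (candidates), or a two-column point matrix.
#' @param reference_boundary closed loop (two-column matrix of (row, col)
#'   points): the outer boundary of the reference region.
#' @param delta proximity threshold in pixels, >= 0.
#' @param whole_loop keep whole loops instead of single points.
#' @param source provenance tag for the result.
#' @return An [sl_point_set()] of the selected points (duplicates removed).
#' @export
select_sl_points <- function(cluster_boundaries, reference_boundary, delta,
                             whole_loop = FALSE, source = NA_character_) {
  if (length(delta) != 1L || !is.numeric(delta) || delta < 0)
    stop_spinocurve("delta must be a nonnegative number", "validation_error")
  ref <- as.matrix(reference_boundary)
  if (nrow(ref) == 0L)
    stop_spinocurve("reference boundary is empty", "validation_error")
  loops <- if (inherits(cluster_boundaries, "contour_set"))
    cluster_boundaries$boundaries else list(as.matrix(cluster_boundaries))
  if (length(loops) == 0L || all(vapply(loops, nrow, 0L) == 0L)) {
    warn_spinocurve("no candidate boundaries: empty selection",
                    "empty_selection_warning")
    return(sl_point_set(matrix(numeric(0), 0, 2), source = source))
  }
  kept <- lapply(loops, function(b) {
    n <- nrow(b)
    if (n > 1L && all(b[1, ] == b[n, ]))  # drop the closing point of a loop
      b <- b[-n, , drop = FALSE]
    b <- unique(b)
    d <- .cpp_min_dist(as.numeric(b[, 1]), as.numeric(b[, 2]),
                       as.numeric(ref[, 1]), as.numeric(ref[, 2]))
    if (whole_loop) {
      if (any(d <= delta)) b else b[0, , drop = FALSE]
    } else {
      b[d <= delta, , drop = FALSE]
    }
  })
  pts <- do.call(rbind, kept)
  if (nrow(pts) == 0L)
    warn_spinocurve("no boundary points within delta of the reference boundary",
                    "empty_selection_warning")
  sl_point_set(pts, source = source)
}

#' Crop a point set to a region of interest
#'
#' Retains points with `row_min <= row <= row_max` and `col_min <= col <=
#' col_max`.  Applying the same ROI twice equals applying it once.
#'
#' @param points an [sl_point_set()].
#' @param roi `c(row_min, row_max, col_min, col_max)`, 0-based inclusive.
#' @return An [sl_point_set()] with `roi_applied = TRUE`.
#' @export
apply_roi <- function(points, roi) {
  stopifnot(inherits(points, "sl_point_set"))
  roi <- as.numeric(roi)
  if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4])
    stop_spinocurve("roi must be c(row_min, row_max, col_min, col_max)",
                    "validation_error")
  p <- points$points
  keep <- p[, 1] >= roi[1] & p[, 1] <= roi[2] &
          p[, 2] >= roi[3] & p[, 2] <= roi[4]
  sl_point_set(p[keep, , drop = FALSE], source = points$source,
               roi_applied = TRUE)
}

#' Run the landmark-extraction pipeline on one image
#'
#' Orchestrates segmentation, erosion, labeling, reference-region selection,
#' boundary tracing, proximity selection and ROI cropping.  With
#' `side = "anterior"` the image is mirrored before segmentation and the
#' returned coordinates are mapped back to the unmirrored frame, so the
#' pipeline traces the anterior vertebral/plate contour instead of the
#' spinolaminar line.
#'
#' @param img a [gray_image()].
#' @param cfg an [analysis_config()]; `cfg$roi` is interpreted in the
#'   original (unmirrored) image frame.
#' @param side `"posterior"` (spinolaminar line) or `"anterior"` (plate).
#' @param keep_stages if `TRUE`, attach intermediate stage results
#'   (clusters, eroded mask, labels, boundaries) as attribute `stages`.
#' @return An [sl_point_set()].
#' @export
extract_landmark_points <- function(img, cfg, side = c("posterior", "anterior"),
                                    keep_stages = FALSE) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "analysis_config"))
  side <- match.arg(side)
  if (!is.null(cfg$roi)) check_roi(cfg$roi, img)
  work <- if (side == "anterior") mirror_image(img) else img

  clusters <- kmeans_segment(work, cfg$K, seed = cfg$seed)
  if (cfg$j > clusters$K)
    stop_spinocurve(sprintf(
      "cluster index j = %d exceeds effective K = %d", cfg$j, clusters$K),
      "validation_error")
  Sj <- select_cluster(clusters, cfg$j)
  M <- erode_inverse(Sj, cfg$d)
  lab <- label_components(M, 8L)
  ref_label <- pick_reference_region(lab, 3L)
  ref_loop <- trace_one_boundary(lab$label_map, ref_label)
  cand <- trace_boundaries(Sj, source_mask = sprintf("S_%d", cfg$j))
  pts <- select_sl_points(cand, ref_loop, cfg$delta,
                          source = sprintf("%s/K=%d,j=%d,d=%d,delta=%g",
                                           side, cfg$K, cfg$j, cfg$d, cfg$delta))
  if (side == "anterior")
    pts$points[, 2] <- mirror_cols(pts$points[, 2], img$width)
  if (!is.null(cfg$roi)) pts <- apply_roi(pts, cfg$roi)
  if (keep_stages)
    attr(pts, "stages") <- list(clusters = clusters, eroded = M, labels = lab,
                                ref_label = ref_label, ref_loop = ref_loop,
                                candidates = cand)
  pts
}
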