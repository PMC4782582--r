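#' Disk structuring element
#'
#' Integer pixel offsets `(dr, dc)` with `dr^2 + dc^2 <= (d/2)^2`, so `d` is
#' a true diameter.  Because the inequality is evaluated on integer offsets,
#' even diameters also give a centered, negation-symmetric disk.  `d = 1`
#' contains only the origin; `d = 3` is the full 3 x 3 neighborhood.
#'
#' @param d diameter in pixels, >= 1.
#' @return An object of class `disk_element`: list with `d` and an
#'   integer matrix `offsets` (two columns `dr`, `dc`).
#' @export
disk_element <- function(d) {
  if (!is_count(d, 1L))
    stop_spinocurve("d must be a positive integer", "validation_error")
  r <- floor(d / 2)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= (d / 2)^2
  structure(list(d = as.integer(d),
                 offsets = as.matrix(g[keep, , drop = FALSE])),
            class = "disk_element")
}

#' Erode the complement of a cluster mask
#'
#' Computes `M = erosion(!S_j, H)` where `H` is the disk structuring element
#' of diameter `d`: `M[p]` is foreground iff every offset of the disk lands
#' on a foreground pixel of the complement of `S_j`.  Pixels outside the
#' image count as background, so the result shrinks at the borders.  The
#' erosion seals background channels narrower than the disk (intervertebral
#' gaps), which disconnects the posterior from the anterior background and
#' makes the reference region well defined.
#'
#' @param mask_Sj logical matrix, the selected cluster mask `S_j`.
#' @param d disk diameter in pixels.
#' @return Logical matrix `M`, the eroded complement.
#' @export
erode_inverse <- function(mask_Sj, d) {
  if (!is.matrix(mask_Sj)) stop_spinocurve("mask must be a matrix", "validation_error")
  mask_Sj <- mask_Sj > 0
  H <- nrow(mask_Sj); W <- ncol(mask_Sj)
  if (d > H && d > W) {
    warn_spinocurve("structuring element larger than the image: empty erosion",
                    "empty_erosion_warning")
    return(matrix(FALSE, H, W))
  }
  comp <- !mask_Sj
  off <- disk_element(d)$offsets
  M <- matrix(TRUE, H, W)
  for (i in seq_len(nrow(off))) {
    dr <- off[i, 1]; dc <- off[i, 2]
    sh <- matrix(FALSE, H, W)
    r_dst <- max(1, 1 - dr):min(H, H - dr)
    c_dst <- max(1, 1 - dc):min(W, W - dc)
    sh[r_dst, c_dst] <- comp[r_dst + dr, c_dst + dc]
    M <- M & sh
  }
  M
}

#' Label connected components (two-pass algorithm)
#'
#' Two-pass connected-component labeling with union-find equivalence
#' resolution: the first pass assigns provisional labels from
#' already-visited neighbors in raster order, the second resolves
#' equivalences.  Labels are renumbered 1..n in raster order of each
#' component's first pixel.  The returned region table is sorted by
#' descending area, ties broken by the smaller first-pixel raster index.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `labeled_regions`: list with `label_map`
#'   (integer matrix, 0 = background), `regions` (data frame with `label`,
#'   `area`, `centroid_row`, `centroid_col`, `min_dist_origin`, 0-based
#'   coordinates, sorted by descending area) and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop_spinocurve("mask must be a matrix", "validation_error")
  if (!connectivity %in% c(4L, 8L))
    stop_spinocurve("connectivity must be 4 or 8", "validation_error")
  lab <- .cpp_label_twopass(mask > 0, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    regions <- data.frame(label = integer(0), area = integer(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          min_dist_origin = numeric(0))
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    r0 <- idx[, 1] - 1; c0 <- idx[, 2] - 1   # 0-based coordinates
    area <- tabulate(l, nbins = n)
    regions <- data.frame(
      label = seq_len(n),
      area = area,
      centroid_row = as.vector(tapply(r0, l, mean)),
      centroid_col = as.vector(tapply(c0, l, mean)),
      min_dist_origin = sqrt(as.vector(tapply(r0^2 + c0^2, l, min)))
    )
    # by construction label order is raster order of first pixel, so a
    # stable sort on -area keeps raster order for ties
    regions <- regions[order(-regions$area, regions$label), , drop = FALSE]
    rownames(regions) <- NULL
  }
  structure(list(label_map = lab, regions = regions,
                 connectivity = as.integer(connectivity)),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d region(s), %d-connected\n",
              nrow(x$regions), x$connectivity))
  print(utils::head(x$regions, 5))
  invisible(x)
}

#' Pick the reference region nearest the upper-left corner
#'
#' Among the `n` largest regions, returns the label of the one whose
#' nearest pixel is closest (Euclidean) to the origin pixel (0, 0); ties
#' are broken by the larger area.  `mode = "centroid"` uses the centroid
#' distance instead of the nearest-pixel distance.
#'
#' @param regions a `labeled_regions` from [label_components()].
#' @param n how many of the largest regions to consider (default 3).
#' @param mode `"nearest_pixel"` (default) or `"centroid"`.
#' @return The label (integer) of the reference region.
#' @export
pick_reference_region <- function(regions, n = 3L,
                                  mode = c("nearest_pixel", "centroid")) {
  stopifnot(inherits(regions, "labeled_regions"))
  mode <- match.arg(mode)
  tab <- regions$regions
  if (nrow(tab) == 0L)
    stop_spinocurve("no regions to select from", "empty_selection_error")
  cand <- utils::head(tab, n)
  dist <- if (mode == "nearest_pixel") cand$min_dist_origin
          else sqrt(cand$centroid_row^2 + cand$centroid_col^2)
  pick <- order(dist, -cand$area)[1]
  cand$label[pick]
}

#' Mask of one labeled region
#'
#' @param regions a `labeled_regions`.
#' @param label region label.
#' @return Logical matrix.
#' @export
region_mask <- function(regions, label) {
  stopifnot(inherits(regions, "labeled_regions"))
  regions$label_map == label
}

# clockwise Moore neighborhood starting west: W NW N NE E SE S SW
.moore_dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.moore_dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)

#' Trace closed outer boundaries
#'
#' Moore boundary tracing of every 8-connected component of a mask.  Each
#' component yields one closed loop over its outer boundary pixels; inner
#' (hole) boundaries are not traced.  Loops are closed (first point equals
#' last point) and oriented clockwise in the (row, col) screen convention.
#' Single-pixel components yield a degenerate loop (the pixel repeated),
#' flagged via the `degenerate` attribute.
#'
#' @param mask logical matrix.
#' @param source_mask optional provenance tag stored with the result.
#' @return An object of class `contour_set`: list with `boundaries` (list
#'   of two-column matrices of 0-based (row, col) points) and `source_mask`.
#' @export
trace_boundaries <- function(mask, source_mask = NA_character_) {
  if (!is.matrix(mask)) stop_spinocurve("mask must be a matrix", "validation_error")
  mask <- mask > 0
  lab <- label_components(mask, 8L)
  loops <- lapply(lab$regions$label[order(lab$regions$label)], function(l)
    trace_one_boundary(lab$label_map, l))
  structure(list(boundaries = loops, source_mask = source_mask),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d closed loop(s)\n", length(x$boundaries)))
  invisible(x)
}

# Moore tracing of the outer boundary of the component with label `l`.
# Starts at the component's first pixel in raster order with a west
# backtrack; stops on re-entering the start pixel from the same direction
# (Jacob's stopping criterion).
trace_one_boundary <- function(label_map, l) {
  H <- nrow(label_map); W <- ncol(label_map)
  idx <- which(label_map == l)
  # column-major which(): convert to raster-order (row-major) first pixel
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  first <- order(rr, cc)[1]
  r0 <- rr[first]; c0 <- cc[first]

  inside <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W &&
    label_map[r, c] == l

  if (!any(vapply(seq_len(8), function(k)
        inside(r0 + .moore_dr[k], c0 + .moore_dc[k]), TRUE))) {
    loop <- rbind(c(r0 - 1L, c0 - 1L), c(r0 - 1L, c0 - 1L))
    colnames(loop) <- c("row", "col")
    attr(loop, "degenerate") <- TRUE
    return(loop)
  }

  # a boundary walk enters each component pixel at most four times
  max_steps <- 4L * length(idx) + 16L
  pts_r <- integer(max_steps); pts_c <- integer(max_steps)
  pts_r[1] <- r0; pts_c[1] <- c0; np <- 1L
  r <- r0; c <- c0
  dir <- 1L  # initial scan start: the west neighbor of the start pixel
  first_nr <- NA_integer_; first_nc <- NA_integer_
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (k in 0:7) {
      kk <- ((dir - 1L + k) %% 8L) + 1L
      nr <- r + .moore_dr[kk]; nc <- c + .moore_dc[kk]
      if (inside(nr, nc)) {
        # next scan start: the neighbor scanned just before the hit,
        # viewed from the new pixel
        prev_kk <- ((kk - 2L) %% 8L) + 1L
        pr <- r + .moore_dr[prev_kk]; pc <- c + .moore_dc[prev_kk]
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (handled above), safety net
    if (step == 1L) { first_nr <- nr; first_nc <- nc }
    # stop when we are about to leave the start pixel toward the same
    # second pixel as on the first step: the contour has closed
    else if (r == r0 && c == c0 && nr == first_nr && nc == first_nc) break
    dir <- dir_index(pr - nr, pc - nc)
    r <- nr; c <- nc
    np <- np + 1L; pts_r[np] <- r; pts_c[np] <- c
  }
  pts_r <- pts_r[seq_len(np)]; pts_c <- pts_c[seq_len(np)]
  if (pts_r[np] == r0 && pts_c[np] == c0 && np > 1L) {
    pts_r <- pts_r[-np]; pts_c <- pts_c[-np]
  }
  loop <- cbind(row = c(pts_r, pts_r[1]) - 1L, col = c(pts_c, pts_c[1]) - 1L)
  loop <- ensure_clockwise(loop)
  attr(loop, "degenerate") <- length(unique(paste(loop[, 1], loop[, 2]))) < 3L
  loop
}

dir_index <- function(dr, dc) {
  which(.moore_dr == dr & .moore_dc == dc)[1]
}

# Clockwise on screen (row down) == negative shoelace area in (x=col,
# y=-row) math coordinates; equivalently positive with y=row.
ensure_clockwise <- function(loop) {
  n <- nrow(loop)
  if (n < 4L) return(loop)
  x <- loop[, 2]; y <- loop[, 1]
  a2 <- sum(x[-n] * y[-1] - x[-1] * y[-n])
  if (a2 < 0) loop <- loop[n:1, , drop = FALSE]
  loop
}

#' Export boundaries as CSV
#'
#' Writes one row per boundary point with columns `loop_id, row, col`
#' (0-based coordinates).
#'
#' @param contours a `contour_set`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_boundaries_csv <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  dfs <- lapply(seq_along(contours$boundaries), function(i) {
    b <- contours$boundaries[[i]]
    data.frame(loop_id = i, row = b[, 1], col = b[, 2])
  })
  write_points_csv(do.call(rbind, dfs), path)
}
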