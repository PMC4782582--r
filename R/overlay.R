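# Overlay rendering for visual QA. Painted directly into an RGB array and
# written with png::writePNG, so output bytes are deterministic and no
# graphics device is needed. Mimics the usual figure grammar: selected
# points red, fitted line dashed magenta, curvature trace continuous green
# (|c| rescaled by 5/L), reference boundary blue.

paint_points <- function(rgb, pts, col) {
  if (is.null(pts) || nrow(pts) == 0L) return(rgb)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  r <- round(pts[, 1]) + 1L; c <- round(pts[, 2]) + 1L
  ok <- r >= 1L & r <= H & c >= 1L & c <= W
  for (ch in 1:3) rgb[cbind(r[ok], c[ok], ch)] <- col[ch]
  rgb
}

#' Render an analysis overlay PNG
#'
#' Draws the selected landmark points, the fitted line (dashed), the
#' reference boundary and a curvature trace (|c| scaled by 5/L, plotted as
#' an offset from the fitted line) over the radiograph.  Display only; the
#' stored measurement is always the signed curvature in 1/px.
#'
#' @param img a [gray_image()].
#' @param path output PNG path.
#' @param points optional [sl_point_set()].
#' @param fit optional `sl_line_fit`.
#' @param curv optional `curvature_profile`.
#' @param ref_loop optional reference boundary loop.
#' @param L plate length for the 5/L curvature display scale (default:
#'   `curv$L`, else 100).
#' @return The path, invisibly.
#' @export
render_overlay <- function(img, path, points = NULL, fit = NULL, curv = NULL,
                           ref_loop = NULL, L = NULL) {
  stopifnot(inherits(img, "gray_image"))
  rgb <- array(img$pixels, dim = c(img$height, img$width, 3))
  if (!is.null(ref_loop))
    rgb <- paint_points(rgb, as.matrix(ref_loop), c(0.2, 0.4, 1))
  if (!is.null(points))
    rgb <- paint_points(rgb, points$points, c(1, 0.15, 0.15))
  if (!is.null(fit)) {
    s <- seq(fit$s_range[1], fit$s_range[2], length.out = 400L)
    ev <- eval_fit(fit, s)
    keep <- (seq_along(s) %% 8L) < 5L   # dashed
    pts <- if (identical(fit$axis, "y")) cbind(s, ev$f)[keep, , drop = FALSE]
           else cbind(ev$f, s)[keep, , drop = FALSE]
    rgb <- paint_points(rgb, pts, c(1, 0.2, 1))
  }
  if (!is.null(curv)) {
    if (is.null(L)) L <- if (is.null(curv$L)) 100 else curv$L
    # display scale: nondimensional |kappa L| drawn at L/5 px per unit
    off <- abs(curv$curvature) * L * (L / 5)
    off <- pmin(off, img$width / 3)
    base_axis <- if (!is.null(fit) && identical(fit$axis, "y")) "y" else "x"
    pts <- if (base_axis == "y") cbind(curv$s_grid, curv$f + off)
           else cbind(curv$f + off, curv$s_grid)
    rgb <- paint_points(rgb, pts, c(0.1, 0.9, 0.2))
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
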