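#' Order landmark points along a coordinate axis
#'
#' Orders points monotonically along `x` (column) or `y` (row) to allow
#' curve fitting.  `axis = "auto"` picks the coordinate with the larger
#' point-set extent.  Points sharing the same ordered coordinate are
#' collapsed to one by averaging the transverse coordinate, so the result
#' is strictly increasing in `s`.
#'
#' @param points an [sl_point_set()] or a two-column (row, col) matrix.
#' @param axis `"auto"`, `"x"` (column is `s`) or `"y"` (row is `s`).
#' @return A list with `s`, `f` (numeric vectors, `s` strictly increasing),
#'   `axis` (the axis chosen) and `n_raw` (input point count).
#' @export
order_points <- function(points, axis = c("auto", "x", "y")) {
  axis <- match.arg(axis)
  p <- if (inherits(points, "sl_point_set")) points$points else as.matrix(points)
  if (nrow(p) < 8L)
    stop_spinocurve(sprintf("need at least 8 points, got %d", nrow(p)),
                    "insufficient_data_error")
  ext_row <- diff(range(p[, 1])); ext_col <- diff(range(p[, 2]))
  if (axis == "auto") axis <- if (ext_row >= ext_col) "y" else "x"
  if (axis == "y") { s_raw <- p[, 1]; f_raw <- p[, 2] }
  else             { s_raw <- p[, 2]; f_raw <- p[, 1] }
  grp <- split(f_raw, s_raw)
  s <- as.numeric(names(grp))
  f <- vapply(grp, mean, numeric(1), USE.NAMES = FALSE)
  ord <- order(s)
  s <- s[ord]; f <- f[ord]
  if (length(s) < 8L)
    stop_spinocurve(sprintf(
      "only %d distinct ordered coordinates; need at least 8", length(s)),
      "insufficient_data_error")
  list(s = s, f = f, axis = axis, n_raw = nrow(p))
}

#' Fit a polynomial to ordered landmark points
#'
#' Least-squares fit of `f(s) = a_d s^d + ... + a_1 s + a_0` (degree 6 by
#' default) in a numerically stable frame: `s` is centered at mid-range and
#' scaled to \[-1, 1\] before building the design matrix.  The frame is
#' stored with the coefficients so that evaluation and differentiation in
#' pixel units are exact; pixel-frame coefficients are also reported.
#'
#' @param ordered a list with `s` and `f` from [order_points()].
#' @param degree polynomial degree (default 6).
#' @return An object of class `sl_line_fit`: `coeffs` (fitting frame,
#'   ascending powers), `coeffs_pixel` (pixel frame), `axis`, `s_range`,
#'   `centering = c(shift, scale)`, `n_points`, `rms_residual`.
#' @export
fit_polynomial <- function(ordered, degree = 6L) {
  s <- ordered$s; f <- ordered$f
  if (!is_count(degree, 1L) || degree > 6L)
    stop_spinocurve("degree must be an integer in 1..6", "validation_error")
  if (length(s) < degree + 2L)
    stop_spinocurve(sprintf(
      "need at least degree + 2 = %d distinct points, got %d",
      degree + 2L, length(s)), "insufficient_data_error")
  shift <- mean(range(s)); scale <- diff(range(s)) / 2
  if (scale <= 0)
    stop_spinocurve("degenerate s range", "insufficient_data_error")
  u <- (s - shift) / scale
  X <- outer(u, 0:degree, "^")
  qrx <- qr(X)
  if (qrx$rank < degree + 1L)
    stop_spinocurve(
      "rank-deficient polynomial design (clustered s values); widen the ROI",
      "conditioning_error")
  co <- qr.coef(qrx, f)
  res <- f - drop(X %*% co)
  structure(
    list(coeffs = unname(co),
         coeffs_pixel = frame_to_pixel_coeffs(unname(co), shift, scale),
         degree = as.integer(degree),
         axis = if (is.null(ordered$axis)) NA_character_ else ordered$axis,
         s_range = range(s),
         centering = c(shift = shift, scale = scale),
         n_points = length(s),
         rms_residual = sqrt(mean(res^2))),
    class = "sl_line_fit"
  )
}

#' @export
print.sl_line_fit <- function(x, ...) {
  cat(sprintf(
    "<sl_line_fit> degree %d on %d points, s in [%g, %g] (axis %s)\n",
    x$degree, x$n_points, x$s_range[1], x$s_range[2], x$axis))
  cat(sprintf("  residual RMS: %.4g px\n", x$rms_residual))
  invisible(x)
}

# Expand g(u), u = (s - shift)/scale, into pixel-frame coefficients of s.
frame_to_pixel_coeffs <- function(co, shift, scale) {
  d <- length(co) - 1L
  out <- numeric(d + 1L)
  for (k in 0:d) {
    # co[k+1] * ((s - shift)/scale)^k expanded binomially
    bin <- choose(k, 0:k) * (-shift)^(k - (0:k)) / scale^k
    out[1:(k + 1L)] <- out[1:(k + 1L)] + co[k + 1L] * bin
  }
  out
}

# Evaluate the fitted polynomial and its first two derivatives in pixel
# units at pixel positions s.
eval_fit <- function(fit, s, extrapolate = FALSE) {
  if (!extrapolate &&
      (min(s) < fit$s_range[1] - 1e-9 || max(s) > fit$s_range[2] + 1e-9))
    stop_spinocurve("requested grid lies outside the fitted s range",
                    "extrapolation_error")
  shift <- fit$centering[["shift"]]; scale <- fit$centering[["scale"]]
  u <- (s - shift) / scale
  co <- fit$coeffs
  d1 <- co[-1] * seq_along(co[-1])
  d2 <- if (length(d1) > 1L) d1[-1] * seq_along(d1[-1]) else 0
  val <- drop(outer(u, seq_along(co) - 1L, "^") %*% co)
  der1 <- drop(outer(u, seq_along(d1) - 1L, "^") %*% d1) / scale
  der2 <- drop(outer(u, seq_along(d2) - 1L, "^") %*% d2) / scale^2
  list(f = val, f1 = der1, f2 = der2)
}

#' Local curvature of a fitted landmark line
#'
#' Signed local curvature `c(s) = f''(s) / (1 + f'(s)^2)^(3/2)` evaluated
#' analytically from the stored polynomial, in 1/pixel.  When a plate
#' length `L` is supplied the nondimensional product `kappa * L` is also
#' reported.  By default curvature is only trusted on the central 90% of
#' the fitted range, because polynomial edge oscillation makes the
#' endpoints unreliable; pass an explicit `s_grid` to override.
#'
#' @param fit an `sl_line_fit`.
#' @param s_grid sample positions in pixels (must lie inside the fitted
#'   range); default: 200 points over the central 90%.
#' @param L optional plate length in pixels for `kappa * L` scaling.
#' @return An object of class `curvature_profile`: `s_grid`, `f`,
#'   `curvature` (1/px), `kappa_L` (or NULL), `kappa_bar`, `total_rotation`,
#'   `arc_length`, `L`.
#' @export
curvature <- function(fit, s_grid = NULL, L = NULL) {
  stopifnot(inherits(fit, "sl_line_fit"))
  if (is.null(s_grid)) {
    mid <- mean(fit$s_range); half <- diff(fit$s_range) / 2
    s_grid <- seq(mid - 0.9 * half, mid + 0.9 * half, length.out = 200L)
  }
  if (is.unsorted(s_grid, strictly = TRUE))
    stop_spinocurve("s_grid must be strictly increasing", "validation_error")
  ev <- eval_fit(fit, s_grid)
  curv <- ev$f2 / (1 + ev$f1^2)^1.5
  avg <- average_curvature(fit, min(s_grid), max(s_grid))
  structure(
    list(s_grid = s_grid, f = ev$f, curvature = curv,
         kappa_L = if (is.null(L)) NULL else curv * L,
         kappa_bar = avg$kappa_bar, total_rotation = avg$total_rotation,
         arc_length = avg$arc_length, L = L),
    class = "curvature_profile"
  )
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "<curvature_profile> %d samples, s in [%g, %g]\n  mean |c| = %.4g /px, kappa_bar = %.4g /px, total rotation = %.4g rad\n",
    length(x$s_grid), min(x$s_grid), max(x$s_grid),
    mean(abs(x$curvature)), x$kappa_bar, x$total_rotation))
  invisible(x)
}

#' Average curvature and total rotation between two positions
#'
#' The total rotation of the tangent between `s1` and `s2` is
#' `theta(s2) - theta(s1)` with `theta = atan(f'(s))`; it equals the
#' arc-length integral of the local curvature.  The average curvature is
#' the total rotation divided by the arc length, computed by adaptive
#' quadrature of `sqrt(1 + f'(s)^2)`.
#'
#' @param fit an `sl_line_fit`.
#' @param s1,s2 positions in pixels, `s1 < s2`, inside the fitted range.
#' @return List with `total_rotation` (rad), `arc_length` (px),
#'   `kappa_bar` (1/px).
#' @export
average_curvature <- function(fit, s1, s2) {
  stopifnot(inherits(fit, "sl_line_fit"))
  if (!(s1 < s2))
    stop_spinocurve("s1 must be smaller than s2", "validation_error")
  if (s1 < fit$s_range[1] - 1e-9 || s2 > fit$s_range[2] + 1e-9)
    stop_spinocurve("s1, s2 must lie inside the fitted range",
                    "extrapolation_error")
  ends <- eval_fit(fit, c(s1, s2))
  rotation <- atan(ends$f1[2]) - atan(ends$f1[1])
  arc <- integrate(function(ss) sqrt(1 + eval_fit(fit, ss)$f1^2),
                   s1, s2, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
  list(total_rotation = rotation, arc_length = arc,
       kappa_bar = rotation / arc)
}

#' Flexural rigidity profile from curvature and bending moment
#'
#' Beam-mechanics interpretation `EI(s) = M(s) / kappa(s)`.  The bending
#' moment `M(s)` is user-supplied on the curvature grid; the tool never
#' infers loads.  Positions where `|kappa|` is below `1e-9 * max |kappa|`
#' are masked as undefined.
#'
#' @param curv a `curvature_profile`.
#' @param moment numeric vector `M(s)` sampled on `curv$s_grid`.
#' @return An object of class `rigidity_profile`: `s_grid`, `EI`, `mask`
#'   (TRUE where rigidity is undefined).
#' @export
flexural_rigidity <- function(curv, moment) {
  stopifnot(inherits(curv, "curvature_profile"))
  if (length(moment) != length(curv$s_grid))
    stop_spinocurve("moment must be sampled on the curvature grid",
                    "validation_error")
  kap <- curv$curvature
  thresh <- 1e-9 * max(abs(kap))
  undef <- abs(kap) <= thresh
  EI <- ifelse(undef, NA_real_, moment / kap)
  if (all(undef))
    warn_spinocurve("curvature is degenerate everywhere; EI undefined",
                    "degenerate_curvature_warning")
  structure(list(s_grid = curv$s_grid, EI = EI, mask = undef),
            class = "rigidity_profile")
}

#' Export a curvature profile as CSV
#'
#' Columns: `s_px, f_px, curvature_per_px` and, when a plate length was
#' given, `kappa_L`.
#'
#' @param curv a `curvature_profile`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
export_curvature_csv <- function(curv, path) {
  stopifnot(inherits(curv, "curvature_profile"))
  df <- data.frame(s_px = curv$s_grid, f_px = curv$f,
                   curvature_per_px = curv$curvature)
  if (!is.null(curv$kappa_L)) df$kappa_L <- curv$kappa_L
  write_points_csv(df, path, digits = 8L)
}
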