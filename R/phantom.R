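#' Phantom specification
#'
#' Describes a synthetic radiograph-like scene with exactly known geometry:
#' a dark background, a bright skull blob in the upper-left quadrant, a
#' chain of bright vertebra-like blobs whose posterior edges trace a smooth
#' parametric spinolaminar (SL) curve, and optionally a very bright
#' anterior plate strip with a built-in lordotic radius expressed in
#' multiples of the plate length.  Additive Gaussian noise is applied last
#' and clipped to \[0, 1\].
#'
#' The vertebral chain is painted as a slab of depth `vertebra_depth`
#' anterior of the SL curve, carved by intervertebral notches of height
#' `gap_px` that stop `bridge_px` short of the posterior edge (the
#' continuous laminar cortical line), so the posterior boundary follows the
#' SL curve exactly while the blobs remain visually distinct.  Posterior is
#' toward smaller column indices; the image is oriented as a left-facing
#' lateral radiograph.
#'
#' @param height,width image size in pixels.
#' @param sl SL curve description: `list(shape = "circle_arc", radius = R)`
#'   (bulging posterior, center of curvature anterior),
#'   `list(shape = "line", col0 = 55, slope = 0)` or
#'   `list(shape = "poly", coeffs = c(a0, a1, ...))` giving the posterior
#'   column as a polynomial in `(row - (height-1)/2)`.
#' @param plate `NULL`, or `list(ratio = 3.7, length_px = 320, width = 6)`:
#'   an anterior plate strip whose outer edge is a circle arc of radius
#'   `ratio * length_px` with a vertical chord of `length_px`, centered
#'   vertically and touching the vertebral bodies.
#' @param background,bone_intensity,plate_intensity intensity levels
#'   (background < bone < plate).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param skull `list(row, col, radius, intensity)`; defaults place a
#'   bone-intensity disk clear of the chain in the upper-left quadrant
#'   (`col`/`intensity` may be omitted).
#' @param n_vertebrae number of vertebra blobs (default scales with
#'   height).
#' @param vertebra_depth slab depth in pixels (posterior edge to vertebral
#'   body front).
#' @param gap_px,bridge_px intervertebral notch height and the depth of
#'   the posterior laminar bridge the notch does not cut through.
#' @param apex_col posterior-most column of the SL curve.
#' @param seed integer; all randomness (noise) flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width,
                         sl = list(shape = "circle_arc", radius = 400),
                         plate = NULL,
                         background = 0.08, bone_intensity = 0.52,
                         plate_intensity = 0.92, noise_sigma = 0.02,
                         skull = list(row = 34, radius = 22),
                         n_vertebrae = NULL, vertebra_depth = 40,
                         gap_px = 4, bridge_px = 13, apex_col = 55,
                         seed = 0L) {
  if (!is_count(height, 32L) || !is_count(width, 32L))
    stop_spinocurve("phantom must be at least 32 x 32", "geometry_error")
  if (!(background < bone_intensity && bone_intensity < plate_intensity &&
        plate_intensity <= 1 && background >= 0))
    stop_spinocurve("need background < bone < plate <= 1", "geometry_error")
  if (is.null(n_vertebrae)) n_vertebrae <- max(6L, round(height / 58))
  if (!is.null(plate)) {
    plate <- modifyList(list(ratio = 3.7, length_px = 320, width = 6), plate)
    if (plate$ratio < 0.51)
      stop_spinocurve("plate ratio must exceed 1/2 (chord of a circle)",
                      "geometry_error")
  }
  skull <- modifyList(list(row = 34, col = NULL, radius = 22,
                           intensity = bone_intensity), skull)
  spec <- structure(
    list(height = as.integer(height), width = as.integer(width), sl = sl,
         plate = plate, background = background,
         bone_intensity = bone_intensity, plate_intensity = plate_intensity,
         noise_sigma = noise_sigma, skull = skull,
         n_vertebrae = as.integer(n_vertebrae),
         vertebra_depth = as.integer(vertebra_depth),
         gap_px = as.integer(gap_px), bridge_px = as.integer(bridge_px),
         apex_col = apex_col, seed = as.integer(seed)),
    class = "phantom_spec")
  spec
}

# SL curve column and derivatives as functions of continuous row t,
# centered at cr = (H-1)/2.
sl_curve_fun <- function(spec) {
  cr <- (spec$height - 1) / 2
  sl <- spec$sl
  shape <- sl$shape
  if (shape == "circle_arc") {
    R <- sl$radius
    if ((spec$height - 1) / 2 >= R)
      stop_spinocurve("SL arc radius too small for the image height",
                      "geometry_error")
    list(
      g  = function(t) spec$apex_col + (R - sqrt(R^2 - (t - cr)^2)),
      g1 = function(t) (t - cr) / sqrt(R^2 - (t - cr)^2),
      g2 = function(t) R^2 / (R^2 - (t - cr)^2)^1.5,
      curvature = function(t) rep(1 / R, length(t))
    )
  } else if (shape == "line") {
    col0 <- if (is.null(sl$col0)) spec$apex_col else sl$col0
    slope <- if (is.null(sl$slope)) 0 else sl$slope
    list(
      g  = function(t) col0 + slope * (t - cr),
      g1 = function(t) rep(slope, length(t)),
      g2 = function(t) rep(0, length(t)),
      curvature = function(t) rep(0, length(t))
    )
  } else if (shape == "poly") {
    co <- sl$coeffs
    d1 <- if (length(co) > 1) co[-1] * seq_along(co[-1]) else 0
    d2 <- if (length(d1) > 1) d1[-1] * seq_along(d1[-1]) else 0
    pv <- function(cf, x) drop(outer(x, seq_along(cf) - 1, "^") %*% cf)
    list(
      g  = function(t) pv(co, t - cr),
      g1 = function(t) pv(d1, t - cr),
      g2 = function(t) pv(d2, t - cr),
      curvature = function(t) pv(d2, t - cr) / (1 + pv(d1, t - cr)^2)^1.5
    )
  } else stop_spinocurve(sprintf("unknown SL shape: %s", shape),
                         "geometry_error")
}

#' Generate a phantom radiograph with ground truth
#'
#' Deterministic given `spec$seed`: the same spec yields bit-identical
#' images.  The ground truth samples the SL curve at ~1 px arc-length
#' spacing with its analytic curvature, and, when a plate is present, the
#' plate outer-edge samples, built-in radius and plate length.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: list with `image` (a
#'   [gray_image()]), `truth` (see details) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  cr <- (H - 1) / 2
  curve <- sl_curve_fun(spec)
  rows0 <- 0:(H - 1)
  g <- curve$g(rows0)
  if (min(g) < 10 || any(!is.finite(g)))
    stop_spinocurve("SL curve leaves the posterior margin (need col >= 10)",
                    "geometry_error")
  Gi <- ceiling(g)                      # posterior-most bright column, 0-based
  Tdep <- spec$vertebra_depth
  E <- Gi + Tdep - 1                    # anterior edge column, 0-based

  # plate geometry: outer edge arc with vertical chord length_px
  plate <- spec$plate
  plate_rows <- integer(0); Pi <- numeric(0); p_real <- numeric(0)
  if (!is.null(plate)) {
    Lp <- plate$length_px
    Rp <- plate$ratio * Lp
    r0p <- round(cr - Lp / 2); r1p <- r0p + Lp
    taper <- 12L
    if (r0p < taper + 2L || r1p > H - taper - 3L)
      stop_spinocurve("plate does not fit vertically (reduce length_px)",
                      "geometry_error")
    plate_rows <- r0p:r1p
    base <- max(E[plate_rows + 1]) + 5
    p_real <- base + sqrt(Rp^2 - (plate_rows - cr)^2) - sqrt(Rp^2 - (Lp / 2)^2)
    Pi <- round(p_real)
    E[plate_rows + 1] <- Pi
    # taper the anterior edge back to the vertebral bodies to avoid steps
    for (k in seq_len(taper)) {
      frac <- (taper - k) / taper
      rA <- r0p - k; rB <- r1p + k
      E[rA + 1] <- max(E[rA + 1], round(E[rA + 1] + frac * (Pi[1] - E[rA + 1])))
      nP <- length(Pi)
      E[rB + 1] <- max(E[rB + 1], round(E[rB + 1] + frac * (Pi[nP] - E[rB + 1])))
    }
  }
  if (max(E) > W - 29L)
    stop_spinocurve("anterior margin too small (need 28 background columns)",
                    "geometry_error")

  # paint the bone slab row by row, carving intervertebral notches
  bone <- matrix(FALSE, H, W)
  pitch <- H / spec$n_vertebrae
  gap_rows <- rep(FALSE, H)
  for (k in seq_len(spec$n_vertebrae - 1L)) {
    b0 <- round(k * pitch)
    gr <- b0:(b0 + spec$gap_px - 1L)
    gap_rows[gr[gr >= 0 & gr < H] + 1L] <- TRUE
  }
  is_plate_row <- rep(FALSE, H); is_plate_row[plate_rows + 1L] <- TRUE
  # bridge depth is measured along the curve normal, so its horizontal
  # extent grows with the local slope
  inv_cos <- sqrt(1 + curve$g1(rows0)^2)
  for (r in seq_len(H)) {
    cols <- Gi[r]:E[r]
    if (gap_rows[r]) {
      # keep the posterior laminar bridge; behind a plate also keep a
      # contact block so the plate stays attached to bone
      lo <- Gi[r] + ceiling(spec$bridge_px * inv_cos[r])
      hi <- if (is_plate_row[r]) E[r] - 18L else E[r]
      if (lo <= hi) cols <- setdiff(cols, lo:hi)
    }
    bone[r, cols + 1L] <- TRUE
  }

  img <- matrix(spec$background, H, W)
  img[bone] <- spec$bone_intensity

  # skull disk, clear of the chain; by default it is sized and placed so
  # that the background corridor between skull and left image edge is wide
  # enough to survive the erosion, keeping the posterior background (and
  # with it the upper-left corner) a single connected reference region
  sk <- spec$skull
  g_at <- curve$g(sk$row)
  if (is.null(sk$col)) {
    sk$radius <- min(sk$radius, floor((g_at - 19) / 2))
    if (sk$radius < 4)
      stop_spinocurve("posterior band too narrow to place a skull blob",
                      "geometry_error")
    sk$col <- g_at - sk$radius - 3
  }
  if (sk$col + sk$radius >= g_at - 2)
    stop_spinocurve("skull overlaps the vertebral chain", "geometry_error")
  dr <- outer(rows0 - sk$row, rep(1, W))
  dc <- outer(rep(1, H), (0:(W - 1)) - sk$col)
  img[dr^2 + dc^2 <= sk$radius^2] <- sk$intensity

  # plate strip: width columns ending at the outer edge
  if (!is.null(plate)) {
    for (i in seq_along(plate_rows)) {
      r <- plate_rows[i] + 1L
      img[r, (Pi[i] - plate$width + 1L):(Pi[i]) + 1L] <- spec$plate_intensity
    }
  }

  if (spec$noise_sigma > 0)
    img <- img + with_local_seed(spec$seed,
      matrix(rnorm(H * W, 0, spec$noise_sigma), H, W))
  img <- pmin(pmax(img, 0), 1)

  # ground truth: SL samples at ~1 px arc-length spacing
  t_fine <- seq(0, H - 1, by = 0.25)
  ds <- sqrt(1 + curve$g1(t_fine)^2)
  nfine <- length(t_fine)
  arc <- c(0, cumsum((ds[-1] + ds[-nfine]) / 2 * diff(t_fine)))
  t_samp <- approx(arc, t_fine, xout = seq(0, max(arc), by = 1))$y
  sl_samples <- cbind(row = t_samp, col = curve$g(t_samp))
  truth <- list(
    sl_samples = sl_samples,
    sl_curvature = curve$curvature(t_samp),
    sl_radius = if (spec$sl$shape == "circle_arc") spec$sl$radius else NA_real_,
    plate_edge = if (is.null(plate)) NULL else
      cbind(row = plate_rows, col = p_real),
    plate_radius_px = if (is.null(plate)) NA_real_ else plate$ratio * plate$length_px,
    plate_ratio = if (is.null(plate)) NA_real_ else plate$ratio,
    plate_L = if (is.null(plate)) NA_real_ else plate$length_px,
    plate_rows = if (is.null(plate)) NULL else range(plate_rows),
    plate_cols = if (is.null(plate)) NULL else range(Pi),
    g_range = range(Gi), anterior_range = range(E)
  )
  structure(list(image = gray_image(img), truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, SL shape %s%s\n",
              x$spec$height, x$spec$width, x$spec$sl$shape,
              if (is.null(x$spec$plate)) "" else
                sprintf(", plate %g L (L = %d px)",
                        x$spec$plate$ratio, x$spec$plate$length_px)))
  invisible(x)
}

#' Segmentation config matched to a phantom
#'
#' Returns the [analysis_config()] that segments the phantom: `K` equal to
#' the number of well-separated intensity modes the K-means can resolve
#' (background splits in two when a plate cluster is present), `j` the
#' bright cluster, `d = 13` and `delta = 18` in the regime used for
#' clinical images, and an ROI bracketing the SL curve below the skull.
#'
#' @param phantom a `phantom`.
#' @return An [analysis_config()].
#' @export
phantom_sl_config <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  H <- phantom$spec$height
  K <- if (is.null(phantom$spec$plate)) 2L else 3L
  g_rng <- phantom$truth$g_range
  analysis_config(
    K = K, j = K, d = 13L, delta = 18,
    roi = c(ceiling(0.2 * H), H - 8L,
            max(0L, g_rng[1] - 4L), g_rng[2] + 6L),
    plate_length_L = if (is.null(phantom$spec$plate)) NULL else
      phantom$spec$plate$length_px,
    fit_axis = "y", seed = phantom$spec$seed)
}

#' Plate-extraction config matched to a phantom
#'
#' Same segmentation parameters as [phantom_sl_config()] but with the ROI
#' bracketing the plate rows and anterior columns (original, unmirrored
#' frame).
#'
#' @param phantom a `phantom` generated with a plate.
#' @return An [analysis_config()].
#' @export
phantom_plate_config <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.null(phantom$spec$plate))
    stop_spinocurve("phantom has no plate", "validation_error")
  pr <- phantom$truth$plate_rows; pc <- phantom$truth$plate_cols
  analysis_config(
    K = 3L, j = 3L, d = 13L, delta = 18,
    roi = c(pr[1], pr[2], pc[1] - 5L, pc[2] + 5L),
    plate_length_L = phantom$spec$plate$length_px,
    fit_axis = "y", seed = phantom$spec$seed)
}

#' Standard arc phantom specification
#'
#' Convenience constructor for SL-recovery experiments: a circle-arc SL
#' curve of the given radius, with the image sized so the visible arc
#' subtends enough rows for a stable degree-6 fit (taller images for
#' larger, flatter radii).
#'
#' @param radius SL arc radius in pixels.
#' @param seed integer seed.
#' @param noise_sigma Gaussian noise level (default 0.02).
#' @return A [phantom_spec()].
#' @export
arc_phantom_spec <- function(radius, seed = 0L, noise_sigma = 0.02) {
  H <- min(2L * round(0.85 * radius), 580L)
  cr <- (H - 1) / 2
  sagitta <- radius - sqrt(radius^2 - cr^2)
  W <- 10L * ceiling((55 + sagitta + 40 + 45) / 10)
  phantom_spec(height = H, width = W,
               sl = list(shape = "circle_arc", radius = radius),
               noise_sigma = noise_sigma, seed = seed)
}

#' Generate a flexion/extension phantom pair
#'
#' Two phantoms differing only in curvature, sharing every other parameter
#' and the same seed (so noise is identical).  With `what = "plate"` the
#' two radii are plate ratios in units of plate length; with `what = "sl"`
#' they are SL arc radii in pixels.
#'
#' @param base a [phantom_spec()] (for `what = "plate"` it must include a
#'   plate).
#' @param flexion_radius,extension_radius the two radii (plate: multiples
#'   of L; sl: pixels).
#' @param what `"plate"` or `"sl"`.
#' @return Named list of two `phantom` objects, `flexion` and `extension`.
#' @export
generate_flexext_pair <- function(base, flexion_radius, extension_radius,
                                  what = c("plate", "sl")) {
  stopifnot(inherits(base, "phantom_spec"))
  what <- match.arg(what)
  mk <- function(r) {
    sp <- base
    if (what == "plate") {
      if (is.null(sp$plate))
        stop_spinocurve("base spec has no plate", "validation_error")
      sp$plate$ratio <- r
    } else {
      sp$sl <- list(shape = "circle_arc", radius = r)
    }
    generate_phantom(sp)
  }
  list(flexion = mk(flexion_radius), extension = mk(extension_radius))
}
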