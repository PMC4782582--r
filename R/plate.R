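#' Extract the anterior plate contour
#'
#' Runs the landmark pipeline on the mirrored image so that the reference
#' region becomes the anterior background and the selected boundary points
#' trace the anterior vertebral contour, including an implanted cervical
#' plate where present.  Returned coordinates are in the original
#' (unmirrored) frame; `cfg$roi` is interpreted in that frame and should
#' bracket the rows spanned by the plate.
#'
#' @param img a [gray_image()].
#' @param cfg an [analysis_config()].
#' @return An [sl_point_set()] of anterior contour points.
#' @export
extract_plate_contour <- function(img, cfg) {
  extract_landmark_points(img, cfg, side = "anterior")
}

#' Fit the osculating circle at the plate mid-point
#'
#' Orders the plate contour points, fits a degree-6 polynomial to locate
#' the arc-length mid-point, then refits a fresh degree-2 polynomial in a
#' frame centered at the mid-point (a truncation of the full fit to
#' second-order terms, done as a refit because zeroing high-order
#' coefficients of an ill-conditioned raw fit is frame-dependent; set
#' `truncate = TRUE` for the literal coefficient truncation).  The
#' osculating radius at the mid-point is `1/|c|`; the plate length `L` is
#' the straight-line distance between the contour endpoints, and the
#' radius is also reported in multiples of `L`.
#'
#' @param points an [sl_point_set()] (or two-column matrix) of plate
#'   contour points, at least 8.
#' @param axis forwarded to [order_points()].
#' @param state optional label (`"flexion"`, `"neutral"`, `"extension"`).
#' @param truncate use literal truncation of the degree-6 fit instead of a
#'   degree-2 refit.
#' @return An object of class `plate_model`: `contour_fit` (degree-6),
#'   `L` (px), `midpoint_s`, `midpoint` (row, col), `osc_radius_px`,
#'   `osc_radius_L`, `osc_center` (row, col), `mean_curvature_invL`,
#'   `curvature_mid` (signed, 1/px), `lordotic` (normal points anterior),
#'   `straight` (TRUE when curvature is numerically zero), `state`.
#' @export
fit_osculating_circle <- function(points, axis = "auto", state = NA_character_,
                                  truncate = FALSE) {
  ordered <- order_points(points, axis)
  fit6 <- fit_polynomial(ordered, degree = 6L)

  # arc-length mid-point of the fitted contour
  total <- average_curvature(fit6, fit6$s_range[1], fit6$s_range[2])$arc_length
  arc_to <- function(s) integrate(function(ss) sqrt(1 + eval_fit(fit6, ss)$f1^2),
                                  fit6$s_range[1], s, rel.tol = 1e-9)$value
  mid_s <- uniroot(function(s) arc_to(s) - total / 2,
                   lower = fit6$s_range[1], upper = fit6$s_range[2],
                   tol = 1e-6)$root

  if (truncate) {
    # express the degree-6 fit in a mid-point-centered frame, drop orders > 2
    co2 <- truncated_coeffs(fit6, mid_s)
    fit2 <- structure(
      list(coeffs = unname(co2),
           coeffs_pixel = frame_to_pixel_coeffs(unname(co2), mid_s, 1),
           degree = 2L, axis = ordered$axis, s_range = range(ordered$s),
           centering = c(shift = mid_s, scale = 1),
           n_points = length(ordered$s), rms_residual = NA_real_),
      class = "sl_line_fit")
    ev2 <- eval_fit(fit2, mid_s)
    c_mid <- ev2$f2 / (1 + ev2$f1^2)^1.5
    f1_mid <- ev2$f1
  } else {
    # Degree-2 refit centered at the arc-length mid-point, with the arc
    # length itself as the abscissa (its quartic truncation bias for a
    # circle is a third of the coordinate frame's).  A parabola only
    # osculates locally, so for contours subtending wide arcs the refit is
    # restricted to an arc window of +/- 0.25 / |c| around the mid-point,
    # re-estimated iteratively; typical plates subtend < 30 degrees and
    # keep every point, so no precision is lost when the window is slack.
    ev_all <- eval_fit(fit6, ordered$s)
    w_arc <- sqrt(1 + ev_all$f1^2)
    np <- length(ordered$s)
    a <- c(0, cumsum((w_arc[-1] + w_arc[-np]) / 2 * diff(ordered$s))) -
      total / 2   # zero at the arc-length mid-point
    keep <- rep(TRUE, np)
    gp <- 0; gpp <- 0
    for (it in 1:3) {
      aa <- a[keep]; ff <- ordered$f[keep]
      sc <- max(abs(aa))
      u <- aa / sc
      co <- unname(qr.coef(qr(cbind(1, u, u^2)), ff))
      gp <- co[2] / sc; gpp <- 2 * co[3] / sc^2
      c_est <- abs(gpp) / sqrt(max(1 - gp^2, 1e-6))
      if (c_est < 1e-12) break
      keep_new <- abs(a) <= 0.25 / c_est
      if (sum(keep_new) < 8L || identical(keep_new, keep)) break
      keep <- keep_new
    }
    # curvature and coordinate slope at the mid-point, mapped back from
    # the arc-length frame: df/ds = g'/sqrt(1 - g'^2), c = g''/sqrt(1 - g'^2)
    denom <- sqrt(max(1 - gp^2, 1e-6))
    c_mid <- gpp / denom
    f1_mid <- gp / denom
  }

  ends <- eval_fit(fit6, fit6$s_range)
  d_ends <- c(fit6$s_range[2] - fit6$s_range[1], ends$f[2] - ends$f[1])
  L <- sqrt(sum(d_ends^2))

  straight <- abs(c_mid) < 1e-12
  if (straight)
    warn_spinocurve("plate contour is numerically straight; infinite radius",
                    "straight_plate_warning")
  radius_px <- if (straight) Inf else 1 / abs(c_mid)

  # center = midpoint + radius * unit normal toward the concave side;
  # in the (s, f) frame the signed normal is (-f', 1)/sqrt(1 + f'^2) * sign(c)
  norm_sf <- c(-f1_mid, 1) / sqrt(1 + f1_mid^2) * sign(c_mid)
  mid_sf <- c(mid_s, eval_fit(fit6, mid_s)$f)
  center_sf <- if (straight) c(NA_real_, NA_real_) else mid_sf + radius_px * norm_sf
  to_rowcol <- function(p_sf) {
    if (identical(ordered$axis, "y")) c(row = p_sf[1], col = p_sf[2])
    else c(row = p_sf[2], col = p_sf[1])
  }

  mean_curv_invL <- if (straight) 0 else (1 / radius_px) * L
  # lordotic when the curve is convex toward the anterior side, i.e. the
  # center of curvature lies posterior (smaller col) of the mid-point
  mid_rc <- to_rowcol(mid_sf); cen_rc <- to_rowcol(center_sf)
  lordotic <- if (straight) NA else unname(cen_rc["col"] < mid_rc["col"])

  structure(
    list(contour_fit = fit6, L = L, midpoint_s = mid_s,
         midpoint = mid_rc, osc_radius_px = radius_px,
         osc_radius_L = radius_px / L, osc_center = cen_rc,
         mean_curvature_invL = mean_curv_invL, curvature_mid = c_mid,
         lordotic = lordotic, straight = straight, state = state),
    class = "plate_model"
  )
}

# Degree-6 coefficients re-centered at s0 (pixel frame), truncated to order 2.
truncated_coeffs <- function(fit6, s0) {
  cp <- fit6$coeffs_pixel
  d <- length(cp) - 1L
  out <- numeric(3)
  for (k in 0:d) {  # cp[k+1] * s^k = cp[k+1] * (u + s0)^k, u = s - s0
    for (m in 0:min(k, 2L))
      out[m + 1L] <- out[m + 1L] + cp[k + 1L] * choose(k, m) * s0^(k - m)
  }
  out
}

#' @export
print.plate_model <- function(x, ...) {
  cat(sprintf("<plate_model>%s L = %.1f px\n",
              if (is.na(x$state)) "" else paste0(" [", x$state, "]"), x$L))
  if (x$straight) cat("  straight plate (infinite osculating radius)\n")
  else cat(sprintf(
    "  osculating radius: %.1f px = %.3g L; mean curvature %.4g 1/L (%s)\n",
    x$osc_radius_px, x$osc_radius_L, x$mean_curvature_invL,
    if (isTRUE(x$lordotic)) "lordotic" else "kyphotic"))
  invisible(x)
}

#' Compare plate curvature across flexion/neutral/extension states
#'
#' Reports the mean plate curvature (in 1/L units) per state and their
#' ordering by decreasing curvature.  No clinical judgment is attached; a
#' larger curvature simply means a smaller lordotic radius.
#'
#' @param models list of `plate_model` objects with distinct `state` labels.
#' @return An object of class `plate_comparison`: data frame `table`
#'   (state, L_px, osc_radius_L, mean_curvature_invL), `ordering`
#'   (states by decreasing curvature), `no_change` flag.
#' @export
compare_plate_states <- function(models) {
  if (length(models) < 2L)
    stop_spinocurve("need at least two plate models", "validation_error")
  ok <- vapply(models, inherits, TRUE, what = "plate_model")
  if (!all(ok)) stop_spinocurve("all inputs must be plate models",
                                "validation_error")
  tab <- do.call(rbind, lapply(models, function(m) data.frame(
    state = m$state, L_px = m$L, osc_radius_L = m$osc_radius_L,
    mean_curvature_invL = m$mean_curvature_invL)))
  Ls <- tab$L_px
  if (max(Ls) / min(Ls) > 3)
    stop_spinocurve(
      "plate lengths differ by more than 3x; check L conventions", "unit_error")
  ord <- order(-tab$mean_curvature_invL)
  no_change <- diff(range(tab$mean_curvature_invL)) < 1e-12
  structure(list(table = tab, ordering = tab$state[ord],
                 no_change = no_change),
            class = "plate_comparison")
}

#' @export
print.plate_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (x$no_change) cat("no change in plate curvature across states\n")
  else cat("curvature ordering (largest first):",
           paste(x$ordering, collapse = " > "), "\n")
  invisible(x)
}

#' Export a plate model as JSON
#'
#' @param model a `plate_model`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
export_plate_json <- function(model, path) {
  stopifnot(inherits(model, "plate_model"))
  out <- list(state = model$state, L_px = model$L,
              osc_radius_px = model$osc_radius_px,
              osc_radius_L = model$osc_radius_L,
              mean_curvature_invL = model$mean_curvature_invL,
              lordotic = model$lordotic, straight = model$straight)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}
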