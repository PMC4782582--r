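#' Gray-scale image container
#'
#' Wraps a 2-D intensity matrix with the coordinate and intensity conventions
#' used throughout the package: intensities in \[0, 1\]; coordinates are
#' (row, col), 0-based, origin at the top-left pixel, rows increasing
#' downward.  The optional `pixel_pitch` records physical size (mm/pixel)
#' and is carried as metadata only.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\], at least 8 x 8.
#' @param pixel_pitch optional physical pixel size in mm/pixel.
#' @param normalize if `TRUE`, min-max normalize `pixels` to \[0, 1\] first
#'   (a constant matrix maps to all zeros).
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `pixel_pitch`.
#' @export
gray_image <- function(pixels, pixel_pitch = 1.0, normalize = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_spinocurve("`pixels` must be a numeric matrix", "dimension_error")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop_spinocurve("image must be at least 8 x 8 pixels", "dimension_error")
  if (anyNA(pixels))
    stop_spinocurve("image contains missing values", "decode_error")
  if (normalize) pixels <- normalize_minmax(pixels)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_spinocurve("intensities must lie in [0, 1] (use normalize = TRUE)",
                    "intensity_error")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_pitch = pixel_pitch),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, intensity range [%.3f, %.3f]\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

normalize_minmax <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Read a radiograph image
#'
#' Reads PNG, TIFF or uncompressed monochrome DICOM pixel data and returns a
#' [gray_image()].  RGB rasters are converted to gray by the unweighted
#' channel mean.  Intensities are min-max normalized to \[0, 1\]; a constant
#' image maps to all zeros.
#'
#' @param path path to a `.png`, `.tif`/`.tiff` or `.dcm` file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop_spinocurve(sprintf("file not found: %s", path), "decode_error")
  ext <- tolower(tools::file_ext(path))
  raw_img <- switch(ext,
    png = try(png::readPNG(path), silent = TRUE),
    tif = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    dcm = ,
    dicom = try(read_dicom_pixels(path), silent = TRUE),
    stop_spinocurve(sprintf("unsupported image format: .%s", ext), "decode_error")
  )
  if (inherits(raw_img, "try-error"))
    stop_spinocurve(sprintf("could not decode %s: %s", path,
                            attr(raw_img, "condition")$message), "decode_error")
  m <- collapse_channels(raw_img)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop_spinocurve("zero-sized raster", "dimension_error")
  gray_image(normalize_minmax(m))
}

collapse_channels <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch >= 3L) return((a[, , 1] + a[, , 2] + a[, , 3]) / 3)  # drop alpha
    return(a[, , 1])
  }
  stop_spinocurve("unsupported raster layout", "decode_error")
}

#' Write a gray image or binary mask as 8-bit PNG
#'
#' @param img a [gray_image()] or a logical/0-1 matrix (masks are written
#'   with foreground 255, background 0).
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_image_png <- function(img, path) {
  m <- if (inherits(img, "gray_image")) img$pixels else img
  if (is.logical(m)) m <- m * 1
  storage.mode(m) <- "double"
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Mirror an image left-right
#'
#' Reverses the column order.  Applied before segmentation, this lets the SL
#' pipeline operate on the anterior side of the vertebral column (implanted
#' plates) instead of the posterior side.  Mirroring is an involution:
#' `mirror_image(mirror_image(img))` is identical to `img`.
#'
#' @param img a [gray_image()].
#' @return A [gray_image()] with columns reversed.
#' @export
mirror_image <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  out <- img
  out$pixels <- img$pixels[, ncol(img$pixels):1, drop = FALSE]
  out
}

# Mirror 0-based column coordinates back to the unmirrored frame.
mirror_cols <- function(cols, width) width - 1 - cols
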