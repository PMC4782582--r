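# Minimal DICOM pixel-data reader.
#
# Scope: single-frame, uncompressed, little-endian monochrome images
# (transfer syntaxes 1.2.840.10008.1.2 implicit VR and ...1.2.1 explicit VR),
# 8 or 16 bits allocated, unsigned or two's-complement pixel representation.
# Everything else (compressed syntaxes, color, sequences with undefined
# length inside the image tags we need) is rejected with a decode error.
# Metadata beyond Rows/Columns/BitsAllocated/PixelRepresentation is ignored.

read_dicom_pixels <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop_spinocurve("not a DICOM part-10 file (missing DICM magic)", "decode_error")

  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()
  pixel_raw <- NULL
  explicit <- TRUE   # the 0002 meta group is always explicit little-endian
  pos <- 133L
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group != 2L && !is.null(fields$ts))
      explicit <- identical(fields$ts, "1.2.840.10008.1.2.1")
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); data_at <- pos + 12L
      } else {
        len <- u16(pos + 6L); data_at <- pos + 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); data_at <- pos + 8L
    }
    if (len < 0 || len == 4294967295)
      stop_spinocurve("undefined-length DICOM element not supported", "decode_error")
    data <- if (len > 0L) raw[data_at:(data_at + len - 1L)] else raw(0)
    key <- sprintf("%04x%04x", group, elem)
    if (key == "00020010")
      fields$ts <- sub(" +$", "", rawToChar(data[data != as.raw(0)]))
    if (key == "00280010") fields$rows <- u16(data_at)
    if (key == "00280011") fields$cols <- u16(data_at)
    if (key == "00280100") fields$bits <- u16(data_at)
    if (key == "00280103") fields$pixrep <- u16(data_at)
    if (key == "00280002" && u16(data_at) != 1L)
      stop_spinocurve("only monochrome (1 sample/pixel) DICOM supported",
                      "decode_error")
    if (key == "7fe00010") { pixel_raw <- data; break }
    pos <- data_at + len
  }

  if (!is.null(fields$ts) &&
      !fields$ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop_spinocurve(sprintf("unsupported DICOM transfer syntax: %s", fields$ts),
                    "decode_error")
  if (is.null(pixel_raw) || is.null(fields$rows) || is.null(fields$cols) ||
      is.null(fields$bits))
    stop_spinocurve("incomplete DICOM image (missing pixel data or shape)",
                    "decode_error")

  n <- fields$rows * fields$cols
  vals <- if (fields$bits <= 8L) {
    if (length(pixel_raw) < n) stop_spinocurve("truncated pixel data", "decode_error")
    as.integer(pixel_raw[seq_len(n)])
  } else {
    if (length(pixel_raw) < 2L * n)
      stop_spinocurve("truncated pixel data", "decode_error")
    signed <- identical(fields$pixrep, 1L)
    readBin(pixel_raw, "integer", n = n, size = 2L, signed = signed,
            endian = "little")
  }
  # DICOM stores pixels row-major (fastest along columns)
  matrix(vals, nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
}
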