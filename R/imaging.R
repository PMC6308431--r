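# Image acquisition and standardization.
#
# Every downstream stage works on the canonical working image: 640 x 480,
# single channel, 8-bit range, contrast-stretched so that 1% of the mass
# (0.5% low + 0.5% high) saturates. 640 x 480 is the lowest standard
# resolution that still carries enough texture for grading.

# ITU-R BT.601 luminance weights (R, G, B); module constant.
GRAYSCALE_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Load a raw embryo image
#'
#' Reads BMP, JPEG or PNG into a `raw_image`: an 8-bit pixel array (matrix for
#' single-channel input, H x W x 3 array for RGB) plus a source tag. No
#' resizing or intensity change is performed at this stage.
#'
#' @param path path to a BMP, JPG/JPEG or PNG file.
#' @param source_tag provenance tag: `"microscope"`, `"smartphone"` or
#'   `"synthetic"`.
#' @return a `raw_image` list with elements `pixels` (values in \[0, 255\]),
#'   `source_tag` and `origin_path`.
#' @export
load_image <- function(path, source_tag = c("microscope", "smartphone",
                                            "synthetic")) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    bmp = read_bmp(path),
    png = ,
    jpg = ,
    jpeg = read_via_ebimage(path),
    stop("unsupported image format '", ext, "' for: ", path)
  )
  new_raw_image(px, source_tag, path)
}

new_raw_image <- function(pixels, source_tag = "synthetic",
                          origin_path = "in-memory") {
  if (length(dim(pixels)) == 3 && dim(pixels)[3] == 1)
    pixels <- pixels[, , 1]
  nch <- if (is.matrix(pixels)) 1L else dim(pixels)[3]
  if (!nch %in% c(1L, 3L))
    stop("unsupported channel count: ", nch, " (need 1 or 3)")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("image too small: need at least 16 x 16 pixels")
  structure(list(pixels = pixels, source_tag = source_tag,
                 origin_path = origin_path),
            class = "raw_image")
}

read_via_ebimage <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image file ", path,
                                           ": ", conditionMessage(e)))
  d <- dim(img)  # EBImage: x (cols), y (rows), [channels]
  a <- EBImage::imageData(img) * 255
  if (length(d) == 2) return(t(a))
  if (d[3] >= 3) {
    out <- array(0, c(d[2], d[1], 3))
    for (ch in 1:3) out[, , ch] <- t(a[, , ch])
    return(out)
  }
  t(a[, , 1])
}

# Minimal decoder for uncompressed (BI_RGB) 8-bit palette and 24-bit BMP.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("cannot decode image file ", path, ": not a BMP")
  readBin(con, "integer", 2, size = 4)            # file size, reserved
  data_offset <- readBin(con, "integer", 1, size = 4)
  header_size <- readBin(con, "integer", 1, size = 4)
  if (header_size < 40) stop("cannot decode image file ", path,
                             ": unsupported BMP header")
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)            # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  compression <- readBin(con, "integer", 1, size = 4)
  if (compression != 0 || !bpp %in% c(8L, 24L))
    stop("cannot decode image file ", path,
         ": only uncompressed 8-bit or 24-bit BMP supported")
  flipped <- h > 0
  h <- abs(h)
  palette <- NULL
  if (bpp == 8) {
    seek(con, 14 + header_size)
    n_pal <- (data_offset - 14 - header_size) %/% 4
    pal_raw <- readBin(con, "raw", n_pal * 4)
    palette <- matrix(as.integer(pal_raw), ncol = 4, byrow = TRUE)[, 1:3]
  }
  seek(con, data_offset)
  row_bytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  raw_px <- readBin(con, "raw", row_bytes * h)
  if (length(raw_px) < row_bytes * h)
    stop("cannot decode image file ", path, ": truncated pixel data")
  rows <- matrix(as.integer(raw_px), nrow = row_bytes)[, seq_len(h),
                                                       drop = FALSE]
  if (bpp == 8) {
    idx <- rows[seq_len(w), , drop = FALSE] + 1L
    gray <- matrix(rowMeans(matrix(palette[idx, ], ncol = 3)), nrow = w)
    out <- t(gray)
  } else {
    b <- rows[seq(1, w * 3, by = 3), , drop = FALSE]
    g <- rows[seq(2, w * 3, by = 3), , drop = FALSE]
    r <- rows[seq(3, w * 3, by = 3), , drop = FALSE]
    out <- array(0, c(h, w, 3))
    out[, , 1] <- t(r); out[, , 2] <- t(g); out[, , 3] <- t(b)
  }
  if (flipped) {
    if (is.matrix(out)) out <- out[rev(seq_len(h)), , drop = FALSE]
    else out <- out[rev(seq_len(h)), , , drop = FALSE]
  }
  out
}

#' Convert a raw image to 8-bit grayscale
#'
#' Three-channel input is combined with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114) and rounded half-up; single-channel input passes
#' through unchanged.
#'
#' @param img a `raw_image` or pixel array.
#' @return numeric intensity matrix in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  px <- if (inherits(img, "raw_image")) img$pixels else img
  if (is.matrix(px)) return(px)
  if (length(dim(px)) != 3 || !dim(px)[3] %in% c(1L, 3L))
    stop("unsupported channel count for grayscale conversion")
  if (dim(px)[3] == 1) return(px[, , 1])
  y <- px[, , 1] * GRAYSCALE_WEIGHTS[1] + px[, , 2] * GRAYSCALE_WEIGHTS[2] +
    px[, , 3] * GRAYSCALE_WEIGHTS[3]
  floor(y + 0.5)  # round half-up
}

# Quantile contrast stretch: the lowest frac/2 maps to 0 and the highest
# frac/2 to 255, linear in between. Identity on (near-)constant input.
# Quantiles are taken from `ref` (the un-padded image content) so that
# synthetic pad margins do not distort the mapping.
stretch_saturate <- function(m, saturation_fraction = 0.01, ref = m) {
  q <- stats::quantile(ref, c(saturation_fraction / 2,
                              1 - saturation_fraction / 2),
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) return(m)
  pmin(pmax((m - q[1]) / (q[2] - q[1]) * 255, 0), 255)
}

#' Standardize a raw image to the canonical working format
#'
#' Grayscale conversion, aspect-preserving resize to 640 x 480 (the larger
#' relative dimension is scaled to fit and the remainder is center-padded with
#' the median border intensity; pad margins are recorded so segmentation can
#' ignore them), then a quantile contrast stretch in which
#' `saturation_fraction` of the pixel mass saturates, split evenly between the
#' dark and bright ends.
#'
#' @param img a `raw_image`, or any pixel array.
#' @param saturation_fraction total saturated proportion (default 0.01 = 1%).
#' @return a `std_image`: list with `pixels` (480 x 640 matrix in \[0, 255\]),
#'   `saturation_fraction`, `pad` (top/bottom/left/right pad widths) and
#'   `provenance`.
#' @export
standardize <- function(img, saturation_fraction = 0.01) {
  gray <- to_grayscale(img)
  out_h <- 480L; out_w <- 640L
  scale <- min(out_h / nrow(gray), out_w / ncol(gray))
  new_h <- max(1L, round(nrow(gray) * scale))
  new_w <- max(1L, round(ncol(gray) * scale))
  resized <- resample_image(gray, new_h, new_w, "bilinear")
  border <- c(resized[1, ], resized[new_h, ], resized[, 1], resized[, new_w])
  fill <- stats::median(border)
  top <- (out_h - new_h) %/% 2L
  left <- (out_w - new_w) %/% 2L
  canvas <- matrix(fill, out_h, out_w)
  canvas[top + seq_len(new_h), left + seq_len(new_w)] <- resized
  pad <- c(top = top, bottom = out_h - new_h - top,
           left = left, right = out_w - new_w - left)
  stretched <- stretch_saturate(canvas, saturation_fraction, ref = resized)
  structure(list(pixels = round(stretched),
                 saturation_fraction = saturation_fraction,
                 pad = pad,
                 provenance = if (inherits(img, "raw_image"))
                   img$origin_path else "in-memory"),
            class = "std_image")
}

#' @export
print.std_image <- function(x, ...) {
  cat("<std_image> 480 x 640, range [", min(x$pixels), ",", max(x$pixels),
      "], pad", paste(x$pad, collapse = "/"), "\n")
  invisible(x)
}

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<raw_image>", d[1], "x", d[2], "x", if (length(d) == 3) d[3] else 1,
      "|", x$source_tag, "|", x$origin_path, "\n")
  invisible(x)
}
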