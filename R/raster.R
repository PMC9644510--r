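# Images are plain numeric arrays dim c(height, width, 3) with values on the
# 8-bit scale [0, 255] (stored as doubles; quantisation happens only on file
# write). Single-channel maps (optical density etc.) are height x width
# matrices.

assert_rgb <- function(x, what = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(what, " must be a height x width x 3 array", call. = FALSE)
  if (any(!is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Read an RGB image into an 8-bit-scale array
#'
#' Reads PNG/TIFF/JPEG into a `height x width x 3` numeric array on the
#' \[0, 255\] scale.
#'
#' @param path image file path.
#' @return numeric array `h x w x 3`, values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
  } else {
    # EBImage handles jpeg and anything else it supports; its arrays are
    # width x height so transpose back
    e <- EBImage::imageData(EBImage::readImage(path))
    img <- aperm(e, c(2, 1, seq_len(length(dim(e)))[-(1:2)]))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB array as a PNG file
#'
#' @param img `h x w x 3` array on the \[0, 255\] scale.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  assert_rgb(img)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Convert 8-bit RGB intensities to optical density
#'
#' Beer-Lambert transform `OD = -log10((I + eps)/255)` per channel, with a
#' small guard `eps` so that `I = 0` stays finite. Values are clipped at 0
#' (a pure-white pixel maps to zero absorbance).
#'
#' @param img `h x w x 3` array on the \[0, 255\] scale (or a matrix for a
#'   single channel).
#' @param eps additive guard in intensity units (default 1).
#' @return array/matrix of the same shape holding optical densities (>= 0).
#' @seealso [od_to_rgb()] for the exact inverse.
#' @export
rgb_to_od <- function(img, eps = 1) {
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] != 3L)
    stop("rgb_to_od expects a 3-channel image", call. = FALSE)
  od <- -log10((pmax(img, 0) + eps) / 255)
  od[od < 0] <- 0
  od
}

#' Convert optical density back to 8-bit-scale intensities
#'
#' Inverse of [rgb_to_od()]: `I = 255 * 10^(-OD) - eps`, clipped to \[0, 255\].
#'
#' @param od optical-density array or matrix.
#' @inheritParams rgb_to_od
#' @return intensities on the \[0, 255\] scale.
#' @export
od_to_rgb <- function(od, eps = 1) {
  pmin(pmax(255 * 10^(-od) - eps, 0), 255)
}

# Vectorised RGB (0..255) -> HSV with hue in [0, 360), s and v in [0, 1].
# Zero-saturation pixels get hue 0 (grDevices convention).
rgb_to_hsv_planes <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  m <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]), maxColorValue = 255
  )
  list(
    h = matrix(m[1, ] * 360, d[1], d[2]),
    s = matrix(m[2, ], d[1], d[2]),
    v = matrix(m[3, ], d[1], d[2])
  )
}

# Summed-area table of a matrix, padded with a leading zero row/column, so
# that the sum over rows r..r+k-1, cols c..c+k-1 is
# S[r+k, c+k] - S[r, c+k] - S[r+k, c] + S[r, c].
summed_area_table <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Mean filter over k x k windows at every valid origin (used by the patch
# response map and by the synthetic generator's field smoothing).
box_mean <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  if (h < k || w < k)
    stop("image (", h, "x", w, ") smaller than the ", k, "x", k, " window",
         call. = FALSE)
  s <- summed_area_table(m)
  ir <- seq_len(h - k + 1L); ic <- seq_len(w - k + 1L)
  (s[ir + k, ic + k, drop = FALSE] - s[ir, ic + k, drop = FALSE] -
     s[ir + k, ic, drop = FALSE] + s[ir, ic, drop = FALSE]) / (k * k)
}
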