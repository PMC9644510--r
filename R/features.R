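# Handcrafted 1247-dimensional colour descriptor:
#   1012 colour-histogram values (10x10x10 joint RGB + 12-bin hue),
#     33 colour moments (mean/var/skew/kurt over R,G,B,H,S,V + median/min/max
#        of R,G,B),
#     54 colour-coherence-vector values (27 quantised colours x
#        coherent/incoherent),
#    128 colour-autocorrelogram values (32 HSV colours x distances 1,3,5,7),
#     20 characteristic-curve values (stain-colour pixel percentage as the
#        saturation lower bound rises).

#' Feature extraction configuration
#'
#' @param ccv_tau coherence area threshold in pixels: connected same-colour
#'   regions of at least this size count as coherent.
#' @param ccv_levels quantisation levels per RGB axis for the CCV (3 gives
#'   27 colour buckets).
#' @param corr_distances Chebyshev ring distances of the autocorrelogram.
#' @param curve characteristic-curve bounds: list with `h1`, `h2` (hue
#'   degrees, stain window `h1 <= h < h2`), `v1`, `v2` (value bounds), and
#'   `s_grid`, the 20 saturation lower bounds.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(ccv_tau = 25, ccv_levels = 3,
                           corr_distances = c(1, 3, 5, 7),
                           curve = list(h1 = 20, h2 = 50, v1 = 0.2,
                                        v2 = 0.95,
                                        s_grid = seq(0.10, 0.48,
                                                     by = 0.02))) {
  if (ccv_tau <= 0) stop("ccv_tau must be positive", call. = FALSE)
  if (curve$h1 >= curve$h2 || curve$v1 >= curve$v2)
    stop("curve bounds must satisfy h1 < h2 and v1 < v2", call. = FALSE)
  if (is.unsorted(curve$s_grid, strictly = TRUE))
    stop("s_grid must be strictly increasing", call. = FALSE)
  structure(list(ccv_tau = ccv_tau, ccv_levels = as.integer(ccv_levels),
                 corr_distances = as.integer(corr_distances), curve = curve),
            class = "feature_config")
}

#' Named block layout of the 1247-dimensional descriptor
#'
#' @return data.frame with block name, start, end (1-based, inclusive) and
#'   length: histogram 1-1012, moments 1013-1045, ccv 1046-1099,
#'   correlogram 1100-1227, curves 1228-1247.
#' @export
feature_blocks <- function() {
  len <- c(histogram = 1012L, moments = 33L, ccv = 54L,
           correlogram = 128L, curves = 20L)
  end <- cumsum(len)
  data.frame(block = names(len), start = end - len + 1L, end = end,
             length = len, row.names = NULL)
}

#' Colour histogram (1012 values)
#'
#' Concatenation of a 10x10x10 joint RGB histogram (1000 bins) and a 12-bin
#' hue histogram, each normalised to sum 1.
#'
#' @param img `h x w x 3` array on the \[0, 255\] scale.
#' @param config a [feature_config()].
#' @return numeric vector of length 1012.
#' @export
color_histogram <- function(img, config = feature_config()) {
  assert_rgb(img)
  n <- prod(dim(img)[1:2])
  if (n == 0L) stop("empty image", call. = FALSE)
  q <- function(ch) pmin(floor(as.vector(img[, , ch]) * 10 / 256), 9)
  idx <- 1L + q(1) + 10L * q(2) + 100L * q(3)
  joint <- tabulate(idx, nbins = 1000L) / n
  hsv <- rgb_to_hsv_planes(img)
  hb <- tabulate(1L + pmin(floor(as.vector(hsv$h) / 30), 11), nbins = 12L) / n
  c(joint, hb)
}

moment4 <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)             # population convention
  if (v <= .Machine$double.eps * max(1, m^2)) return(c(m, 0, 0, 0))
  c(m, v, mean((x - m)^3) / v^1.5, mean((x - m)^4) / v^2 - 3)
}

#' Colour moments (33 values)
#'
#' Mean, population variance, skewness and excess kurtosis of each of
#' R, G, B (0-255 scale), H (degrees), S, V (24 values), followed by the
#' median, min and max of R, G, B (9 values). Zero-variance channels report
#' 0 skewness/kurtosis.
#'
#' @inheritParams color_histogram
#' @return numeric vector of length 33.
#' @export
color_moments <- function(img, config = feature_config()) {
  assert_rgb(img)
  hsv <- rgb_to_hsv_planes(img)
  chans <- list(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]), as.vector(hsv$h), as.vector(hsv$s),
                as.vector(hsv$v))
  mom <- unlist(lapply(chans, moment4), use.names = FALSE)
  ord <- unlist(lapply(chans[1:3], function(x)
    c(median(x), min(x), max(x))), use.names = FALSE)
  c(mom, ord)
}

# 8-connected component size per pixel of a logical mask: EBImage
# 4-connected labelling followed by union of diagonally adjacent labels.
# Returns, for each TRUE pixel (column-major order), the size of its merged
# component.
pixel_component_sizes_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (nl == 0L) return(integer(0))
  sizes <- tabulate(lab[lab > 0], nbins = nl)
  h <- nrow(lab); w <- ncol(lab)
  if (h > 1L && w > 1L) {
    a <- lab[-h, -w]; b <- lab[-1, -1]     # down-right diagonal pairs
    c_ <- lab[-1, -w]; d <- lab[-h, -1]    # up-right diagonal pairs
    k1 <- a > 0 & b > 0 & a != b
    k2 <- c_ > 0 & d > 0 & c_ != d
    edges <- rbind(cbind(a[k1], b[k1]), cbind(c_[k2], d[k2]))
    if (nrow(edges)) {
      g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, nl - igraph::vcount(g)))
      memb <- igraph::components(g)$membership[seq_len(nl)]
      merged <- as.numeric(tapply(sizes, memb, sum))  # indexed by 1..n_comp
      sizes <- merged[memb]
    }
  }
  sizes[lab[lab > 0]]
}

#' Colour coherence vector (54 values)
#'
#' RGB is quantised to 27 colours (3 levels per axis); within each colour,
#' pixels belonging to 8-connected components of at least `ccv_tau` pixels
#' are coherent, the rest incoherent. Output is the
#' (coherent, incoherent) pixel fraction per colour; all 54 values sum to 1.
#'
#' @inheritParams color_histogram
#' @return numeric vector of length 54.
#' @export
color_coherence_vector <- function(img, config = feature_config()) {
  assert_rgb(img)
  L <- config$ccv_levels
  n <- prod(dim(img)[1:2])
  q <- function(ch) pmin(floor(img[, , ch] * L / 256), L - 1)
  qidx <- q(1) + L * q(2) + L * L * q(3)     # h x w matrix of 0..26
  out <- numeric(2L * L^3)
  for (col in sort(unique(as.vector(qidx)))) {
    mask <- qidx == col
    px_sizes <- pixel_component_sizes_8(mask)
    coh <- sum(px_sizes >= config$ccv_tau)
    out[2L * col + 1L] <- coh / n
    out[2L * col + 2L] <- (sum(mask) - coh) / n
  }
  out
}

#' Colour autocorrelogram (128 values)
#'
#' HSV is quantised to 32 colours (4 hue x 4 saturation x 2 value levels).
#' For each colour c and Chebyshev ring distance d in `corr_distances`, the
#' entry is the probability that a pixel at distance exactly d from a
#' colour-c pixel also has colour c (in-bounds neighbours only; colours
#' absent from the image report 0). Layout: colour-major, distances inner.
#'
#' @inheritParams color_histogram
#' @return numeric vector of length `32 * length(corr_distances)` (128 by
#'   default), values in \[0, 1\].
#' @export
color_correlogram <- function(img, config = feature_config()) {
  assert_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  dmax <- max(config$corr_distances)
  if (h < 2 * dmax + 1 || w < 2 * dmax + 1)
    stop("image smaller than 2*max(distance)+1 = ", 2 * dmax + 1, call. = FALSE)
  hsv <- rgb_to_hsv_planes(img)
  Q <- pmin(floor(hsv$h / 90), 3) + 4 * pmin(floor(hsv$s * 4), 3) +
    16 * pmin(floor(hsv$v * 2), 1)          # 0..31 matrix
  out <- numeric(32L * length(config$corr_distances))
  for (di in seq_along(config$corr_distances)) {
    d <- config$corr_distances[di]
    offs <- expand.grid(dy = -d:d, dx = -d:d)
    offs <- offs[pmax(abs(offs$dy), abs(offs$dx)) == d, ]
    match_c <- numeric(32L); total_c <- numeric(32L)
    for (o in seq_len(nrow(offs))) {
      dy <- offs$dy[o]; dx <- offs$dx[o]
      r_a <- max(1, 1 - dy):min(h, h - dy)
      c_a <- max(1, 1 - dx):min(w, w - dx)
      A <- Q[r_a, c_a, drop = FALSE]
      B <- Q[r_a + dy, c_a + dx, drop = FALSE]
      total_c <- total_c + tabulate(A + 1L, nbins = 32L)
      eq <- A == B
      match_c <- match_c + tabulate(A[eq] + 1L, nbins = 32L)
    }
    vals <- ifelse(total_c > 0, match_c / total_c, 0)
    out[(seq_len(32L) - 1L) * length(config$corr_distances) + di] <- vals
  }
  out
}

#' Characteristic curve (20 values)
#'
#' Percentage of pixels whose colour lies in the stain window
#' (`h1 <= h < h2`, `v1 <= v < v2`) with saturation strictly above
#' `s_low`, evaluated at each of the 20 grid points of `s_grid`. The curve
#' is non-increasing in `s_low`.
#'
#' @inheritParams color_histogram
#' @return numeric vector of percentages (length of `s_grid`, 20 by
#'   default).
#' @export
characteristic_curve <- function(img, config = feature_config()) {
  assert_rgb(img)
  cv <- config$curve
  hsv <- rgb_to_hsv_planes(img)
  gate <- hsv$h >= cv$h1 & hsv$h < cv$h2 & hsv$v >= cv$v1 & hsv$v < cv$v2
  s <- hsv$s[gate]
  n <- length(hsv$s)
  vapply(cv$s_grid, function(sl) 100 * sum(s > sl) / n, numeric(1))
}

feature_vector_one <- function(img, config) {
  v <- c(color_histogram(img, config), color_moments(img, config),
         color_coherence_vector(img, config),
         color_correlogram(img, config), characteristic_curve(img, config))
  if (any(!is.finite(v))) stop("non-finite feature value", call. = FALSE)
  v
}

feature_names <- function() {
  blk <- feature_blocks()
  unlist(mapply(function(b, l) sprintf("%s_%03d", b, seq_len(l)),
                blk$block, blk$length, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Extract the 1247-dimensional descriptor of an image or patch set
#'
#' Whole-image mode computes the five feature blocks on the full image.
#' Patch mode computes a descriptor per patch of a [extract_top_patches()]
#' result and averages them component-wise (the image descriptor is the
#' mean of its patch descriptors).
#'
#' @param image `h x w x 3` RGB array on the \[0, 255\] scale.
#' @param patches optional `patch_set`; when given, patch mode is used.
#' @param config a [feature_config()].
#' @return named numeric vector of length 1247 with attribute `blocks`
#'   (see [feature_blocks()]).
#' @export
extract_features <- function(image, patches = NULL,
                             config = feature_config()) {
  assert_rgb(image)
  if (is.null(patches)) {
    v <- feature_vector_one(image, config)
  } else {
    pt <- patches$patches
    if (is.null(pt) || nrow(pt) == 0L)
      stop("empty patch set", call. = FALSE)
    acc <- 0
    for (i in seq_len(nrow(pt))) {
      blockpx <- crop_patch(image, pt$row0[i], pt$col0[i], patches$size)
      acc <- acc + feature_vector_one(blockpx, config)
    }
    v <- acc / nrow(pt)
  }
  names(v) <- feature_names()
  attr(v, "blocks") <- feature_blocks()
  v
}
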