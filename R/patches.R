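# Patch-of-interest extraction: whole IHC images are dominated by unstained
# stroma and unspecific background, so classification works on the K most
# protein-stained square patches, ranked by a mean-filter response on the
# unmixed protein channel.

#' Mean-filter response map of a protein channel
#'
#' `response(r, c)` is the mean protein optical density over the
#' `size x size` window whose top-left corner sits at (r, c), computed for
#' every valid origin (stride 1, box filter).
#'
#' @param protein_od protein concentration matrix from [unmix()].
#' @param size window side in pixels (default 224).
#' @return `(h - size + 1) x (w - size + 1)` response matrix.
#' @export
response_map <- function(protein_od, size = 224) {
  box_mean(as.matrix(protein_od), as.integer(size))
}

#' Extract the K most-stained patches of an image
#'
#' Patch origins are ranked by descending mean-filter response; ties are
#' broken in row-major origin order. Overlapping patches are permitted
#' (inevitable at large K). Each patch carries its protein-fraction value:
#' the percentage of its pixels whose protein OD exceeds `od_threshold`.
#'
#' @inheritParams response_map
#' @param k number of patches (>= 1).
#' @param od_threshold DAB positivity floor in OD units (default 0.15).
#' @param image_id identifier carried on the result.
#' @return object of class `patch_set`: list with `image_id`, `k`, `size`,
#'   and `patches`, a data.frame (row0, col0 0-based origins, response,
#'   fraction) ordered by non-increasing response.
#' @export
extract_top_patches <- function(protein_od, k, size = 224,
                                od_threshold = 0.15, image_id = "image") {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  resp <- response_map(protein_od, size)
  n <- length(resp)
  if (n < k)
    stop("only ", n, " valid patch origins available, need k = ", k,
         call. = FALSE)
  # fraction of positive pixels for every origin, via a second summed table
  pos <- box_mean((as.matrix(protein_od) > od_threshold) * 1, size) * 100
  rr <- row(resp); cc <- col(resp)
  ord <- order(-resp, rr, cc)[seq_len(k)]       # row-major tie-break
  patches <- data.frame(
    row0 = rr[ord] - 1L, col0 = cc[ord] - 1L,
    response = resp[ord], fraction = pos[ord]
  )
  structure(list(image_id = image_id, k = k, size = as.integer(size),
                 patches = patches),
            class = "patch_set")
}

#' Protein fraction of a patch
#'
#' Percentage of pixels whose protein OD exceeds the positivity threshold.
#'
#' @param patch_od protein OD matrix of the patch.
#' @param od_threshold positivity floor in OD units.
#' @return percentage in \[0, 100\].
#' @export
protein_fraction <- function(patch_od, od_threshold = 0.15) {
  100 * mean(patch_od > od_threshold)
}

#' Mean stain intensity of a protein channel after background removal
#'
#' Background pixels are those below the positivity threshold (or an
#' explicit mask); the mean OD over the remaining foreground is returned.
#'
#' @param protein_od protein OD matrix.
#' @param background_mask optional logical matrix marking background pixels;
#'   defaults to `protein_od <= od_threshold`.
#' @param od_threshold positivity floor used when no mask is given.
#' @return mean foreground OD (scalar).
#' @export
mean_channel_intensity <- function(protein_od, background_mask = NULL,
                                   od_threshold = 0.15) {
  if (is.null(background_mask)) background_mask <- protein_od <= od_threshold
  if (!identical(dim(background_mask), dim(protein_od)))
    stop("mask shape mismatch", call. = FALSE)
  fg <- protein_od[!background_mask]
  if (length(fg) == 0L) stop("empty foreground", call. = FALSE)
  mean(fg)
}

# crop the pixel block of one patch out of an image or channel
crop_patch <- function(x, row0, col0, size) {
  if (length(dim(x)) == 3L)
    x[row0 + seq_len(size), col0 + seq_len(size), , drop = FALSE]
  else
    x[row0 + seq_len(size), col0 + seq_len(size), drop = FALSE]
}
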