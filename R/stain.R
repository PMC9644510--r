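# Linear spectral unmixing of H-DAB stains in optical-density space.
# Stain concentrations combine linearly in OD (Beer-Lambert), so a per-pixel
# least-squares solve against the stain basis separates the brown DAB
# (protein) channel from the purple hematoxylin (nuclear) channel.

#' Construct a stain matrix
#'
#' Columns are unit-norm optical-density absorption vectors, one per stain.
#' The default is the community-standard H-DAB pair: hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778).
#'
#' @param vectors 3 x n numeric matrix of stain OD triples (columns), or
#'   `NULL` for the H-DAB default.
#' @param names stain names, one per column; must include `"dab"` (the
#'   protein stain) for downstream channel naming.
#' @return object of class `stain_matrix`: unit-normalised 3 x n matrix with
#'   column names.
#' @examples
#' M <- stain_matrix()
#' colSums(M^2)  # unit norms
#' @export
stain_matrix <- function(vectors = NULL,
                         names = c("hematoxylin", "dab")) {
  if (is.null(vectors)) {
    vectors <- cbind(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L)
    stop("stain vectors must be OD triples (3 rows)", call. = FALSE)
  if (length(names) != ncol(vectors))
    stop("one name per stain vector required", call. = FALSE)
  if (any(vectors < 0))
    stop("stain vectors must have non-negative components", call. = FALSE)
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop("zero stain vector", call. = FALSE)
  vectors <- sweep(vectors, 2, nrm, "/")
  if (qr(vectors)$rank < ncol(vectors))
    stop("stain vectors are linearly dependent", call. = FALSE)
  colnames(vectors) <- names
  structure(vectors, class = c("stain_matrix", "matrix"))
}

#' Unmix an optical-density image into per-stain concentration channels
#'
#' Per-pixel least squares `OD = M %*% c`; negative concentrations are
#' clipped to zero (or, with `nonneg = TRUE`, resolved by an exact two-stain
#' non-negative solve). The per-pixel Euclidean residual of the clipped
#' reconstruction is recorded.
#'
#' @param od `h x w x 3` optical-density array (see [rgb_to_od()]).
#' @param matrix a [stain_matrix()].
#' @param nonneg use exact non-negative least squares instead of
#'   clip-after-solve (differences arise only at near-blank pixels).
#' @return object of class `stain_channels`: list with `protein_od` (DAB
#'   concentration matrix), `dna_od` (hematoxylin), `residual`, and the
#'   matrix used.
#' @export
unmix <- function(od, matrix = stain_matrix(), nonneg = FALSE) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("od must be a h x w x 3 array", call. = FALSE)
  M <- unclass(matrix)
  mtm <- crossprod(M)
  if (abs(det(mtm)) < 1e-12)
    stop("singular stain matrix", call. = FALSE)
  d <- dim(od)
  X <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- X %*% M %*% solve(mtm)           # n x n_stains
  if (nonneg && ncol(M) == 2L) {
    neg <- which(conc[, 1] < 0 | conc[, 2] < 0)
    if (length(neg)) {
      # exact NNLS for 2 variables: best single-stain fit, clipped at 0
      for (j in 1:2) {
        cj <- pmax(X[neg, , drop = FALSE] %*% M[, j] / sum(M[, j]^2), 0)
        rj <- rowSums((X[neg, , drop = FALSE] -
                         cj %*% t(M[, j]))^2)
        if (j == 1L) { c1 <- cj; r1 <- rj } else { c2 <- cj; r2 <- rj }
      }
      use1 <- r1 <= r2
      conc[neg, 1] <- ifelse(use1, c1, 0)
      conc[neg, 2] <- ifelse(use1, 0, c2)
    }
  }
  conc[conc < 0] <- 0
  resid <- sqrt(rowSums((X - conc %*% t(M))^2))
  idx_dab <- match("dab", colnames(M))
  if (is.na(idx_dab)) idx_dab <- ncol(M)
  idx_dna <- if (ncol(M) >= 2L) setdiff(seq_len(ncol(M)), idx_dab)[1] else NA
  structure(list(
    protein_od = matrix(conc[, idx_dab], d[1], d[2]),
    dna_od = if (!is.na(idx_dna)) matrix(conc[, idx_dna], d[1], d[2]) else NULL,
    residual = matrix(resid, d[1], d[2]),
    matrix = matrix
  ), class = "stain_channels")
}

#' Recombine stain channels into an optical-density image
#'
#' Linear recombination `M %*% c`; the round-trip companion of [unmix()]
#' used mainly for verification.
#'
#' @param channels a `stain_channels` object (or list with `protein_od`,
#'   `dna_od`).
#' @param matrix the [stain_matrix()] to recombine with.
#' @return `h x w x 3` optical-density array.
#' @export
reconstruct <- function(channels, matrix = stain_matrix()) {
  M <- unclass(matrix)
  p <- channels$protein_od
  h <- channels$dna_od
  if (is.null(p)) stop("channels must contain protein_od", call. = FALSE)
  if (!is.null(h) && !identical(dim(p), dim(h)))
    stop("channel shape mismatch", call. = FALSE)
  idx_dab <- match("dab", colnames(M)); if (is.na(idx_dab)) idx_dab <- ncol(M)
  idx_dna <- setdiff(seq_len(ncol(M)), idx_dab)[1]
  X <- as.vector(p) %*% t(M[, idx_dab])
  if (!is.null(h) && !is.na(idx_dna)) X <- X + as.vector(h) %*% t(M[, idx_dna])
  array(X, c(dim(p), 3L))
}
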