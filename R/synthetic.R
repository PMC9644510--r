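# Synthetic H-DAB stained-tissue generator. Images are rendered through the
# Beer-Lambert forward model (transmitted I = bg * 10^(-sum c_s * v_s) - eps,
# the same eps guard as rgb_to_od), so linear unmixing recovers the generated
# concentration maps exactly in the noise-free case. Expression level is
# encoded by the stained-area fraction and DAB optical density.

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Default expression-level rendering map
#'
#' Maps each annotation level to a (stained fraction, DAB optical density)
#' pair. The three classes are separable but overlapping once per-image
#' jitter is added, emulating the graded staining of real tissue.
#'
#' @return named list `low`, `medium`, `high`, each
#'   `c(stained_fraction, dab_od)`.
#' @export
level_render_map <- function() {
  list(low    = c(stained_fraction = 0.15, dab_od = 0.4),
       medium = c(stained_fraction = 0.40, dab_od = 0.7),
       high   = c(stained_fraction = 0.70, dab_od = 1.0))
}

#' Specification of one synthetic IHC image
#'
#' @param width,height image size in pixels.
#' @param n_nuclei number of rendered nuclei; default scales with area
#'   (one per ~2000 px).
#' @param nucleus_radius_range min/max nucleus radius in pixels.
#' @param stained_fraction fraction of tissue area carrying protein stain in
#'   \[0, 1\]; `NA` (default) lets [generate_image()] take it from the level
#'   map.
#' @param tissue_fraction fraction of the image occupied by stainable
#'   tissue (a central disk). The default 1 treats the whole image as
#'   tissue; smaller values emulate sections whose unstained stromal
#'   background surrounds a limited informative area.
#' @param dab_od DAB optical density in stained regions (>= 0); `NA` defers
#'   to the level map.
#' @param hema_od hematoxylin optical density inside nuclei.
#' @param background_rgb incident-light RGB triple (8-bit scale).
#' @param noise_sd additive Gaussian camera noise, 8-bit intensity units.
#' @param seed RNG seed for this image.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 1024, height = 1024, n_nuclei = NULL,
                           nucleus_radius_range = c(6, 14),
                           stained_fraction = NA, dab_od = NA,
                           tissue_fraction = 1,
                           hema_od = 0.6, background_rgb = c(255, 255, 255),
                           noise_sd = 2, seed = 1L) {
  if (width < 8 || height < 8)
    stop("image dimensions must be at least 8 pixels", call. = FALSE)
  if (!is.na(stained_fraction) &&
      (stained_fraction < 0 || stained_fraction > 1))
    stop("stained_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.na(dab_od) && dab_od < 0) stop("dab_od must be >= 0", call. = FALSE)
  if (hema_od < 0) stop("hema_od must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (tissue_fraction <= 0 || tissue_fraction > 1)
    stop("tissue_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_nuclei = as.integer(n_nuclei %||% max(8L, round(width * height / 2000))),
    nucleus_radius_range = nucleus_radius_range,
    stained_fraction = stained_fraction, dab_od = dab_od,
    tissue_fraction = tissue_fraction, hema_od = hema_od,
    background_rgb = background_rgb, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# box blur with edge replication keeping the input size (field smoothing)
blur_same <- function(m, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  r <- (k - 1L) %/% 2L
  pad <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)),
           c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r)), drop = FALSE]
  box_mean(pad, k)
}

# Blob-shaped stain mask covering exactly n_on pixels inside the tissue
# region: smooth random field (blurred noise) thresholded at its empirical
# quantile, restricted to a central disk holding tissue_fraction of the
# image when tissue_fraction < 1.
stain_field_mask <- function(h, w, frac, blob_scale, tissue_fraction = 1) {
  tissue <- matrix(TRUE, h, w)
  if (tissue_fraction < 1) {
    r2 <- tissue_fraction * h * w / pi
    tissue <- outer((seq_len(h) - (h + 1) / 2)^2,
                    (seq_len(w) - (w + 1) / 2)^2, "+") <= r2
  }
  n_on <- round(frac * sum(tissue))
  m <- matrix(FALSE, h, w)
  if (n_on <= 0) return(m)
  if (n_on >= sum(tissue)) { m[tissue] <- TRUE; return(m) }
  field <- blur_same(matrix(runif(h * w), h, w), blob_scale)
  field[!tissue] <- -Inf
  ord <- order(field, decreasing = TRUE)
  m[ord[seq_len(n_on)]] <- TRUE
  m
}

#' Generate one labelled synthetic IHC image
#'
#' Renders purple nuclei (hematoxylin) on a weakly stained stroma and paints
#' the DAB protein stain on a blob-shaped region covering
#' `stained_fraction` of the image, then pushes the optical-density maps
#' through the Beer-Lambert forward model. The true concentration maps and
#' stained-pixel mask are kept as ground truth.
#'
#' Fields `stained_fraction`/`dab_od` left `NA` in `spec` are filled from
#' [level_render_map()] for the requested `level`; explicit values in `spec`
#' win.
#'
#' @param spec a [synthetic_spec()].
#' @param level expression annotation, one of `"high"`, `"medium"`, `"low"`.
#' @param protein_id,condition,image_id metadata carried on the result.
#' @return object of class `labeled_image`: list with `pixels`
#'   (`h x w x 3`, \[0, 255\] scale), `label`, `protein_id`, `condition`,
#'   `image_id`, and `truth` (list `dab_od`, `hema_od`, `mask`,
#'   `stained_fraction`, `dab_value`).
#' @examples
#' img <- generate_image(synthetic_spec(width = 64, height = 64, seed = 3),
#'                       level = "medium")
#' mean(img$truth$mask)  # ~0.40
#' @export
generate_image <- function(spec, level = c("high", "medium", "low"),
                           protein_id = "P1", condition = "normal",
                           image_id = NULL) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec", call. = FALSE)
  level <- match.arg(level)
  lm <- level_render_map()[[level]]
  frac <- spec$stained_fraction %||% lm[["stained_fraction"]]
  dab <- spec$dab_od %||% lm[["dab_od"]]
  h <- spec$height; w <- spec$width
  set.seed(spec$seed)

  # hematoxylin: nuclei disks + weak textured stroma
  hema <- 0.15 * spec$hema_od *
    (0.5 + blur_same(matrix(runif(h * w), h, w), 7L))
  rr <- spec$nucleus_radius_range
  cy <- runif(spec$n_nuclei, 1, h); cx <- runif(spec$n_nuclei, 1, w)
  rad <- runif(spec$n_nuclei, rr[1], rr[2])
  for (i in seq_len(spec$n_nuclei)) {
    r0 <- max(1L, floor(cy[i] - rad[i])); r1 <- min(h, ceiling(cy[i] + rad[i]))
    c0 <- max(1L, floor(cx[i] - rad[i])); c1 <- min(w, ceiling(cx[i] + rad[i]))
    if (r0 > r1 || c0 > c1) next
    yy <- r0:r1; xx <- c0:c1
    dd <- outer((yy - cy[i])^2, (xx - cx[i])^2, "+")
    sub <- hema[yy, xx, drop = FALSE]
    sub[dd <= rad[i]^2] <- spec$hema_od
    hema[yy, xx] <- sub
  }

  blob_scale <- round(mean(rr)) * 2L + 1L
  mask <- stain_field_mask(h, w, frac, blob_scale, spec$tissue_fraction)
  dab_map <- matrix(0, h, w)
  dab_map[mask] <- dab

  M <- unclass(stain_matrix())
  od <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    od[, , ch] <- hema * M[ch, "hematoxylin"] + dab_map * M[ch, "dab"]
  pixels <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    pixels[, , ch] <- spec$background_rgb[ch] * 10^(-od[, , ch]) - 1
  if (spec$noise_sd > 0)
    pixels <- pixels + array(rnorm(length(pixels), 0, spec$noise_sd),
                             dim(pixels))
  pixels <- pmin(pmax(pixels, 0), 255)

  structure(list(
    pixels = pixels, label = level, protein_id = protein_id,
    condition = condition,
    image_id = image_id %||% sprintf("%s_%s_s%d", protein_id, condition,
                                     spec$seed),
    truth = list(dab_od = dab_map, hema_od = hema, mask = mask,
                 stained_fraction = frac, dab_value = dab)
  ), class = "labeled_image")
}

#' Specification of a synthetic cohort
#'
#' @param n_proteins number of proteins.
#' @param images_per_protein images per protein *per condition* (normal and
#'   cancer are both always rendered).
#' @param level_assignment named character vector protein_id -> level, or
#'   `NULL` for a balanced round-robin assignment over low/medium/high.
#' @param effect shift applied to cancer renderings: a single number (added
#'   to `stained_fraction`) or a list with elements `stained_fraction`
#'   and/or `dab_od`.
#' @param affected_proteins protein ids receiving the effect (default all).
#' @param width,height per-image size in pixels.
#' @param fraction_sd,od_sd per-image Gaussian jitter of the rendering
#'   parameters (creates within-level variability).
#' @param noise_sd camera noise passed to each image.
#' @param render_levels if `FALSE`, every image is rendered with the
#'   medium-level parameters regardless of its label (a null cohort for
#'   chance-level checks).
#' @param seed cohort RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_proteins, images_per_protein,
                        level_assignment = NULL, effect = 0,
                        affected_proteins = NULL,
                        width = 1024, height = 1024,
                        fraction_sd = 0.06, od_sd = 0.08, noise_sd = 2,
                        render_levels = TRUE, seed = 1L) {
  if (n_proteins < 1 || images_per_protein < 1)
    stop("n_proteins and images_per_protein must be >= 1", call. = FALSE)
  if (is.numeric(effect) && length(effect) == 1L)
    effect <- list(stained_fraction = effect, dab_od = 0)
  effect$stained_fraction <- effect$stained_fraction %||% 0
  effect$dab_od <- effect$dab_od %||% 0
  pids <- sprintf("P%03d", seq_len(n_proteins))
  if (is.null(level_assignment)) {
    level_assignment <- setNames(
      rep(c("low", "medium", "high"), length.out = n_proteins), pids)
  }
  if (!all(level_assignment %in% c("high", "medium", "low")))
    stop("levels must be high/medium/low", call. = FALSE)
  structure(list(
    n_proteins = as.integer(n_proteins),
    images_per_protein = as.integer(images_per_protein),
    protein_ids = names(level_assignment),
    level_assignment = level_assignment, effect = effect,
    affected_proteins = affected_proteins %||% names(level_assignment),
    width = width, height = height, fraction_sd = fraction_sd,
    od_sd = od_sd, noise_sd = noise_sd, render_levels = render_levels,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Renders `images_per_protein` images per protein in each of the two
#' conditions (normal, cancer). Rendering parameters start from the
#' protein's assigned level ([level_render_map()]), receive per-image
#' Gaussian jitter, and cancer images of affected proteins additionally
#' receive the cohort effect shift. Fully reproducible under the cohort
#' seed.
#'
#' @param cspec a [cohort_spec()].
#' @return list with `images` (list of `labeled_image`) and `manifest`
#'   (data.frame: image_path, image_id, protein_id, condition, label).
#' @export
generate_cohort <- function(cspec) {
  if (!inherits(cspec, "cohort_spec"))
    stop("cspec must be a cohort_spec", call. = FALSE)
  set.seed(cspec$seed)
  images <- list()
  rows <- list()
  counter <- 0L
  for (pid in cspec$protein_ids) {
    lv <- cspec$level_assignment[[pid]]
    base <- if (cspec$render_levels) level_render_map()[[lv]] else
      level_render_map()[["medium"]]
    for (cond in c("normal", "cancer")) {
      sh_f <- if (cond == "cancer" && pid %in% cspec$affected_proteins)
        cspec$effect$stained_fraction else 0
      sh_d <- if (cond == "cancer" && pid %in% cspec$affected_proteins)
        cspec$effect$dab_od else 0
      for (i in seq_len(cspec$images_per_protein)) {
        counter <- counter + 1L
        frac <- min(max(base[["stained_fraction"]] + sh_f +
                          rnorm(1, 0, cspec$fraction_sd), 0.01), 0.99)
        dab <- max(base[["dab_od"]] + sh_d + rnorm(1, 0, cspec$od_sd), 0.05)
        img_seed <- (cspec$seed * 10007L + counter * 131L) %% 2147483597L
        sp <- synthetic_spec(width = cspec$width, height = cspec$height,
                             stained_fraction = frac, dab_od = dab,
                             noise_sd = cspec$noise_sd, seed = img_seed)
        iid <- sprintf("%s_%s_%02d", pid, cond, i)
        images[[iid]] <- generate_image(sp, level = lv, protein_id = pid,
                                        condition = cond, image_id = iid)
        rows[[iid]] <- data.frame(image_path = NA_character_, image_id = iid,
                                  protein_id = pid, condition = cond,
                                  label = lv, stringsAsFactors = FALSE)
      }
    }
  }
  list(images = images, manifest = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Write a cohort to disk as PNG files plus a CSV manifest
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame with `image_path` filled in; also written
#'   to `dir/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    p <- file.path(dir, paste0(man$image_id[i], ".png"))
    write_rgb_image(cohort$images[[man$image_id[i]]]$pixels, p)
    man$image_path[i] <- p
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  man
}
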