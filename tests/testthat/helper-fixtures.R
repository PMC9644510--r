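# Shared in-code fixtures, memoised so expensive objects build once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small noise-free synthetic image with known ground truth
tiny_image <- function(frac = 0.30, dab = 0.8, seed = 7, wh = 64,
                       noise = 0) {
  generate_image(
    synthetic_spec(width = wh, height = wh, stained_fraction = frac,
                   dab_od = dab, noise_sd = noise, seed = seed),
    level = "medium")
}

# deterministic RGB test pattern (not synthetic tissue): blocks of colour
pattern_image <- function(wh = 32) {
  img <- array(0, c(wh, wh, 3))
  img[, , 1] <- 200; img[, , 2] <- 120; img[, , 3] <- 40
  img[seq_len(wh / 2), , 2] <- 220
  img[, seq_len(wh / 2), 3] <- 180
  img
}

# the three-level family with a limited informative tissue area used by the
# patch-count search checks
k_search_family <- function(n_per_level = 12, wh = 64, seed0 = 100) {
  set.seed(99)
  fr <- c(low = 0.20, medium = 0.45, high = 0.75)
  imgs <- list()
  s <- seed0
  for (l in names(fr)) {
    for (i in seq_len(n_per_level)) {
      s <- s + 1
      f <- min(max(fr[[l]] + rnorm(1, 0, 0.05), 0.02), 0.95)
      sp <- synthetic_spec(width = wh, height = wh, stained_fraction = f,
                           dab_od = 0.8, tissue_fraction = 0.15,
                           noise_sd = 1, seed = s)
      imgs[[paste0(l, i)]] <- generate_image(sp, l,
                                             image_id = paste0(l, i))
    }
  }
  imgs
}

# separable / null cohorts for the cross-validation checks (one condition)
cv_cohort <- function(null = FALSE, n_proteins = 30, images = 5, wh = 96,
                      seed = if (null) 12 else 11) {
  co <- generate_cohort(cohort_spec(n_proteins, images, width = wh,
                                    height = wh, render_levels = !null,
                                    seed = seed))
  man <- co$manifest[co$manifest$condition == "normal", ]
  feats <- t(vapply(man$image_id, function(iid)
    extract_features(co$images[[iid]]$pixels), numeric(1247)))
  list(manifest = man, features = feats)
}

crop_patch_px <- function(img, row0, col0, size) {
  img[row0 + seq_len(size), col0 + seq_len(size), , drop = FALSE]
}

# small hyperparameter grids keeping the model checks fast
test_grids <- function() {
  list(svm = expand.grid(cost = c(1, 8, 64), gamma = c(0.01, 0.1, 1)),
       rf = 200)
}
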