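# Pipeline plumbing: one configuration object holding every stage's
# parameters (defaults match the shipped operating point: 224-pixel
# patches, K = 81, K-search grid 11..201 by 10, OD positivity floor 0.15,
# SDA F thresholds 3.84/2.71, 10 folds, alpha 0.05), YAML round-trip, and
# an end-to-end driver from a CSV manifest to artifact files.

#' Pipeline configuration
#'
#' @param patch_size patch side in pixels.
#' @param k patches per image.
#' @param k_grid candidate K values for [select_patch_count()].
#' @param od_threshold DAB positivity floor (OD units).
#' @param mode `"image"` (whole-image features) or `"patch"` (average of
#'   per-patch features).
#' @param model classifier kind (`"svm"`, `"rf"`, `"dnn"`).
#' @param folds cross-validation folds.
#' @param f_enter,f_remove SDA partial-F thresholds.
#' @param max_features SDA cap (`NA` = automatic).
#' @param alpha screening significance level.
#' @param seed pipeline seed.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(patch_size = 224, k = 81,
                            k_grid = seq(11, 201, by = 10),
                            od_threshold = 0.15, mode = "image",
                            model = "svm", folds = 10, f_enter = 3.84,
                            f_remove = 2.71, max_features = NA,
                            alpha = 0.05, seed = 1L) {
  stopifnot(mode %in% c("image", "patch"),
            model %in% c("svm", "rf", "dnn"))
  structure(list(patch_size = as.integer(patch_size), k = as.integer(k),
                 k_grid = as.integer(k_grid), od_threshold = od_threshold,
                 mode = mode, model = model, folds = as.integer(folds),
                 f_enter = f_enter, f_remove = f_remove,
                 max_features = max_features, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config`: the path, invisibly; `load_config`: the
#'   configuration object.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "image_id", "protein_id", "condition", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  man
}

#' Run the full pipeline on a cohort manifest
#'
#' Executes unmixing, patch extraction, feature extraction, grouped
#' cross-validated classification, and (when both conditions are present)
#' biomarker screening; artifacts are written under `out_dir` stamped with
#' the configuration hash and seed.
#'
#' @param manifest data.frame (or CSV path) with columns image_path,
#'   image_id, protein_id, condition, label.
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @param location_p optional location-change P table for the screen.
#' @param images optional named list of in-memory `labeled_image` objects
#'   keyed by image_id (bypasses file reading; used by the synthetic path).
#' @return list with `features`, `cv` (see [cross_validate()]), `screen`
#'   (or `NULL`), `config_hash`, and the artifact paths.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = tempfile("ihcscore_run_"),
                         location_p = NULL, images = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fc <- feature_config()
  feats <- matrix(NA_real_, nrow(manifest), 1247,
                  dimnames = list(manifest$image_id, feature_names()))
  for (i in seq_len(nrow(manifest))) {
    iid <- manifest$image_id[i]
    px <- if (!is.null(images) && !is.null(images[[iid]])) {
      images[[iid]]$pixels
    } else {
      if (is.na(manifest$image_path[i]) ||
          !file.exists(manifest$image_path[i]))
        stop("manifest row ", i, " (", iid, "): image file not found: ",
             manifest$image_path[i], call. = FALSE)
      read_rgb_image(manifest$image_path[i])
    }
    if (config$mode == "patch") {
      ch <- unmix(rgb_to_od(px))
      ps <- extract_top_patches(ch$protein_od, k = config$k,
                                size = config$patch_size,
                                od_threshold = config$od_threshold,
                                image_id = iid)
      feats[i, ] <- extract_features(px, patches = ps, config = fc)
    } else {
      feats[i, ] <- extract_features(px, config = fc)
    }
  }
  plan <- grouped_kfold(manifest$protein_id, k = config$folds,
                        seed = config$seed, labels = manifest$label)
  sda_args <- list(f_enter = config$f_enter, f_remove = config$f_remove)
  if (!is.na(config$max_features))
    sda_args$max_features <- config$max_features
  cv <- cross_validate(feats, manifest$label, manifest$protein_id,
                       manifest$image_id, kind = config$model, plan = plan,
                       sda = sda_args, seed = config$seed)
  scr <- NULL
  pred <- merge(cv$predictions,
                manifest[, c("image_id", "condition")], by = "image_id")
  if (all(c("normal", "cancer") %in% pred$condition) &&
      all(table(pred$protein_id, pred$condition) >= 2))
    scr <- screen_cohort(pred, location_p = location_p,
                         alpha = config$alpha)
  hash <- config_hash(config)
  stamp <- function(df) { df$config_hash <- hash; df$seed <- config$seed; df }
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    metrics = file.path(out_dir, "metrics.json"),
    confusion = file.path(out_dir, "confusion.csv"),
    config = file.path(out_dir, "config.yaml")
  )
  write.csv(data.frame(image_id = rownames(feats), feats,
                       check.names = FALSE), paths$features,
            row.names = FALSE)
  write.csv(stamp(cv$predictions), paths$predictions, row.names = FALSE)
  jsonlite::write_json(list(accuracy = cv$report$accuracy,
                            recall = cv$report$recall,
                            precision = cv$report$precision,
                            f1 = cv$report$f1, config_hash = hash,
                            seed = config$seed),
                       paths$metrics, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame.matrix(cv$report$confusion), paths$confusion)
  save_config(config, paths$config)
  if (!is.null(scr)) {
    paths$screen <- file.path(out_dir, "screen.csv")
    write.csv(stamp(as.data.frame(scr)), paths$screen, row.names = FALSE)
  }
  list(features = feats, cv = cv, screen = scr, config_hash = hash,
       paths = paths)
}
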