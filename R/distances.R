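# Distribution machinery for choosing the patch count K: per-level pools of
# patch protein-fraction values are compared with the first-order Wasserstein
# distance; the K whose three pairwise distances sum largest (averaged over
# random re-samplings) wins. Gaussian fits of the pooled fractions provide
# the simple two-threshold baseline classifier.

#' First-order Wasserstein distance between two 1-D samples
#'
#' Empirical W1 via quantile-function integration: the integral of
#' `|F_a^{-1}(q) - F_b^{-1}(q)|`. For equal-sized samples this equals the
#' mean absolute difference of the sorted samples.
#'
#' @param a,b non-empty numeric samples (sizes may differ).
#' @return distance >= 0; zero iff the empirical distributions coincide.
#' @examples
#' wasserstein_1d(c(0, 1), c(1, 2))  # 1
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  all_v <- sort(c(a, b))
  if (length(all_v) == 1L) return(0)
  deltas <- diff(all_v)
  grid <- all_v[-length(all_v)]
  fa <- findInterval(grid, sort(a)) / length(a)
  fb <- findInterval(grid, sort(b)) / length(b)
  sum(abs(fa - fb) * deltas)
}

#' Maximum-likelihood gamma fit
#'
#' Fits shape/scale by MLE. Zeros (blank patches) are replaced by half the
#' smallest positive value to stay on the gamma support.
#'
#' @param samples numeric vector; must contain variation and no negatives.
#' @return object of class `gamma_fit`: list `shape`, `scale`, `n`.
#' @export
fit_gamma <- function(samples) {
  if (any(samples < 0)) stop("negative values", call. = FALSE)
  pos <- samples[samples > 0]
  if (length(pos) == 0L || stats::var(samples) == 0)
    stop("degenerate sample: no variation on the positive support",
         call. = FALSE)
  samples[samples == 0] <- min(pos) / 2
  # the optimiser probes invalid parameter regions and warns about NaN
  # densities on the way; the converged fit is unaffected
  fit <- suppressWarnings(MASS::fitdistr(samples, "gamma"))
  structure(list(shape = unname(fit$estimate["shape"]),
                 scale = 1 / unname(fit$estimate["rate"]),
                 n = length(samples)),
            class = "gamma_fit")
}

pooled_fractions <- function(img, k_max, size, od_threshold) {
  ch <- unmix(rgb_to_od(img$pixels))
  ps <- extract_top_patches(ch$protein_od, k = k_max, size = size,
                            od_threshold = od_threshold,
                            image_id = img$image_id)
  ps$patches$fraction
}

#' Select the patch count K by the Wasserstein-distance criterion
#'
#' For each candidate K and each of `repeats` random re-samplings of
#' `n_per_level` images per expression level: extract the top-K patches of
#' every sampled image, pool the patch protein-fraction values per level,
#' and sum the three pairwise Wasserstein distances d(high, medium),
#' d(medium, low), d(high, low). The chosen K maximises the repeat-averaged
#' sum. Because the top-K origins for smaller K are a prefix of the ranking
#' for the largest K, patches are extracted once per image at `max(grid)`.
#'
#' @param images list of `labeled_image` objects (all three levels present).
#' @param grid strictly increasing candidate K values (default 11..201 by
#'   10).
#' @param repeats random re-samplings to average over (default 5).
#' @param n_per_level images sampled per level per repeat (default 100;
#'   capped at availability, sampling without replacement).
#' @param size patch side in pixels.
#' @param od_threshold DAB positivity floor for the fraction values.
#' @param seed RNG seed for the re-sampling.
#' @return object of class `patch_count_search`: list with `grid`,
#'   `distances` (data.frame repeat/k/d_high_med/d_med_low/d_high_low/total),
#'   `mean_total` (per K), `chosen_k`.
#' @export
select_patch_count <- function(images, grid = seq(11, 201, by = 10),
                               repeats = 5, n_per_level = 100, size = 224,
                               od_threshold = 0.15, seed = 1L) {
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and strictly increasing", call. = FALSE)
  labels <- vapply(images, function(x) x$label, character(1))
  by_level <- split(seq_along(images), labels)
  missing <- setdiff(c("high", "medium", "low"), names(by_level))
  if (length(missing))
    stop("missing expression level(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  k_max <- max(grid)
  fr <- lapply(images, pooled_fractions, k_max = k_max, size = size,
               od_threshold = od_threshold)
  set.seed(seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    picked <- lapply(by_level, function(idx)
      sample(idx, min(n_per_level, length(idx))))
    for (k in grid) {
      pool <- lapply(picked, function(idx)
        unlist(lapply(fr[idx], function(v) v[seq_len(k)]), use.names = FALSE))
      d_hm <- wasserstein_1d(pool$high, pool$medium)
      d_ml <- wasserstein_1d(pool$medium, pool$low)
      d_hl <- wasserstein_1d(pool$high, pool$low)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, k = k, d_high_med = d_hm, d_med_low = d_ml,
        d_high_low = d_hl, total = d_hm + d_ml + d_hl)
    }
  }
  dist_tab <- do.call(rbind, rows)
  mean_total <- tapply(dist_tab$total, dist_tab$k, mean)
  mean_total <- mean_total[as.character(grid)]
  chosen_k <- grid[which.max(mean_total)]
  structure(list(grid = grid, distances = dist_tab,
                 mean_total = as.numeric(mean_total), chosen_k = chosen_k),
            class = "patch_count_search")
}

# density-intersection point of two Gaussians, constrained between the means
gaussian_intersection <- function(m1, s1, m2, s2) {
  if (m1 >= m2) stop("means must be ordered", call. = FALSE)
  if (abs(s1 - s2) < 1e-12) return((m1 + m2) / 2)
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real density intersection", call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0L)
    stop("no density intersection between the class means", call. = FALSE)
  inside[1]
}

#' Fit per-level Gaussians and derive the two decision thresholds
#'
#' Fits a Gaussian to the pooled patch protein-fraction values of each
#' expression level and returns the density-intersection points of the
#' adjacent pairs (low/medium and medium/high) as classification
#' thresholds.
#'
#' @param fractions_by_level named list with non-empty numeric elements
#'   `low`, `medium`, `high`; means must be ordered low < medium < high.
#' @return object of class `threshold_pair`: list `t_low_med`,
#'   `t_med_high` (with `t_low_med < t_med_high`) plus the fitted
#'   means/sds.
#' @export
fit_gaussian_thresholds <- function(fractions_by_level) {
  need <- c("low", "medium", "high")
  if (!all(need %in% names(fractions_by_level)))
    stop("need elements low, medium, high", call. = FALSE)
  mu <- vapply(fractions_by_level[need], mean, numeric(1))
  sdv <- vapply(fractions_by_level[need], stats::sd, numeric(1))
  if (any(!is.finite(sdv)) || any(sdv == 0))
    stop("each level needs a non-degenerate sample", call. = FALSE)
  if (!(mu[["low"]] < mu[["medium"]] && mu[["medium"]] < mu[["high"]]))
    stop("level means must be ordered low < medium < high", call. = FALSE)
  t1 <- gaussian_intersection(mu[["low"]], sdv[["low"]],
                              mu[["medium"]], sdv[["medium"]])
  t2 <- gaussian_intersection(mu[["medium"]], sdv[["medium"]],
                              mu[["high"]], sdv[["high"]])
  if (!(t1 < t2)) stop("degenerate thresholds (t_low_med >= t_med_high)",
                       call. = FALSE)
  structure(list(t_low_med = t1, t_med_high = t2, means = mu, sds = sdv),
            class = "threshold_pair")
}

#' Classify fraction (or intensity) values by two thresholds
#'
#' Values below `t_low_med` are low, values in
#' \[`t_low_med`, `t_med_high`) medium, and values at or above `t_med_high`
#' high (upper classes are left-closed so every value gets a label).
#'
#' @param x numeric vector of protein-fraction or intensity values.
#' @param thresholds a [fit_gaussian_thresholds()] result, or a list with
#'   `t_low_med < t_med_high`.
#' @return character vector of levels.
#' @export
classify_by_threshold <- function(x, thresholds) {
  t1 <- thresholds$t_low_med; t2 <- thresholds$t_med_high
  if (!(t1 < t2)) stop("invalid thresholds", call. = FALSE)
  ifelse(x < t1, "low", ifelse(x < t2, "medium", "high"))
}

#' Majority-vote image label from per-patch threshold calls
#'
#' @param patch_levels character vector of per-patch levels.
#' @return single level; ties go to the higher expression class.
#' @export
vote_patch_labels <- function(patch_levels) {
  counts <- table(factor(patch_levels, levels = c("high", "medium", "low")))
  names(counts)[which.max(counts)]   # first max: high > medium > low
}
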