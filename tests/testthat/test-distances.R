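# Wasserstein distance, gamma fits, K selection, Gaussian thresholds.

# brute-force W1 for equal-sized samples: mean |sorted difference|
w1_oracle <- function(a, b) mean(abs(sort(a) - sort(b)))

test_that("wasserstein_1d equals the sorted-pairing oracle", {
  expect_equal(wasserstein_1d(c(0, 1), c(1, 2)), 1)
  expect_equal(wasserstein_1d(1:5, 1:5), 0)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:400, 1)
    a <- rnorm(n, sample(0:5, 1), runif(1, 0.5, 3))
    b <- rgamma(n, 2, 1)
    expect_equal(wasserstein_1d(a, b), w1_oracle(a, b), tolerance = 1e-10)
    expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))   # symmetry
    # translation property
    cshift <- runif(1, 1, 4)
    expect_equal(wasserstein_1d(a + cshift, a), cshift, tolerance = 1e-10)
  }
  # unequal sizes against a fine common refinement
  a <- c(0, 0, 1); b <- c(0.5, 1)
  # quantile integral computed by hand: F_a = 2/3 on [0,0.5), 2/3 on [0.5,1);
  # F_b = 0 on [0,0.5), 1/2 on [0.5,1)
  expect_equal(wasserstein_1d(a, b), (2/3) * 0.5 + (2/3 - 1/2) * 0.5)
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
})

test_that("gamma MLE recovers simulated parameters", {
  set.seed(5)
  x <- rgamma(10000, shape = 2, scale = 3)
  f <- fit_gamma(x)
  expect_equal(f$shape, 2, tolerance = 0.05 * 2)
  expect_equal(f$scale, 3, tolerance = 0.05 * 3)
  expect_equal(f$shape * f$scale, mean(x), tolerance = 0.01 * mean(x))
  # exponential special case
  e <- fit_gamma(rexp(5000, rate = 1))
  expect_equal(e$shape, 1, tolerance = 0.08)
  expect_error(fit_gamma(rep(2, 10)), "degenerate")
  expect_error(fit_gamma(c(-1, 2, 3)), "negative")
  # zeros survive via the half-minimum substitution
  expect_s3_class(fit_gamma(c(0, 0, rgamma(200, 2, 1))), "gamma_fit")
})

test_that("gaussian thresholds sit at density intersections", {
  # equal variance -> midpoint
  set.seed(6)
  tp <- fit_gaussian_thresholds(list(low = rnorm(5000, 20, 5),
                                     medium = rnorm(5000, 50, 5),
                                     high = rnorm(5000, 80, 5)))
  expect_equal(tp$t_low_med, 35, tolerance = 0.5)
  expect_equal(tp$t_med_high, 65, tolerance = 0.5)
  # unequal variances: compare with a dense numeric grid search
  lo <- rnorm(20000, 30, 4); me <- rnorm(20000, 55, 12); hi <- rnorm(20000, 85, 6)
  tp2 <- fit_gaussian_thresholds(list(low = lo, medium = me, high = hi))
  grid <- seq(30, 55, by = 1e-4)
  d1 <- abs(dnorm(grid, mean(lo), sd(lo)) - dnorm(grid, mean(me), sd(me)))
  expect_equal(tp2$t_low_med, grid[which.min(d1)], tolerance = 1e-3)
  expect_error(fit_gaussian_thresholds(list(low = rnorm(100, 60, 5),
                                            medium = rnorm(100, 50, 5),
                                            high = rnorm(100, 80, 5))),
               "ordered")
})

test_that("threshold classification follows the boundary contract", {
  th <- list(t_low_med = 52, t_med_high = 68)
  expect_equal(classify_by_threshold(c(40, 52, 60, 68, 90), th),
               c("low", "medium", "medium", "high", "high"))
  expect_error(classify_by_threshold(1, list(t_low_med = 5, t_med_high = 5)),
               "invalid")
  expect_equal(vote_patch_labels(c("high", "high", "medium")), "high")
  expect_equal(vote_patch_labels(c("high", "medium")), "high")  # tie rule
})

test_that("patch-count search honours contracts on small inputs", {
  imgs <- fixture("kfam", function() k_search_family())
  # singleton grid
  res1 <- select_patch_count(imgs, grid = 11, repeats = 1, n_per_level = 6,
                             size = 8, seed = 3)
  expect_equal(res1$chosen_k, 11)
  expect_error(select_patch_count(imgs[1:12], grid = c(5, 11), repeats = 1,
                                  n_per_level = 3, size = 8),
               "missing expression level")
  expect_error(select_patch_count(imgs, grid = c(11, 11), repeats = 1,
                                  n_per_level = 3, size = 8), "increasing")
})

test_that("identically rendered levels give near-zero distances", {
  set.seed(42)
  imgs <- list()
  for (l in c("low", "medium", "high")) for (i in 1:6) {
    sp <- synthetic_spec(width = 48, height = 48, stained_fraction = 0.3,
                         dab_od = 0.7, noise_sd = 1,
                         seed = 500 + i + match(l, c("low", "medium", "high")) * 50)
    imgs[[paste0(l, i)]] <- generate_image(sp, l, image_id = paste0(l, i))
  }
  res <- select_patch_count(imgs, grid = c(11, 41), repeats = 2,
                            n_per_level = 6, size = 8, seed = 4)
  # distances are a small fraction of the fraction scale (0-100)
  expect_lt(max(res$mean_total), 12)
})
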