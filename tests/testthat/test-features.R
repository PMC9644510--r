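# The 1247-dimensional handcrafted colour descriptor.

test_that("descriptor length and block sizes hold on any input", {
  imgs <- list(pattern_image(),
               fixture("tiny", function() tiny_image())$pixels)
  blk <- feature_blocks()
  expect_equal(blk$length, c(1012L, 33L, 54L, 128L, 20L))
  expect_equal(sum(blk$length), 1247L)
  for (img in imgs) {
    v <- extract_features(img)
    expect_length(v, 1247)
    expect_true(all(is.finite(v)))
  }
})

test_that("colour histogram is a normalised delta for single-colour images", {
  img <- array(0, c(5, 5, 3))
  img[, , 1] <- 130; img[, , 2] <- 40; img[, , 3] <- 250
  h <- color_histogram(img)
  joint <- h[1:1000]
  expect_equal(sum(joint), 1, tolerance = 1e-9)
  expect_equal(sum(joint > 0), 1)
  expect_equal(max(joint), 1)
  # hand-binned 2x2 two-colour oracle
  im2 <- array(0, c(2, 2, 3))
  im2[1, , ] <- rep(c(10, 10, 10), each = 2)    # bin (0,0,0) -> index 1
  im2[2, , ] <- rep(c(200, 100, 30), each = 2)  # bins (7,3,1)
  h2 <- color_histogram(im2)
  idx2 <- 1 + 7 + 10 * 3 + 100 * 1
  expect_equal(h2[1], 0.5)
  expect_equal(h2[idx2], 0.5)
  expect_equal(sum(h2[1:1000] > 0), 2)
  expect_equal(sum(h2[1001:1012]), 1, tolerance = 1e-9)
})

test_that("colour moments match closed forms", {
  img <- array(100, c(3, 3, 3))
  m <- color_moments(img)
  expect_length(m, 33)
  # constant image: means = constant, var/skew/kurt = 0 for RGB
  expect_equal(m[1:4], c(100, 0, 0, 0))
  expect_equal(m[5:8], c(100, 0, 0, 0))
  # two-pixel 0/255 channel: population mean and variance
  im2 <- array(0, c(1, 2, 3)); im2[1, 2, 1] <- 255
  m2 <- color_moments(im2)
  expect_equal(m2[1], 127.5)
  expect_equal(m2[2], 16256.25)
  # order statistics block: median/min/max of R
  expect_equal(m2[25:27], c(127.5, 0, 255))
})

test_that("coherence vector separates large regions from speckle", {
  # 4x4: 12-pixel region of colour A + 4 isolated pixels of colour B
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- 250; img[, , 2] <- 250; img[, , 3] <- 250   # colour A
  bpix <- cbind(c(1, 1, 3, 4), c(1, 4, 2, 4))
  for (i in 1:4) img[bpix[i, 1], bpix[i, 2], ] <- c(10, 10, 10)
  # isolated? (3,2) and (4,?) could touch diagonally; keep truly isolated:
  img[3, 2, ] <- c(250, 250, 250); img[4, 4, ] <- c(250, 250, 250)
  img[1, 1, ] <- c(10, 10, 10); img[1, 4, ] <- c(10, 10, 10)
  # now exactly 2 isolated dark pixels and 14 bright pixels
  v <- color_coherence_vector(img, feature_config(ccv_tau = 3))
  expect_equal(sum(v), 1, tolerance = 1e-12)
  dark_idx <- 0                      # quantised colour 0 (all channels low)
  bright_idx <- 26                   # colour 26 (all channels high)
  expect_equal(v[2 * bright_idx + 1], 14 / 16)   # coherent bright
  expect_equal(v[2 * dark_idx + 2], 2 / 16)      # incoherent dark
})

test_that("coherence uses 8-connectivity", {
  # a diagonal chain of 3 pixels forms ONE component under 8-connectivity
  img <- array(0, c(5, 5, 3))
  img[, , 1:3] <- 240
  for (i in 1:3) img[i, i, ] <- c(5, 5, 5)
  v <- color_coherence_vector(img, feature_config(ccv_tau = 3))
  expect_equal(v[2 * 0 + 1], 3 / 25)   # all three dark pixels coherent
  expect_equal(v[2 * 0 + 2], 0)
})

test_that("ccv fractions sum to one on random images", {
  set.seed(9)
  for (i in 1:5) {
    img <- array(runif(12 * 12 * 3, 0, 255), c(12, 12, 3))
    expect_equal(sum(color_coherence_vector(img)), 1, tolerance = 1e-12)
  }
})

test_that("autocorrelogram matches exhaustive neighbour counting", {
  # uniform image: own colour 1, all other colours 0
  img <- array(0, c(16, 16, 3)); img[, , 1] <- 180; img[, , 2] <- 90
  v <- color_correlogram(img)
  expect_length(v, 128)
  expect_equal(sum(v == 1), 4)       # one colour x four distances
  expect_true(all(v %in% c(0, 1)))
  # checkerboard: at Chebyshev distance 1 most neighbours are opposite,
  # compare against exhaustive enumeration
  ch <- array(0, c(16, 16, 3))
  pat <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  ch[, , 1] <- 40 + 200 * pat; ch[, , 2] <- 40; ch[, , 3] <- 40
  vch <- color_correlogram(ch, feature_config(corr_distances = 1L))
  brute <- function(img, d) {
    hsv <- grDevices::rgb2hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                              as.vector(img[, , 3]), maxColorValue = 255)
    q <- matrix(pmin(floor(hsv[1, ] * 360 / 90), 3) +
                  4 * pmin(floor(hsv[2, ] * 4), 3) +
                  16 * pmin(floor(hsv[3, ] * 2), 1), nrow(img), ncol(img))
    match_c <- numeric(32); tot_c <- numeric(32)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q)))
      for (dy in -d:d) for (dx in -d:d) {
        if (max(abs(dy), abs(dx)) != d) next
        r2 <- r + dy; c2 <- cc + dx
        if (r2 < 1 || c2 < 1 || r2 > nrow(q) || c2 > ncol(q)) next
        col <- q[r, cc] + 1
        tot_c[col] <- tot_c[col] + 1
        if (q[r2, c2] == q[r, cc]) match_c[col] <- match_c[col] + 1
      }
    ifelse(tot_c > 0, match_c / tot_c, 0)
  }
  expect_equal(vch, brute(ch, 1), tolerance = 1e-12)
  expect_error(color_correlogram(array(0, c(10, 10, 3))), "smaller")
  # probability bounds on a random image
  set.seed(10)
  rimg <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  vr <- color_correlogram(rimg)
  expect_true(all(vr >= 0 & vr <= 1))
})

test_that("characteristic curve follows the saturation tail", {
  cfg <- feature_config()
  # image with no stain-hued pixels -> all zero
  blue <- array(0, c(8, 8, 3)); blue[, , 3] <- 200
  expect_equal(characteristic_curve(blue, cfg), rep(0, 20))
  # fully stain-coloured, s = 1, v in bounds -> all 100
  stain <- array(0, c(8, 8, 3))
  stain[, , 1] <- 180; stain[, , 2] <- 90; stain[, , 3] <- 0  # h = 30, s = 1
  expect_equal(characteristic_curve(stain, cfg), rep(100, 20))
  # uniform saturation on [0,1]: p(s_low) ~ 100 * (1 - s_low)
  set.seed(11)
  n <- 200
  s <- runif(n); v <- 0.6; h <- 35
  # build RGB from HSV (h in 20-50 sector: R max, G between, B min)
  cfull <- v * s
  x <- cfull * (1 - abs((h / 60) %% 2 - 1))
  img <- array(0, c(1, n, 3))
  img[1, , 1] <- (v - cfull + cfull) * 255
  img[1, , 2] <- (v - cfull + x) * 255
  img[1, , 3] <- (v - cfull) * 255
  cc <- characteristic_curve(img, cfg)
  expect_equal(cc, 100 * vapply(cfg$curve$s_grid, function(sl)
    mean(s > sl), numeric(1)), tolerance = 1e-8)
  # monotone non-increasing on arbitrary images
  for (i in 1:5) {
    rimg <- array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3))
    expect_true(all(diff(characteristic_curve(rimg, cfg)) <= 1e-12))
  }
})

test_that("patch-mode features are the mean of per-patch descriptors", {
  img <- fixture("tiny", function() tiny_image())$pixels
  ch <- unmix(rgb_to_od(img))
  ps1 <- extract_top_patches(ch$protein_od, k = 1, size = 16)
  v1 <- extract_features(img, ps1)
  direct <- extract_features(crop_patch_px(img, ps1$patches$row0[1],
                                           ps1$patches$col0[1], 16))
  expect_equal(unname(v1), unname(direct))
  ps3 <- extract_top_patches(ch$protein_od, k = 3, size = 16)
  v3 <- extract_features(img, ps3)
  per <- vapply(1:3, function(i)
    extract_features(crop_patch_px(img, ps3$patches$row0[i],
                                   ps3$patches$col0[i], 16)),
    numeric(1247))
  expect_equal(as.numeric(v3), as.numeric(rowMeans(per)), tolerance = 1e-12)
  expect_error(extract_features(img, list(patches = data.frame())), "empty")
})
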