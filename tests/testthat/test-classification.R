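# Grouped cross-validation, the three model kinds, and evaluation metrics.

sep_data <- function(n_per = 20, seed = 17) {
  set.seed(seed)
  lab <- rep(c("high", "medium", "low"), each = n_per)
  x <- cbind(f1 = as.integer(factor(lab, levels = c("low", "medium", "high"))) +
               rnorm(3 * n_per, 0, 0.1),
             f2 = rnorm(3 * n_per))
  list(x = x, labels = lab,
       proteins = paste0("P", rep(seq_len(3 * n_per / 2), each = 2)))
}

test_that("grouped folds keep proteins intact and partition all images", {
  pids <- rep(sprintf("P%02d", 1:20), times = sample(2:6, 20, replace = TRUE))
  plan <- grouped_kfold(pids, k = 10, seed = 3)
  expect_equal(sort(unique(plan$assignment)), 1:10)
  expect_equal(as.vector(table(plan$assignment)), rep(2L, 10))  # balanced deal
  fold_of <- plan$assignment[pids]
  # all images of one protein share a fold; folds partition the image set
  for (p in unique(pids))
    expect_length(unique(fold_of[pids == p]), 1)
  expect_equal(sum(table(fold_of)), length(pids))
  expect_error(grouped_kfold(c("a", "b"), k = 10), "fewer proteins")
})

test_that("stratified deal balances labels across folds", {
  pids <- rep(sprintf("P%02d", 1:30), each = 2)
  labs <- rep(rep(c("high", "medium", "low"), each = 10), each = 2)
  plan <- grouped_kfold(pids, k = 10, seed = 5, labels = labs)
  pl <- setNames(labs[seq(1, 60, 2)], pids[seq(1, 60, 2)])
  per_fold <- table(plan$assignment, pl[names(plan$assignment)])
  expect_true(all(per_fold == 1))   # one protein of each level per fold
})

test_that("all three model kinds fit separable data and predict simplexes", {
  d <- sep_data()
  for (kind in c("svm", "rf", "dnn")) {
    m <- train_model(d$x, d$labels, kind, grids = test_grids(), seed = 2,
                     dnn_epochs = 100)
    pr <- predict(m, d$x)
    expect_equal(rowSums(pr[, c("p_high", "p_medium", "p_low")]),
                 rep(1, nrow(pr)), tolerance = 1e-9)
    expect_true(all(pr[, 1:3] >= 0))
    expect_gt(mean(pr$label == d$labels), 0.95)
    # argmax consistency
    probs <- as.matrix(pr[, c("p_high", "p_medium", "p_low")])
    expect_equal(pr$label,
                 c("high", "medium", "low")[apply(probs, 1, which.max)])
  }
  expect_error(train_model(d$x, rep("high", nrow(d$x)), "svm"),
               "two classes")
  m <- train_model(d$x, d$labels, "rf", grids = test_grids(), seed = 2)
  expect_error(predict(m, d$x[, 1, drop = FALSE]), "width")
})

test_that("rf probabilities equal tree-vote fractions", {
  d <- sep_data(seed = 18)
  m <- train_model(d$x, d$labels, "rf", grids = list(rf = 5), seed = 4)
  votes <- predict(m$fit, d$x, predict.all = TRUE)$individual
  frac <- t(apply(votes, 1, function(v)
    table(factor(v, levels = m$levels)) / length(v)))
  pr <- predict(m, d$x)
  expect_equal(unname(as.matrix(pr[, paste0("p_", m$levels)])),
               unname(frac), tolerance = 1e-12)
})

test_that("dnn training is deterministic under a fixed seed", {
  d <- sep_data(seed = 19)
  m1 <- train_model(d$x, d$labels, "dnn", seed = 7, dnn_epochs = 50)
  m2 <- train_model(d$x, d$labels, "dnn", seed = 7, dnn_epochs = 50)
  expect_identical(m1$fit$W, m2$fit$W)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("evaluation metrics match closed forms", {
  perfect <- evaluate_predictions(c("high", "medium", "low"),
                                  c("high", "medium", "low"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  # all-one-class predictions on balanced truth
  rep3 <- rep(c("high", "medium", "low"), each = 10)
  allhigh <- evaluate_predictions(rep("high", 30), rep3)
  expect_equal(allhigh$accuracy, 1 / 3)
  expect_equal(allhigh$f1, (2 * (1 / 3) * 1 / (1 / 3 + 1)) / 3,
               tolerance = 1e-12)
  # confusion bookkeeping
  set.seed(20)
  pred <- sample(c("high", "medium", "low"), 60, replace = TRUE)
  ev <- evaluate_predictions(pred, rep3[c(1:30, 1:30)])
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
  expect_equal(unname(rowSums(ev$confusion)), rep(20L, 3))
  expect_error(evaluate_predictions(character(0), character(0)), "aligned")
})

test_that("label-permuted features cross-validate near chance", {
  set.seed(21)
  n <- 90
  x <- matrix(rnorm(n * 8), n, 8)
  labels <- rep(c("high", "medium", "low"), each = n / 3)
  proteins <- paste0("P", rep(1:30, each = 3))
  # protein labels must be constant per protein: assign by protein
  labels <- rep(rep(c("high", "medium", "low"), each = 10), each = 3)
  cv <- suppressWarnings(
    cross_validate(x, labels, proteins, kind = "svm", sda = NULL,
                   grids = test_grids(), seed = 5))
  expect_gt(cv$report$accuracy, 1 / 3 - 0.15)
  expect_lt(cv$report$accuracy, 1 / 3 + 0.15)
})

test_that("feature selection and tuning see only training folds", {
  # a canary feature equal to the label index injected into TEST rows only
  # must not change the training-side results
  set.seed(22)
  n <- 60
  x <- matrix(rnorm(n * 6), n, 6)
  labels <- rep(rep(c("high", "medium", "low"), each = 5), each = 4)
  proteins <- paste0("P", rep(1:15, each = 4))
  plan <- grouped_kfold(proteins, k = 5, seed = 1, labels = labels)
  x_leak <- cbind(x, canary = 0)
  te <- plan$assignment[proteins] == 1
  x_leak[te, "canary"] <- as.integer(factor(labels[te]))
  x_clean <- cbind(x, canary = 0)
  cv_leak <- suppressWarnings(
    cross_validate(x_leak, labels, proteins, kind = "rf", plan = plan,
                   sda = list(f_enter = 1, f_remove = 0.5),
                   grids = list(rf = 50), seed = 9))
  cv_clean <- suppressWarnings(
    cross_validate(x_clean, labels, proteins, kind = "rf", plan = plan,
                   sda = list(f_enter = 1, f_remove = 0.5),
                   grids = list(rf = 50), seed = 9))
  # fold-1 models were trained without the canary: selected sets identical
  expect_identical(cv_leak$selected_per_fold[[1]],
                   cv_clean$selected_per_fold[[1]])
})
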