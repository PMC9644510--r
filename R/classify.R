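# Expression-level classifiers under protein-level grouped cross-validation.
# Proteins (not images) are dealt into folds, so all images of one protein
# land on the same side of every split. Model kinds: RBF SVM (e1071, grid
# search over cost/gamma), random forest (randomForest, tree-count grid),
# and a small feed-forward network (two hidden layers of 200 ReLU units,
# trained with full-batch Adam against one-hot targets under MSE loss,
# softmax applied at inference).

EXPRESSION_LEVELS <- c("high", "medium", "low")

#' Protein-level grouped k-fold plan
#'
#' Proteins are shuffled under `seed` and dealt round-robin into `k` folds;
#' every image inherits its protein's fold. When `labels` are supplied the
#' shuffled proteins are dealt within label strata (a grouped stratified
#' k-fold), which keeps the class composition of training and test sides
#' comparable even for small cohorts; without `labels` the deal is plain
#' round-robin.
#'
#' @param protein_ids character vector, one entry per image.
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @param labels optional per-image expression labels used to stratify the
#'   deal (a protein's label is its most frequent image label).
#' @return object of class `cv_plan`: list with `k`, `assignment` (named
#'   integer vector protein -> fold), `seed`.
#' @export
grouped_kfold <- function(protein_ids, k = 10, seed = 1L, labels = NULL) {
  prots <- unique(protein_ids)
  if (length(prots) < k)
    stop("fewer proteins (", length(prots), ") than folds (", k, ")",
         call. = FALSE)
  set.seed(seed)
  shuffled <- sample(prots)
  if (!is.null(labels)) {
    plab <- vapply(shuffled, function(p) {
      names(which.max(table(labels[protein_ids == p])))
    }, character(1))
    shuffled <- shuffled[order(match(plab, unique(plab)))]  # stable: random in stratum
  }
  assignment <- setNames(rep(seq_len(k), length.out = length(shuffled)),
                         shuffled)
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# ---- feed-forward network -------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_train <- function(x, y_onehot, hidden = c(200, 200), epochs = 200,
                      lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x)
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  sizes <- c(ncol(x), hidden, ncol(y_onehot))
  nw <- length(sizes) - 1L
  W <- lapply(seq_len(nw), function(i)
    matrix(rnorm(sizes[i] * sizes[i + 1], 0, sqrt(2 / sizes[i])),
           sizes[i], sizes[i + 1]))
  b <- lapply(seq_len(nw), function(i) rep(0, sizes[i + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  n <- nrow(xs)
  t_step <- 0
  for (ep in seq_len(epochs)) {
    # forward
    a <- list(xs)
    for (i in seq_len(nw)) {
      z <- sweep(a[[i]] %*% W[[i]], 2, b[[i]], "+")
      a[[i + 1]] <- if (i < nw) pmax(z, 0) else z   # ReLU hidden, linear out
    }
    # backward (MSE): dL/dz_out = 2 (out - y) / (n * n_out)
    delta <- 2 * (a[[nw + 1]] - y_onehot) / (n * ncol(y_onehot))
    gW <- vector("list", nw); gb <- vector("list", nw)
    for (i in nw:1) {
      gW[[i]] <- crossprod(a[[i]], delta)
      gb[[i]] <- colSums(delta)
      if (i > 1L) delta <- (delta %*% t(W[[i]])) * (a[[i]] > 0)
    }
    t_step <- t_step + 1
    corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
    for (i in seq_len(nw)) {
      mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW[[i]]
      vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW[[i]]^2
      W[[i]] <- W[[i]] - lr * (mW[[i]] / corr1) /
        (sqrt(vW[[i]] / corr2) + eps)
      mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gb[[i]]
      vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gb[[i]]^2
      b[[i]] <- b[[i]] - lr * (mb[[i]] / corr1) /
        (sqrt(vb[[i]] / corr2) + eps)
    }
  }
  list(W = W, b = b, center = ctr, scale = scl)
}

mlp_forward <- function(net, x) {
  a <- scale(as.matrix(x), net$center, net$scale)
  nw <- length(net$W)
  for (i in seq_len(nw)) {
    a <- sweep(a %*% net$W[[i]], 2, net$b[[i]], "+")
    if (i < nw) a <- pmax(a, 0)
  }
  softmax_rows(a)
}

# ---- training / prediction ------------------------------------------------

inner_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Default hyperparameter grids
#'
#' SVM: cost 2^-3..2^7, gamma 2^-9..2^1; random forest: 100/300/500 trees.
#'
#' @return named list `svm` (data.frame cost, gamma) and `rf` (ntree
#'   vector).
#' @export
default_grids <- function() {
  list(svm = expand.grid(cost = 2^seq(-3, 7, by = 1),
                         gamma = 2^seq(-9, 1, by = 1)),
       rf = c(100, 300, 500))
}

#' Train an expression-level classifier
#'
#' @param x numeric `n x p` feature matrix.
#' @param labels levels (high/medium/low; at least two classes present).
#' @param kind `"svm"`, `"rf"` or `"dnn"`.
#' @param grids hyperparameter grids as in [default_grids()]; ignored by
#'   the dnn.
#' @param inner_k folds of the inner grid-search CV (default 3).
#' @param seed RNG seed (weight init, inner folds, forests).
#' @param dnn_epochs,dnn_hidden network training length and layer sizes.
#' @return object of class `ihc_model`.
#' @export
train_model <- function(x, labels, kind = c("svm", "rf", "dnn"),
                        grids = default_grids(), inner_k = 3, seed = 1L,
                        dnn_epochs = 200, dnn_hidden = c(200, 200)) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(colnames(x)) || any(colnames(x) == ""))
    colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  lv <- EXPRESSION_LEVELS[EXPRESSION_LEVELS %in% labels]
  y <- factor(labels, levels = lv)
  fit <- NULL; params <- NULL
  if (kind == "svm") {
    grid <- grids$svm
    best <- 1L
    if (nrow(grid) > 1L) {
      fold <- inner_folds(nrow(x), inner_k, seed)
      acc <- vapply(seq_len(nrow(grid)), function(gi) {
        hits <- 0L
        for (f in seq_len(inner_k)) {
          tr <- fold != f
          if (length(unique(y[tr])) < 2L) next
          m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = grid$cost[gi], gamma = grid$gamma[gi])
          hits <- hits + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
        }
        hits / nrow(x)
      }, numeric(1))
      best <- which.max(acc)
    }
    set.seed(seed)
    fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], probability = TRUE)
    params <- grid[best, ]
  } else if (kind == "rf") {
    ntrees <- grids$rf
    best <- 1L
    if (length(ntrees) > 1L) {
      fold <- inner_folds(nrow(x), inner_k, seed)
      acc <- vapply(seq_along(ntrees), function(gi) {
        hits <- 0L
        for (f in seq_len(inner_k)) {
          tr <- fold != f
          if (length(unique(y[tr])) < 2L) next
          set.seed(seed + f)
          m <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                          ntree = ntrees[gi])
          hits <- hits + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
        }
        hits / nrow(x)
      }, numeric(1))
      best <- which.max(acc)
    }
    set.seed(seed)
    fit <- randomForest::randomForest(x, y, ntree = ntrees[best])
    params <- list(ntree = ntrees[best])
  } else {
    onehot <- outer(as.integer(y), seq_along(lv),
                    function(i, j) as.numeric(i == j))
    fit <- mlp_train(x, onehot, hidden = dnn_hidden, epochs = dnn_epochs,
                     seed = seed)
    params <- list(hidden = dnn_hidden, epochs = dnn_epochs)
  }
  structure(list(kind = kind, fit = fit, levels = lv, params = params,
                 p = ncol(x), feature_names = colnames(x)),
            class = "ihc_model")
}

#' Predict expression-level probabilities
#'
#' @param object an `ihc_model`.
#' @param newdata feature matrix with the training width.
#' @param ... unused.
#' @return data.frame `p_high`, `p_medium`, `p_low` (simplex rows) and
#'   `label` (argmax; ties resolved in the order high > medium > low).
#' @export
predict.ihc_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature width ", ncol(newdata), " does not match training width ",
         object$p, call. = FALSE)
  colnames(newdata) <- object$feature_names
  lv <- object$levels
  if (object$kind == "svm") {
    pr <- predict(object$fit, newdata, probability = TRUE)
    probs <- attr(pr, "probabilities")[, lv, drop = FALSE]
  } else if (object$kind == "rf") {
    probs <- predict(object$fit, newdata, type = "prob")[, lv, drop = FALSE]
  } else {
    probs <- mlp_forward(object$fit, newdata)
    colnames(probs) <- lv
  }
  full <- matrix(0, nrow(probs), 3,
                 dimnames = list(NULL, EXPRESSION_LEVELS))
  full[, lv] <- probs
  full <- full / rowSums(full)
  label <- EXPRESSION_LEVELS[apply(full, 1, which.max)]
  out <- data.frame(p_high = full[, "high"], p_medium = full[, "medium"],
                    p_low = full[, "low"], label = label,
                    stringsAsFactors = FALSE)
  out
}

#' Evaluate predictions against truth
#'
#' @param predicted,truth level vectors of equal length.
#' @return object of class `evaluation_report`: `accuracy`, macro-averaged
#'   `recall`, `precision`, `f1` (zero-division counts as 0), `per_class`
#'   table and 3x3 `confusion` (rows = truth).
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("predicted and truth must be non-empty and aligned", call. = FALSE)
  pf <- factor(predicted, levels = EXPRESSION_LEVELS)
  tf <- factor(truth, levels = EXPRESSION_LEVELS)
  confusion <- table(truth = tf, predicted = pf)
  acc <- sum(diag(confusion)) / sum(confusion)
  per <- t(vapply(EXPRESSION_LEVELS, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(recall = rec, precision = prec, f1 = f1)
  }, numeric(3)))
  structure(list(accuracy = acc, recall = mean(per[, "recall"]),
                 precision = mean(per[, "precision"]),
                 f1 = mean(per[, "f1"]), per_class = per,
                 confusion = confusion),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro recall %.4f | macro precision %.4f | macro F1 %.4f\n",
              x$accuracy, x$recall, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Grouped cross-validation with per-fold feature selection
#'
#' For every fold of the plan: run [sda_select()] on the training images
#' only, train the requested model on the selected features, and predict
#' the held-out images. Metrics are pooled over all held-out predictions.
#'
#' @param features `n x p` matrix, one row per image.
#' @param labels,protein_ids,image_ids aligned per-image vectors.
#' @param kind model kind (`"svm"`, `"rf"`, `"dnn"`).
#' @param plan a [grouped_kfold()] plan covering every protein.
#' @param sda list of arguments forwarded to [sda_select()] (set to `NULL`
#'   to skip selection).
#' @param grids hyperparameter grids ([default_grids()]).
#' @param seed RNG seed for model training.
#' @param ... forwarded to [train_model()].
#' @return list with `report` ([evaluate_predictions()]),
#'   `predictions` (data.frame image_id, protein_id, fold, truth, p_high,
#'   p_medium, p_low, label), `selected_per_fold`.
#' @export
cross_validate <- function(features, labels, protein_ids, image_ids = NULL,
                           kind = "svm", plan = NULL, sda = list(),
                           grids = default_grids(), seed = 1L, ...) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n || length(protein_ids) != n)
    stop("features, labels and protein_ids must align", call. = FALSE)
  image_ids <- image_ids %||% sprintf("img%04d", seq_len(n))
  if (is.null(plan))
    plan <- grouped_kfold(protein_ids, seed = seed, labels = labels)
  if (!all(protein_ids %in% names(plan$assignment)))
    stop("plan does not cover all proteins", call. = FALSE)
  fold_of <- plan$assignment[protein_ids]
  preds <- vector("list", plan$k)
  selected <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    if (length(te) == 0L) next
    xtr <- features[tr, , drop = FALSE]
    xte <- features[te, , drop = FALSE]
    if (!is.null(sda)) {
      sres <- do.call(sda_select, c(list(x = xtr, labels = labels[tr]), sda))
      idx <- sres$selected
      if (length(idx) == 0L) {
        # nothing met f_enter (uninformative data): fall back to the five
        # highest-variance features so downstream models get non-degenerate
        # inputs
        idx <- order(apply(xtr, 2, stats::var),
                     decreasing = TRUE)[seq_len(min(5L, ncol(xtr)))]
      }
      selected[[f]] <- idx
      xtr <- xtr[, idx, drop = FALSE]
      xte <- xte[, idx, drop = FALSE]
    }
    model <- train_model(xtr, labels[tr], kind = kind, grids = grids,
                         seed = seed + f, ...)
    pr <- predict(model, xte)
    preds[[f]] <- cbind(data.frame(image_id = image_ids[te],
                                   protein_id = protein_ids[te], fold = f,
                                   truth = labels[te],
                                   stringsAsFactors = FALSE), pr)
  }
  predictions <- do.call(rbind, preds)
  list(report = evaluate_predictions(predictions$label, predictions$truth),
       predictions = predictions, selected_per_fold = selected, plan = plan)
}
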