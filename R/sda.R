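# Stepwise discriminant analysis: forward selection on Wilks' lambda
# (det(W)/det(T) over the selected set) with partial-F entry/removal tests.
# With |S| features selected, the candidate j changes lambda by the factor
#   (w_jj - w_jS W_SS^-1 w_Sj) / (t_jj - t_jS T_SS^-1 t_Sj),
# the ratio of residual within- and total-scatter variances of j given S,
# which is computed for all candidates at once.

scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  g <- length(unique(labels))
  xt <- scale(x, center = TRUE, scale = FALSE)
  Tm <- crossprod(xt)
  Wm <- matrix(0, p, p)
  for (cl in unique(labels)) {
    xc <- x[labels == cl, , drop = FALSE]
    xc <- scale(xc, center = TRUE, scale = FALSE)
    Wm <- Wm + crossprod(xc)
  }
  # ridge jitter keeps near-collinear feature sets invertible
  ridge <- 1e-8 * sum(diag(Wm)) / p
  diag(Wm) <- diag(Wm) + ridge
  diag(Tm) <- diag(Tm) + ridge
  list(W = Wm, T = Tm, n = n, g = g, p = p)
}

# residual variance of every feature given the selected set, from scatter S
residual_diag <- function(S, sel) {
  d <- diag(S)
  if (length(sel) == 0L) return(d)
  A <- S[sel, , drop = FALSE]                      # k x p
  d - colSums(solve(S[sel, sel, drop = FALSE], A) * A)
}

#' Stepwise discriminant feature selection (Wilks' lambda)
#'
#' Classic forward-stepwise procedure: at each step the candidate that
#' minimises Wilks' lambda enters if its partial F meets `f_enter`; after
#' each entry, included features whose partial F has dropped below
#' `f_remove` are removed. Ties are broken by the lowest feature index, so
#' selection is deterministic.
#'
#' @param x numeric `n x p` feature matrix (or data.frame).
#' @param labels class labels, length n, at least two classes.
#' @param f_enter partial-F threshold to enter (default 3.84).
#' @param f_remove partial-F threshold to stay (default 2.71; must be
#'   `<= f_enter`).
#' @param max_features cap on the selected set; default
#'   `min(p, n - n_classes - 1)`.
#' @return object of class `sda_result`: list with `selected` (ordered
#'   indices), `wilks_trajectory` (lambda after each accepted step),
#'   `f_stats` (partial F at entry), `n`, `p`.
#' @export
sda_select <- function(x, labels, f_enter = 3.84, f_remove = 2.71,
                       max_features = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("labels must contain at least two classes", call. = FALSE)
  if (ncol(x) == 0L) stop("no features", call. = FALSE)
  if (nrow(x) <= length(unique(labels)))
    stop("need more samples than classes", call. = FALSE)
  if (f_remove > f_enter)
    stop("f_remove must not exceed f_enter", call. = FALSE)
  sc <- scatter_matrices(x, labels)
  n <- sc$n; g <- sc$g; p <- sc$p
  max_features <- min(max_features %||% (n - g - 1L), p, n - g - 1L)
  sel <- integer(0)
  lambda <- 1
  traj <- numeric(0); fstats <- numeric(0)
  eps <- 1e-12
  repeat {
    if (length(sel) >= max_features) break
    rw <- residual_diag(sc$W, sel)
    rt <- residual_diag(sc$T, sel)
    cand <- setdiff(seq_len(p), sel)
    ratio <- rep(NA_real_, p)
    ok <- cand[rt[cand] > eps & rw[cand] > eps]
    ratio[ok] <- rw[ok] / rt[ok]
    if (!length(ok) || all(is.na(ratio))) break
    j <- which.min(ratio)                      # lowest index wins ties
    k <- length(sel)
    f_j <- (1 / ratio[j] - 1) * (n - g - k) / (g - 1)
    if (!is.finite(f_j) || f_j < f_enter) break
    sel <- c(sel, j)
    lambda <- lambda * ratio[j]
    traj <- c(traj, lambda)
    fstats <- c(fstats, f_j)
    # backward pass: drop features whose partial F fell below f_remove
    repeat {
      if (length(sel) <= 1L) break
      k <- length(sel)
      f_rm <- vapply(seq_along(sel), function(ii) {
        rest <- sel[-ii]
        rwi <- residual_diag(sc$W, rest)[sel[ii]]
        rti <- residual_diag(sc$T, rest)[sel[ii]]
        if (rti <= eps || rwi <= eps) return(Inf)
        (rti / rwi - 1) * (n - g - (k - 1)) / (g - 1)
      }, numeric(1))
      worst <- which.min(f_rm)
      if (f_rm[worst] >= f_remove || sel[worst] == j) break
      drop_idx <- sel[worst]
      rest <- sel[-worst]
      rw_r <- residual_diag(sc$W, rest)[drop_idx]
      rt_r <- residual_diag(sc$T, rest)[drop_idx]
      lambda <- lambda / (rw_r / rt_r)
      sel <- rest
      traj <- c(traj, lambda)
    }
  }
  structure(list(selected = sel, wilks_trajectory = traj, f_stats = fstats,
                 n = n, p = p, n_classes = g),
            class = "sda_result")
}

#' Wilks' lambda of a feature subset, computed from scratch
#'
#' Determinant ratio `det(W_SS) / det(T_SS)` of the within- and total-
#' scatter matrices restricted to `subset`; the independent check of the
#' incremental updates in [sda_select()].
#'
#' @inheritParams sda_select
#' @param subset feature indices.
#' @return Wilks' lambda in (0, 1\].
#' @export
wilks_lambda <- function(x, labels, subset) {
  sc <- scatter_matrices(as.matrix(x), as.character(labels))
  det(sc$W[subset, subset, drop = FALSE]) /
    det(sc$T[subset, subset, drop = FALSE])
}
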