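# Biomarker screening: per-protein expression calls are voted from the
# per-image predictions, expression change between normal and cancer images
# is tested with an independent two-sample t-test on a scalar expression
# score, and the resulting P value is combined (OR) with subcellular-
# location-change P values from an external table. A protein is flagged as
# a candidate biomarker when either test falls below alpha.

#' Majority-vote expression level of a set of predictions
#'
#' @param predictions data.frame with columns `label`, `p_high`,
#'   `p_medium`, `p_low` (as returned by [predict.ihc_model()]).
#' @return single level. Ties between label counts are broken by the larger
#'   summed probability among the tied classes, then by the order
#'   high > medium > low.
#' @export
vote_level <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop("no predictions to vote over", call. = FALSE)
  counts <- table(factor(predictions$label, levels = EXPRESSION_LEVELS))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  sums <- vapply(top, function(cl)
    sum(predictions[[paste0("p_", cl)]]), numeric(1))
  top[which.max(sums)]   # which.max keeps high > medium > low on exact ties
}

#' Scalar expression score of a probability vector
#'
#' Expected ordinal level `0*p_low + 1*p_medium + 2*p_high`, in \[0, 2\];
#' the univariate quantity the expression-change t-test runs on.
#'
#' @param predictions data.frame with `p_high`, `p_medium`, `p_low`
#'   columns (or a single named 3-vector).
#' @return numeric vector of scores.
#' @export
expression_score <- function(predictions) {
  if (is.numeric(predictions) && length(predictions) == 3L)
    predictions <- as.data.frame(as.list(predictions))
  predictions$p_medium + 2 * predictions$p_high
}

#' Test expression change between normal and cancer predictions
#'
#' Two-sided independent two-sample t-test (pooled variance by default,
#' Welch optional) on the expression scores of the two groups.
#'
#' @param normal,cancer prediction data.frames (>= 2 rows each) or numeric
#'   score vectors.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list with `p_value`, `statistic`, `df`, `degenerate` (TRUE when
#'   both groups had zero variance: equal means give P = 1, unequal means
#'   P = 0 by convention).
#' @export
expression_change_test <- function(normal, cancer, welch = FALSE) {
  a <- if (is.data.frame(normal)) expression_score(normal) else as.numeric(normal)
  b <- if (is.data.frame(cancer)) expression_score(cancer) else as.numeric(cancer)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two images per condition", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(list(p_value = if (mean(a) == mean(b)) 1 else 0,
                statistic = NA_real_, df = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Screen proteins for biomarker status
#'
#' Combines per-protein expression-change P values with subcellular-
#' location-change P values: `expression_flag = p_expression < alpha`,
#' `location_flag = any compartment P < alpha`, and
#' `biomarker_flag = expression_flag | location_flag`.
#'
#' @param expression_p data.frame with `protein_id`, `p_expression` and
#'   optionally `level_normal`, `level_cancer`; one row per protein.
#' @param location_p optional data.frame `protein_id`, `compartment`,
#'   `p_value` (several rows per protein allowed); `NULL` for
#'   expression-only screening.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `screen_result` with one row per protein:
#'   levels, P values, `p_location_min`, the three flags; attribute
#'   `detection_rate` holds `100 * flagged / proteins`.
#' @export
screen_biomarkers <- function(expression_p, location_p = NULL,
                              alpha = 0.05) {
  if (anyDuplicated(expression_p$protein_id))
    stop("duplicate protein ids", call. = FALSE)
  out <- expression_p
  out$expression_flag <- out$p_expression < alpha
  out$p_location_min <- NA_real_
  out$location_flag <- FALSE
  if (!is.null(location_p) && nrow(location_p) > 0L) {
    mins <- tapply(location_p$p_value, location_p$protein_id, min)
    m <- mins[out$protein_id]
    out$p_location_min <- as.numeric(m)
    out$location_flag <- !is.na(m) & m < alpha
  }
  out$biomarker_flag <- out$expression_flag | out$location_flag
  attr(out, "detection_rate") <- 100 * sum(out$biomarker_flag) / nrow(out)
  class(out) <- c("screen_result", class(out))
  out
}

#' Screen a cohort from per-image predictions
#'
#' Groups the per-image probability table by protein, votes the normal and
#' cancer expression levels, runs the expression-change t-test, and applies
#' [screen_biomarkers()].
#'
#' @param predictions data.frame with `protein_id`, `condition`
#'   (normal/cancer), `p_high`, `p_medium`, `p_low`, `label` columns.
#' @param location_p optional location-change table (see
#'   [screen_biomarkers()]).
#' @param alpha significance level.
#' @param welch use the Welch t-statistic.
#' @return a `screen_result` data.frame (see [screen_biomarkers()]).
#' @export
screen_cohort <- function(predictions, location_p = NULL, alpha = 0.05,
                          welch = FALSE) {
  need <- c("protein_id", "condition", "p_high", "p_medium", "p_low", "label")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rows <- lapply(split(predictions, predictions$protein_id), function(df) {
    nr <- df[df$condition == "normal", , drop = FALSE]
    ca <- df[df$condition == "cancer", , drop = FALSE]
    tst <- expression_change_test(nr, ca, welch = welch)
    data.frame(protein_id = df$protein_id[1],
               level_normal = vote_level(nr), level_cancer = vote_level(ca),
               p_expression = tst$p_value, stringsAsFactors = FALSE)
  })
  screen_biomarkers(do.call(rbind, c(rows, make.row.names = FALSE)),
                    location_p = location_p, alpha = alpha)
}

#' Bundled literature biomarker screening table
#'
#' Loads the packaged transcription of the 22-protein colon-cancer
#' literature biomarker dataset: per-protein voted expression levels and
#' expression-change P values, plus per-compartment subcellular-location-
#' change P values from the companion location predictor.
#'
#' @return list with `expression` (protein_id, level_normal, level_cancer,
#'   p_expression) and `location` (protein_id, compartment, p_value).
#' @export
lbd_screen_table <- function() {
  ex <- read.csv(system.file("extdata", "lbd_expression_pvalues.csv",
                             package = "ihcscore"), stringsAsFactors = FALSE)
  lo <- read.csv(system.file("extdata", "lbd_location_pvalues.csv",
                             package = "ihcscore"), stringsAsFactors = FALSE)
  list(expression = ex, location = lo)
}
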