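#' Rank-based AUC for presence vs background predictions
#'
#' Mann-Whitney form with mid-rank tie correction:
#' `(concordant + 0.5 * tied) / (n_p * n_b)` — the probability that a random
#' presence outranks a random background cell. Invariant under any strictly
#' increasing transform of the predictions.
#'
#' @param pred_presence Predictions at (test) presence records.
#' @param pred_background Predictions at background cells.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pred_presence, pred_background) {
  n_p <- length(pred_presence); n_b <- length(pred_background)
  if (n_p == 0L || n_b == 0L) stop("empty prediction vector")
  r <- rank(c(pred_presence, pred_background), ties.method = "average")
  (sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2) / (n_p * n_b)
}

#' Maximum True Skill Statistic over swept thresholds
#'
#' Sweeps every unique predicted value as a candidate threshold `t`, with
#' sensitivity the fraction of presence predictions `>= t` and specificity
#' the fraction of background predictions `< t`. Returns the maximum of
#' `sensitivity + specificity - 1` and the smallest threshold attaining it.
#'
#' @param pred_presence,pred_background Prediction vectors (non-empty).
#' @return List with `tss` and `threshold`.
#' @export
max_tss <- function(pred_presence, pred_background) {
  n_p <- length(pred_presence); n_b <- length(pred_background)
  if (n_p == 0L || n_b == 0L) stop("empty prediction vector")
  thr <- sort(unique(c(pred_presence, pred_background)))
  sp <- sort(pred_presence)
  sb <- sort(pred_background)
  # counts below each threshold via binary search on the sorted vectors
  sens <- (n_p - findInterval(thr, sp, left.open = TRUE)) / n_p  # frac >= t
  spec <- findInterval(thr, sb, left.open = TRUE) / n_b          # frac < t
  tss <- sens + spec - 1
  best <- which.max(tss)   # first maximizer = smallest threshold
  list(tss = tss[best], threshold = thr[best])
}

#' Point-biserial correlation of predictions with presence labels
#'
#' Pearson correlation between the pooled predictions and the binary label
#' (presence = 1, background = 0).
#'
#' @param pred_presence,pred_background Prediction vectors.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when the pooled
#'   predictions have zero variance or the pooled size is below 3.
#' @export
point_biserial <- function(pred_presence, pred_background) {
  x <- c(pred_presence, pred_background)
  y <- c(rep(1, length(pred_presence)), rep(0, length(pred_background)))
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Evaluate one model on test presences vs background
#'
#' @param model A fitted [fit_sdm()] model.
#' @param test_presence Data frame of predictor values at test presences.
#' @param background Data frame of predictor values at background cells.
#' @param aicc_presence Optional data frame for the AICc likelihood (default
#'   `test_presence`); pass the training presences to score parsimony on the
#'   data the model was fitted to.
#' @return One-row data frame with `auc`, `tss_max`, `tss_threshold`, `cor`,
#'   `aicc`, `n_presence_test`, `n_background`.
#' @export
evaluate_sdm <- function(model, test_presence, background,
                         aicc_presence = test_presence) {
  pp <- predict(model, test_presence, scale = "cloglog")
  pb <- predict(model, background, scale = "cloglog")
  pp <- pp[!is.na(pp)]; pb <- pb[!is.na(pb)]
  ts <- max_tss(pp, pb)
  data.frame(auc = auc(pp, pb), tss_max = ts$tss, tss_threshold = ts$threshold,
             cor = point_biserial(pp, pb),
             aicc = aicc_sdm(model, aicc_presence, background),
             n_presence_test = length(pp), n_background = length(pb))
}

#' Average per-fold evaluation results
#'
#' Metric-wise arithmetic mean across folds (never a threshold-wise
#' re-optimization); the per-fold rows are retained and an extra row with
#' `fold = "mean"` is appended.
#'
#' @param fold_results Data frame of per-fold metric rows (one per fold) with
#'   a `fold` column.
#' @return Data frame of the input rows plus the averaged row.
#' @export
evaluate_folds <- function(fold_results) {
  if (nrow(fold_results) < 1L) stop("no fold results to average")
  if (anyNA(fold_results$fold)) stop("missing fold identifiers")
  num <- vapply(fold_results, is.numeric, TRUE)
  avg <- fold_results[1, , drop = FALSE]
  for (cn in names(fold_results)[num])
    avg[[cn]] <- mean(fold_results[[cn]], na.rm = TRUE)
  avg$fold <- "mean"
  fold_results$fold <- as.character(fold_results$fold)
  rbind(fold_results, avg)
}

#' Evaluate a larger-extent model on a nested target extent
#'
#' Predicts with a model trained at a larger (or equal) extent onto the
#' target extent's own test presences and background, so every source model
#' is scored against identical test data. Errors if the target rectangle is
#' not nested within the model's training extent (recorded in the model
#' metadata as `rect`).
#'
#' @param model A fitted [fit_sdm()] model whose `meta$rect` is the training
#'   extent rectangle.
#' @param target_extent The target [extent_spec()] (level-1 replicate).
#' @param test_presence,background Data frames of predictor values from the
#'   target extent.
#' @return One-row data frame as in [evaluate_sdm()].
#' @export
transfer_evaluate <- function(model, target_extent, test_presence,
                              background) {
  src <- model$meta$rect
  if (!is.null(src) && !rect_contains(src, target_extent$rect))
    stop("target extent '", target_extent$replicate_id,
         "' is not nested in the model's training extent")
  evaluate_sdm(model, test_presence, background)
}
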