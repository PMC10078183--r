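#' k-fold cross-validation over grid cells
#'
#' Randomly partitions cells into `k` near-equal folds (sizes differing by at
#' most one); each fold is predicted by a model trained on the remaining
#' folds, so every cell is predicted exactly once out-of-fold. Folds are
#' assigned uniformly at random at the cell level, without spatial blocking.
#'
#' @param n number of cells.
#' @param k number of folds (2 <= k <= n; 10 in the standard workflow).
#' @param seed integer seed for the fold assignment.
#' @param fit_fn function(train_idx) returning a fitted object.
#' @param predict_fn function(fit, test_idx) returning numeric predictions.
#' @return list with `predictions` (length n, out-of-fold), `folds`
#'   (assignment vector), `fits` (per-fold fits, NULL where fitting failed)
#'   and `failed` (fold indices that errored).
#' @export
kfold_cv <- function(n, k, seed, fit_fn, predict_fn) {
  stop_if(k < 2, "k must be >= 2")
  stop_if(n < k, "need at least k cells")
  set.seed(derive_seed(seed, "folds"))
  folds <- sample(rep_len(seq_len(k), n))
  preds <- rep(NA_real_, n)
  fits <- vector("list", k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- tryCatch(fit_fn(train), error = function(e) {
      warning(sprintf("fold %d failed: %s", f, conditionMessage(e)), call. = FALSE)
      NULL
    })
    fits[[f]] <- fit
    if (is.null(fit)) failed <- c(failed, f) else preds[test] <- predict_fn(fit, test)
  }
  list(predictions = preds, folds = folds, fits = fits, failed = failed)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2 per
#' positive-negative pair.
#'
#' @param labels binary labels (0/1 or logical); both classes must be present.
#' @param scores numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stop_if(length(unique(labels)) < 2, "AUC undefined: both classes required")
  stop_if(length(labels) != length(scores), "labels and scores must match")
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Convert abundance predictions to presence-absence
#'
#' A cell is classed present iff its prediction strictly exceeds the mean or
#' median computed over the stated reference set (which need not equal the
#' cells being classified: field validation thresholds on the selected-square
#' set, internal validation on all cells).
#'
#' @param predictions numeric predictions to classify.
#' @param method `"mean"` or `"median"`.
#' @param reference_set predictions over which the threshold is computed;
#'   defaults to `predictions`.
#' @return list with `pa` (logical) and `threshold`.
#' @export
threshold_to_pa <- function(predictions, method = c("mean", "median"),
                            reference_set = predictions) {
  method <- match.arg(method)
  stop_if(!length(reference_set), "reference set must be nonempty")
  thr <- if (method == "mean") mean(reference_set) else stats::median(reference_set)
  list(pa = predictions > thr, threshold = thr)
}

#' Root-mean-square log error
#'
#' `sqrt(mean((log1p(predicted) - log1p(observed))^2))`, natural log; the
#' abundance-scale error metric robust to the heavy right tail of count data.
#'
#' @param predicted,observed nonnegative vectors of equal length.
#' @return RMSLE (>= 0).
#' @export
rmsle <- function(predicted, observed) {
  stop_if(length(predicted) != length(observed), "lengths differ")
  stop_if(any(predicted < 0) || any(observed < 0), "inputs must be nonnegative")
  sqrt(mean((log1p(predicted) - log1p(observed))^2))
}

#' Pearson and Spearman correlations of predictions against observations
#'
#' Spearman is Pearson on average ranks (ties averaged); reporting both
#' exposes the influence of extreme squares on the raw-value correlation.
#'
#' @param predicted,observed numeric vectors (length >= 3, non-constant).
#' @return named vector `c(pearson_r = ..., spearman_rs = ...)`.
#' @export
correlate <- function(predicted, observed) {
  stop_if(length(predicted) != length(observed), "lengths differ")
  stop_if(length(predicted) < 3, "need at least three pairs")
  stop_if(stats::sd(predicted) == 0 || stats::sd(observed) == 0,
          "correlation undefined for constant vectors")
  c(pearson_r = stats::cor(predicted, observed),
    spearman_rs = stats::cor(predicted, observed, method = "spearman"))
}

#' Cross-validated evaluation report for a zero-inflated model
#'
#' Runs k-fold cross-validation of a zero-inflated fit over the cells, then
#' scores the out-of-fold predictions: AICc of the full-data fit, train/test
#' AUC after mean-thresholding abundance to presence-absence, RMSLE, and
#' Pearson/Spearman correlations against the observed counts.
#'
#' @param X_count,X_zero design matrices.
#' @param y observed per-cell counts.
#' @param family `"poisson"` or `"negbin"`.
#' @param types prediction types evaluated (any of `"count"`, `"whole"`).
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return list with `aicc`, per-type metric lists under `metrics`
#'   (`auc_train`, `auc_test`, `rmsle`, `correlation`, out-of-fold
#'   `predictions`), the full-data `fit` and the fold assignment.
#' @export
evaluate_zi_cv <- function(X_count, X_zero, y, family,
                           types = c("count", "whole"), k = 10, seed = 1L) {
  full <- fit_zi(X_count, X_zero, y, family)
  n <- length(y)
  cv <- kfold_cv(n, k, seed,
                 fit_fn = function(tr) fit_zi(X_count[tr, , drop = FALSE],
                                              X_zero[tr, , drop = FALSE],
                                              y[tr], family),
                 predict_fn = function(fit, te) te)  # fold fits only; predict below
  pa_obs <- y > 0
  ## abundance predictions are first mean-thresholded to presence-absence and
  ## the binarized prediction is scored against observed presence-absence
  mk_auc <- function(scores, labels) {
    pa <- threshold_to_pa(scores, "mean")
    tryCatch(auc(labels, as.numeric(pa$pa)), error = function(e) NA_real_)
  }
  metrics <- list()
  for (type in types) {
    oof <- rep(NA_real_, n)
    for (f in seq_along(cv$fits)) {
      if (is.null(cv$fits[[f]])) next
      te <- which(cv$folds == f)
      oof[te] <- predict_zi(cv$fits[[f]],
                            list(X_count = X_count[te, , drop = FALSE],
                                 X_zero = X_zero[te, , drop = FALSE]),
                            type = type)
    }
    train_pred <- predict_zi(full, list(X_count = X_count, X_zero = X_zero),
                             type = type)
    ok <- !is.na(oof)
    metrics[[type]] <- list(
      auc_train = mk_auc(train_pred, pa_obs),
      auc_test = if (any(ok)) mk_auc(oof[ok], pa_obs[ok]) else NA_real_,
      rmsle = rmsle(oof[ok], y[ok]),
      correlation = correlate(oof[ok], y[ok]),
      predictions = oof)
  }
  list(aicc = aicc(full), metrics = metrics, fit = full, folds = cv$folds,
       failed = cv$failed)
}
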