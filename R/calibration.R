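#' Stratified selection of field-survey squares
#'
#' Selects `n_random` cells uniformly at random, then `n_per_stratum` cells
#' (excluding those already selected) from each of four strata defined by
#' crossing record presence (`Y > 0`) with predicted abundance class.
#' Low/high predicted abundance follows the model's zero prediction,
#' thresholded at its mean over all cells: a cell whose excess-zero
#' probability is at most the mean counts as high predicted abundance. The
#' default 50 + 4 x 10 design yields 90 squares.
#'
#' @param Y observed per-cell counts.
#' @param zero_pred per-cell zero predictions from the fitted model.
#' @param n_random squares drawn completely at random (default 50).
#' @param n_per_stratum squares per stratum (default 10).
#' @param seed integer seed.
#' @return data frame `cell_id`, `stratum` with stratum labels `random`,
#'   `noATI_low`, `noATI_high`, `ATI_low`, `ATI_high`.
#' @export
select_squares <- function(Y, zero_pred, n_random = 50, n_per_stratum = 10,
                           seed = 1L) {
  n <- length(Y)
  stop_if(length(zero_pred) != n, "zero_pred must have one value per cell")
  set.seed(derive_seed(seed, "squares"))
  random_ids <- sample.int(n, n_random)
  high <- zero_pred <= mean(zero_pred)   # low excess-zero prob => high predicted abundance
  has_rec <- Y > 0
  stratum_of <- ifelse(has_rec,
                       ifelse(high, "ATI_high", "ATI_low"),
                       ifelse(high, "noATI_high", "noATI_low"))
  chosen <- data.frame(cell_id = random_ids, stratum = "random")
  for (st in c("noATI_low", "noATI_high", "ATI_low", "ATI_high")) {
    pool <- setdiff(which(stratum_of == st), chosen$cell_id)
    stop_if(length(pool) < n_per_stratum,
            sprintf("stratum '%s' has only %d available cells (need %d)",
                    st, length(pool), n_per_stratum))
    pick <- pool[sample.int(length(pool), n_per_stratum)]
    chosen <- rbind(chosen, data.frame(cell_id = pick, stratum = st))
  }
  chosen
}

#' Survey-effort-adjusted tree density
#'
#' `observed_count / (coverage_fraction * cell_area)`: trees per square metre
#' over the area actually searched.
#'
#' @param observed_count trees found.
#' @param coverage_fraction fraction of the square surveyed, in (0, 1].
#' @param cell_area square area in m^2 (default 1e6).
#' @return density in trees per m^2.
#' @export
tree_density <- function(observed_count, coverage_fraction, cell_area = 1e6) {
  stop_if(any(coverage_fraction <= 0 | coverage_fraction > 1),
          "coverage_fraction must be in (0, 1]")
  observed_count / (coverage_fraction * cell_area)
}

#' Calibrate model predictions against field measurements
#'
#' Ordinary least squares of the field metric (raw abundance or
#' effort-adjusted density) on the model prediction over the surveyed
#' squares: `metric = a + b * prediction`.
#'
#' @param predictions_surveyed model predictions for the surveyed squares.
#' @param field_values field metric for the same squares (same order).
#' @param metric `"abundance"` or `"density"`; recorded for the total.
#' @return a `calibration_result`: `intercept`, `slope`, their standard
#'   errors, the `lm` fit and the metric.
#' @export
calibrate <- function(predictions_surveyed, field_values,
                      metric = c("abundance", "density")) {
  metric <- match.arg(metric)
  stop_if(length(predictions_surveyed) != length(field_values), "lengths differ")
  stop_if(length(field_values) < 3, "need at least three surveyed squares")
  stop_if(stats::sd(predictions_surveyed) == 0, "constant predictions cannot be calibrated")
  fit <- stats::lm(field_values ~ predictions_surveyed)
  cf <- summary(fit)$coefficients
  structure(list(intercept = cf[1, 1], slope = cf[2, 1],
                 se_intercept = cf[1, 2], se_slope = cf[2, 2],
                 metric = metric, lm = fit),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration (%s): a = %.4g (SE %.3g), b = %.4g (SE %.3g)\n",
              x$metric, x$intercept, x$se_intercept, x$slope, x$se_slope))
  invisible(x)
}

#' Landscape-wide population total from calibrated predictions
#'
#' Applies the calibration `a + b * prediction` to every cell and sums. For
#' the density metric the calibrated per-cell density (trees per m^2) is
#' multiplied by the cell area before summation, the unit-consistent reading
#' of summing per-square estimates. Negative per-cell estimates are retained
#' by default; `clip_negative` floors them at zero before summation.
#'
#' @param calibration a `calibration_result`.
#' @param predictions_all_cells model predictions for every grid cell.
#' @param cell_area cell area in m^2 (density metric only; default 1e6).
#' @param clip_negative floor negative per-cell estimates at 0 (default FALSE).
#' @return list with `total` and the per-cell `estimates` (on the metric's
#'   own scale, before any area multiplication).
#' @export
national_total <- function(calibration, predictions_all_cells, cell_area = 1e6,
                           clip_negative = FALSE) {
  est <- calibration$intercept + calibration$slope * predictions_all_cells
  if (clip_negative) est <- pmax(est, 0)
  total <- if (calibration$metric == "density") sum(est * cell_area) else sum(est)
  list(total = total, estimates = est)
}

#' AUC of model predictions against field presence-absence
#'
#' Abundance-type predictions are first binarized at the median over the
#' threshold reference set (the full set of selected squares, even when only
#' a subset was completed); suitability-type predictions are used directly as
#' scores.
#'
#' @param predictions predictions for the surveyed squares.
#' @param field_pa observed presence-absence for those squares.
#' @param threshold_reference predictions over which the median threshold is
#'   taken (default `predictions`); ignored for `type = "suitability"`.
#' @param type `"abundance"` (median-threshold then score) or
#'   `"suitability"` (raw scores).
#' @return AUC.
#' @export
field_auc <- function(predictions, field_pa, threshold_reference = predictions,
                      type = c("abundance", "suitability")) {
  type <- match.arg(type)
  scores <- if (type == "abundance") {
    as.numeric(threshold_to_pa(predictions, "median", threshold_reference)$pa)
  } else {
    predictions
  }
  auc(field_pa, scores)
}
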