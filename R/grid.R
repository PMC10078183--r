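#' Aggregate occurrence records to per-cell pseudo-abundance
#'
#' Counts the records falling in each grid cell under the half-open cell
#' convention (`[x_min, x_min + s)` in both axes), turning presence-only
#' points into the per-cell count ("pseudo-abundance") response that the
#' zero-inflated models are fitted to.
#'
#' @param records data frame with `x`, `y` in projected metres.
#' @param landscape a `landscape` (defines extent, origin and cell size).
#' @param on_outside `"error"` (default) or `"drop"`: what to do with records
#'   outside the landscape extent; dropped or failing records are reported by
#'   row index.
#' @return integer vector `Y`, one count per cell in cell-id order;
#'   `sum(Y)` equals the number of in-bounds records.
#' @export
aggregate_to_counts <- function(records, landscape, on_outside = c("error", "drop")) {
  on_outside <- match.arg(on_outside)
  cfg <- landscape$config
  s <- cfg$cell_size
  col <- floor(records$x / s) + 1
  row <- floor(records$y / s) + 1
  inside <- col >= 1 & col <= cfg$n_cols & row >= 1 & row <= cfg$n_rows
  if (any(!inside)) {
    ids <- which(!inside)
    msg <- sprintf("%d record(s) outside the landscape extent (rows %s%s)",
                   length(ids), paste(utils::head(ids, 5), collapse = ", "),
                   if (length(ids) > 5) ", ..." else "")
    if (on_outside == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    col <- col[inside]; row <- row[inside]
  }
  cell <- (row - 1) * cfg$n_cols + col
  Y <- integer(cfg$n_rows * cfg$n_cols)
  if (length(cell)) {
    tab <- tabulate(cell, nbins = length(Y))
    Y <- as.integer(tab)
  }
  Y
}

#' Variance-to-mean ratio of counts
#'
#' The overdispersion diagnostic for count data: sample variance (n-1
#' denominator) divided by the sample mean. Ratios well above 1 indicate
#' overdispersion relative to the Poisson and motivate a negative-binomial
#' count component.
#'
#' @param Y nonnegative counts with positive mean.
#' @return the ratio.
#' @export
overdispersion_ratio <- function(Y) {
  stop_if(length(Y) < 2, "need at least two counts")
  m <- mean(Y)
  stop_if(m <= 0, "variance:mean ratio undefined for all-zero counts")
  stats::var(Y) / m
}

#' Collinearity screening of numeric covariates
#'
#' Pairwise Pearson correlations and variance inflation factors
#' (`VIF_j = 1 / (1 - R^2_j)` from regressing covariate j on the others),
#' flagging `|r| > 0.6` or `VIF >= 5`, the conventional screening thresholds
#' for predictor sets in distribution models.
#'
#' @param X data frame or matrix of numeric covariates (>= 2 columns, n > p).
#' @param r_threshold,vif_threshold flag thresholds (defaults 0.6 and 5).
#' @return list with `correlation` (matrix), `vif` (named vector, `Inf` for
#'   aliased covariates), `flagged_pairs` and `flagged_vif`.
#' @export
screen_collinearity <- function(X, r_threshold = 0.6, vif_threshold = 5) {
  X <- as.data.frame(X)
  stop_if(ncol(X) < 2, "need at least two numeric covariates")
  stop_if(nrow(X) <= ncol(X), "need more observations than covariates")
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  stop_if(any(const), sprintf("constant covariate(s): %s",
                              paste(names(X)[const], collapse = ", ")))
  r <- stats::cor(X)
  vif <- vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  pairs <- which(abs(r) > r_threshold & upper.tri(r), arr.ind = TRUE)
  flagged_pairs <- if (nrow(pairs)) {
    data.frame(var1 = rownames(r)[pairs[, 1]], var2 = colnames(r)[pairs[, 2]],
               r = r[pairs])
  } else {
    data.frame(var1 = character(0), var2 = character(0), r = numeric(0))
  }
  list(correlation = r, vif = vif, flagged_pairs = flagged_pairs,
       flagged_vif = names(vif)[vif >= vif_threshold])
}

#' Residual spatial trend check
#'
#' Pearson correlations of model residuals with the x and y cell coordinates:
#' a cheap check that no strong spatial trend is left unmodelled.
#'
#' @param residuals numeric vector, one per cell.
#' @param coords data frame or matrix with columns `x` and `y`.
#' @return named numeric vector `c(r_x = ..., r_y = ...)`.
#' @export
residual_spatial_check <- function(residuals, coords) {
  coords <- as.data.frame(coords)
  stop_if(length(residuals) != nrow(coords),
          "one residual per coordinate row required")
  safe_cor <- function(a, b) if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  c(r_x = safe_cor(residuals, coords$x), r_y = safe_cor(residuals, coords$y))
}

#' Pool rare factor levels into "other"
#'
#' Combines levels rarer than `min_count` into a single `"other"` level, the
#' usual device for stabilising categorical terms in count models.
#'
#' @param f a factor.
#' @param min_count levels with fewer observations are pooled.
#' @param other label of the pooled level.
#' @return a factor.
#' @export
pool_rare_levels <- function(f, min_count, other = "other") {
  f <- as.factor(f)
  tab <- table(f)
  rare <- names(tab)[tab < min_count]
  if (!length(rare)) return(f)
  lv <- levels(f)
  lv[lv %in% rare] <- other
  factor(lv[as.integer(f)], levels = unique(c(setdiff(lv, other), other)))
}
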