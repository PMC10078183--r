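#' Configure a synthetic landscape
#'
#' Describes a rectangular grid of square cells carrying spatially
#' autocorrelated numeric covariates and spatially coherent categorical
#' covariates, the synthetic stand-in for a real 1-km environmental raster
#' stack.
#'
#' @param n_rows,n_cols positive integers; grid dimensions.
#' @param cell_size cell side length in metres (default 1000, a 1-km grid).
#' @param n_numeric number of numeric covariates.
#' @param n_categorical number of categorical covariates.
#' @param n_levels integer vector (recycled) of level counts, each >= 2.
#' @param correlation_length spatial smoothness scale in metres: numeric
#'   covariates are white noise smoothed with a Gaussian kernel of this
#'   standard deviation, a cheap surrogate for a Gaussian process.
#' @param seed integer seed controlling covariate generation.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows, n_cols, cell_size = 1000,
                             n_numeric = 4, n_categorical = 1,
                             n_levels = 3, correlation_length = 5000,
                             seed = 1L) {
  stop_if(n_rows < 1 || n_cols < 1, "grid dimensions must be positive")
  stop_if(cell_size <= 0, "cell_size must be positive")
  stop_if(n_numeric < 0 || n_categorical < 0, "covariate counts must be nonnegative")
  n_levels <- rep_len(as.integer(n_levels), max(n_categorical, 1L))
  stop_if(n_categorical > 0 && any(n_levels < 2), "all level counts must be >= 2")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, n_numeric = as.integer(n_numeric),
                 n_categorical = as.integer(n_categorical),
                 n_levels = n_levels,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Configure the generative truth of a synthetic landscape
#'
#' Holds the parameters of the data-generating process the zero-inflated
#' analysis assumes: a log-linear negative-binomial count process for true
#' per-cell abundance, a logistic excess-zero (non-sampling) process, and a
#' within-cell detection probability.
#'
#' @param beta_count coefficient vector on the log link, intercept first,
#'   conformable with the landscape design matrix.
#' @param theta negative-binomial dispersion (> 0); variance is
#'   `mu + mu^2 / theta`, so large `theta` approaches Poisson.
#' @param gamma_zero coefficient vector on the logit link for the probability
#'   that a cell goes unsampled (an excess zero), intercept first.
#' @param detection_prob probability in (0, 1] that an individual present in a
#'   sampled cell is recorded (binomial thinning; default 1, the zero-only
#'   bias regime).
#' @param seed integer seed for abundance and sampling simulation.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(beta_count, theta, gamma_zero,
                         detection_prob = 1, seed = 1L) {
  stop_if(theta <= 0, "theta must be > 0")
  stop_if(detection_prob <= 0 || detection_prob > 1,
          "detection_prob must be in (0, 1]")
  structure(list(beta_count = as.numeric(beta_count), theta = theta,
                 gamma_zero = as.numeric(gamma_zero),
                 detection_prob = detection_prob, seed = as.integer(seed)),
            class = "truth_config")
}

## separable Gaussian smoothing of a matrix, edge-renormalized
smooth_matrix <- function(m, sigma) {
  if (sigma < 1e-8) return(m)
  gauss_weights <- function(n) {
    w <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * sigma^2))
    w / rowSums(w)
  }
  gauss_weights(nrow(m)) %*% m %*% t(gauss_weights(ncol(m)))
}

#' Generate a synthetic landscape
#'
#' Numeric covariates are spatially autocorrelated fields (smoothed white
#' noise), centred and scaled across cells. Categorical covariates are
#' obtained by quantile-thresholding an independent smoothed latent field,
#' giving spatially coherent classes such as land-class mosaics.
#'
#' @param config a [landscape_config()].
#' @return an object of class `landscape`: a list with `cells` (a data frame
#'   with `cell_id`, `row`, `col`, `x_min`, `y_min` and one column per
#'   covariate) and the `config`. Cell `(row, col)` covers the half-open
#'   square `[x_min, x_min + s) x [y_min, y_min + s)`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols; s <- config$cell_size
  sigma <- config$correlation_length / s
  set.seed(config$seed)
  row_idx <- rep(seq_len(nr), each = nc)
  col_idx <- rep(seq_len(nc), times = nr)
  cells <- data.frame(cell_id = seq_len(nr * nc), row = row_idx, col = col_idx,
                      x_min = (col_idx - 1) * s, y_min = (row_idx - 1) * s)
  if (config$n_numeric > 0) {
    for (j in seq_len(config$n_numeric)) {
      f <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
      v <- as.vector(t(f))  # row-major to match cells ordering
      v <- if (length(v) > 1 && stats::sd(v) > 0) as.numeric(scale(v)) else v - mean(v)
      cells[[paste0("env", j)]] <- v
    }
  }
  if (config$n_categorical > 0) {
    for (j in seq_len(config$n_categorical)) {
      L <- config$n_levels[j]
      f <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
      v <- as.vector(t(f))
      br <- stats::quantile(v, probs = seq(0, 1, length.out = L + 1))
      br[1] <- -Inf; br[L + 1] <- Inf
      br <- unique(br)
      lab <- cut(v, breaks = br, labels = FALSE, right = FALSE)
      cells[[paste0("class", j)]] <- factor(paste0("l", lab),
                                            levels = paste0("l", seq_len(length(br) - 1)))
    }
  }
  structure(list(cells = cells, config = config), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("landscape: %d x %d cells of %g m (%d numeric, %d categorical covariates)\n",
              cfg$n_rows, cfg$n_cols, cfg$cell_size, cfg$n_numeric, cfg$n_categorical))
  invisible(x)
}

#' Design matrix of a landscape
#'
#' Intercept plus all covariate columns; categorical covariates are one-hot
#' encoded against the first (reference) level, matching the treatment-contrast
#' convention of the fitted models.
#'
#' @param landscape a `landscape` or a cell data frame.
#' @return numeric model matrix with one row per cell.
#' @export
landscape_design <- function(landscape) {
  cells <- if (inherits(landscape, "landscape")) landscape$cells else landscape
  covs <- setdiff(names(cells), c("cell_id", "row", "col", "x_min", "y_min", "Y"))
  if (!length(covs)) return(matrix(1, nrow(cells), 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(stats::reformulate(covs), data = cells)
}

#' Simulate true per-cell abundance
#'
#' Draws `N_i ~ NegBin(mu_i = exp(x_i beta), theta)` from the landscape design.
#'
#' @param landscape a `landscape`.
#' @param truth a [truth_config()]; `beta_count` must conform to
#'   [landscape_design()] of the landscape.
#' @return integer vector of true abundances, one per cell.
#' @export
simulate_true_abundance <- function(landscape, truth) {
  X <- landscape_design(landscape)
  stop_if(ncol(X) != length(truth$beta_count),
          sprintf("beta_count has %d coefficients but the design has %d columns",
                  length(truth$beta_count), ncol(X)))
  set.seed(derive_seed(truth$seed, "abundance"))
  mu <- exp(drop(X %*% truth$beta_count))
  stats::rnbinom(nrow(X), size = truth$theta, mu = mu)
}

#' Simulate biased sampling of true abundance
#'
#' Each cell is an excess zero (unsampled) with probability
#' `pi_i = logistic(x_i gamma)`; otherwise the observed count is a binomial
#' thinning `Binomial(N_i, detection_prob)` of the true abundance. The excess
#' flags are returned for oracle tests only and must never reach fitting code.
#'
#' @param landscape a `landscape`.
#' @param N true abundances from [simulate_true_abundance()].
#' @param truth a [truth_config()].
#' @return list with `Y` (observed counts), `excess` (logical flags) and `pi`
#'   (the excess-zero probabilities).
#' @export
simulate_sampling <- function(landscape, N, truth) {
  X <- landscape_design(landscape)
  stop_if(length(N) != nrow(X), "N must have one entry per cell")
  stop_if(ncol(X) != length(truth$gamma_zero),
          sprintf("gamma_zero has %d coefficients but the design has %d columns",
                  length(truth$gamma_zero), ncol(X)))
  set.seed(derive_seed(truth$seed, "sampling"))
  pi <- logistic(drop(X %*% truth$gamma_zero))
  excess <- stats::runif(length(N)) < pi
  Y <- ifelse(excess, 0L, stats::rbinom(length(N), N, truth$detection_prob))
  list(Y = as.integer(Y), excess = excess, pi = pi)
}

#' Scatter occurrence points inside sampled cells
#'
#' Places exactly `Y_i` points uniformly inside cell `i`'s square, emulating
#' individual tree records. A small fraction of records is labelled "ancient",
#' the rest "veteran", mirroring the typical composition of ancient-tree
#' inventories; the label plays no role in any model.
#'
#' @param landscape a `landscape`.
#' @param Y nonnegative integer counts per cell.
#' @param seed integer seed.
#' @param prop_ancient proportion of records labelled ancient (default 0.11).
#' @return data frame of records: `record_id`, `x`, `y`, `cell_id`,
#'   `recorder_id` (NA until assigned), `status`.
#' @export
place_points <- function(landscape, Y, seed = 1L, prop_ancient = 0.11) {
  cells <- landscape$cells
  stop_if(length(Y) != nrow(cells), "Y must have one entry per cell")
  stop_if(any(Y < 0), "Y must be nonnegative")
  set.seed(derive_seed(seed, "points"))
  total <- sum(Y)
  if (total == 0) {
    return(data.frame(record_id = integer(0), x = numeric(0), y = numeric(0),
                      cell_id = integer(0), recorder_id = integer(0),
                      status = character(0)))
  }
  idx <- rep(seq_len(nrow(cells)), times = Y)
  s <- landscape$config$cell_size
  data.frame(record_id = seq_len(total),
             x = cells$x_min[idx] + stats::runif(total) * s,
             y = cells$y_min[idx] + stats::runif(total) * s,
             cell_id = cells$cell_id[idx],
             recorder_id = NA_integer_,
             status = ifelse(stats::runif(total) < prop_ancient,
                             "ancient", "veteran"))
}

#' Simulate recorders and assign records to them
#'
#' Recorder home bases are placed uniformly over the landscape; each record is
#' assigned to a recorder with probability proportional to
#' `exp(-distance / activity_decay)`, so recorders mostly collect near home.
#' The home-base locations feed the recorder-density bias surface.
#'
#' @param landscape a `landscape`.
#' @param records record data frame from [place_points()].
#' @param n_recorders number of recorders (>= 1).
#' @param activity_decay distance scale of recorder activity in metres (> 0);
#'   large values make assignment effectively uniform.
#' @param seed integer seed.
#' @return list with `homes` (data frame `recorder_id`, `x`, `y`) and
#'   `records` (input with `recorder_id` filled in).
#' @export
simulate_recorders <- function(landscape, records, n_recorders,
                               activity_decay, seed = 1L) {
  stop_if(n_recorders < 1, "need at least one recorder")
  stop_if(activity_decay <= 0, "activity_decay must be > 0")
  cfg <- landscape$config
  set.seed(derive_seed(seed, "recorders"))
  homes <- data.frame(recorder_id = seq_len(n_recorders),
                      x = stats::runif(n_recorders, 0, cfg$n_cols * cfg$cell_size),
                      y = stats::runif(n_recorders, 0, cfg$n_rows * cfg$cell_size))
  if (nrow(records)) {
    d <- sqrt(outer(records$x, homes$x, `-`)^2 + outer(records$y, homes$y, `-`)^2)
    w <- exp(-(d - apply(d, 1, min)) / activity_decay)  # shift for stability
    records$recorder_id <- apply(w, 1, function(p) sample.int(n_recorders, 1, prob = p))
  }
  list(homes = homes, records = records)
}

#' Simulate partial-coverage field surveys
#'
#' For each selected square a coverage fraction is drawn, the observed count is
#' `Binomial(N_true, coverage * detection_prob)` (a surveyor finds each tree in
#' the covered part independently), and the effort-adjusted density is
#' `observed / (coverage * cell_area)`.
#'
#' @param square_ids cell ids of the squares surveyed.
#' @param N_true true abundances for those squares (same order).
#' @param coverage_dist function of `n` returning coverage fractions in (0, 1];
#'   default `function(n) runif(n, 0.2, 1)`.
#' @param detection_prob per-tree detection probability in (0, 1].
#' @param cell_area square area in m^2 (default 1e6, a 1-km cell).
#' @param seed integer seed.
#' @return data frame: `cell_id`, `coverage_fraction`, `observed_count`,
#'   `surveyed_area`, `density`.
#' @export
simulate_field_survey <- function(square_ids, N_true,
                                  coverage_dist = function(n) stats::runif(n, 0.2, 1),
                                  detection_prob = 1, cell_area = 1e6, seed = 1L) {
  stop_if(length(square_ids) != length(N_true),
          "square_ids and N_true must have equal length")
  stop_if(detection_prob <= 0 || detection_prob > 1,
          "detection_prob must be in (0, 1]")
  set.seed(derive_seed(seed, "survey"))
  n <- length(square_ids)
  cv <- coverage_dist(n)
  stop_if(any(cv <= 0 | cv > 1), "coverage_dist must yield fractions in (0, 1]")
  obs <- stats::rbinom(n, N_true, cv * detection_prob)
  data.frame(cell_id = square_ids, coverage_fraction = cv, observed_count = obs,
             surveyed_area = cv * cell_area,
             density = obs / (cv * cell_area))
}
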