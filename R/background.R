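#' Uniform random pseudo-absence background
#'
#' @param landscape a `landscape`.
#' @param n number of background points (>= 1).
#' @param seed integer seed.
#' @return a `background_set`: data frame `x`, `y`, `cell_id` with attributes
#'   `method` and `seed`.
#' @export
random_background <- function(landscape, n, seed = 1L) {
  stop_if(n < 1, "n must be >= 1")
  cfg <- landscape$config
  set.seed(derive_seed(seed, "background"))
  pts <- data.frame(x = stats::runif(n, 0, cfg$n_cols * cfg$cell_size),
                    y = stats::runif(n, 0, cfg$n_rows * cfg$cell_size))
  as_background(pts, landscape, method = "random", seed = seed)
}

as_background <- function(pts, landscape, method, seed) {
  cfg <- landscape$config
  s <- cfg$cell_size
  pts$cell_id <- (pmin(floor(pts$y / s), cfg$n_rows - 1)) * cfg$n_cols +
    pmin(floor(pts$x / s), cfg$n_cols - 1) + 1
  structure(pts, method = method, seed = seed,
            class = c("background_set", "data.frame"))
}

#' Buffer-restricted pseudo-absence background
#'
#' Samples `n` points uniformly over the union of disks of the given radius
#' centred on the occurrence records, intersected with the landscape: the
#' background-restriction bias correction (1-, 2-, 5- or 10-km buffers in the
#' usual protocol). Implemented by rejection from the bounding box of the
#' union; sampling aborts if the acceptance rate shows the target region to be
#' effectively empty.
#'
#' @param records data frame with `x`, `y` (nonempty).
#' @param landscape a `landscape`.
#' @param radius buffer radius in metres (> 0).
#' @param n number of points.
#' @param seed integer seed.
#' @return a `background_set`.
#' @export
buffer_restricted_background <- function(records, landscape, radius, n, seed = 1L) {
  stop_if(nrow(records) == 0, "records must be nonempty")
  stop_if(radius <= 0, "radius must be > 0")
  stop_if(n < 1, "n must be >= 1")
  cfg <- landscape$config
  W <- cfg$n_cols * cfg$cell_size; H <- cfg$n_rows * cfg$cell_size
  xlo <- max(0, min(records$x) - radius); xhi <- min(W, max(records$x) + radius)
  ylo <- max(0, min(records$y) - radius); yhi <- min(H, max(records$y) + radius)
  stop_if(xlo >= xhi || ylo >= yhi,
          "buffer union does not intersect the landscape")
  set.seed(derive_seed(seed, "buffer"))
  out_x <- numeric(0); out_y <- numeric(0)
  tries <- 0L
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 1000L)
    cx <- stats::runif(m, xlo, xhi); cy <- stats::runif(m, ylo, yhi)
    ok <- vapply(seq_len(m), function(i) {
      any((records$x - cx[i])^2 + (records$y - cy[i])^2 <= radius^2)
    }, logical(1))
    out_x <- c(out_x, cx[ok]); out_y <- c(out_y, cy[ok])
    tries <- tries + 1L
    stop_if(tries > 200L && !length(out_x),
            "buffer union has negligible area inside the landscape")
  }
  as_background(data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)]),
                landscape, method = "buffer", seed = seed)
}

#' Kernel-density bias surface from point sources
#'
#' Per-cell weight is the sum over source points (recorder home bases, town
#' centroids, ...) of a Gaussian kernel of the distance from the cell centroid
#' to the point, the "bias file" surface steering pseudo-absence placement
#' toward heavily recorded areas.
#'
#' @param points data frame with `x`, `y` (nonempty).
#' @param landscape a `landscape`.
#' @param bandwidth Gaussian kernel standard deviation in metres (> 0;
#'   default 5 cell sizes).
#' @return a `bias_surface`: numeric per-cell weights with attributes
#'   `provenance` and `bandwidth`.
#' @export
kernel_density_surface <- function(points, landscape, bandwidth = NULL) {
  stop_if(nrow(points) == 0, "points must be nonempty")
  cfg <- landscape$config
  bandwidth <- bandwidth %||% (5 * cfg$cell_size)
  stop_if(bandwidth <= 0, "bandwidth must be > 0")
  cells <- landscape$cells
  cxm <- cells$x_min + cfg$cell_size / 2
  cym <- cells$y_min + cfg$cell_size / 2
  d2 <- outer(cxm, points$x, `-`)^2 + outer(cym, points$y, `-`)^2
  w <- rowSums(exp(-d2 / (2 * bandwidth^2)))
  structure(w, provenance = "point_kernel_density", bandwidth = bandwidth,
            class = "bias_surface")
}

#' Bias surface from a per-cell raster
#'
#' Min-max rescales per-cell values to \[0, 1\] weights, ascending (higher
#' value attracts more pseudo-absences, e.g. altitude or record density) or
#' descending (for distance-type sources where nearness should attract
#' sampling).
#'
#' @param values one numeric value per cell.
#' @param direction `"ascending"` or `"descending"`.
#' @param provenance label stored on the surface (default `"raster_rescale"`;
#'   use `"record_density"` when `values` are the per-cell counts Y).
#' @return a `bias_surface`.
#' @export
raster_bias_surface <- function(values, direction = c("ascending", "descending"),
                                provenance = "raster_rescale") {
  direction <- match.arg(direction)
  rng <- range(values)
  if (rng[2] == rng[1]) {
    warning("constant raster: bias surface is uniform", call. = FALSE)
    w <- rep(1, length(values))
  } else {
    w <- (values - rng[1]) / (rng[2] - rng[1])
    if (direction == "descending") w <- 1 - w
  }
  structure(w, provenance = provenance, bandwidth = NULL, class = "bias_surface")
}

#' @export
print.bias_surface <- function(x, ...) {
  cat(sprintf("bias_surface (%s): %d cells, weights in [%.3g, %.3g]\n",
              attr(x, "provenance"), length(x), min(x), max(x)))
  invisible(x)
}

#' Bias-surface-weighted pseudo-absence background
#'
#' Draws `n` cells with probability proportional to the surface weight (with
#' replacement across draws, as in standard presence-background practice;
#' presence cells are not excluded) and places one uniform point inside each
#' drawn cell.
#'
#' @param surface a `bias_surface` with at least one positive weight.
#' @param landscape a `landscape` with one cell per surface weight.
#' @param n number of points.
#' @param seed integer seed.
#' @return a `background_set`.
#' @export
weighted_background <- function(surface, landscape, n, seed = 1L) {
  stop_if(n < 1, "n must be >= 1")
  w <- as.numeric(surface)
  stop_if(length(w) != nrow(landscape$cells),
          "surface must have one weight per landscape cell")
  stop_if(any(w < 0), "bias surface weights must be nonnegative")
  stop_if(all(w == 0), "bias surface has no positive weight")
  cfg <- landscape$config
  set.seed(derive_seed(seed, "weighted_bg"))
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  cells <- landscape$cells
  pts <- data.frame(
    x = cells$x_min[idx] + stats::runif(n) * cfg$cell_size,
    y = cells$y_min[idx] + stats::runif(n) * cfg$cell_size)
  as_background(pts, landscape, method = "bias_surface", seed = seed)
}
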