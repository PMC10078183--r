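#' Systematic spatial filtering of occurrence records
#'
#' Overlays a coarse grid of the given resolution (anchored at the landscape
#' origin by default) and keeps exactly one uniformly chosen record per
#' occupied coarse cell, the classic systematic thinning of dense occurrence
#' data at 2-, 5- or 10-km resolutions.
#'
#' @param records data frame with `x`, `y`.
#' @param resolution coarse-grid cell side in metres (> 0).
#' @param seed integer seed.
#' @param anchor length-2 origin of the coarse grid (default `c(0, 0)`).
#' @return the retained subset of `records` (rows, identities preserved).
#' @export
systematic_sample <- function(records, resolution, seed = 1L, anchor = c(0, 0)) {
  stop_if(nrow(records) == 0, "records must be nonempty")
  stop_if(resolution <= 0, "resolution must be > 0")
  cx <- floor((records$x - anchor[1]) / resolution)
  cy <- floor((records$y - anchor[2]) / resolution)
  key <- paste(cx, cy)
  set.seed(derive_seed(seed, "systematic"))
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(ix) {
    if (length(ix) == 1) ix else sample(ix, 1)
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

## single-linkage components: records closer than link are joined; grid-binned
## union-find, correctness defined by the brute-force pairwise oracle
single_linkage_components <- function(x, y, link) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  ix <- floor(x / link); iy <- floor(y / link)
  key <- paste(ix, iy)
  bins <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(ix[i] + dx, iy[i] + dy)
      for (j in bins[[k]]) {
        if (j > i && (x[j] - x[i])^2 + (y[j] - y[i])^2 < link^2) union(i, j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster-based spatial filtering of occurrence records
#'
#' Groups records into single-linkage connected components of the graph
#' joining pairs closer than `link_distance` (so two records of one cluster
#' may be far apart, provided each is within the link distance of some other
#' member), then keeps one uniformly chosen record per cluster; isolated
#' records are their own cluster and are always retained.
#'
#' @param records data frame with `x`, `y`.
#' @param link_distance linkage distance in metres (default 1000).
#' @param seed integer seed.
#' @return the retained subset of `records`.
#' @export
cluster_filter <- function(records, link_distance = 1000, seed = 1L) {
  stop_if(link_distance <= 0, "link_distance must be > 0")
  if (nrow(records) == 0) return(records)
  comp <- single_linkage_components(records$x, records$y, link_distance)
  set.seed(derive_seed(seed, "cluster"))
  keep <- unlist(lapply(split(seq_len(nrow(records)), comp), function(ix) {
    if (length(ix) == 1) ix else sample(ix, 1)
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' Weighted-distance spatial filtering of occurrence records
#'
#' Computes each record's nearest-neighbour distance, min-max rescales the
#' distances to weights in \[0, 1\], and draws `n_keep` records without
#' replacement with selection probability proportional to weight, so spatially
#' isolated records are favoured. Records at weight 0 (the tightest clusters)
#' become selectable only once every positive-weight record is taken.
#'
#' @param records data frame with `x`, `y` (>= 2 rows).
#' @param n_keep number of records to retain (1 <= n_keep <= n).
#' @param seed integer seed.
#' @return the retained subset of `records`.
#' @export
weighted_distance_sample <- function(records, n_keep, seed = 1L) {
  n <- nrow(records)
  stop_if(n < 2, "need at least two records")
  stop_if(n_keep < 1 || n_keep > n, "n_keep must be between 1 and the number of records")
  if (n_keep == n) return(records)
  d <- nearest_neighbour_dist(records$x, records$y)
  rng <- range(d)
  w <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else rep(1, n)
  set.seed(derive_seed(seed, "wdist"))
  pos <- which(w > 0)
  if (n_keep <= length(pos)) {
    keep <- pos[sample.int(length(pos), n_keep, prob = w[pos])]
  } else {
    zero <- setdiff(seq_len(n), pos)
    keep <- c(pos, zero[sample.int(length(zero), n_keep - length(pos))])
  }
  records[sort(keep), , drop = FALSE]
}
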