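# Internal numerical helpers shared across modules.

logistic <- function(x) stats::plogis(x)

## log(exp(a) + exp(b)) elementwise, overflow-safe
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## log(1 + exp(x)), overflow-safe
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

## Euclidean nearest-neighbour distance to another point in the same set.
## Grid-binned at the scale of the typical spacing; falls back to brute force
## for small n. Correctness is defined by the brute-force pairwise oracle.
nearest_neighbour_dist <- function(x, y) {
  n <- length(x)
  stop_if(n < 2, "need at least two points for nearest-neighbour distances")
  if (n <= 400) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    return(apply(d, 1, min))
  }
  span <- max(max(x) - min(x), max(y) - min(y), .Machine$double.eps)
  h <- max(span / ceiling(sqrt(n)), 1e-9)
  res <- rep(NA_real_, n)
  repeat {
    ix <- floor((x - min(x)) / h)
    iy <- floor((y - min(y)) / h)
    key <- paste(ix, iy)
    bins <- split(seq_len(n), key)
    bin_of <- match(key, names(bins))
    for (i in seq_len(n)) {
      if (!is.na(res[i])) next
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        k <- paste(ix[i] + dx, iy[i] + dy)
        cand <- c(cand, bins[[k]])
      }
      cand <- cand[cand != i]
      if (length(cand)) {
        dmin <- sqrt(min((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
        if (dmin <= h) res[i] <- dmin
      }
    }
    if (!anyNA(res)) return(res)
    h <- h * 2  # widen the search radius for points with no close neighbour
  }
}

## Deterministic child seed derived from a parent seed and a stage label;
## keeps every stage's stream independent while staying within 32-bit range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
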