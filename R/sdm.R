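#' Fit a penalized presence-background suitability model
#'
#' Logistic regression of presence (1) versus background (0) on per-point
#' covariates, with an optional ridge penalty `lambda` on the non-intercept
#' coefficients. Presence-background logistic regression estimates the same
#' relative suitability surface as an inhomogeneous-Poisson-process /
#' maximum-entropy model, so it serves as the model stage on which the
#' occurrence-filtering and background corrections act.
#'
#' @param presences,background data frames of points with the covariate
#'   columns named in `covariates`.
#' @param covariates character vector of covariate column names; factors are
#'   one-hot encoded against their first level.
#' @param lambda ridge penalty (>= 0) on non-intercept coefficients.
#' @param quadratic if TRUE, add squared terms for numeric covariates.
#' @return a `pb_fit`: list with `coefficients`, `lambda`, `loglik`
#'   (unpenalized, at the optimum), `k` (coefficient count), `n`, `converged`,
#'   and the encoding metadata needed for prediction.
#' @export
fit_presence_background <- function(presences, background, covariates,
                                    lambda = 0, quadratic = FALSE) {
  stop_if(nrow(presences) < 1 || nrow(background) < 1,
          "need at least one presence and one background point")
  stop_if(lambda < 0, "lambda must be >= 0")
  dat <- rbind(presences[, covariates, drop = FALSE],
               background[, covariates, drop = FALSE])
  y <- c(rep(1, nrow(presences)), rep(0, nrow(background)))
  levs <- lapply(dat, function(col) if (is.factor(col)) levels(col) else NULL)
  X <- pb_design(dat, covariates, levs, quadratic)
  n <- nrow(X); p <- ncol(X)
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1pexp(eta)) + lambda / 2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    mu <- logistic(drop(X %*% b))
    g <- -drop(crossprod(X, y - mu))
    g[-1] <- g[-1] + lambda * b[-1]
    g
  }
  opt <- stats::optim(rep(0, p), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  g <- grad(opt$par)
  converged <- max(abs(g)) < 1e-5 * max(1, abs(opt$value))
  eta <- drop(X %*% opt$par)
  ## perfectly separated classes have no finite MLE at lambda = 0
  if (lambda == 0 && any(y == 1) && any(y == 0) &&
      min(eta[y == 1]) > max(eta[y == 0])) {
    stop("complete separation with lambda = 0; refit with lambda > 0",
         call. = FALSE)
  }
  structure(list(coefficients = stats::setNames(opt$par, colnames(X)),
                 lambda = lambda,
                 loglik = sum(y * eta - log1pexp(eta)),
                 k = p, n = n, converged = converged,
                 covariates = covariates, levels = levs,
                 quadratic = quadratic),
            class = "pb_fit")
}

pb_design <- function(dat, covariates, levs, quadratic) {
  cols <- list(`(Intercept)` = rep(1, nrow(dat)))
  for (v in covariates) {
    col <- dat[[v]]
    if (!is.null(levs[[v]])) {
      bad <- setdiff(unique(as.character(col)), levs[[v]])
      stop_if(length(bad), sprintf("unseen level(s) in '%s': %s", v,
                                   paste(bad, collapse = ", ")))
      col <- factor(col, levels = levs[[v]])
      for (l in levs[[v]][-1]) cols[[paste0(v, l)]] <- as.numeric(col == l)
    } else {
      cols[[v]] <- as.numeric(col)
      if (quadratic) cols[[paste0(v, "^2")]] <- as.numeric(col)^2
    }
  }
  do.call(cbind, cols)
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("presence-background fit: %d coefficients, lambda = %g, logLik = %.2f (n = %d)\n",
              x$k, x$lambda, x$loglik, x$n))
  invisible(x)
}

#' Predict suitability over a landscape
#'
#' Logistic of the fitted linear predictor at each cell, a relative
#' suitability in (0, 1) monotone in the linear predictor.
#'
#' @param fit a `pb_fit`.
#' @param landscape a `landscape` (or cell data frame) whose covariate columns
#'   encode identically to training.
#' @return numeric vector of per-cell suitabilities.
#' @export
predict_suitability <- function(fit, landscape) {
  cells <- if (inherits(landscape, "landscape")) landscape$cells else landscape
  X <- pb_design(cells, fit$covariates, fit$levels, fit$quadratic)
  logistic(drop(X %*% fit$coefficients))
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; undefined for `n <= k + 1`.
#' One formula serves presence-background and zero-inflated fits alike: any
#' fit exposing `loglik`, `k` and `n` can be scored.
#'
#' @param fit a fitted object with `loglik`, `k`, `n`, or the three values
#'   given directly.
#' @param k,n parameter and observation counts when `fit` is a log-likelihood.
#' @return the AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (is.list(fit)) { ll <- fit$loglik; k <- fit$k; n <- fit$n } else ll <- fit
  stop_if(n <= k + 1, "AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the AICc-best model among candidates
#'
#' @param candidates list of fitted models exposing `loglik`, `k`, `n`.
#' @return the candidate with minimal AICc; ties break toward smaller `k`.
#' @export
select_model_by_aicc <- function(candidates) {
  stop_if(!length(candidates), "need at least one candidate")
  scores <- vapply(candidates, aicc, numeric(1))
  ks <- vapply(candidates, function(f) f$k, numeric(1))
  best <- order(scores, ks)[1]
  candidates[[best]]
}
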