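## Zero-inflated Poisson / negative-binomial regression.
##
## Mixture: with probability pi_i = logistic(z_i gamma) the observation is a
## structural (excess) zero; otherwise y_i ~ Poisson(mu_i) or
## NegBin(mu_i, theta) with mu_i = exp(x_i beta) and NB variance
## mu + mu^2 / theta. Parameters are packed c(beta, gamma[, log_theta]).

unpack_zi <- function(params, pc, pz, family) {
  list(beta = params[seq_len(pc)],
       gamma = params[pc + seq_len(pz)],
       log_theta = if (family == "negbin") params[pc + pz + 1] else NA_real_)
}

## per-observation log-likelihood, log-sum-exp stable
zi_loglik_obs <- function(params, X_count, X_zero, y, family = c("poisson", "negbin")) {
  family <- match.arg(family)
  stop_if(any(y < 0) || any(y != round(y)), "y must be nonnegative integers")
  p <- unpack_zi(params, ncol(X_count), ncol(X_zero), family)
  eta <- drop(X_count %*% p$beta)
  zeta <- drop(X_zero %*% p$gamma)
  mu <- exp(eta)
  ll <- numeric(length(y))
  z0 <- y == 0
  if (family == "poisson") {
    logf0 <- -mu
    if (any(!z0)) ll[!z0] <- stats::dpois(y[!z0], mu[!z0], log = TRUE)
  } else {
    theta <- exp(p$log_theta)
    logf0 <- theta * (p$log_theta - log(theta + mu))
    if (any(!z0)) ll[!z0] <- stats::dnbinom(y[!z0], size = theta, mu = mu[!z0], log = TRUE)
  }
  ll[!z0] <- ll[!z0] - log1pexp(zeta[!z0])
  ll[z0] <- log_sum_exp2(zeta[z0], logf0[z0]) - log1pexp(zeta[z0])
  ll
}

#' Zero-inflated model log-likelihood
#'
#' `sum_i log[ pi_i 1(y_i = 0) + (1 - pi_i) f(y_i; mu_i, theta) ]` with `f`
#' the Poisson or negative-binomial pmf, evaluated with log-sum-exp
#' stabilisation.
#'
#' @param params packed parameter vector `c(beta, gamma)` (Poisson) or
#'   `c(beta, gamma, log_theta)` (negative binomial).
#' @param X_count,X_zero design matrices of the count (log link) and zero
#'   (logit link) components.
#' @param y nonnegative integer counts.
#' @param family `"poisson"` or `"negbin"`.
#' @return scalar log-likelihood.
#' @export
zi_loglik <- function(params, X_count, X_zero, y, family = c("poisson", "negbin")) {
  sum(zi_loglik_obs(params, X_count, X_zero, y, match.arg(family)))
}

## analytic score of zi_loglik in the packed parameterization
zi_score <- function(params, X_count, X_zero, y, family) {
  p <- unpack_zi(params, ncol(X_count), ncol(X_zero), family)
  eta <- drop(X_count %*% p$beta)
  zeta <- drop(X_zero %*% p$gamma)
  mu <- exp(eta)
  pi <- logistic(zeta)
  z0 <- y == 0
  n <- length(y)
  dzeta <- numeric(n); deta <- numeric(n)
  if (family == "poisson") {
    logf0 <- -mu
    dlogf0_deta <- -mu
    deta[!z0] <- y[!z0] - mu[!z0]
  } else {
    theta <- exp(p$log_theta)
    logf0 <- theta * (p$log_theta - log(theta + mu))
    dlogf0_deta <- -theta * mu / (theta + mu)
    deta[!z0] <- y[!z0] - mu[!z0] * (y[!z0] + theta) / (theta + mu[!z0])
  }
  A <- log_sum_exp2(zeta[z0], logf0[z0])
  s <- exp(zeta[z0] - A)              # posterior weight of the excess component
  dzeta[z0] <- s - pi[z0]
  dzeta[!z0] <- -pi[!z0]
  deta[z0] <- (1 - s) * dlogf0_deta[z0]
  g <- c(drop(crossprod(X_count, deta)), drop(crossprod(X_zero, dzeta)))
  if (family == "negbin") {
    dth_pos <- digamma(y[!z0] + theta) - digamma(theta) + p$log_theta + 1 -
      log(theta + mu[!z0]) - (y[!z0] + theta) / (theta + mu[!z0])
    dth_zero <- (1 - s) * (p$log_theta + 1 - log(theta + mu[z0]) -
                             theta / (theta + mu[z0]))
    g <- c(g, theta * (sum(dth_pos) + sum(dth_zero)))
  }
  g
}

#' Fit a zero-inflated Poisson or negative-binomial regression
#'
#' Maximizes the mixture log-likelihood by BFGS with the analytic score,
#' warm-started from a plain count GLM on the positive-count cells (count
#' component) and a logistic regression on the zero indicator (zero
#' component). Standard errors come from the inverse observed information at
#' the optimum. Non-convergence is flagged, never masked.
#'
#' @param X_count,X_zero design matrices (include an intercept column); both
#'   components receive the full covariate design in the default workflow.
#' @param y nonnegative integer counts with at least one zero and one
#'   positive value.
#' @param family `"poisson"` or `"negbin"`.
#' @param init optional packed start values.
#' @param tol relative gradient tolerance for the convergence flag.
#' @param max_iter BFGS iteration cap.
#' @return a `zi_fit`: coefficients `beta`, `gamma`, `log_theta` (NB only)
#'   with standard errors, `loglik`, pointwise log-likelihood, `k`, `n`,
#'   `converged`, and the training designs needed for non-nested comparison.
#' @export
fit_zi <- function(X_count, X_zero, y, family = c("poisson", "negbin"),
                   init = NULL, tol = 1e-6, max_iter = 500L) {
  family <- match.arg(family)
  stop_if(any(y < 0) || any(y != round(y)), "y must be nonnegative integers")
  stop_if(all(y == 0), "all-zero response: zero-inflated model not identifiable")
  stop_if(!any(y == 0), "no zeros in response: nothing for the zero component to fit")
  pc <- ncol(X_count); pz <- ncol(X_zero)
  k <- pc + pz + (family == "negbin")
  stop_if(length(y) <= k, "need more observations than parameters")
  if (is.null(init)) {
    g0 <- stats::glm.fit(X_zero, as.numeric(y == 0),
                         family = stats::binomial())$coefficients
    pos <- y > 0
    b0 <- tryCatch(
      stats::glm.fit(X_count[pos, , drop = FALSE], y[pos],
                     family = stats::poisson())$coefficients,
      error = function(e) NULL)
    if (is.null(b0) || anyNA(b0)) {
      b0 <- c(log(mean(y[pos])), rep(0, pc - 1))
    }
    g0[is.na(g0)] <- 0
    init <- c(b0, g0)
    if (family == "negbin") {
      mu0 <- mean(y[pos])
      v0 <- stats::var(y[pos])
      th0 <- if (is.finite(v0) && v0 > mu0) mu0^2 / (v0 - mu0) else 1
      init <- c(init, log(max(th0, 1e-3)))
    }
  }
  stop_if(length(init) != k, "init has the wrong length")
  ## optimizer may probe extreme parameter values; treat overflow as a barrier
  negll <- function(par) {
    if (any(!is.finite(par)) || max(abs(par)) > 50) return(1e15)
    v <- -suppressWarnings(zi_loglik(par, X_count, X_zero, y, family))
    if (!is.finite(v)) 1e15 else v
  }
  neggr <- function(par) {
    if (any(!is.finite(par)) || max(abs(par)) > 50) return(rep(0, length(par)))
    g <- -suppressWarnings(zi_score(par, X_count, X_zero, y, family))
    g[!is.finite(g)] <- 0
    g
  }
  opt <- stats::optim(init, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  grad <- zi_score(opt$par, X_count, X_zero, y, family)
  converged <- max(abs(grad)) < tol * max(1, abs(opt$value))
  hess <- tryCatch(stats::optimHess(opt$par, negll, neggr), error = function(e) NULL)
  se <- rep(NA_real_, k)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      dv <- diag(vc)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  p <- unpack_zi(opt$par, pc, pz, family)
  cn <- colnames(X_count) %||% paste0("x", seq_len(pc))
  zn <- colnames(X_zero) %||% paste0("z", seq_len(pz))
  structure(list(
    beta = stats::setNames(p$beta, cn),
    gamma = stats::setNames(p$gamma, zn),
    log_theta = unname(p$log_theta),
    se_beta = stats::setNames(se[seq_len(pc)], cn),
    se_gamma = stats::setNames(se[pc + seq_len(pz)], zn),
    se_log_theta = if (family == "negbin") se[k] else NA_real_,
    family = family,
    loglik = -opt$value,
    pointwise = zi_loglik_obs(opt$par, X_count, X_zero, y, family),
    params = opt$par, k = k, n = length(y), y = y,
    converged = converged, max_abs_grad = max(abs(grad))),
    class = "zi_fit")
}

#' @export
print.zi_fit <- function(x, ...) {
  cat(sprintf("zero-inflated %s fit: logLik = %.2f, k = %d, n = %d%s\n",
              x$family, x$loglik, x$k, x$n,
              if (x$converged) "" else " (NOT converged)"))
  tab <- coef_table(x)
  print(tab, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Coefficient table of a zero-inflated fit
#'
#' One row per term and component with estimate, standard error and Z value,
#' the usual two-component reporting layout (`log_theta` rides with the count
#' component for the negative binomial).
#'
#' @param fit a `zi_fit`.
#' @return data frame with columns `term`, `component`, `estimate`, `se`, `z`.
#' @export
coef_table <- function(fit) {
  tab <- data.frame(
    term = c(names(fit$beta), names(fit$gamma)),
    component = c(rep("count", length(fit$beta)), rep("zero", length(fit$gamma))),
    estimate = c(fit$beta, fit$gamma),
    se = c(fit$se_beta, fit$se_gamma))
  if (fit$family == "negbin") {
    tab <- rbind(tab, data.frame(term = "log_theta", component = "count",
                                 estimate = fit$log_theta, se = fit$se_log_theta))
  }
  tab$z <- tab$estimate / tab$se
  rownames(tab) <- NULL
  tab
}

#' Predictions from a zero-inflated fit
#'
#' The three prediction types of a two-component model: `"count"` is
#' `mu = exp(x beta)`, the abundance estimate free of the zero-generating
#' process; `"zero"` is `pi = logistic(z gamma)`, the probability that a cell
#' is an excess zero; `"whole"` is `(1 - pi) mu`, the expected observed count.
#' When the excess zeros come from non-sampling rather than ecology, the count
#' prediction is the better estimate of true abundance while the whole-model
#' prediction tracks the biased observations.
#'
#' @param fit a `zi_fit`.
#' @param newdata a `landscape`, a cell data frame, or a list with elements
#'   `X_count` and `X_zero`.
#' @param type `"count"`, `"whole"` or `"zero"`.
#' @return numeric vector of per-cell predictions.
#' @export
predict_zi <- function(fit, newdata, type = c("count", "whole", "zero")) {
  type <- match.arg(type)
  if (!fit$converged) {
    warning("predictions from a non-converged fit", call. = FALSE)
  }
  if (inherits(newdata, "landscape") || is.data.frame(newdata)) {
    X <- landscape_design(newdata)
    stop_if(!all(names(fit$beta) %in% colnames(X)),
            "newdata design lacks count-component columns")
    stop_if(!all(names(fit$gamma) %in% colnames(X)),
            "newdata design lacks zero-component columns")
    Xc <- X[, names(fit$beta), drop = FALSE]
    Xz <- X[, names(fit$gamma), drop = FALSE]
  } else {
    Xc <- newdata$X_count; Xz <- newdata$X_zero
  }
  mu <- exp(drop(Xc %*% fit$beta))
  if (type == "count") return(mu)
  pi <- logistic(drop(Xz %*% fit$gamma))
  if (type == "zero") pi else (1 - pi) * mu
}

#' Vuong test for non-nested count models
#'
#' Compares two fits to the same response by the pointwise log-likelihood
#' differences `m_i`; `Z = (sum(m) - C) / (sqrt(n) sd(m))` where `C` is 0
#' (`"none"`), `k1 - k2` (`"aic"`), or the difference of the AICc penalty
#' halves (`"aicc"`). Negative Z favours `fit2`.
#'
#' @param fit1,fit2 `zi_fit` objects on the same `y`.
#' @param correction `"none"`, `"aic"` or `"aicc"`.
#' @return list with `z`, one-sided p-values `p_fit1` (evidence for fit1) and
#'   `p_fit2`, and the correction constant `C`.
#' @export
vuong_test <- function(fit1, fit2, correction = c("none", "aic", "aicc")) {
  correction <- match.arg(correction)
  stop_if(fit1$n != fit2$n, "fits have different n")
  stop_if(!isTRUE(all.equal(fit1$y, fit2$y)), "fits were made on different responses")
  m <- fit1$pointwise - fit2$pointwise
  n <- fit1$n
  stop_if(stats::sd(m) == 0, "Vuong statistic undefined: identical pointwise log-likelihoods")
  C <- switch(correction,
              none = 0,
              aic = fit1$k - fit2$k,
              aicc = (fit1$k + fit1$k * (fit1$k + 1) / (n - fit1$k - 1)) -
                     (fit2$k + fit2$k * (fit2$k + 1) / (n - fit2$k - 1)))
  z <- (sum(m) - C) / (sqrt(n) * stats::sd(m))
  list(z = z, p_fit1 = stats::pnorm(z, lower.tail = FALSE),
       p_fit2 = stats::pnorm(z), C = C)
}
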