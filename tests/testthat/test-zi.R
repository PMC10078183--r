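test_that("mixture log-likelihood matches the brute-force oracle on random instances", {
  set.seed(77)
  for (case in 1:100) {
    n <- sample(5:30, 1)
    Xc <- cbind(1, rnorm(n)); Xz <- cbind(1, rnorm(n))
    y <- rpois(n, 2)
    if (!any(y == 0)) y[1] <- 0L
    fam <- sample(c("poisson", "negbin"), 1)
    k <- ncol(Xc) + ncol(Xz) + (fam == "negbin")
    par <- rnorm(k, sd = 0.7)
    expect_equal(zi_loglik(par, Xc, Xz, y, fam),
                 bf_zi_loglik(par, Xc, Xz, y, fam),
                 tolerance = 1e-10)
  }
})

test_that("degenerate mixtures reduce to closed forms", {
  y <- c(0L, 3L, 1L); X <- matrix(1, 3, 1)
  ## pi == 0: plain Poisson log-likelihood
  expect_equal(zi_loglik(c(log(2), -100), X, X, y, "poisson"),
               sum(dpois(y, 2, log = TRUE)), tolerance = 1e-9)
  ## single zero with pi = 0.5, mu = 2: log(0.5 + 0.5 e^-2)
  X1 <- matrix(1, 1, 1)
  expect_equal(zi_loglik(c(log(2), 0), X1, X1, 0L, "poisson"),
               log(0.5 + 0.5 * exp(-2)), tolerance = 1e-12)
  expect_error(zi_loglik(c(0, 0), X, X, c(-1, 0, 1), "poisson"), "nonnegative")
  expect_error(zi_loglik(c(0, 0), X, X, c(0.5, 1, 0), "poisson"), "integer")
})

test_that("analytic score matches central finite differences", {
  set.seed(15)
  for (fam in c("poisson", "negbin")) {
    n <- 60
    Xc <- cbind(1, rnorm(n), rnorm(n)); Xz <- cbind(1, rnorm(n))
    y <- rpois(n, 2); y[1:10] <- 0L
    k <- 3 + 2 + (fam == "negbin")
    for (rep in 1:5) {
      par <- rnorm(k, sd = 0.5)
      g <- biastree:::zi_score(par, Xc, Xz, y, fam)
      h <- 1e-5
      fd <- vapply(seq_len(k), function(j) {
        e <- rep(0, k); e[j] <- h
        (zi_loglik(par + e, Xc, Xz, y, fam) -
           zi_loglik(par - e, Xc, Xz, y, fam)) / (2 * h)
      }, numeric(1))
      expect_equal(g, fd, tolerance = 1e-5)
    }
  }
})

test_that("intercept-only fit recovers known mixture parameters", {
  set.seed(42)
  n <- 5000
  y <- ifelse(runif(n) < 0.5, 0L, rpois(n, 5))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_zi(X, X, y, "poisson")
  expect_true(f$converged)
  expect_lt(abs(plogis(f$gamma[1]) - 0.5), 0.03)
  expect_lt(abs(exp(f$beta[1]) - 5), 0.2)
  ## the optimum cannot be worse than the warm start
  expect_gte(f$loglik, zi_loglik(c(log(mean(y[y > 0])), qlogis(mean(y == 0))),
                                 X, X, y, "poisson"))
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(8)
  n <- 1500
  x <- rnorm(n); z <- rnorm(n)
  mu <- exp(1 + 0.5 * x); pi <- plogis(-0.5 + 0.8 * z)
  y <- ifelse(runif(n) < pi, 0L, rnbinom(n, size = 1.5, mu = mu))
  f <- fit_zi(cbind(1, x), cbind(1, z), y, "negbin")
  g <- glmmTMB::glmmTMB(y ~ x, ziformula = ~ z, family = glmmTMB::nbinom2,
                        data = data.frame(y, x, z))
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(glmmTMB::fixef(g)$cond), tolerance = 1e-3)
  expect_equal(unname(f$gamma), unname(glmmTMB::fixef(g)$zi), tolerance = 1e-3)
  expect_equal(f$log_theta, log(glmmTMB::sigma(g)), tolerance = 1e-3)
})

test_that("without excess zeros the count component matches a plain GLM", {
  set.seed(3)
  n <- 2000
  x <- rnorm(n)
  y <- rpois(n, exp(1.5 + 0.6 * x))
  expect_gt(sum(y == 0), 0)
  f <- fit_zi(cbind(1, x), cbind(1, x), y, "poisson")
  g <- glm(y ~ x, poisson)
  expect_lt(plogis(f$gamma[1]), 0.05)  # near-zero excess-zero probability
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 0.02)
})

test_that("negative binomial at huge dispersion matches the Poisson fit", {
  set.seed(6)
  n <- 1000
  y <- ifelse(runif(n) < 0.3, 0L, rpois(n, 4))
  X <- matrix(1, n, 1)
  fp <- fit_zi(X, X, y, "poisson")
  fn <- fit_zi(X, X, y, "negbin",
               init = c(fp$beta, fp$gamma, log(1e6)))
  expect_lt(abs(fn$loglik - fp$loglik), 1e-3 * n)
})

test_that("the three prediction types follow their closed forms and ordering", {
  n <- 50
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- c(rep(0L, 25), rpois(25, 3) + 1L)
  f <- fit_zi(X, X, y, "poisson")
  f$beta[1] <- 1; f$gamma[1] <- 0
  nd <- list(X_count = X[1:2, , drop = FALSE], X_zero = X[1:2, , drop = FALSE])
  expect_equal(predict_zi(f, nd, "count"), rep(exp(1), 2))
  expect_equal(predict_zi(f, nd, "zero"), rep(0.5, 2))
  expect_equal(predict_zi(f, nd, "whole"), rep(exp(1) / 2, 2))
  ## pi = 0: whole equals count exactly
  f$gamma[1] <- -200
  expect_equal(predict_zi(f, nd, "whole"), predict_zi(f, nd, "count"))
})

test_that("whole-model predictions never exceed count predictions", {
  d <- biased_dataset(seed = 19, n_rows = 15, n_cols = 15)
  f <- fit_zi(d$X, d$X, d$Y, "negbin")
  cnt <- predict_zi(f, d$land, "count")
  wh <- predict_zi(f, d$land, "whole")
  zr <- predict_zi(f, d$land, "zero")
  expect_true(all(wh <= cnt))
  expect_true(all(zr > 0 & zr < 1))
  expect_true(all(is.finite(cnt)))
  ## fitted mean approximately reproduces the sample mean: the intercept score
  ## equations tie sum((1 - s_i) mu_i) to sum(y), which tracks sum((1 - pi_i) mu_i)
  ## up to the covariance between the posterior and prior excess-zero weights
  expect_equal(mean(wh[seq_along(d$Y)]), mean(d$Y), tolerance = 0.1)
})

test_that("parameter recovery improves with sample size", {
  true_par <- c(1, 0.5, 0, 0.8)
  err_at <- function(n, nrep = 3) {
    errs <- vapply(seq_len(nrep), function(r) {
      set.seed(n + r)
      x <- rnorm(n); z <- rnorm(n)
      y <- ifelse(runif(n) < plogis(0 + 0.8 * z), 0L,
                  rpois(n, exp(1 + 0.5 * x)))
      f <- fit_zi(cbind(1, x), cbind(1, z), y, "poisson")
      sqrt(mean((c(f$beta, f$gamma) - true_par)^2))
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(500), err_at(2000), err_at(8000))
  expect_lt(e[3], e[1])
})

test_that("Vuong comparison follows its definition and error contract", {
  set.seed(30)
  n <- 400
  x <- rnorm(n)
  y <- ifelse(runif(n) < 0.4, 0L, rnbinom(n, size = 0.6, mu = exp(1 + 0.5 * x)))
  X <- cbind(1, x)
  fp <- fit_zi(X, X, y, "poisson")
  fn <- fit_zi(X, X, y, "negbin")
  v <- vuong_test(fp, fn, "none")
  m <- fp$pointwise - fn$pointwise
  expect_equal(v$z, sum(m) / (sqrt(n) * sd(m)), tolerance = 1e-12)
  ## correction constants
  expect_equal(vuong_test(fp, fn, "aic")$C, fp$k - fn$k)
  ## identical pointwise log-likelihoods are undefined, not silently zero
  expect_error(vuong_test(fp, fp, "none"), "undefined")
})

test_that("Vuong AIC correction constant matches the closed form for large models", {
  ## two stand-in fits differing by one parameter, k = 81 vs 80 at n = 10^4
  set.seed(1)
  n <- 10000
  base <- rnorm(n, sd = 0.1)
  f1 <- structure(list(pointwise = base + 0.001, k = 81, n = n, y = rep(0L, n),
                       loglik = sum(base)), class = "zi_fit")
  f2 <- structure(list(pointwise = base, k = 80, n = n, y = rep(0L, n),
                       loglik = sum(base)), class = "zi_fit")
  expect_equal(vuong_test(f1, f2, "aic")$C, 1)
  aicc_half <- function(k) k + k * (k + 1) / (n - k - 1)
  expect_equal(vuong_test(f1, f2, "aicc")$C, aicc_half(81) - aicc_half(80))
})

test_that("degenerate responses are rejected", {
  X <- matrix(1, 20, 1)
  expect_error(fit_zi(X, X, rep(0L, 20), "poisson"), "all-zero")
  expect_error(fit_zi(X, X, rep(2L, 20), "poisson"), "zero")
})
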