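test_that("minimal landscape is valid and generation is deterministic", {
  l1 <- generate_landscape(landscape_config(1, 1, seed = 3))
  expect_equal(nrow(l1$cells), 1)
  expect_true(all(is.finite(l1$cells$env1)))
  expect_true(l1$cells$class1 %in% paste0("l", 1:3))

  a <- tiny_landscape(seed = 11)
  b <- tiny_landscape(seed = 11)
  expect_identical(a$cells, b$cells)
  expect_error(landscape_config(0, 5), "positive")
})

test_that("longer correlation length raises lag-1 spatial autocorrelation", {
  moran_lag1 <- function(v, nr, nc) {
    m <- matrix(v, nr, nc, byrow = TRUE)
    z <- m - mean(m)
    num <- den <- 0; W <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          num <- num + z[i, j] * z[ii, jj]; W <- W + 1
        }
      }
      den <- den + z[i, j]^2
    }
    (length(v) / W) * (num / den)
  }
  smooth <- generate_landscape(landscape_config(25, 25, n_numeric = 1,
                                                correlation_length = 10000, seed = 5))
  rough <- generate_landscape(landscape_config(25, 25, n_numeric = 1,
                                               correlation_length = 100, seed = 5))
  expect_gt(moran_lag1(smooth$cells$env1, 25, 25),
            moran_lag1(rough$cells$env1, 25, 25))
})

test_that("true abundance follows the stated count process", {
  land <- generate_landscape(landscape_config(100, 100, n_numeric = 0,
                                              n_categorical = 0, seed = 2))
  # Poisson limit: theta huge, intercept log 5
  tr <- truth_config(log(5), 1e6, 0, seed = 9)
  N <- simulate_true_abundance(land, tr)
  se <- sqrt(5 / length(N))
  expect_lt(abs(mean(N) - 5), 3 * se)
  # vanishing mean
  N0 <- simulate_true_abundance(land, truth_config(-20, 1, 0, seed = 1))
  expect_true(all(N0 == 0))
  # NB variance identity: var = mu + mu^2 / theta
  trnb <- truth_config(log(5), 0.2, 0, seed = 4)
  Nnb <- simulate_true_abundance(land, trnb)
  expect_lt(abs(var(Nnb) - 130) / 130, 0.15)
  expect_error(simulate_true_abundance(land, truth_config(c(1, 2), 1, 0)),
               "design")
})

test_that("sampling process censors, flags and thins as specified", {
  land <- generate_landscape(landscape_config(100, 100, n_numeric = 0,
                                              n_categorical = 0, seed = 2))
  N <- simulate_true_abundance(land, truth_config(log(5), 1e6, 0, seed = 9))
  # pi = 0, detection 1: Y == N
  s0 <- simulate_sampling(land, N, truth_config(log(5), 1e6, -50, seed = 1))
  expect_identical(s0$Y, as.integer(N))
  expect_false(any(s0$excess))
  # pi -> 1: all censored
  s1 <- simulate_sampling(land, N, truth_config(log(5), 1e6, 50, seed = 1))
  expect_true(all(s1$Y == 0))
  # gamma intercept 0: flagged fraction ~ 0.5
  sh <- simulate_sampling(land, N, truth_config(log(5), 1e6, 0, seed = 3))
  expect_lt(abs(mean(sh$excess) - 0.5), 3 * sqrt(0.25 / length(N)))
  # flag consistency
  expect_true(all(sh$Y[sh$excess] == 0))
  expect_error(truth_config(1, 1, 0, detection_prob = 0), "detection_prob")
})

test_that("zero-inflated marginal zero rate matches the mixture in the homogeneous case", {
  land <- generate_landscape(landscape_config(100, 100, n_numeric = 0,
                                              n_categorical = 0, seed = 2))
  tr <- truth_config(log(3), 0.5, qlogis(0.4), detection_prob = 0.8, seed = 21)
  N <- simulate_true_abundance(land, tr)
  s <- simulate_sampling(land, N, tr)
  ## P(Y=0) = pi + (1-pi) * NB0 under binomial-thinned mean (thinned NB keeps theta)
  p0 <- 0.4 + 0.6 * dnbinom(0, size = 0.5, mu = 3 * 0.8)
  expect_lt(abs(mean(s$Y == 0) - p0), 4 * sqrt(p0 * (1 - p0) / length(N)))
})

test_that("point placement conserves counts and respects cell bounds", {
  land <- tiny_landscape(3, 3, seed = 2)
  Y <- rep(0L, 9)
  expect_equal(nrow(place_points(land, Y)), 0)
  Y[5] <- 3L
  rec <- place_points(land, Y, seed = 8)
  expect_equal(nrow(rec), 3)
  cell <- land$cells[5, ]
  expect_true(all(rec$x >= cell$x_min & rec$x < cell$x_min + 1000))
  expect_true(all(rec$y >= cell$y_min & rec$y < cell$y_min + 1000))
  Y2 <- rpois(9, 4)
  expect_equal(nrow(place_points(land, Y2, seed = 1)), sum(Y2))
})

test_that("recorder assignment is deterministic, exhaustive, and distance-decaying", {
  land <- tiny_landscape(10, 10, seed = 6)
  Y <- rpois(100, 1)
  rec <- place_points(land, Y, seed = 3)
  one <- simulate_recorders(land, rec, 1, 5000, seed = 2)
  expect_true(all(one$records$recorder_id == 1))
  r1 <- simulate_recorders(land, rec, 5, 3000, seed = 7)
  r2 <- simulate_recorders(land, rec, 5, 3000, seed = 7)
  expect_identical(r1, r2)
  ## enormous decay: assignment independent of distance (uniform across recorders)
  counts <- integer(4)
  for (s in 1:12) {
    ra <- simulate_recorders(land, rec, 4, 1e12, seed = s)
    counts <- counts + tabulate(ra$records$recorder_id, 4)
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("field surveys are effort-consistent and density is unbiased", {
  ids <- 1:4
  full <- simulate_field_survey(ids, c(10, 0, 5, 7),
                                coverage_dist = function(n) rep(1, n), seed = 1)
  expect_equal(full$observed_count, c(10, 0, 5, 7))
  expect_equal(full$density, c(10, 0, 5, 7) / 1e6)
  ## half coverage halves the expected count
  many <- simulate_field_survey(rep(1, 4000), rep(100L, 4000),
                                coverage_dist = function(n) rep(0.5, n), seed = 5)
  expect_lt(abs(mean(many$observed_count) - 50), 3 * 5 / sqrt(4000))
  ## density estimator unbiased for N/area under full detection
  mixed <- simulate_field_survey(rep(1, 4000), rep(100L, 4000),
                                 coverage_dist = function(n) runif(n, 0.2, 1),
                                 seed = 6)
  expect_lt(abs(mean(mixed$density) - 100 / 1e6) / (100 / 1e6), 0.05)
})
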