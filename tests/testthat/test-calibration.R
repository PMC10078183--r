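test_that("stratified square selection yields the designed counts and strata", {
  d <- biased_dataset(seed = 29, n_rows = 40, n_cols = 40)
  f <- fit_zi(d$X, d$X, d$Y, "negbin")
  zp <- predict_zi(f, d$land, "zero")
  sq <- select_squares(d$Y, zp, n_random = 50, n_per_stratum = 10, seed = 3)
  expect_equal(nrow(sq), 90)
  expect_equal(sum(sq$stratum == "random"), 50)
  expect_equal(as.vector(table(sq$stratum)[c("ATI_high", "ATI_low", "noATI_high", "noATI_low")]),
               rep(10L, 4))
  expect_equal(anyDuplicated(sq$cell_id[sq$stratum != "random"]), 0)
  ## brute-force reclassification of every stratified square
  thr <- mean(zp)
  for (i in which(sq$stratum != "random")) {
    id <- sq$cell_id[i]
    expected <- if (d$Y[id] > 0) {
      if (zp[id] <= thr) "ATI_high" else "ATI_low"
    } else {
      if (zp[id] <= thr) "noATI_high" else "noATI_low"
    }
    expect_equal(sq$stratum[i], expected)
  }
})

test_that("degenerate landscapes fail stratification with a named stratum", {
  Y <- rep(1L, 100)  # every cell has records: noATI strata empty
  zp <- runif(100)
  expect_error(select_squares(Y, zp, 10, 5, seed = 1), "noATI")
})

test_that("tree density is the effort-adjusted quotient", {
  expect_equal(tree_density(10, 1, 1e6), 1e-5)
  expect_equal(tree_density(5, 0.5, 1e6), tree_density(10, 1, 1e6))
  set.seed(9)
  for (i in 1:20) {
    n <- rpois(1, 20); cv <- runif(1, 0.05, 1)
    expect_equal(tree_density(n, cv, 1e6), n / (cv * 1e6))
  }
  expect_error(tree_density(3, 0), "coverage")
})

test_that("calibration recovers exact linear relationships and matches normal equations", {
  p <- c(1, 3, 5, 9)
  cal <- suppressWarnings(calibrate(p, 2 * p + 1, metric = "abundance"))  # exact fit
  expect_equal(cal$intercept, 1, tolerance = 1e-10)
  expect_equal(cal$slope, 2, tolerance = 1e-10)
  ## 4-point case against the brute-force normal-equations solution
  y4 <- c(2.2, 1.8, 5.5, 7.1)
  cal4 <- calibrate(p, y4, metric = "density")
  A <- cbind(1, p)
  beta <- solve(t(A) %*% A, t(A) %*% y4)
  expect_equal(c(cal4$intercept, cal4$slope), as.numeric(beta), tolerance = 1e-10)
  expect_error(calibrate(rep(2, 4), y4), "constant")
  ## uncorrelated noise: slope near zero on average
  set.seed(5)
  slopes <- vapply(1:40, function(i) {
    calibrate(rnorm(30), rnorm(30), "abundance")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.15)
})

test_that("the landscape total is linear in predictions and unit-consistent", {
  p <- c(0.5, 1.5, 2, 4)
  cal <- structure(list(intercept = 3, slope = 2, metric = "abundance"),
                   class = "calibration_result")
  tot <- national_total(cal, p)
  expect_equal(tot$total, 3 * 4 + 2 * sum(p))  # a*n + b*sum(p), exact identity
  cal0 <- structure(list(intercept = 7, slope = 0, metric = "abundance"),
                    class = "calibration_result")
  expect_equal(national_total(cal0, p)$total, 7 * 4)
  ## identity calibration sums the predictions
  cal1 <- structure(list(intercept = 0, slope = 1, metric = "abundance"),
                    class = "calibration_result")
  expect_equal(national_total(cal1, p)$total, sum(p))
  ## clipping floors negative per-cell estimates
  caln <- structure(list(intercept = -2, slope = 1, metric = "abundance"),
                    class = "calibration_result")
  expect_equal(national_total(caln, p, clip_negative = TRUE)$total,
               sum(pmax(p - 2, 0)))
  expect_equal(national_total(caln, p)$total, sum(p - 2))
})

test_that("density and abundance calibrations agree under full coverage", {
  set.seed(13)
  pred <- runif(30, 0, 5)
  counts <- rpois(30, 10 * pred + 1)
  cell_area <- 1e6
  cal_a <- calibrate(pred, counts, "abundance")
  cal_d <- calibrate(pred, counts / cell_area, "density")
  Ta <- national_total(cal_a, pred)$total
  Td <- national_total(cal_d, pred, cell_area = cell_area)$total
  expect_equal(Ta, Td, tolerance = 1e-8)
})

test_that("end-to-end totals converge on the truth as survey effort grows", {
  ## unbiased random surveys + a well-specified count model: relative error
  ## of T shrinks with the number of surveyed squares
  err_at <- function(n_squares, nrep = 8) {
    errs <- vapply(seq_len(nrep), function(r) {
      d <- biased_dataset(seed = 100 * n_squares + r, n_rows = 30, n_cols = 30,
                          family_truth = "poisson")
      f <- fit_zi(d$X, d$X, d$Y, "poisson")
      cnt <- predict_zi(f, d$land, "count")
      set.seed(r)
      ids <- sample(length(d$Y), n_squares)
      srv <- simulate_field_survey(ids, d$N[ids], seed = r)
      cal <- calibrate(cnt[ids], srv$density, "density")
      T_ <- national_total(cal, cnt, cell_area = 1e6)$total
      abs(T_ - sum(d$N)) / sum(d$N)
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(25), err_at(100))
  expect_lt(e[2], e[1])
})

test_that("field AUC thresholds abundance at the median of the reference set", {
  pred <- c(0.1, 0.4, 5, 9, 2, 0.2)
  pa <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(field_auc(pred, pa, type = "suitability"), 1)
  ## median computed on the full selected set even when fewer were surveyed
  ref90 <- c(pred, rep(0.05, 6))   # reference set larger than surveyed set
  got <- field_auc(pred, pa, threshold_reference = ref90, type = "abundance")
  thr <- median(ref90)
  manual <- auc(pa, as.numeric(pred > thr))
  expect_equal(got, manual)
  ## shuffled predictions: AUC near 1/2 over replicates
  set.seed(77)
  aucs <- vapply(1:200, function(i) field_auc(sample(pred), pa, type = "suitability"),
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
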