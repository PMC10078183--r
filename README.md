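# biastree

Estimating species abundance from spatially biased citizen-science records.

Large occurrence databases — the motivating case is a national inventory of
ancient and veteran trees recorded by volunteers on a 1-km grid — mix two
kinds of zeros: cells where the species is truly absent, and cells nobody
ever surveyed. `biastree` implements the bias-correction workflow for such
data end to end:

* **Spatial filtering** of occurrence records: systematic (one record per
  coarse cell), single-linkage cluster filtering, and weighted-distance
  thinning that favours isolated records.
* **Pseudo-absence manipulation**: uniform backgrounds, buffer-restricted
  backgrounds, and "bias file" surfaces (kernel density of recorder homes or
  town centroids, rescaled rasters, record density) that steer background
  points toward well-recorded areas.
* **Presence–background suitability models** (penalized logistic regression,
  the explicit-likelihood equivalent of a maximum-entropy model) tuned by
  AICc over a ridge-penalty grid.
* **Zero-inflated Poisson / negative-binomial regression** on per-cell
  pseudo-abundance, with count (\(\mu\)), zero (\(\pi\)) and whole-model
  (\((1-\pi)\mu\)) predictions, analytic-score fitting, and Vuong AIC/AICc
  comparison of non-nested fits. The count component estimates abundance free
  of the zero-generating (non-sampling) process; the zero component maps
  suspected under-recording.
* **Validation and calibration**: k-fold cross-validation with AUC, RMSLE and
  rank correlations; stratified field-survey simulation (50 random + 4×10
  stratified squares, partial coverage, incomplete completion);
  effort-adjusted density `count / (coverage × area)`; OLS calibration of
  predictions against field metrics; and a landscape-wide population total
  `T = Σ (a + b·prediction)`.
* A **synthetic landscape generator** with known truth (spatially smooth
  covariates, NB abundance, logistic excess-zero process, recorder home
  bases), so every stage is testable against the true per-cell abundance.

## Worked example

```r
library(biastree)
land  <- generate_landscape(landscape_config(n_rows = 40, n_cols = 40, seed = 11,
                                             n_numeric = 3, n_categorical = 1))
truth <- truth_config(beta_count = c(0.5, 0.8, -0.4, 0.3, 0.3, -0.3), theta = 0.4,
                      gamma_zero = c(1.2, -0.9, 0.6, 0, 0.4, 0), seed = 11)
N       <- simulate_true_abundance(land, truth)       # true per-cell abundance
obs     <- simulate_sampling(land, N, truth)          # biased observation
records <- place_points(land, obs$Y, seed = 11)       # point records
Y       <- aggregate_to_counts(records, land)         # pseudo-abundance

X      <- landscape_design(land)
fit_p  <- fit_zi(X, X, Y, "poisson")
fit_nb <- fit_zi(X, X, Y, "negbin")
fit_nb
vuong_test(fit_p, fit_nb, "aicc")$z
```

```
zero-inflated negbin fit: logLik = -1236.13, k = 13, n = 1600
        term component estimate    se      z
 (Intercept)     count    0.495 0.223  2.224
        env1     count    0.888 0.131  6.780
        env2     count   -0.362 0.128 -2.836
        ...
   log_theta     count   -0.659 0.244 -2.706
Vuong Z: -4.87
```

The count-component coefficients recover the generating
`beta = (0.5, 0.8, -0.4, ...)`, and the negative Vuong statistic says the
negative-binomial fit is preferred over the Poisson — the expected verdict
for data with a variance:mean ratio of 21.5. Calibrating the count
predictions against a simulated 90-square field survey and summing over the
landscape:

```r
cnt <- predict_zi(fit_nb, land, "count")
sq  <- select_squares(Y, predict_zi(fit_nb, land, "zero"), 50, 10, seed = 2)
srv <- simulate_field_survey(sq$cell_id, N[sq$cell_id], seed = 3)
cal <- calibrate(cnt[sq$cell_id], srv$density, metric = "density")
national_total(cal, cnt, cell_area = 1e6)$total
```

```
calibration (density): a = 1.059e-07 (SE 7.75e-07), b = 1.022e-06 (SE 2.22e-07)
calibrated landscape total: 4413     (true total: 3924)
```

The whole pipeline — simulate, aggregate, apply every configured bias
correction, fit, cross-validate, survey, calibrate — runs from one config:

```r
res <- run_pipeline(default_pipeline_config(seed = 1), output_dir = "run1")
res$comparison   # one row per model variant: AICc, AUC, RMSLE, field r/rs, totals
```

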