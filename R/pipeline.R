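#' Default pipeline configuration
#'
#' The study conditions of the synthetic workflow: a 50 x 50 grid of 1-km
#' cells with three smooth numeric covariates and one three-level class
#' covariate; true abundance from a log-linear negative-binomial process with
#' strong overdispersion; a covariate-driven excess-zero (non-sampling)
#' process leaving roughly a tenth of cells with positive observed counts;
#' recorder home bases for the recorder-density bias surface; and a 50 + 4x10
#' stratified field-survey design with partial coverage, random accessibility
#' rejection and incomplete completion.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param seed global seed; every stage derives its own stream from it.
#' @return a nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(n_rows = 50, n_cols = 50, seed = 1L) {
  list(
    seed = as.integer(seed),
    landscape = list(n_rows = n_rows, n_cols = n_cols, cell_size = 1000,
                     n_numeric = 3, n_categorical = 1, n_levels = 3,
                     correlation_length = 5000),
    truth = list(
      beta_count = c(0.5, 0.8, -0.4, 0.3, 0.3, -0.3),
      theta = 0.4,
      gamma_zero = c(1.2, -0.9, 0.6, 0, 0.4, 0),
      detection_prob = 1),
    recorders = list(n_recorders = 30, activity_decay = 10000),
    corrections = list(
      list(method = "none"),
      list(method = "systematic", resolution = 2000),
      list(method = "systematic", resolution = 5000),
      list(method = "cluster", link_distance = 1000),
      list(method = "wdist", keep_fraction = 0.2),
      list(method = "buffer", radius = 5000),
      list(method = "bias_recorders", bandwidth = 5000),
      list(method = "bias_record_density")),
    sdm = list(n_background = 2000, lambda_grid = c(0, 0.01, 0.1, 1),
               quadratic = FALSE),
    zi = list(families = c("poisson", "negbin")),
    evaluation = list(k = 10),
    survey = list(n_random = 50, n_per_stratum = 10,
                  coverage_min = 0.2, coverage_max = 1,
                  detection_prob = 1,
                  accessibility_reject_prob = 4 / 90,
                  completion_prob = 52 / 90),
    calibration = list(clip_negative = FALSE)
  )
}

## cheap polynomial rolling hash of the serialized config, for artifact stamping
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full bias-correction and calibration pipeline
#'
#' Executes simulate -> aggregate -> correct-bias -> fit -> evaluate ->
#' survey -> calibrate on a synthetic landscape with known truth. Fitting and
#' evaluation never see the truth (true abundances and excess flags); the
#' simulated field survey observes the true abundances, exactly as real field
#' work observes the real world. Artifacts (cell table, records, per-model
#' comparison table, run metadata) are written to `output_dir` when given.
#'
#' @param config a config list as from [default_pipeline_config()], or the
#'   path to a YAML file with the same structure.
#' @param output_dir optional directory for artifacts; created if missing.
#' @return list with `landscape`, `truth` (oracle-only), `records`, `Y`,
#'   `zi_fits`, `zi_reports`, `pb_fits`, `survey` (selection + results),
#'   `comparison` (one row per model variant) and `meta`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed
  meta <- list(config_hash = config_hash(config), seed = seed,
               started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  ## --- simulate -------------------------------------------------------------
  lc <- config$landscape
  land <- generate_landscape(landscape_config(
    lc$n_rows, lc$n_cols, lc$cell_size, lc$n_numeric, lc$n_categorical,
    lc$n_levels, lc$correlation_length, seed = derive_seed(seed, "landscape")))
  tc <- config$truth
  truth <- truth_config(tc$beta_count, tc$theta, tc$gamma_zero,
                        tc$detection_prob %||% 1, seed = derive_seed(seed, "truth"))
  N <- simulate_true_abundance(land, truth)
  samp <- simulate_sampling(land, N, truth)
  records <- place_points(land, samp$Y, seed = derive_seed(seed, "place"))
  rec <- simulate_recorders(land, records, config$recorders$n_recorders,
                            config$recorders$activity_decay,
                            seed = derive_seed(seed, "recorders"))
  records <- rec$records

  ## --- aggregate ------------------------------------------------------------
  Y <- aggregate_to_counts(records, land)
  stopifnot(identical(Y, samp$Y))  # conservation: placement then re-binning

  ## --- zero-inflated models -------------------------------------------------
  X <- landscape_design(land)
  zi_fits <- list(); zi_reports <- list()
  k_cv <- config$evaluation$k %||% 10
  for (fam in config$zi$families) {
    rep_ <- if (k_cv >= 2) {
      evaluate_zi_cv(X, X, Y, fam, k = k_cv,
                     seed = derive_seed(seed, paste0("cv_", fam)))
    } else {
      ## cross-validation disabled: full-data fit only
      fit <- fit_zi(X, X, Y, fam)
      na_m <- list(auc_train = NA_real_, auc_test = NA_real_, rmsle = NA_real_,
                   correlation = c(pearson_r = NA_real_, spearman_rs = NA_real_),
                   predictions = rep(NA_real_, length(Y)))
      list(aicc = aicc(fit), metrics = list(count = na_m, whole = na_m),
           fit = fit, folds = NULL, failed = integer(0))
    }
    zi_fits[[fam]] <- rep_$fit
    zi_reports[[fam]] <- rep_
  }
  vuong <- if (all(c("negbin", "poisson") %in% names(zi_fits))) {
    vuong_test(zi_fits$poisson, zi_fits$negbin, correction = "aicc")
  }

  ## --- presence-background models per bias correction ----------------------
  covs <- setdiff(names(land$cells), c("cell_id", "row", "col", "x_min", "y_min"))
  cell_covs_at <- function(pts) {
    s <- land$config$cell_size
    idx <- (pmin(floor(pts$y / s), land$config$n_rows - 1)) * land$config$n_cols +
      pmin(floor(pts$x / s), land$config$n_cols - 1) + 1
    cbind(pts[, c("x", "y")], land$cells[idx, covs, drop = FALSE])
  }
  pb_fits <- list()
  for (corr in config$corrections) {
    nm <- corr$method
    if (!is.null(corr$resolution)) nm <- paste0(nm, "_", corr$resolution / 1000, "km")
    pres <- switch(corr$method,
      none = records,
      systematic = systematic_sample(records, corr$resolution,
                                     seed = derive_seed(seed, nm)),
      cluster = cluster_filter(records, corr$link_distance,
                               seed = derive_seed(seed, nm)),
      wdist = weighted_distance_sample(
        records, max(2, ceiling((corr$keep_fraction %||% 0.2) * nrow(records))),
        seed = derive_seed(seed, nm)),
      records)
    nbg <- config$sdm$n_background
    bg <- switch(corr$method,
      buffer = buffer_restricted_background(records, land, corr$radius, nbg,
                                            seed = derive_seed(seed, nm)),
      bias_recorders = weighted_background(
        kernel_density_surface(rec$homes, land, corr$bandwidth), land, nbg,
        seed = derive_seed(seed, nm)),
      bias_record_density = weighted_background(
        raster_bias_surface(Y, "ascending", provenance = "record_density"),
        land, nbg, seed = derive_seed(seed, nm)),
      random_background(land, nbg, seed = derive_seed(seed, nm)))
    p_df <- cell_covs_at(pres); b_df <- cell_covs_at(bg)
    cands <- lapply(config$sdm$lambda_grid, function(lam) {
      tryCatch(fit_presence_background(p_df, b_df, covs, lambda = lam,
                                       quadratic = isTRUE(config$sdm$quadratic)),
               error = function(e) NULL)
    })
    cands <- Filter(Negate(is.null), cands)
    stop_if(!length(cands), sprintf("stage fit-sdm (%s): no candidate converged", nm))
    pb_fits[[nm]] <- select_model_by_aicc(cands)
  }

  ## --- field survey ---------------------------------------------------------
  sv <- config$survey
  best_zi <- if ("negbin" %in% names(zi_fits)) zi_fits$negbin else zi_fits[[1]]
  zero_pred <- predict_zi(best_zi, land, type = "zero")
  squares <- select_squares(Y, zero_pred, sv$n_random, sv$n_per_stratum,
                            seed = derive_seed(seed, "select"))
  set.seed(derive_seed(seed, "access"))
  ## inaccessible squares are rejected and replaced by a fresh draw of the
  ## same kind (random or same stratum)
  inaccessible <- stats::runif(nrow(squares)) < (sv$accessibility_reject_prob %||% 0)
  if (any(inaccessible)) {
    for (i in which(inaccessible)) {
      st <- squares$stratum[i]
      pool <- if (st == "random") seq_along(Y) else {
        high <- zero_pred <= mean(zero_pred)
        stratum_of <- ifelse(Y > 0, ifelse(high, "ATI_high", "ATI_low"),
                             ifelse(high, "noATI_high", "noATI_low"))
        which(stratum_of == st)
      }
      pool <- setdiff(pool, squares$cell_id)
      if (length(pool)) squares$cell_id[i] <- pool[sample.int(length(pool), 1)]
    }
  }
  set.seed(derive_seed(seed, "complete"))
  completed <- stats::runif(nrow(squares)) < (sv$completion_prob %||% 1)
  if (!any(completed)) completed[1] <- TRUE
  surveyed <- squares[completed, , drop = FALSE]
  cell_area <- land$config$cell_size^2
  results <- simulate_field_survey(
    surveyed$cell_id, N[surveyed$cell_id],
    coverage_dist = function(n) stats::runif(n, sv$coverage_min, sv$coverage_max),
    detection_prob = sv$detection_prob %||% 1, cell_area = cell_area,
    seed = derive_seed(seed, "fieldwork"))

  ## --- calibration and comparison table ------------------------------------
  model_preds <- list()
  for (fam in names(zi_fits)) {
    model_preds[[paste0("zi_", fam, "_count")]] <-
      list(values = predict_zi(zi_fits[[fam]], land, "count"), type = "abundance")
    model_preds[[paste0("zi_", fam, "_whole")]] <-
      list(values = predict_zi(zi_fits[[fam]], land, "whole"), type = "abundance")
  }
  for (nm in names(pb_fits)) {
    model_preds[[paste0("sdm_", nm)]] <-
      list(values = predict_suitability(pb_fits[[nm]], land), type = "suitability")
  }
  rows <- lapply(names(model_preds), function(nm) {
    mp <- model_preds[[nm]]
    pred_surv <- mp$values[surveyed$cell_id]
    cal_d <- calibrate(pred_surv, results$density, metric = "density")
    tot_d <- national_total(cal_d, mp$values, cell_area = cell_area,
                            clip_negative = isTRUE(config$calibration$clip_negative))
    cal_a <- calibrate(pred_surv, results$observed_count, metric = "abundance")
    tot_a <- national_total(cal_a, mp$values,
                            clip_negative = isTRUE(config$calibration$clip_negative))
    f_auc <- tryCatch(field_auc(pred_surv, results$observed_count > 0,
                                threshold_reference = mp$values[squares$cell_id],
                                type = mp$type),
                      error = function(e) NA_real_)
    cors <- tryCatch(correlate(pred_surv, results$density),
                     error = function(e) c(pearson_r = NA_real_, spearman_rs = NA_real_))
    is_zi <- grepl("^zi_", nm)
    rep_ <- if (is_zi) zi_reports[[sub("^zi_([a-z]+)_.*$", "\\1", nm)]]
    mt <- if (is_zi) rep_$metrics[[sub("^zi_[a-z]+_", "", nm)]]
    data.frame(model = nm,
               aicc = if (is_zi) rep_$aicc else aicc(pb_fits[[sub("^sdm_", "", nm)]]),
               auc_train = if (is_zi) mt$auc_train else NA_real_,
               auc_test = if (is_zi) mt$auc_test else NA_real_,
               rmsle = if (is_zi) mt$rmsle else NA_real_,
               field_auc = f_auc,
               field_r = unname(cors["pearson_r"]),
               field_rs = unname(cors["spearman_rs"]),
               total_abundance = tot_a$total,
               total_density = tot_d$total)
  })
  comparison <- do.call(rbind, rows)

  out <- list(landscape = land,
              truth = list(N = N, pi = samp$pi, excess = samp$excess,
                           config = truth),
              records = records, recorder_homes = rec$homes, Y = Y,
              zi_fits = zi_fits, zi_reports = zi_reports, vuong = vuong,
              pb_fits = pb_fits,
              survey = list(squares = squares, completed = completed,
                            results = results),
              comparison = comparison, meta = meta)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(land$cells, Y = Y),
                     file.path(output_dir, "cells.csv"), row.names = FALSE)
    utils::write.csv(records, file.path(output_dir, "records.csv"), row.names = FALSE)
    utils::write.csv(comparison, file.path(output_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(surveyed, results[, -1]),
                     file.path(output_dir, "survey_results.csv"), row.names = FALSE)
    ## truth table: oracle material for tests/diagnostics only, never model input
    utils::write.csv(data.frame(cell_id = land$cells$cell_id, N = N,
                                pi = samp$pi, excess = samp$excess),
                     file.path(output_dir, "truth_oracle.csv"), row.names = FALSE)
    jsonlite::write_json(meta, file.path(output_dir, "run_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
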