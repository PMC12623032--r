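#' Serialize / restore a fitted risk model as versioned JSON
#'
#' The JSON stores everything needed for standalone prediction: coefficients,
#' their covariance, the design legend, the frozen standardization
#' (centers/scales), the model spec, and the Breslow baseline cumulative
#' hazard as a step list. Numbers are written at full precision so a reloaded
#' model reproduces in-memory predictions exactly.
#'
#' @param fitted A `cox_fit` with baseline.
#' @param path Output path.
#' @return `read_model_json()` returns a `cox_fit` equivalent for prediction.
#' @export
write_model_json <- function(fitted, path) {
  stopifnot(inherits(fitted, "cox_fit"))
  if (is.null(fitted$baseline)) {
    stop("model has no baseline; call breslow_baseline() first", call. = FALSE)
  }
  x <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("ipirisk")),
    coefficients = as.list(fitted$coefficients),
    vcov = list(names = colnames(fitted$vcov),
                values = as.vector(fitted$vcov)),
    legend = fitted$legend,
    std = list(centers = as.list(fitted$std$centers),
               scales = as.list(fitted$std$scales)),
    spec = list(individualized = fitted$spec$individualized,
                horizon = fitted$spec$horizon, ties = fitted$spec$ties,
                sds = as.list(fitted$spec$sds)),
    baseline = list(time = fitted$baseline$time,
                    hazard = fitted$baseline$hazard,
                    max_time = fitted$baseline$max_time),
    n = fitted$n, n_events = fitted$n_events,
    loglik = fitted$loglik
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$coefficients)
  vcov <- matrix(unlist(x$vcov$values), p, p,
                 dimnames = list(x$vcov$names, x$vcov$names))
  sds <- unlist(x$spec$sds)
  spec <- model_spec(individualized = x$spec$individualized,
                     horizon = x$spec$horizon, ties = x$spec$ties,
                     sd_age = sds[["age"]], sd_bmi = sds[["bmi"]],
                     sd_fpg = sds[["fpg"]], sd_hba1c = sds[["hba1c"]],
                     sd_logtrig = sds[["logtrig"]])
  bt <- as.numeric(x$baseline$time)
  bh <- as.numeric(x$baseline$hazard)
  structure(
    list(coefficients = unlist(x$coefficients), vcov = vcov,
         loglik = x$loglik, convergence = NULL, ties = x$spec$ties,
         legend = x$legend,
         std = list(centers = unlist(x$std$centers),
                    scales = unlist(x$std$scales)),
         spec = spec, n = x$n, n_events = x$n_events,
         baseline = list(time = bt, hazard = bh,
                         max_time = x$baseline$max_time,
                         H0 = stats::stepfun(bt, c(0, bh)))),
    class = "cox_fit"
  )
}

# Cheap stable content hash (polynomial rolling hash over the deparsed
# object) for provenance records.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance <- function(config = NULL, seed = NULL) {
  list(
    package = "ipirisk",
    package_version = as.character(utils::packageVersion("ipirisk")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = if (!is.null(config)) content_hash(config) else NULL
  )
}

#' Simulate and write trial + observational cohorts
#'
#' Writes `trial.csv` and `observational.csv` in the cohort schema plus a
#' `provenance.json` recording the package version, seeds, and a config
#' hash. The trial config's baseline hazard and arm effects are calibrated to
#' the marginal targets before simulation.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_trial,n_obs Cohort sizes.
#' @param seed Master seed; trial and observational cohorts use derived
#'   streams.
#' @param calibrate Calibrate the generating model to
#'   `targets` before simulating (default TRUE).
#' @param targets Marginal calibration targets: placebo 3-year risk and the
#'   lifestyle/metformin risk reductions.
#' @param trial_config,obs_config Optional full [sim_config()] overrides.
#' @return Invisibly, the paths written.
#' @export
cmd_simulate <- function(out_dir, n_trial = 2640, n_obs = 2104, seed = 1L,
                         calibrate = TRUE,
                         targets = c(placebo_risk = 0.227, lifestyle = 0.58,
                                     metformin = 0.31),
                         trial_config = NULL, obs_config = NULL) {
  if (n_trial < 1 || n_obs < 1) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_trial <- trial_config %||%
    dpp_sim_config(n = n_trial, seed = child_seed(seed, 11L))
  if (calibrate) {
    cfg_trial <- calibrate_generating_model(
      targets[["placebo_risk"]], targets[["lifestyle"]],
      targets[["metformin"]], cfg_trial)
  }
  cfg_obs <- obs_config %||%
    mesa_sim_config(n = n_obs, seed = child_seed(seed, 12L),
                    baseline_hazard = cfg_trial$baseline_hazard,
                    coefficients = cfg_trial$coefficients)
  trial <- simulate_trial_cohort(cfg_trial)
  obs <- simulate_observational_cohort(cfg_obs)
  paths <- c(trial = file.path(out_dir, "trial.csv"),
             observational = file.path(out_dir, "observational.csv"),
             provenance = file.path(out_dir, "provenance.json"))
  write_cohort_csv(trial, paths[["trial"]])
  write_cohort_csv(obs, paths[["observational"]])
  jsonlite::write_json(provenance(list(cfg_trial, cfg_obs), seed),
                       paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Develop the risk models from a trial cohort
#'
#' Runs the development pipeline in order: Gower k-NN imputation,
#' full-sample fits of the individualized and nonindividualized models, and
#' internal 10-fold cross-validation of each. Writes the individualized model
#' as `model.json` (sufficient for standalone prediction), the hazard-ratio
#' table as `hazard_ratios.csv`, and an `internal_validation.json` summary.
#'
#' @param cohort_csv Path to a trial cohort CSV.
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param k Cross-validation folds.
#' @param n_boot Bootstrap resamples.
#' @param ties Ties method.
#' @param horizon Prediction horizon (years).
#' @return Invisibly, a list with the fitted models and CV results.
#' @export
cmd_develop <- function(cohort_csv, out_dir, seed = 1L, k = 10L,
                        n_boot = 200L, ties = "efron", horizon = 3) {
  cohort <- read_cohort_csv(cohort_csv)
  if (!all(trial_arms() %in% cohort$arm)) {
    stop("development requires a trial cohort with all three arms",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_missing <- vapply(cohort[predictor_columns()],
                      function(x) sum(is.na(x)), integer(1))
  message("imputation counts per column: ",
          paste(names(n_missing), n_missing, sep = "=", collapse = ", "))
  complete <- impute_knn(cohort)
  spec_ind <- model_spec(individualized = TRUE, horizon = horizon,
                         ties = ties)
  spec_non <- model_spec(individualized = FALSE, horizon = horizon,
                         ties = ties)
  fit_ind <- fit_risk_model(complete, spec_ind)
  fit_non <- fit_risk_model(complete, spec_non)
  cv_ind <- crossvalidate(cohort, spec_ind, k = k, seed = seed,
                          n_boot = n_boot)
  cv_non <- crossvalidate(cohort, spec_non, k = k, seed = seed,
                          n_boot = n_boot)
  labels <- horizon_labels(cohort$time, cohort$event, horizon)
  nri_int <- nri(cv_ind$risks, cv_non$risks, labels, n_boot = n_boot,
                 seed = seed)
  write_model_json(fit_ind, file.path(out_dir, "model.json"))
  utils::write.csv(hazard_ratio_table(fit_ind),
                   file.path(out_dir, "hazard_ratios.csv"), row.names = FALSE)
  summary <- list(
    provenance = provenance(seed = seed),
    imputation_counts = as.list(n_missing),
    internal = list(
      individualized = list(
        c_statistic = cv_ind$report$c_statistic,
        mean_fold_c = cv_ind$mean_fold_c,
        brier = cv_ind$report$brier,
        net_benefit = cv_ind$report$net_benefit
      ),
      nonindividualized = list(
        c_statistic = cv_non$report$c_statistic,
        mean_fold_c = cv_non$mean_fold_c,
        brier = cv_non$report$brier,
        net_benefit = cv_non$report$net_benefit
      ),
      nri = nri_int[c("event_nri", "nonevent_nri", "overall_nri",
                      "lower", "upper")]
    )
  )
  jsonlite::write_json(summary, file.path(out_dir,
                                          "internal_validation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(fit_individualized = fit_ind,
                 fit_nonindividualized = fit_non,
                 cv_individualized = cv_ind, cv_nonindividualized = cv_non,
                 nri_internal = nri_int))
}

#' Externally validate a serialized model on a cohort
#'
#' Scores every subject at the horizon under their observed arm (`"none"`
#' maps to no intervention), computes the full external validation report,
#' counterfactual risks with optimal-strategy shares, and the three-policy
#' NNT evaluation, and writes machine-readable JSON plus human-readable
#' tables.
#'
#' @param model_json Path to a [write_model_json()] file.
#' @param cohort_csv Path to the validation cohort CSV.
#' @param out_dir Output directory.
#' @param seed RNG seed (bootstraps).
#' @param n_boot Bootstrap resamples.
#' @return Invisibly, a list with the report, counterfactuals, summary table,
#'   and policy evaluation.
#' @export
cmd_validate <- function(model_json, cohort_csv, out_dir, seed = 1L,
                         n_boot = 200L) {
  fitted <- read_model_json(model_json)
  cohort <- read_cohort_csv(cohort_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  complete <- impute_knn(cohort)
  horizon <- fitted$spec$horizon
  risks <- predict_risk(fitted, complete, complete$arm, horizon = horizon)
  report <- validation_report(
    risks, cohort$time, cohort$event, horizon = horizon,
    groupings = list(race_ethnicity = cohort$race_ethnicity,
                     sex = cohort$sex),
    seed = seed, n_boot = n_boot)
  cf <- counterfactual_risks(fitted, complete)
  strata <- summarize_by_optimal(cf)
  policies <- evaluate_policies(cf)
  utils::write.csv(strata, file.path(out_dir, "optimal_strategy_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(policies, file.path(out_dir, "policy_evaluation.csv"),
                   row.names = FALSE)
  out <- list(
    provenance = provenance(seed = seed),
    external = list(
      c_statistic = report$c_statistic,
      brier = report$brier,
      net_benefit = report$net_benefit,
      prevalence = report$prevalence
    ),
    optimal_shares = as.list(attr(policies, "optimal_shares")),
    policies = policies
  )
  jsonlite::write_json(out, file.path(out_dir, "external_validation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(report = report, counterfactuals = cf, strata = strata,
                 policies = policies, risks = risks))
}

#' Single-subject risk calculator
#'
#' Computes the 3-year predicted risk under lifestyle, metformin, and no
#' intervention for one clinical profile, and names the optimal strategy.
#' Race is not an accepted input by design. Values outside plausible clinical
#' ranges warn but are not rejected.
#'
#' @param model_json Path to a serialized model, or a `cox_fit`.
#' @param age Years.
#' @param sex `"male"` or `"female"`.
#' @param fpg Fasting plasma glucose, mg/dL.
#' @param hba1c Glycated hemoglobin, percent.
#' @param bmi Body mass index, kg/m2.
#' @param triglycerides mg/dL.
#' @return List: `risks` (named per-arm), `optimal_arm`.
#' @export
cmd_risk <- function(model_json, age, sex, fpg, hba1c, bmi, triglycerides) {
  fitted <- if (inherits(model_json, "cox_fit")) model_json else
    read_model_json(model_json)
  args <- list(age = age, sex = sex, fpg = fpg, hba1c = hba1c, bmi = bmi,
               triglycerides = triglycerides)
  missing_fields <- names(args)[vapply(args, function(x) {
    is.null(x) || length(x) != 1L || is.na(x)
  }, logical(1))]
  if (length(missing_fields)) {
    stop("missing required field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (!sex %in% c("male", "female")) {
    stop('`sex` must be "male" or "female"', call. = FALSE)
  }
  plaus <- list(age = c(18, 90), fpg = c(50, 200), hba1c = c(3.5, 9),
                bmi = c(15, 60), triglycerides = c(30, 1000))
  for (v in names(plaus)) {
    x <- args[[v]]
    if (x < plaus[[v]][1] || x > plaus[[v]][2]) {
      warning("`", v, "` = ", x, " is outside the plausible range [",
              plaus[[v]][1], ", ", plaus[[v]][2],
              "]; prediction is an extrapolation", call. = FALSE)
    }
  }
  subject <- data.frame(id = 1L, age = age, sex = sex, race_ethnicity = "na",
                        fpg = fpg, hba1c = hba1c, bmi = bmi,
                        triglycerides = triglycerides, arm = "none",
                        time = 1, event = 0L, stringsAsFactors = FALSE)
  cf <- counterfactual_risks(fitted, subject)
  list(
    risks = c(lifestyle = cf$risk_lifestyle, metformin = cf$risk_metformin,
              none = cf$risk_placebo),
    optimal_arm = cf$optimal_arm
  )
}
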