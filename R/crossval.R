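# Stratified fold assignment: events and nonevents are shuffled separately
# and dealt round-robin over one continuing sequence of folds, so total fold
# sizes differ by at most 1 while events stay balanced.
assign_folds <- function(events, k, seed) {
  n <- length(events)
  with_seed(seed, {
    ev <- sample(which(events == 1))
    ne <- sample(which(events == 0))
    fold <- integer(n)
    fold[c(ev, ne)] <- rep_len(seq_len(k), n)
    fold
  })
}

#' Internal validation by stratified k-fold cross-validation
#'
#' Folds are stratified by the event indicator and reproducible from the
#' seed. The whole pipeline runs inside each training fold to avoid leakage:
#' missing predictors are imputed within the training fold, the held-out fold
#' is imputed using training-fold donors, the model is fitted on the training
#' fold, and held-out subjects are scored at the horizon under their observed
#' arm. Out-of-fold predictions are pooled and all metrics computed once on
#' the pooled predictions; per-fold C-statistics are reported alongside.
#'
#' @param cohort Trial cohort (may contain missing predictors).
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param seed RNG seed for fold assignment and bootstraps.
#' @param groupings Named list of subgroup vectors for the report; defaults
#'   to race/ethnicity and sex from the cohort.
#' @param ... Passed to [validation_report()].
#' @return List: pooled out-of-fold `risks`, `report`, `fold` assignment,
#'   `fold_c` per-fold C-statistics, and their mean `mean_fold_c`.
#' @export
crossvalidate <- function(cohort, spec = model_spec(), k = 10L, seed = 1L,
                          groupings = NULL, ...) {
  validate_cohort(cohort, allow_missing = TRUE)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  n <- nrow(cohort)
  fold <- assign_folds(cohort$event, k, seed)
  if (min(tabulate(fold[cohort$event == 1], nbins = k)) < 1) {
    fold <- assign_folds(cohort$event, k, child_seed(seed, 1L))
    if (min(tabulate(fold[cohort$event == 1], nbins = k)) < 1) {
      stop("a fold has no events even after reshuffling; reduce k",
           call. = FALSE)
    }
  }
  risks <- rep(NA_real_, n)
  fold_c <- numeric(k)
  horizon <- spec$horizon
  for (f in seq_len(k)) {
    test <- fold == f
    train <- cohort[!test, , drop = FALSE]
    train <- impute_knn(train)
    heldout <- impute_knn(cohort[test, , drop = FALSE], donors = train)
    fitted <- fit_risk_model(train, spec)
    risks[test] <- predict_risk(fitted, heldout, heldout$arm,
                                horizon = horizon)
    lab_f <- horizon_labels(heldout$time, heldout$event, horizon)
    fold_c[f] <- concordance_value(risks[test], lab_f)
  }
  if (is.null(groupings)) {
    groupings <- list(race_ethnicity = cohort$race_ethnicity,
                      sex = cohort$sex)
  }
  report <- validation_report(risks, cohort$time, cohort$event,
                              horizon = horizon, groupings = groupings,
                              seed = seed, ...)
  list(risks = risks, report = report, fold = fold, fold_c = fold_c,
       mean_fold_c = mean(fold_c))
}

#' Compare the individualized and nonindividualized models
#'
#' Fits both model variants (with and without the arm-specific slopes for
#' age, FPG, and BMI) on the development cohort, validates each internally by
#' cross-validation and externally on the validation cohort, and scores the
#' individualized model against the nonindividualized standard with the NRI.
#' A comparison table collects discrimination per model, cohort, and
#' subgroup.
#'
#' @param cohort_dev Development (trial) cohort.
#' @param cohort_val External validation cohort (arm may be `"none"`).
#' @param seed RNG seed.
#' @param k Cross-validation folds.
#' @param horizon Prediction horizon in years.
#' @param ties Partial-likelihood ties method.
#' @param categories NRI risk categories.
#' @param n_boot Bootstrap resamples for CIs.
#' @param ... Passed to [validation_report()].
#' @return List with both fitted models, internal and external reports per
#'   model, internal and external NRI records, and the comparison table.
#' @export
compare_models <- function(cohort_dev, cohort_val, seed = 1L, k = 10L,
                           horizon = 3, ties = "efron",
                           categories = c(0.10, 0.20), n_boot = 1000L, ...) {
  validate_cohort(cohort_dev, allow_missing = TRUE)
  validate_cohort(cohort_val, allow_missing = TRUE)
  spec_ind <- model_spec(individualized = TRUE, horizon = horizon,
                         ties = ties)
  spec_non <- model_spec(individualized = FALSE, horizon = horizon,
                         ties = ties)

  cv_ind <- crossvalidate(cohort_dev, spec_ind, k = k, seed = seed,
                          n_boot = n_boot, ...)
  cv_non <- crossvalidate(cohort_dev, spec_non, k = k, seed = seed,
                          n_boot = n_boot, ...)
  labels_dev <- horizon_labels(cohort_dev$time, cohort_dev$event, horizon)
  nri_internal <- nri(cv_ind$risks, cv_non$risks, labels_dev,
                      categories = categories, n_boot = n_boot, seed = seed)

  dev_complete <- impute_knn(cohort_dev)
  fit_ind <- fit_risk_model(dev_complete, spec_ind)
  fit_non <- fit_risk_model(dev_complete, spec_non)

  val_complete <- impute_knn(cohort_val, donors = dev_complete)
  risks_val_ind <- predict_risk(fit_ind, val_complete, val_complete$arm,
                                horizon = horizon)
  risks_val_non <- predict_risk(fit_non, val_complete, val_complete$arm,
                                horizon = horizon)
  groupings_val <- list(race_ethnicity = cohort_val$race_ethnicity,
                        sex = cohort_val$sex)
  ext_ind <- validation_report(risks_val_ind, cohort_val$time,
                               cohort_val$event, horizon = horizon,
                               groupings = groupings_val, seed = seed,
                               n_boot = n_boot, ...)
  ext_non <- validation_report(risks_val_non, cohort_val$time,
                               cohort_val$event, horizon = horizon,
                               groupings = groupings_val, seed = seed,
                               n_boot = n_boot, ...)
  labels_val <- horizon_labels(cohort_val$time, cohort_val$event, horizon)
  nri_external <- nri(risks_val_ind, risks_val_non, labels_val,
                      categories = categories, n_boot = n_boot, seed = seed)

  comparison <- comparison_table(
    list(internal = list(individualized = cv_ind$report,
                         nonindividualized = cv_non$report),
         external = list(individualized = ext_ind,
                         nonindividualized = ext_non))
  )
  list(
    fit_individualized = fit_ind,
    fit_nonindividualized = fit_non,
    internal = list(individualized = cv_ind, nonindividualized = cv_non,
                    nri = nri_internal),
    external = list(individualized = ext_ind, nonindividualized = ext_non,
                    nri = nri_external),
    comparison = comparison
  )
}

comparison_table <- function(reports) {
  rows <- list()
  for (cohort in names(reports)) {
    for (model in names(reports[[cohort]])) {
      rep <- reports[[cohort]][[model]]
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, model = model, group = "overall",
        n = rep$n, c_statistic = rep$c_statistic$c_statistic,
        brier = rep$brier$brier, ipa = rep$brier$ipa,
        net_benefit = rep$net_benefit$net_benefit
      )
      for (g in names(rep$subgroup_c)) {
        sg <- rep$subgroup_c[[g]]
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = cohort, model = model,
          group = paste(g, sg$group, sep = ":"),
          n = sg$n, c_statistic = sg$c_statistic,
          brier = NA_real_, ipa = NA_real_, net_benefit = NA_real_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
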