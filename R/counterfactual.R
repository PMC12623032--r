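#' Counterfactual risks under each intervention scenario
#'
#' Computes each subject's predicted risk at the model horizon under all
#' three interventions ("what if" scenarios), holding covariates fixed and
#' switching the arm, and identifies the optimal preventive strategy as the
#' arm with the lowest predicted risk. Ties break toward lifestyle (the
#' first-line recommendation), then metformin. Predictions are a pure
#' function of covariates: the subject's observed arm plays no role.
#'
#' @param fitted A `cox_fit` with baseline (see [fit_risk_model()]).
#' @param cohort Cohort with complete predictors; arm may be `"none"`.
#' @param horizon Years (default: the model spec's horizon).
#' @return A `counterfactual_risks` data frame: `id`, `risk_lifestyle`,
#'   `risk_metformin`, `risk_placebo`, `optimal_arm`.
#' @export
counterfactual_risks <- function(fitted, cohort, horizon = NULL) {
  validate_cohort(cohort, allow_missing = FALSE)
  risks <- vapply(trial_arms(), function(a) {
    predict_risk(fitted, cohort, a, horizon = horizon)
  }, numeric(nrow(cohort)))
  if (nrow(cohort) == 1L) risks <- matrix(risks, nrow = 1,
                                          dimnames = list(NULL, trial_arms()))
  # argmin with ties toward lifestyle, then metformin (column order)
  opt <- trial_arms()[apply(risks, 1, which.min)]
  out <- data.frame(
    id = cohort$id,
    risk_lifestyle = risks[, "lifestyle"],
    risk_metformin = risks[, "metformin"],
    risk_placebo = risks[, "placebo"],
    optimal_arm = opt,
    stringsAsFactors = FALSE
  )
  class(out) <- c("counterfactual_risks", "data.frame")
  out
}

risk_column <- function(arm) paste0("risk_", arm)

#' Summarize counterfactual risk by optimal-strategy stratum
#'
#' For each optimal-arm stratum: subject count, percent of the sample, and
#' the mean (SD) predicted risk under each of the three scenarios, in
#' percent.
#'
#' @param risks A [counterfactual_risks()] result.
#' @return Data frame with one row per optimal-arm stratum.
#' @export
summarize_by_optimal <- function(risks) {
  stopifnot(nrow(risks) > 0)
  strata <- intersect(trial_arms(), unique(risks$optimal_arm))
  rows <- lapply(strata, function(s) {
    sub <- risks[risks$optimal_arm == s, ]
    row <- data.frame(optimal_arm = s, n = nrow(sub),
                      pct_sample = 100 * nrow(sub) / nrow(risks))
    for (a in trial_arms()) {
      r <- sub[[risk_column(a)]]
      row[[paste0("mean_risk_", a)]] <- 100 * mean(r)
      row[[paste0("sd_risk_", a)]] <- 100 * stats::sd(r)
    }
    row
  })
  do.call(rbind, rows)
}

#' Evaluate treatment policies by number needed to treat
#'
#' Three policies are compared: treat everyone with lifestyle, treat everyone
#' with metformin, and treat each subject with their model-predicted optimal
#' strategy. For each, the absolute risk reduction is the mean predicted
#' no-intervention (placebo) risk minus the mean risk under the policy's
#' assignments, and NNT is its reciprocal. An ARR of zero or less yields an
#' undefined NNT (`NA`), with the ARR still reported.
#'
#' @param risks A [counterfactual_risks()] result.
#' @return A `policy_evaluation` data frame (one row per policy: mean
#'   assigned risk, mean placebo risk, ARR, NNT) with the optimal-arm shares
#'   attached as attribute `"optimal_shares"`.
#' @export
evaluate_policies <- function(risks) {
  stopifnot(nrow(risks) > 0)
  assigned <- list(
    "all-lifestyle" = risks$risk_lifestyle,
    "all-metformin" = risks$risk_metformin,
    "model-guided" = ifelse(risks$optimal_arm == "lifestyle",
                            risks$risk_lifestyle,
                     ifelse(risks$optimal_arm == "metformin",
                            risks$risk_metformin, risks$risk_placebo))
  )
  mean_placebo <- mean(risks$risk_placebo)
  rows <- lapply(names(assigned), function(pol) {
    m <- mean(assigned[[pol]])
    arr <- mean_placebo - m
    data.frame(policy = pol, mean_assigned_risk = m,
               mean_placebo_risk = mean_placebo, arr = arr,
               nnt = if (arr > 0) 1 / arr else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  shares <- table(factor(risks$optimal_arm, levels = trial_arms()))
  attr(out, "optimal_shares") <- as.numeric(shares) / nrow(risks)
  names(attr(out, "optimal_shares")) <- trial_arms()
  class(out) <- c("policy_evaluation", "data.frame")
  out
}
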