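#' Map a generating coefficient set onto design-matrix columns
#'
#' Returns the generating per-SD log hazard ratios named like the columns of
#' the individualized design matrix, so fitted coefficients can be compared
#' term by term.
#'
#' @param config A [sim_config()] (typically calibrated).
#' @return Named numeric vector of generating log hazard ratios.
#' @export
generating_beta <- function(config) {
  coefs <- config$coefficients
  out <- c(
    hba1c = coefs$hba1c,
    logtrig = coefs$triglycerides,
    sex_female = coefs$sex_female,
    arm_lifestyle = unname(coefs$arm[["lifestyle"]]),
    arm_metformin = unname(coefs$arm[["metformin"]])
  )
  for (v in c("age", "bmi", "fpg")) {
    for (a in trial_arms()) {
      out[paste0(v, "_", a)] <- unname(coefs[[v]][[a]])
    }
  }
  out
}

#' Parameter-recovery simulation study
#'
#' Simulates replicate trials from the calibrated generating model and refits
#' the individualized Cox model to each, recording the fitted per-SD log
#' hazard ratios and their standard errors. The fitted model standardizes
#' with the same constants the generator uses, so coefficients are directly
#' comparable to the generating values.
#'
#' @param n_reps Number of replicate trials.
#' @param n Subjects per trial.
#' @param seed Master seed; each replicate uses a derived stream.
#' @param targets Calibration targets: marginal placebo 3-year risk and the
#'   lifestyle/metformin risk reductions.
#' @param ties Ties method for the fits.
#' @return List: `log_hr` and `se` (`n_reps x p` matrices), `generating`
#'   (named truth vector), and the calibrated `config`.
#' @export
recovery_study <- function(n_reps = 100L, n = 2640L, seed = 1L,
                           targets = c(placebo_risk = 0.227,
                                       lifestyle = 0.58, metformin = 0.31),
                           ties = "efron") {
  base <- dpp_sim_config(n = n, seed = seed)
  cal <- calibrate_generating_model(targets[[1]], targets[[2]], targets[[3]],
                                    base)
  gen <- generating_beta(cal)
  std <- cal$standardization
  spec <- model_spec(ties = ties,
                     sd_age = std$scales[["age"]],
                     sd_bmi = std$scales[["bmi"]],
                     sd_fpg = std$scales[["fpg"]],
                     sd_hba1c = std$scales[["hba1c"]],
                     sd_logtrig = std$scales[["logtrig"]])
  log_hr <- se <- matrix(NA_real_, n_reps, length(gen),
                         dimnames = list(NULL, names(gen)))
  for (r in seq_len(n_reps)) {
    cfg <- cal
    cfg$seed <- child_seed(seed, 1000L + r)
    co <- simulate_trial_cohort(cfg)
    fit <- fit_cox(build_design(co, spec))
    log_hr[r, ] <- fit$coefficients[colnames(log_hr)]
    se[r, ] <- sqrt(diag(fit$vcov))[colnames(se)]
  }
  list(log_hr = log_hr, se = se, generating = gen, config = cal)
}

#' Summarize a recovery study
#'
#' Geometric-mean fitted hazard ratios with Monte-Carlo standard errors,
#' generating values, and pooled empirical 95% Wald-CI coverage.
#'
#' @param study A [recovery_study()] result.
#' @return List: `table` (per coefficient: generating HR, geometric-mean
#'   fitted HR, MC SE of the mean log HR) and `coverage` pooled over all
#'   coefficients and replicates.
#' @export
summarize_recovery <- function(study) {
  mean_log <- colMeans(study$log_hr)
  mc_se <- apply(study$log_hr, 2, stats::sd) / sqrt(nrow(study$log_hr))
  covered <- abs(sweep(study$log_hr, 2, study$generating)) <=
    stats::qnorm(0.975) * study$se
  list(
    table = data.frame(
      term = names(mean_log),
      generating_hr = exp(study$generating),
      geomean_hr = exp(mean_log),
      mc_se_log = mc_se,
      z = (mean_log - study$generating) / mc_se
    ),
    coverage = mean(covered)
  )
}
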