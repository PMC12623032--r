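#' Simulate a randomized prevention-trial cohort
#'
#' Draws covariates from the config's marginals joined by a Gaussian copula,
#' allocates subjects to the three trial arms, and generates diabetes onset
#' times from a proportional-hazards model with constant (or Weibull)
#' baseline hazard via inverse-transform sampling,
#' `T = -log(U) / (h0 * exp(lp))`. Observed time is the minimum of the event
#' time, an independent exponential dropout time, and administrative
#' censoring; the event indicator is set accordingly. Output is bit-for-bit
#' reproducible from the config seed.
#'
#' @param config A [sim_config()]; allocation must put positive mass on each
#'   of `lifestyle`, `metformin`, `placebo` and none on `"none"`.
#' @return A cohort `data.frame` with columns
#'   `id, age, sex, race_ethnicity, fpg, hba1c, bmi, triglycerides, arm,
#'   time, event`.
#' @export
simulate_trial_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  alloc <- config$allocation
  if (any(alloc[trial_arms()] <= 0)) {
    stop("trial allocation must give positive mass to lifestyle, metformin, ",
         "and placebo", call. = FALSE)
  }
  if (alloc[["none"]] > 0) {
    stop('arm "none" is reserved for observational cohorts', call. = FALSE)
  }
  check_generating_coefficients(config$coefficients)
  simulate_cohort_impl(config)
}

#' Simulate an untreated observational cohort
#'
#' Like [simulate_trial_cohort()] but every subject is on arm `"none"` and the
#' event process uses the placebo (no-intervention) coefficient set, so the
#' observational population is governed by the same hazard model as untreated
#' trial subjects.
#'
#' @param config A [sim_config()] whose allocation mass is entirely on
#'   `"none"`.
#' @return A cohort `data.frame`; see [simulate_trial_cohort()].
#' @export
simulate_observational_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(config$allocation[["none"]] - 1) > 1e-8) {
    stop('observational allocation must be entirely on arm "none"',
         call. = FALSE)
  }
  check_generating_coefficients(config$coefficients)
  simulate_cohort_impl(config)
}

check_generating_coefficients <- function(coefs) {
  missing_terms <- character(0)
  for (nm in c("hba1c", "triglycerides", "sex_female")) {
    if (is.null(coefs[[nm]])) missing_terms <- c(missing_terms, nm)
  }
  for (nm in c("age", "fpg", "bmi")) {
    have <- names(coefs[[nm]])
    lack <- setdiff(trial_arms(), have)
    if (is.null(coefs[[nm]]) || length(lack)) {
      missing_terms <- c(missing_terms, paste0(nm, ":", lack))
    }
  }
  lack <- setdiff(c("lifestyle", "metformin"), names(coefs$arm))
  if (length(lack)) missing_terms <- c(missing_terms, paste0("arm:", lack))
  if (length(missing_terms)) {
    stop("generating coefficient set incomplete; absent terms: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  invisible(coefs)
}

# Draw one covariate from its (truncated) marginal given latent-normal z.
marginal_from_latent <- function(z, spec) {
  u <- stats::pnorm(z)
  if (spec$family == "normal") {
    pl <- stats::pnorm(spec$lower, spec$mean, spec$sd)
    pu <- stats::pnorm(spec$upper, spec$mean, spec$sd)
    stats::qnorm(pl + u * (pu - pl), spec$mean, spec$sd)
  } else {
    lo <- if (spec$lower <= 0) -Inf else log(spec$lower)
    hi <- if (is.infinite(spec$upper)) Inf else log(spec$upper)
    pl <- stats::pnorm(lo, spec$mean, spec$sd)
    pu <- stats::pnorm(hi, spec$mean, spec$sd)
    exp(stats::qnorm(pl + u * (pu - pl), spec$mean, spec$sd))
  }
}

# Generating linear predictor (log relative hazard) for given covariates/arm.
# Arm "none" is treated as no intervention: placebo slopes, zero arm effect.
generating_lp <- function(age, fpg, hba1c, bmi, triglycerides, sex, arm,
                          coefficients, standardization) {
  ctr <- standardization$centers
  scl <- standardization$scales
  z_age <- (age - ctr[["age"]]) / scl[["age"]]
  z_fpg <- (fpg - ctr[["fpg"]]) / scl[["fpg"]]
  z_hba <- (hba1c - ctr[["hba1c"]]) / scl[["hba1c"]]
  z_bmi <- (bmi - ctr[["bmi"]]) / scl[["bmi"]]
  z_trg <- (log(triglycerides) - ctr[["logtrig"]]) / scl[["logtrig"]]
  eff_arm <- ifelse(arm == "none", "placebo", arm)
  arm_main <- c(coefficients$arm[c("lifestyle", "metformin")], placebo = 0,
                none = 0)
  lp <- coefficients$hba1c * z_hba +
    coefficients$triglycerides * z_trg +
    coefficients$sex_female * (sex == "female") +
    coefficients$age[eff_arm] * z_age +
    coefficients$fpg[eff_arm] * z_fpg +
    coefficients$bmi[eff_arm] * z_bmi +
    arm_main[arm]
  unname(lp)
}

simulate_cohort_impl <- function(config) {
  n <- config$n
  specs <- config$covariates
  cov_names <- vapply(specs, `[[`, character(1), "name")
  R <- config$correlation[cov_names, cov_names]
  with_seed(config$seed, {
    L <- tryCatch(chol(R), error = function(e) {
      stop("correlation matrix is not positive definite: ",
           conditionMessage(e), call. = FALSE)
    })
    Z <- matrix(stats::rnorm(n * length(specs)), n) %*% L
    X <- lapply(seq_along(specs), function(j) {
      marginal_from_latent(Z[, j], specs[[j]])
    })
    names(X) <- cov_names
    sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    arm <- sample(all_arms(), n, replace = TRUE, prob = config$allocation)
    lp <- generating_lp(X$age, X$fpg, X$hba1c, X$bmi, X$triglycerides,
                        sex, arm, config$coefficients, config$standardization)
    u <- stats::runif(n)
    rate <- config$baseline_hazard * exp(lp)
    t_event <- if (config$baseline_shape == "exponential") {
      -log(u) / rate
    } else {
      (-log(u) / rate)^(1 / config$weibull_shape)
    }
    t_drop <- if (config$dropout_rate > 0) {
      stats::rexp(n, config$dropout_rate)
    } else {
      rep(Inf, n)
    }
    t_cens <- pmin(t_drop, config$admin_censor_years)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    cohort <- data.frame(
      id = seq_len(n),
      age = X$age, sex = sex, race_ethnicity = race,
      fpg = X$fpg, hba1c = X$hba1c, bmi = X$bmi,
      triglycerides = X$triglycerides,
      arm = arm, time = time, event = event,
      stringsAsFactors = FALSE
    )
    if (length(config$missingness)) {
      cohort <- inject_missingness(cohort, config$missingness,
                                   seed = child_seed(config$seed, 104L))
    }
    cohort
  })
}

#' Calibrate the simulator's baseline hazard and arm main effects
#'
#' Sets the baseline hazard rate so that the marginal 3-year risk in the
#' placebo arm hits `target_placebo_risk_3y`, then sets the lifestyle and
#' metformin arm main effects so their marginal 3-year risks are reduced by
#' the requested fractions relative to placebo. Each quantity is found by
#' univariate root-finding on the closed-form marginal risk
#' `mean(1 - exp(-horizon * h0 * exp(lp)))` over a large Monte-Carlo draw of
#' the covariate distribution (deterministic given the config seed).
#'
#' @param target_placebo_risk_3y Marginal placebo-arm risk at `horizon`, in
#'   (0, 1).
#' @param target_reduction_lifestyle,target_reduction_metformin Fractional
#'   risk reductions vs placebo, each in `[0, 1)` (e.g. 0.58 and 0.31).
#' @param config The [sim_config()] to calibrate.
#' @param horizon Risk horizon in years (default 3).
#' @param tol Absolute tolerance on the achieved marginal risks.
#' @param n_mc Monte-Carlo sample size for the marginal-risk integral.
#' @return The config with `baseline_hazard` and `coefficients$arm` replaced.
#' @export
calibrate_generating_model <- function(target_placebo_risk_3y,
                                       target_reduction_lifestyle,
                                       target_reduction_metformin,
                                       config,
                                       horizon = 3,
                                       tol = 0.005,
                                       n_mc = 100000L) {
  stopifnot(inherits(config, "sim_config"))
  if (target_placebo_risk_3y <= 0 || target_placebo_risk_3y >= 1) {
    stop("`target_placebo_risk_3y` must lie in (0, 1)", call. = FALSE)
  }
  for (r in c(target_reduction_lifestyle, target_reduction_metformin)) {
    if (r < 0 || r >= 1) {
      stop("arm risk reductions must lie in [0, 1)", call. = FALSE)
    }
  }
  check_generating_coefficients(config$coefficients)
  specs <- config$covariates
  cov_names <- vapply(specs, `[[`, character(1), "name")
  R <- config$correlation[cov_names, cov_names]
  draws <- with_seed(child_seed(config$seed, 271L), {
    Z <- matrix(stats::rnorm(n_mc * length(specs)), n_mc) %*% chol(R)
    X <- lapply(seq_along(specs), function(j) {
      marginal_from_latent(Z[, j], specs[[j]])
    })
    names(X) <- cov_names
    X$sex <- ifelse(stats::runif(n_mc) < config$p_female, "female", "male")
    X
  })
  lp_for_arm <- function(arm) {
    coefs <- config$coefficients
    coefs$arm <- c(lifestyle = 0, metformin = 0)  # main effects added later
    generating_lp(draws$age, draws$fpg, draws$hba1c, draws$bmi,
                  draws$triglycerides, draws$sex,
                  rep(arm, n_mc), coefs, config$standardization)
  }
  marginal_risk <- function(h0, lp, shift = 0) {
    ch <- if (config$baseline_shape == "exponential") h0 * horizon else
      h0 * horizon^config$weibull_shape
    mean(1 - exp(-ch * exp(lp + shift)))
  }
  lp_pl <- lp_for_arm("placebo")
  f <- function(log_h0) {
    marginal_risk(exp(log_h0), lp_pl) - target_placebo_risk_3y
  }
  root <- tryCatch(
    stats::uniroot(f, c(log(1e-8), log(50)), tol = 1e-12),
    error = function(e) {
      stop("baseline-hazard root-finding failed on bracket [1e-8, 50]: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  h0 <- exp(root$root)
  solve_arm <- function(arm, reduction) {
    lp_a <- lp_for_arm(arm)
    target <- (1 - reduction) * target_placebo_risk_3y
    g <- function(b) marginal_risk(h0, lp_a, b) - target
    r <- tryCatch(
      stats::uniroot(g, c(-20, 10), tol = 1e-12),
      error = function(e) {
        stop("arm-effect root-finding for ", arm,
             " failed on bracket [-20, 10]: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    r$root
  }
  arm_eff <- c(
    lifestyle = solve_arm("lifestyle", target_reduction_lifestyle),
    metformin = solve_arm("metformin", target_reduction_metformin)
  )
  achieved_pl <- marginal_risk(h0, lp_pl)
  if (abs(achieved_pl - target_placebo_risk_3y) > tol) {
    stop("calibration failed to reach placebo target within tolerance",
         call. = FALSE)
  }
  config$baseline_hazard <- h0
  config$coefficients$arm <- arm_eff
  config
}

#' Set predictor cells missing completely at random
#'
#' @param cohort A cohort `data.frame`.
#' @param fractions Named fractions in `[0, 1)` over predictor columns
#'   (`age, sex, fpg, hba1c, bmi, triglycerides`); outcome columns (`time`,
#'   `event`) and `arm` are rejected.
#' @param seed Integer RNG seed; the missingness mask is reproducible.
#' @return The cohort with the selected cells set to `NA`.
#' @export
inject_missingness <- function(cohort, fractions, seed) {
  validate_cohort(cohort, allow_missing = TRUE)
  check_missingness(fractions)
  with_seed(seed, {
    for (col in names(fractions)) {
      if (fractions[[col]] <= 0) next
      mask <- stats::runif(nrow(cohort)) < fractions[[col]]
      cohort[[col]][mask] <- NA
    }
    cohort
  })
}

#' Validate a cohort table against the schema
#'
#' Checks columns, arm and sex levels, positive follow-up times, a 0/1 event
#' indicator, and unique subject ids. Arm `"none"` may not be mixed with
#' randomized arms.
#'
#' @param cohort A `data.frame`.
#' @param allow_missing Whether `NA` predictor cells are permitted.
#' @return The cohort, invisibly; errors describe the offending field.
#' @export
validate_cohort <- function(cohort, allow_missing = FALSE) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$id)) {
    stop("cohort has duplicated subject ids", call. = FALSE)
  }
  if (anyNA(cohort$time) || any(cohort$time <= 0)) {
    stop("cohort `time` must be > 0 for all rows", call. = FALSE)
  }
  if (anyNA(cohort$event) || !all(cohort$event %in% c(0, 1))) {
    stop("cohort `event` must be 0 or 1", call. = FALSE)
  }
  if (anyNA(cohort$arm) || !all(cohort$arm %in% all_arms())) {
    stop("cohort `arm` must be one of ", paste(all_arms(), collapse = ", "),
         call. = FALSE)
  }
  if (any(cohort$arm == "none") && any(cohort$arm != "none")) {
    stop('arm "none" may not be mixed with randomized arms', call. = FALSE)
  }
  sex_ok <- cohort$sex %in% c("male", "female")
  if (!all(sex_ok | is.na(cohort$sex))) {
    stop('cohort `sex` must be "male" or "female"', call. = FALSE)
  }
  if (!allow_missing) {
    n_na <- vapply(cohort[predictor_columns()], function(x) sum(is.na(x)),
                   integer(1))
    if (any(n_na > 0)) {
      stop("cohort has missing predictor cells (impute first): ",
           paste(names(n_na)[n_na > 0], collapse = ", "), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The on-disk schema is the header
#' `id,age,sex,race_ethnicity,fpg,hba1c,bmi,triglycerides,arm,time,event`
#' with missing cells empty.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @param allow_missing Passed to [validate_cohort()].
#' @return `read_cohort_csv()` returns a validated cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path, allow_missing = TRUE) {
  validate_cohort(cohort, allow_missing = allow_missing)
  utils::write.csv(cohort[cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, allow_missing = TRUE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  validate_cohort(cohort, allow_missing = allow_missing)
  cohort
}
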