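#' Describe the marginal distribution of one simulated covariate
#'
#' A covariate spec holds the marginal distribution a cohort simulator draws
#' from: a (possibly truncated) normal on the native scale, or a lognormal for
#' strictly positive right-skewed quantities such as triglycerides.
#'
#' @param name Covariate name (one of `age`, `fpg`, `hba1c`, `bmi`,
#'   `triglycerides`).
#' @param mean,sd Location and scale. For `family = "normal"` these are the
#'   native-unit mean and SD. For `family = "lognormal"` they are the log-scale
#'   location and scale (`meanlog`, `sdlog`); published median/IQR summaries
#'   map to `meanlog = log(median)` and
#'   `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#' @param family `"normal"` or `"lognormal"`.
#' @param lower,upper Truncation bounds in native units. Defaults are wide
#'   guard rails against physiologically impossible values, not eligibility
#'   windows.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, mean, sd, family = c("normal", "lognormal"),
                           lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  if (!is.numeric(sd) || sd <= 0) {
    stop("covariate `", name, "`: sd must be > 0", call. = FALSE)
  }
  if (lower >= upper) {
    stop("covariate `", name, "`: truncation bounds must satisfy lower < upper",
         call. = FALSE)
  }
  if (family == "lognormal" && lower < 0) lower <- 0
  structure(
    list(name = name, mean = mean, sd = sd, family = family,
         lower = lower, upper = upper),
    class = "covariate_spec"
  )
}

#' @rdname covariate_spec
#' @details `dpp_covariate_specs()` and `mesa_covariate_specs()` return the
#'   default marginals of the trial-like (prediabetic, mean age 51, BMI 34,
#'   FPG 106) and observational-like (older, leaner: age 64, BMI 30, FPG 101)
#'   populations. Triglycerides are lognormal matched to the published
#'   median/IQR (144 (101, 205) and 118 (84, 167) mg/dL respectively).
#' @export
dpp_covariate_specs <- function() {
  iqr_sdlog <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))
  list(
    covariate_spec("age", 51, 11, lower = 16, upper = 100),
    covariate_spec("fpg", 106, 7, lower = 60, upper = 180),
    covariate_spec("hba1c", 5.78, 0.40, lower = 3.5, upper = 9),
    covariate_spec("bmi", 34, 7, lower = 12, upper = 75),
    covariate_spec("triglycerides", log(144), iqr_sdlog(101, 205),
                   family = "lognormal", lower = 20, upper = 2000)
  )
}

#' @rdname covariate_spec
#' @export
mesa_covariate_specs <- function() {
  iqr_sdlog <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))
  list(
    covariate_spec("age", 64, 10, lower = 16, upper = 100),
    covariate_spec("fpg", 101, 10, lower = 60, upper = 180),
    covariate_spec("hba1c", 5.75, 0.30, lower = 3.5, upper = 9),
    covariate_spec("bmi", 30, 6, lower = 12, upper = 75),
    covariate_spec("triglycerides", log(118), iqr_sdlog(84, 167),
                   family = "lognormal", lower = 20, upper = 2000)
  )
}

#' Generating hazard coefficients for the trial-like simulator
#'
#' Per-SD log hazard ratios used as the simulator's generating truth. The
#' continuous slopes are interpreted per 1 SD on the standardization scale of
#' the config (`age` per 10.6 years, `bmi` per 6.6 kg/m2, `fpg` per
#' 6.7 mg/dL, `hba1c` per 0.40 percentage points, triglycerides per 1 SD of
#' the natural log). Age, FPG, and BMI carry one slope per trial arm
#' ("conditional on treatment"); HbA1c, triglycerides, and sex are shared.
#' Arm main effects default to zero and are normally set by
#' [calibrate_generating_model()].
#'
#' @return A named list of generating coefficients.
#' @export
dpp_generating_coefficients <- function() {
  list(
    hba1c = log(1.21),
    triglycerides = log(1.24),
    sex_female = log(1.16),
    age = c(lifestyle = log(0.95), metformin = log(1.02), placebo = log(0.97)),
    bmi = c(lifestyle = log(1.37), metformin = log(0.89), placebo = log(1.04)),
    fpg = c(lifestyle = log(1.47), metformin = log(1.53), placebo = log(1.90)),
    arm = c(lifestyle = 0, metformin = 0)
  )
}

#' Default covariate correlation and standardization
#'
#' `default_correlation()` returns the Gaussian-copula correlation matrix
#' used by the default configs: 0.2 between FPG-HbA1c, FPG-BMI, and
#' BMI-triglycerides, 0 elsewhere (the source cohorts publish only marginal
#' summaries, so these correlations are a documented free knob).
#' `default_standardization()` returns the fixed centers and per-SD scales
#' of the generating hazard model (age 10.6 years, FPG 6.7 mg/dL, BMI
#' 6.6 kg/m2, HbA1c 0.40 points, log-triglycerides 0.52).
#'
#' @return A correlation matrix, or a list with `centers` and `scales`.
#' @export
default_correlation <- function() {
  vars <- c("age", "fpg", "hba1c", "bmi", "triglycerides")
  R <- diag(5)
  dimnames(R) <- list(vars, vars)
  R["fpg", "hba1c"] <- R["hba1c", "fpg"] <- 0.2
  R["fpg", "bmi"] <- R["bmi", "fpg"] <- 0.2
  R["bmi", "triglycerides"] <- R["triglycerides", "bmi"] <- 0.2
  R
}

#' @rdname default_correlation
#' @export
default_standardization <- function() {
  list(
    centers = c(age = 51, fpg = 106, hba1c = 5.78, bmi = 34,
                logtrig = log(144)),
    scales = c(age = 10.6, fpg = 6.7, hba1c = 0.40, bmi = 6.6,
               logtrig = log(205 / 101) / (2 * stats::qnorm(0.75)))
  )
}

#' Assemble a cohort simulation configuration
#'
#' Bundles everything that determines a simulated cohort: sample size, arm
#' allocation, covariate marginals joined by a Gaussian copula, the generating
#' proportional-hazards coefficients, the baseline hazard, censoring, and
#' missingness. Identical config + seed reproduces the cohort bit for bit.
#'
#' @param n Number of subjects.
#' @param allocation Named probabilities over
#'   `c("lifestyle","metformin","placebo","none")`; must sum to 1.
#' @param covariates List of [covariate_spec()] objects.
#' @param correlation Covariate correlation matrix on the Gaussian-copula
#'   scale (symmetric positive definite, unit diagonal), rows/columns named
#'   after the covariates.
#' @param coefficients Generating coefficient list, see
#'   [dpp_generating_coefficients()].
#' @param standardization List with `centers` and `scales` used to turn native
#'   covariates into the z-scores the generating coefficients multiply. Fixed
#'   across cohorts so trial-like and observational-like populations share one
#'   hazard model.
#' @param baseline_hazard Constant baseline hazard rate (events/year), > 0.
#' @param baseline_shape `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Shape parameter when `baseline_shape = "weibull"`
#'   (cumulative hazard `h0 * t^shape`); 1 recovers the exponential.
#' @param admin_censor_years Administrative censoring time (years).
#' @param dropout_rate Independent exponential dropout hazard (per year).
#' @param p_female Probability of female sex.
#' @param race_probs Named multinomial probabilities for the 4-level
#'   race/ethnicity label (evaluation-only; never a model predictor).
#' @param missingness Named per-column MCAR fractions in `[0, 1)` applied by
#'   the simulators via [inject_missingness()]; empty by default.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n,
                       allocation,
                       covariates = dpp_covariate_specs(),
                       correlation = default_correlation(),
                       coefficients = dpp_generating_coefficients(),
                       standardization = default_standardization(),
                       baseline_hazard = 0.0857,
                       baseline_shape = c("exponential", "weibull"),
                       weibull_shape = 1,
                       admin_censor_years = 3.2,
                       dropout_rate = 0.02,
                       p_female = 0.67,
                       race_probs = c(white = 0.62, black = 0.16,
                                      hispanic = 0.17, other = 0.05),
                       missingness = numeric(0),
                       seed = 1L) {
  baseline_shape <- match.arg(baseline_shape)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (is.null(names(allocation)) || !setequal(names(allocation), all_arms())) {
    stop("`allocation` must be named over ",
         paste(all_arms(), collapse = ", "), call. = FALSE)
  }
  allocation <- allocation[all_arms()]
  if (any(allocation < 0) || abs(sum(allocation) - 1) > 1e-8) {
    stop("`allocation` probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  }
  cov_names <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) {
    stop("duplicate covariate names in `covariates`", call. = FALSE)
  }
  check_correlation(correlation, cov_names)
  if (baseline_hazard <= 0) {
    stop("`baseline_hazard` must be > 0", call. = FALSE)
  }
  if (weibull_shape <= 0) stop("`weibull_shape` must be > 0", call. = FALSE)
  if (admin_censor_years <= 0) {
    stop("`admin_censor_years` must be > 0", call. = FALSE)
  }
  if (dropout_rate < 0) stop("`dropout_rate` must be >= 0", call. = FALSE)
  if (p_female < 0 || p_female > 1) {
    stop("`p_female` must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(race_probs) - 1) > 1e-8 || any(race_probs < 0)) {
    stop("`race_probs` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(missingness)) check_missingness(missingness)
  structure(
    list(schema_version = "1",
         n = as.integer(n),
         allocation = allocation,
         covariates = covariates,
         correlation = correlation,
         coefficients = coefficients,
         standardization = standardization,
         baseline_hazard = baseline_hazard,
         baseline_shape = baseline_shape,
         weibull_shape = weibull_shape,
         admin_censor_years = admin_censor_years,
         dropout_rate = dropout_rate,
         p_female = p_female,
         race_probs = race_probs,
         missingness = missingness,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

check_correlation <- function(R, cov_names) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(R)) || !setequal(rownames(R), cov_names)) {
    stop("correlation matrix rows/columns must be named after the covariates: ",
         paste(cov_names, collapse = ", "), call. = FALSE)
  }
  R <- R[cov_names, cov_names]
  if (max(abs(R - t(R))) > 1e-10) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-10) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop("correlation matrix is not positive definite ",
         "(smallest eigenvalue ", format(ev), ")", call. = FALSE)
  }
  invisible(R)
}

check_missingness <- function(fractions) {
  bad <- setdiff(names(fractions), predictor_columns())
  if (length(bad)) {
    stop("missingness fractions allowed only on predictor columns (",
         paste(predictor_columns(), collapse = ", "), "); offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(fractions < 0 | fractions >= 1)) {
    stop("missingness fractions must lie in [0, 1)", call. = FALSE)
  }
  invisible(fractions)
}

#' Default trial-like and observational-like configurations
#'
#' `dpp_sim_config()` emulates a three-arm diabetes-prevention trial
#' (equal allocation to lifestyle, metformin, placebo; 67% female).
#' `mesa_sim_config()` emulates an older, leaner untreated cohort (all
#' subjects on arm `"none"`, 50% female) sharing the trial's generating hazard
#' model with placebo slopes.
#'
#' @param n Number of subjects.
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
dpp_sim_config <- function(n = 2640, seed = 1L, ...) {
  sim_config(
    n = n,
    allocation = c(lifestyle = 1 / 3, metformin = 1 / 3, placebo = 1 / 3,
                   none = 0),
    seed = seed,
    ...
  )
}

#' @rdname dpp_sim_config
#' @export
mesa_sim_config <- function(n = 2104, seed = 2L, ...) {
  args <- list(...)
  defaults <- list(
    covariates = mesa_covariate_specs(),
    p_female = 0.50,
    race_probs = c(white = 0.32, black = 0.27, hispanic = 0.24, other = 0.17)
  )
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(sim_config, c(
    list(n = n,
         allocation = c(lifestyle = 0, metformin = 0, placebo = 0, none = 1),
         seed = seed),
    args
  ))
}

#' Read / write a simulation configuration
#'
#' Configs serialize to JSON (or YAML when the file extension is `.yaml`/
#' `.yml` and the yaml package is available) with an explicit seed and schema
#' version.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$covariates <- lapply(x$covariates, unclass)
  x$correlation <- list(variables = rownames(config$correlation),
                        values = as.vector(config$correlation))
  # named numeric vectors must serialize as objects, not bare arrays
  x$allocation <- as.list(x$allocation)
  x$race_probs <- as.list(x$race_probs)
  x$missingness <- as.list(x$missingness)
  x$standardization <- lapply(x$standardization, as.list)
  x$coefficients <- lapply(x$coefficients, function(v) {
    if (length(v) > 1L || !is.null(names(v))) as.list(v) else v
  })
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vars <- x$correlation$variables
  R <- matrix(unlist(x$correlation$values), length(vars), length(vars),
              dimnames = list(vars, vars))
  covs <- lapply(seq_len(nrow(x$covariates) %||% length(x$covariates)),
                 function(i) {
    cv <- if (is.data.frame(x$covariates)) as.list(x$covariates[i, ]) else
      x$covariates[[i]]
    covariate_spec(cv$name, cv$mean, cv$sd, cv$family,
                   cv$lower %||% -Inf, cv$upper %||% Inf)
  })
  coefs <- x$coefficients
  for (nm in c("age", "bmi", "fpg", "arm")) {
    coefs[[nm]] <- unlist(coefs[[nm]])
  }
  sim_config(
    n = x$n,
    allocation = unlist(x$allocation),
    covariates = covs,
    correlation = R,
    coefficients = coefs,
    standardization = list(centers = unlist(x$standardization$centers),
                           scales = unlist(x$standardization$scales)),
    baseline_hazard = x$baseline_hazard,
    baseline_shape = x$baseline_shape,
    weibull_shape = x$weibull_shape,
    admin_censor_years = x$admin_censor_years,
    dropout_rate = x$dropout_rate,
    p_female = x$p_female,
    race_probs = unlist(x$race_probs),
    missingness = if (length(x$missingness)) unlist(x$missingness) else
      numeric(0),
    seed = x$seed
  )
}
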