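#' Specify the risk-model structure
#'
#' The individualized model carries main effects for HbA1c, log-triglycerides,
#' sex, and arm, plus one slope per arm for age, FPG, and BMI ("conditional on
#' treatment" parameterization: disjoint arm-specific columns, which is a
#' linear reparameterization of reference-plus-interaction coding). The
#' nonindividualized variant shares a single slope for age, FPG, and BMI
#' across arms. Continuous predictors are centered at the fitting cohort's
#' means and scaled by the spec's SD constants so hazard ratios read per 1 SD;
#' the age/BMI/FPG constants default to the published per-SD units
#' (10.6 years, 6.6 kg/m2, 6.7 mg/dL), and `NA` for the HbA1c and
#' log-triglyceride SDs means "use the fitting cohort's SD".
#'
#' @param individualized Include arm-specific slopes for age, FPG, BMI?
#' @param horizon Prediction horizon in years (default 3).
#' @param ties Partial-likelihood ties method, `"efron"` or `"breslow"`.
#' @param sd_age,sd_bmi,sd_fpg,sd_hba1c,sd_logtrig Standardization constants
#'   in native units (log scale for triglycerides); `NA` = cohort SD.
#' @return A `model_spec` list. Reference levels are sex = male,
#'   arm = placebo.
#' @export
model_spec <- function(individualized = TRUE,
                       horizon = 3,
                       ties = c("efron", "breslow"),
                       sd_age = 10.6, sd_bmi = 6.6, sd_fpg = 6.7,
                       sd_hba1c = NA_real_, sd_logtrig = NA_real_) {
  ties <- match.arg(ties)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  for (s in c(sd_age, sd_bmi, sd_fpg)) {
    if (!is.na(s) && s <= 0) {
      stop("standardization constants must be > 0", call. = FALSE)
    }
  }
  structure(
    list(individualized = isTRUE(individualized), horizon = horizon,
         ties = ties,
         sds = c(age = sd_age, bmi = sd_bmi, fpg = sd_fpg,
                 hba1c = sd_hba1c, logtrig = sd_logtrig)),
    class = "model_spec"
  )
}

continuous_predictors <- function() c("age", "fpg", "hba1c", "bmi")

# Resolve centers (cohort means) and scales (spec constants, cohort SD where
# the spec leaves them NA) from a complete cohort.
resolve_standardization <- function(cohort, spec) {
  logtrig <- log(cohort$triglycerides)
  centers <- c(age = mean(cohort$age), fpg = mean(cohort$fpg),
               hba1c = mean(cohort$hba1c), bmi = mean(cohort$bmi),
               logtrig = mean(logtrig))
  sds <- spec$sds
  scales <- c(
    age = sds[["age"]], fpg = sds[["fpg"]], bmi = sds[["bmi"]],
    hba1c = if (is.na(sds[["hba1c"]])) stats::sd(cohort$hba1c) else
      sds[["hba1c"]],
    logtrig = if (is.na(sds[["logtrig"]])) stats::sd(logtrig) else
      sds[["logtrig"]]
  )
  for (v in names(scales)) {
    if (is.na(scales[[v]]) || scales[[v]] <= 0) {
      stop("zero-variance or invalid standardization for predictor `", v, "`",
           call. = FALSE)
    }
  }
  list(centers = centers, scales = scales)
}

# Rows of the design matrix for given covariates and (possibly counterfactual)
# arm, using frozen centers/scales. Arm "none" maps to the no-intervention
# (placebo) reference.
design_rows <- function(df, arm, std, spec) {
  n <- nrow(df)
  if (length(arm) == 1L) arm <- rep(arm, n)
  unknown <- setdiff(unique(arm), all_arms())
  if (length(unknown)) {
    stop("unknown arm level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  arm_eff <- ifelse(arm == "none", "placebo", arm)
  z <- function(x, v) (x - std$centers[[v]]) / std$scales[[v]]
  z_age <- z(df$age, "age")
  z_fpg <- z(df$fpg, "fpg")
  z_hba <- z(df$hba1c, "hba1c")
  z_bmi <- z(df$bmi, "bmi")
  z_trg <- z(log(df$triglycerides), "logtrig")
  cols <- list(
    hba1c = z_hba,
    logtrig = z_trg,
    sex_female = as.numeric(df$sex == "female"),
    arm_lifestyle = as.numeric(arm_eff == "lifestyle"),
    arm_metformin = as.numeric(arm_eff == "metformin")
  )
  if (spec$individualized) {
    for (v in c("age", "bmi", "fpg")) {
      zv <- switch(v, age = z_age, bmi = z_bmi, fpg = z_fpg)
      for (a in trial_arms()) {
        cols[[paste0(v, "_", a)]] <- zv * (arm_eff == a)
      }
    }
  } else {
    cols$age <- z_age
    cols$bmi <- z_bmi
    cols$fpg <- z_fpg
  }
  do.call(cbind, cols)
}

design_legend <- function(spec, std) {
  arm_label <- c(lifestyle = "Lifestyle", metformin = "Metformin",
                 placebo = "Placebo")
  rows <- list(
    data.frame(column = "hba1c", variable = "hba1c", arm = NA_character_,
               label = sprintf("Glycated hemoglobin, per %.2f%%",
                               std$scales[["hba1c"]])),
    data.frame(column = "logtrig", variable = "triglycerides",
               arm = NA_character_,
               label = "Triglycerides, per 1 SD of log"),
    data.frame(column = "sex_female", variable = "sex", arm = NA_character_,
               label = "Sex: Female (vs Male)"),
    data.frame(column = "arm_lifestyle", variable = "arm",
               arm = "lifestyle", label = "Arm: Lifestyle (vs Placebo)"),
    data.frame(column = "arm_metformin", variable = "arm",
               arm = "metformin", label = "Arm: Metformin (vs Placebo)")
  )
  unit <- c(age = "years", bmi = "kg/m2", fpg = "mg/dL")
  vlab <- c(age = "Age", bmi = "Body mass index", fpg = "Fasting glucose")
  for (v in c("age", "bmi", "fpg")) {
    if (spec$individualized) {
      for (a in trial_arms()) {
        rows[[length(rows) + 1L]] <- data.frame(
          column = paste0(v, "_", a), variable = v, arm = a,
          label = sprintf("%s, per %.1f %s, conditional on treatment: %s",
                          vlab[[v]], std$scales[[v]], unit[[v]],
                          arm_label[[a]]))
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        column = v, variable = v, arm = NA_character_,
        label = sprintf("%s, per %.1f %s", vlab[[v]], std$scales[[v]],
                        unit[[v]]))
    }
  }
  do.call(rbind, rows)
}

#' Build the model design matrix from a cohort
#'
#' @param cohort Complete (post-imputation) cohort containing the three trial
#'   arms.
#' @param spec A [model_spec()].
#' @return A `cox_design` list: design matrix `X` (one column per
#'   coefficient, continuous predictors centered and per-SD scaled), `legend`
#'   mapping columns to report rows, frozen `std` (centers/scales), `times`,
#'   `events`, and the spec.
#' @export
build_design <- function(cohort, spec = model_spec()) {
  validate_cohort(cohort, allow_missing = FALSE)
  if (any(cohort$arm == "none")) {
    stop("model fitting requires randomized trial arms, found arm \"none\"",
         call. = FALSE)
  }
  for (v in c(continuous_predictors(), "triglycerides")) {
    if (stats::sd(cohort[[v]]) <= 0) {
      stop("zero-variance predictor: ", v, call. = FALSE)
    }
  }
  std <- resolve_standardization(cohort, spec)
  X <- design_rows(cohort, cohort$arm, std, spec)
  structure(
    list(X = X, legend = design_legend(spec, std), std = std, spec = spec,
         times = cohort$time, events = cohort$event),
    class = "cox_design"
  )
}

# ---- partial likelihood machinery -----------------------------------------

rev_cumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x[nrow(x):1, , drop = FALSE], 2, cumsum)[nrow(x):1, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

# Log partial likelihood, score, and observed information at beta.
# X/times/events must already be sorted by ascending time.
cox_derivatives <- function(beta, X, times, events, ties, pair_a, pair_b) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)  # guard exp overflow; partial likelihood is shift-free
  w <- exp(eta)
  wX <- w * X
  X2 <- X[, pair_a, drop = FALSE] * X[, pair_b, drop = FALSE]
  wX2 <- w * X2
  S0 <- rev_cumsum(w)
  S1 <- rev_cumsum(wX)
  S2 <- rev_cumsum(wX2)

  ev_idx <- which(events == 1)
  ut <- unique(times[ev_idx])
  grp <- match(times[ev_idx], ut)
  d <- tabulate(grp, nbins = length(ut))
  i0 <- findInterval(ut, times, left.open = TRUE) + 1L

  s0_j <- S0[i0]
  E <- S1[i0, , drop = FALSE] / s0_j
  S2bar <- S2[i0, , drop = FALSE] / s0_j

  loglik <- sum(eta[ev_idx]) - sum(d * log(s0_j))
  U <- colSums(X[ev_idx, , drop = FALSE]) - colSums(d * E)
  ivec <- colSums(d * S2bar) -
    colSums(d * (E[, pair_a, drop = FALSE] * E[, pair_b, drop = FALSE]))

  if (ties == "efron" && any(d > 1)) {
    for (j in which(d > 1)) {
      ids <- ev_idx[grp == j]
      dj <- d[j]
      s0D <- sum(w[ids])
      s1D <- colSums(wX[ids, , drop = FALSE])
      s2D <- colSums(wX2[ids, , drop = FALSE])
      frac <- (seq_len(dj) - 1) / dj
      # remove the Breslow contribution of this group
      loglik <- loglik + dj * log(s0_j[j])
      U <- U + dj * E[j, ]
      ivec <- ivec - dj * (S2bar[j, ] - E[j, pair_a] * E[j, pair_b])
      for (f in frac) {
        den <- s0_j[j] - f * s0D
        e_l <- (S1[i0[j], ] - f * s1D) / den
        s2_l <- (S2[i0[j], ] - f * s2D) / den
        loglik <- loglik - log(den)
        U <- U - e_l
        ivec <- ivec + (s2_l - e_l[pair_a] * e_l[pair_b])
      }
    }
  }
  info <- matrix(0, p, p)
  info[cbind(pair_a, pair_b)] <- ivec
  info[cbind(pair_b, pair_a)] <- ivec
  list(loglik = loglik, U = U, info = info)
}

#' Fit the Cox model by Newton-Raphson on the partial likelihood
#'
#' Maximizes the Cox partial likelihood with Efron (default) or Breslow ties
#' handling, using Newton-Raphson with step-halving. Convergence is declared
#' when the maximum absolute score falls below `1e-8` or the relative
#' log-likelihood change falls below `1e-10`. The coefficient covariance is
#' the inverse observed information. Coefficients diverging with a
#' nondecreasing likelihood (monotone likelihood) are flagged by name.
#'
#' @param design A [build_design()] result, or a plain numeric matrix.
#' @param times,events Follow-up times and 0/1 event indicators; taken from
#'   the design when it carries them.
#' @param ties `"efron"` or `"breslow"`; defaults to the design's spec.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return A `cox_fit` list: `coefficients`, `vcov`, `loglik`,
#'   `convergence` (iterations, final gradient norm), `legend`, `std`,
#'   `spec`, and sorted fitting data for baseline estimation.
#' @export
fit_cox <- function(design, times = NULL, events = NULL, ties = NULL,
                    max_iter = 50L) {
  if (inherits(design, "cox_design")) {
    X <- design$X
    times <- times %||% design$times
    events <- events %||% design$events
    ties <- ties %||% design$spec$ties
    legend <- design$legend
    std <- design$std
    spec <- design$spec
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    ties <- ties %||% "efron"
    legend <- data.frame(column = colnames(X), variable = colnames(X),
                         arm = NA_character_, label = colnames(X))
    std <- NULL
    spec <- NULL
  }
  ties <- match.arg(ties, c("efron", "breslow"))
  if (anyNA(X) || anyNA(times) || anyNA(events)) {
    stop("design, times, and events must be complete", call. = FALSE)
  }
  if (sum(events) < 1) stop("at least one event is required", call. = FALSE)

  ord <- order(times)
  Xs <- X[ord, , drop = FALSE]
  ts <- times[ord]
  es <- events[ord]
  p <- ncol(X)
  # (pair_a, pair_b) enumerates the a <= b index pairs of the information
  pair_a <- unlist(lapply(seq_len(p), seq_len))
  pair_b <- rep(seq_len(p), times = seq_len(p))

  beta <- rep(0, p)
  der <- cox_derivatives(beta, Xs, ts, es, ties, pair_a, pair_b)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(
      solve(der$info, der$U),
      error = function(e) {
        stop("singular information matrix; columns involved: ",
             paste(colnames(X), collapse = ", "), call. = FALSE)
      }
    )
    new_beta <- beta + step
    new_der <- cox_derivatives(new_beta, Xs, ts, es, ties, pair_a, pair_b)
    halvings <- 0L
    while (!is.finite(new_der$loglik) || new_der$loglik < der$loglik) {
      halvings <- halvings + 1L
      if (halvings > 20L) break
      new_beta <- beta + (new_beta - beta) / 2
      new_der <- cox_derivatives(new_beta, Xs, ts, es, ties, pair_a, pair_b)
    }
    rel_change <- abs(new_der$loglik - der$loglik) / (abs(der$loglik) + 1)
    beta <- new_beta
    prev_ll <- der$loglik
    der <- new_der
    if (max(abs(der$U)) < 1e-8 || rel_change < 1e-10) break
    if (iter >= max_iter) {
      warning("Newton-Raphson did not converge in ", max_iter, " iterations",
              call. = FALSE)
      break
    }
  }
  diverging <- abs(beta) > 15 & der$loglik >= prev_ll
  if (any(diverging) && max(abs(der$U)) >= 1e-8) {
    warning("possible monotone likelihood; diverging coefficient(s): ",
            paste(colnames(X)[diverging], collapse = ", "), call. = FALSE)
  }
  vcov <- solve(der$info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(
    list(coefficients = beta, vcov = vcov, loglik = der$loglik,
         convergence = list(iterations = iter,
                            gradient_norm = max(abs(der$U))),
         ties = ties, legend = legend, std = std, spec = spec,
         n = nrow(X), n_events = sum(events),
         sorted = list(X = Xs, times = ts, events = es)),
    class = "cox_fit"
  )
}

#' Breslow baseline cumulative hazard
#'
#' `H0(t) = sum over event times <= t of d_j / sum(at risk) exp(lp)`, a
#' right-continuous step function anchored at the design's centered covariate
#' reference (a male placebo subject at the cohort covariate means).
#'
#' @param fitted A [fit_cox()] result.
#' @param design,times,events Optional; default to the data the model was
#'   fitted on.
#' @return The fitted model with a `baseline` element: step `time`s,
#'   cumulative `hazard`, and an `H0(t)` evaluator.
#' @export
breslow_baseline <- function(fitted, design = NULL, times = NULL,
                             events = NULL) {
  stopifnot(inherits(fitted, "cox_fit"))
  if (is.null(design)) {
    Xs <- fitted$sorted$X
    ts <- fitted$sorted$times
    es <- fitted$sorted$events
  } else {
    X <- if (inherits(design, "cox_design")) design$X else as.matrix(design)
    times <- times %||% design$times
    events <- events %||% design$events
    ord <- order(times)
    Xs <- X[ord, , drop = FALSE]
    ts <- times[ord]
    es <- events[ord]
  }
  w <- exp(drop(Xs %*% fitted$coefficients))
  S0 <- rev_cumsum(w)
  ev_idx <- which(es == 1)
  ut <- unique(ts[ev_idx])
  d <- tabulate(match(ts[ev_idx], ut), nbins = length(ut))
  i0 <- findInterval(ut, ts, left.open = TRUE) + 1L
  H0 <- cumsum(d / S0[i0])
  fitted$baseline <- list(
    time = ut, hazard = H0, max_time = max(ts),
    H0 = stats::stepfun(ut, c(0, H0))
  )
  fitted
}

#' Fit the full risk model to a cohort
#'
#' Convenience wrapper: [build_design()], [fit_cox()], [breslow_baseline()].
#'
#' @param cohort Complete trial cohort.
#' @param spec A [model_spec()].
#' @return A `cox_fit` with baseline, ready for [predict_risk()].
#' @export
fit_risk_model <- function(cohort, spec = model_spec()) {
  design <- build_design(cohort, spec)
  fitted <- fit_cox(design)
  breslow_baseline(fitted)
}

#' Predict absolute risk at a horizon under a chosen arm
#'
#' `risk = 1 - exp(-H0(horizon) * exp(lp(subject, arm)))`. The arm is a
#' counterfactual choice: any of the three trial arms may be requested
#' regardless of the subject's observed arm (`"none"` maps to placebo / no
#' intervention).
#'
#' @param fitted A `cox_fit` with baseline.
#' @param newdata Data frame of subjects with complete predictors.
#' @param arm Single arm or one per subject.
#' @param horizon Years (default: the spec's horizon). Beyond the last
#'   observed time the last baseline step is used, with a warning.
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(fitted, newdata, arm, horizon = NULL) {
  stopifnot(inherits(fitted, "cox_fit"))
  if (is.null(fitted$baseline)) {
    stop("model has no baseline hazard; call breslow_baseline() first",
         call. = FALSE)
  }
  if (is.null(fitted$std)) {
    stop("prediction requires a model fitted from build_design()",
         call. = FALSE)
  }
  horizon <- horizon %||% fitted$spec$horizon
  miss <- predictor_columns()[!predictor_columns() %in% names(newdata)]
  if (length(miss)) {
    stop("newdata lacks predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(newdata[predictor_columns()])) {
    stop("newdata has missing predictor values", call. = FALSE)
  }
  if (horizon > fitted$baseline$max_time) {
    warning("horizon ", horizon, " exceeds the last observed time ",
            format(fitted$baseline$max_time),
            "; using the last baseline step", call. = FALSE)
  }
  X <- design_rows(newdata, arm, fitted$std, fitted$spec)
  lp <- drop(X %*% fitted$coefficients)
  H <- fitted$baseline$H0(min(horizon, fitted$baseline$max_time))
  1 - exp(-H * exp(lp))
}

#' Hazard-ratio report table
#'
#' Exponentiated coefficients with Wald 95% confidence intervals on the log
#' scale, one row per model column plus the male reference row, labelled in
#' the per-SD reporting convention (shared effects first, then the
#' arm-conditional blocks).
#'
#' @param fitted A `cox_fit`.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with `label`, `hr`, `lower`, `upper`, `display`.
#' @export
hazard_ratio_table <- function(fitted, conf = 0.95) {
  stopifnot(inherits(fitted, "cox_fit"))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(diag(fitted$vcov))
  beta <- fitted$coefficients
  tab <- data.frame(
    column = names(beta),
    label = fitted$legend$label[match(names(beta), fitted$legend$column)],
    hr = exp(beta),
    lower = exp(beta - zq * se),
    upper = exp(beta + zq * se),
    stringsAsFactors = FALSE
  )
  tab$display <- sprintf("%.2f (%.2f, %.2f)", tab$hr, tab$lower, tab$upper)
  ref <- data.frame(column = "sex_male", label = "Sex: Male",
                    hr = 1, lower = NA_real_, upper = NA_real_,
                    display = "1.00 (reference)")
  sex_row <- which(tab$column == "sex_female")
  out <- rbind(tab[setdiff(seq_len(nrow(tab)), sex_row), ],
               tab[sex_row, ], ref)
  rownames(out) <- NULL
  out
}
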