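# Shared fixtures, built in code.

# A hand-sized cohort with fixed values (n = 6), complete.
tiny_cohort <- function() {
  data.frame(
    id = 1:6,
    age = c(50, 60, 55, 45, 52, 58),
    sex = c("female", "male", "female", "female", "male", "male"),
    race_ethnicity = c("white", "black", "white", "hispanic", "other",
                       "white"),
    fpg = c(100, 110, 105, 98, 112, 107),
    hba1c = c(5.6, 6.0, 5.8, 5.5, 6.1, 5.9),
    bmi = c(30, 38, 34, 28, 36, 33),
    triglycerides = c(120, 180, 150, 100, 200, 160),
    arm = c("lifestyle", "metformin", "placebo", "lifestyle", "metformin",
            "placebo"),
    time = c(1.5, 2.0, 0.8, 3.2, 2.7, 1.1),
    event = c(0L, 1L, 1L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# Trial config carrying the canonical calibrated generating model (baseline
# hazard and arm main effects solved once, against a fixed reference config,
# and cached for the test session).
calibrated_config <- local({
  cache <- NULL
  function(n = 2640, seed = 1L, ...) {
    if (is.null(cache)) {
      cal <- calibrate_generating_model(0.227, 0.58, 0.31,
                                        dpp_sim_config(n = 2640, seed = 1L))
      cache <<- list(baseline_hazard = cal$baseline_hazard,
                     arm = cal$coefficients$arm)
    }
    cfg <- dpp_sim_config(n = n, seed = seed, ...)
    cfg$baseline_hazard <- cache$baseline_hazard
    cfg$coefficients$arm <- cache$arm
    cfg
  }
})

# Model spec whose standardization constants equal the generating ones, so
# fitted per-SD coefficients are directly comparable to generating values.
generating_spec <- function(individualized = TRUE, ...) {
  std <- default_standardization()
  model_spec(individualized = individualized,
             sd_hba1c = std$scales[["hba1c"]],
             sd_logtrig = std$scales[["logtrig"]], ...)
}

# Random small survival fixture for oracle comparisons.
random_fixture <- function(n, seed, p = 3, tie_rounding = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    beta <- runif(p, -0.8, 0.8)
    t <- rexp(n, 0.5 * exp(drop(X %*% beta)))
    if (!is.null(tie_rounding)) t <- round(t, tie_rounding) + 0.01
    cens <- rexp(n, 0.2)
    list(X = X, time = pmin(t, cens), event = as.integer(t <= cens))
  })
}

# Brute-force weighted concordance over all (case, noncase) pairs.
bruteforce_concordance <- function(risks, labels) {
  keep <- labels$weight > 0
  r <- risks[keep]; y <- labels$label[keep]; w <- labels$weight[keep]
  ci <- which(y == 1); ni <- which(y == 0)
  if (!length(ci) || !length(ni)) return(NA_real_)
  num <- 0; den <- 0
  for (a in ci) for (b in ni) {
    ww <- w[a] * w[b]
    num <- num + ww * (if (r[a] > r[b]) 1 else if (r[a] == r[b]) 0.5 else 0)
    den <- den + ww
  }
  num / den
}

# Hand Kaplan-Meier survival at a time (events before censorings at ties).
hand_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1 & times <= at]))) {
    d <- sum(times == t & events == 1)
    n_at <- sum(times >= t)
    s <- s * (1 - d / n_at)
  }
  s
}

# A fake fitted model with chosen per-SD coefficients and baseline H0 at the
# horizon; lets counterfactual logic be tested deterministically.
fake_model <- function(coefs, H3 = 0.25, individualized = TRUE) {
  spec <- generating_spec(individualized = individualized)
  std <- default_standardization()
  std <- list(centers = c(age = 51, fpg = 106, hba1c = 5.78, bmi = 34,
                          logtrig = log(144)),
              scales = std$scales)
  legend <- ipirisk:::design_legend(spec, std)
  beta <- setNames(numeric(nrow(legend)), legend$column)
  beta[names(coefs)] <- coefs
  structure(
    list(coefficients = beta,
         vcov = diag(length(beta)) * 0.001,
         loglik = NA_real_, ties = "efron", legend = legend, std = std,
         spec = spec, n = NA_integer_, n_events = NA_integer_,
         baseline = list(time = 3, hazard = H3, max_time = 3.2,
                         H0 = stats::stepfun(3, c(0, H3)))),
    class = "cox_fit"
  )
}

# Published-style per-SD coefficients with calibrated-scale arm main effects.
published_style_coefs <- function() {
  c(hba1c = log(1.21), logtrig = log(1.24), sex_female = log(1.16),
    arm_lifestyle = -0.95, arm_metformin = -0.33,
    age_lifestyle = log(0.95), age_metformin = log(1.02),
    age_placebo = log(0.97),
    bmi_lifestyle = log(1.37), bmi_metformin = log(0.89),
    bmi_placebo = log(1.04),
    fpg_lifestyle = log(1.47), fpg_metformin = log(1.53),
    fpg_placebo = log(1.90))
}

# Minimal horizon_labels object with unit weights (no censoring).
plain_labels <- function(label, weight = rep(1, length(label))) {
  structure(
    data.frame(status = ifelse(label == 1, "event", "event_free"),
               label = label, weight = weight, stringsAsFactors = FALSE),
    scheme = "ipcw", horizon = 3, n_unweightable = 0L,
    class = c("horizon_labels", "data.frame")
  )
}
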