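# Closed-form Cox partial log-likelihood for no-ties data (oracle).
pll_no_ties <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  eta <- x * beta
  sum(vapply(which(event == 1), function(i) {
    eta[i] - log(sum(exp(eta[i:length(eta)])))
  }, numeric(1)))
}

test_that("partial log-likelihood at the null counts risk sets", {
  X <- matrix(c(1, 0, -1), ncol = 1)
  der <- ipirisk:::cox_derivatives(
    0, X, times = c(1, 2, 3), events = c(1, 1, 1), ties = "efron",
    pair_a = 1L, pair_b = 1L
  )
  expect_equal(der$loglik, -(log(3) + log(2) + log(1)))
})

test_that("single-covariate fit matches an independent grid maximizer", {
  x <- c(0.5, -1.2, 0.3, 1.8)
  time <- c(2, 1, 4, 3)
  event <- c(1, 1, 1, 1)
  fit <- fit_cox(matrix(x, ncol = 1), time, event)
  # two-stage grid search over the closed-form partial likelihood
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, pll_no_ties, numeric(1), x = x, time = time,
               event = event)
  b0 <- grid[which.max(ll)]
  grid2 <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-7)
  ll2 <- vapply(grid2, pll_no_ties, numeric(1), x = x, time = time,
                event = event)
  expect_equal(unname(fit$coefficients), grid2[which.max(ll2)],
               tolerance = 1e-6)
})

test_that("fits agree with the survival package on random fixtures", {
  for (s in 1:20) {
    has_ties <- s %% 2 == 0
    fx <- random_fixture(n = 40 + 8 * s, seed = 100 + s,
                         tie_rounding = if (has_ties) 0 else NULL)
    for (ties in c("efron", "breslow")) {
      fit <- fit_cox(fx$X, fx$time, fx$event, ties = ties)
      oracle <- survival::coxph(
        survival::Surv(fx$time, fx$event) ~ fx$X, ties = ties)
      expect_equal(unname(fit$coefficients), unname(coef(oracle)),
                   tolerance = 1e-6)
      expect_equal(unname(sqrt(diag(fit$vcov))),
                   unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-6)
    }
    if (!has_ties) {
      # Breslow baseline: with no ties survival's estimator coincides
      fit <- breslow_baseline(fit_cox(fx$X, fx$time, fx$event,
                                      ties = "breslow"))
      oracle <- survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$X,
                                ties = "breslow")
      bh <- survival::basehaz(oracle, centered = FALSE)
      expect_equal(fit$baseline$H0(bh$time), bh$hazard, tolerance = 1e-6)
    }
  }
})

test_that("score test at the null equals the log-rank statistic", {
  fx <- random_fixture(n = 80, seed = 55, p = 1)
  grp <- as.integer(fx$X[, 1] > 0)
  der <- ipirisk:::cox_derivatives(
    0, matrix(grp[order(fx$time)], ncol = 1), sort(fx$time),
    fx$event[order(fx$time)], ties = "efron", pair_a = 1L, pair_b = 1L
  )
  score_stat <- der$U^2 / der$info[1, 1]
  lr <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ grp)
  expect_equal(unname(score_stat), unname(lr$chisq), tolerance = 1e-8)
})

test_that("Breslow baseline obeys its closed-form identities", {
  # beta = 0, one event among n at risk at t1 -> H0(t1) = 1/n
  X <- matrix(c(0.3, -1, 2, 0.1, -0.4), 5, 1)
  fit <- fit_cox(X, times = c(1, 2, 3, 4, 5), events = c(1, 0, 0, 0, 1))
  fit$coefficients[] <- 0  # baseline at the null
  fit <- breslow_baseline(fit)
  expect_equal(fit$baseline$H0(1), 1 / 5)
  # no events before t -> H0 = 0
  expect_equal(fit$baseline$H0(0.5), 0)
  # null-covariate exponential simulation: H0(3) ~ 3 h0
  coefs <- dpp_generating_coefficients()
  coefs$hba1c <- coefs$triglycerides <- coefs$sex_female <- 0
  for (v in c("age", "fpg", "bmi")) coefs[[v]][] <- 0
  cfg <- dpp_sim_config(n = 50000, seed = 19, coefficients = coefs,
                        baseline_hazard = 0.1, admin_censor_years = 4,
                        dropout_rate = 0)
  co <- simulate_trial_cohort(cfg)
  m <- fit_risk_model(co, generating_spec())
  expect_equal(m$baseline$H0(3), 0.3, tolerance = 0.02)
})

test_that("design matrix encodes centering, scaling, and arm structure", {
  co <- tiny_cohort()
  co$bmi <- c(40.6, rep(34 + (34 - 40.6) / 5, 5))  # mean exactly 34
  spec <- model_spec(sd_bmi = 6.6)
  d <- build_design(co, spec)
  expect_equal(unname(d$X[1, "bmi_lifestyle"]), 1.0)
  expect_equal(unname(d$X[1, "bmi_metformin"]), 0)
  expect_equal(unname(d$X[1, "bmi_placebo"]), 0)
  # subject at all covariate means on placebo: zeros except the sex indicator
  co2 <- tiny_cohort()
  means <- co2[1, ]
  means$age <- mean(co2$age); means$fpg <- mean(co2$fpg)
  means$hba1c <- mean(co2$hba1c); means$bmi <- mean(co2$bmi)
  means$triglycerides <- exp(mean(log(co2$triglycerides)))
  means$sex <- "female"; means$arm <- "placebo"; means$id <- 99L
  d2 <- build_design(rbind(co2, means), model_spec())
  row <- d2$X[7, ]
  expect_equal(unname(row["sex_female"]), 1)
  expect_true(all(abs(row[setdiff(names(row), "sex_female")]) < 1e-10))
  # individualized: 3 arm-specific columns per interacted predictor
  expect_length(grep("^fpg_", colnames(d$X)), 3)
  d_non <- build_design(tiny_cohort(), model_spec(individualized = FALSE))
  expect_identical(grep("^fpg", colnames(d_non$X), value = TRUE), "fpg")
  expect_equal(ncol(d_non$X), 8)
  expect_equal(ncol(d$X), 14)
  # errors name the offender
  bad <- tiny_cohort(); bad$arm[1] <- "tea"
  expect_error(build_design(bad, model_spec()), "arm")
  flat <- tiny_cohort(); flat$fpg <- 100
  expect_error(build_design(flat, model_spec()), "fpg")
})

test_that("fitted coefficients are invariant to native-unit rescaling", {
  cal <- calibrated_config(n = 1500, seed = 29)
  co <- simulate_trial_cohort(cal)
  f1 <- fit_cox(build_design(co, model_spec(sd_bmi = 6.6)))
  co2 <- co
  co2$bmi <- co2$bmi * 10  # e.g. report BMI in different units
  f2 <- fit_cox(build_design(co2, model_spec(sd_bmi = 66)))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("risk predictions follow the survival transform", {
  cal <- calibrated_config(n = 2000, seed = 37)
  co <- simulate_trial_cohort(cal)
  m <- fit_risk_model(co, generating_spec())
  # reference subject: all covariate means, male, placebo
  ref <- data.frame(
    id = 1L, age = m$std$centers[["age"]], sex = "male",
    race_ethnicity = "white", fpg = m$std$centers[["fpg"]],
    hba1c = m$std$centers[["hba1c"]], bmi = m$std$centers[["bmi"]],
    triglycerides = exp(m$std$centers[["logtrig"]]),
    arm = "placebo", time = 1, event = 0L
  )
  expect_equal(predict_risk(m, ref, "placebo"),
               1 - exp(-m$baseline$H0(3)))
  # one-SD FPG increase under placebo multiplies the hazard by the fitted HR
  up <- ref; up$fpg <- up$fpg + m$std$scales[["fpg"]]
  r0 <- predict_risk(m, ref, "placebo")
  r1 <- predict_risk(m, up, "placebo")
  hr <- exp(m$coefficients[["fpg_placebo"]])
  expect_equal(log(1 - r1), hr * log(1 - r0), tolerance = 1e-10)
  expect_gt(hr, 1.3)  # generating truth is strongly positive
  # monotone in the linear predictor, with risk -> 0 in the limit
  lo <- ref; lo$fpg <- 60; lo$bmi <- 15; lo$hba1c <- 3.6
  expect_lt(predict_risk(m, lo, "lifestyle"), r0)
  expect_gte(predict_risk(m, lo, "lifestyle"), 0)
  # horizon past follow-up warns and uses the last step
  expect_warning(predict_risk(m, ref, "placebo", horizon = 50),
                 "last baseline step")
})

test_that("hazard ratio table follows the per-SD display convention", {
  m <- fake_model(published_style_coefs())
  m$vcov <- diag(length(m$coefficients)) * 0.067^2
  m$coefficients["fpg_placebo"] <- 0.6419
  tab <- hazard_ratio_table(m)
  row <- tab[tab$column == "fpg_placebo", ]
  expect_equal(row$display, "1.90 (1.67, 2.17)")
  expect_identical(tab$display[tab$column == "sex_male"],
                   "1.00 (reference)")
  # a null coefficient shows HR 1 with a CI spanning 1
  m0 <- m; m0$coefficients[] <- 0
  tab0 <- hazard_ratio_table(m0)
  expect_true(all(abs(tab0$hr[tab0$column != "sex_male"] - 1) < 1e-12))
  expect_true(all(tab0$lower < 1 & tab0$upper > 1, na.rm = TRUE))
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(fit_cox(matrix(1:4, 2), times = c(1, 2), events = c(0, 0)),
               "at least one event")
  X <- cbind(a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))  # collinear
  expect_error(fit_cox(X, times = 1:4, events = c(1, 1, 1, 0)), "singular")
})
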