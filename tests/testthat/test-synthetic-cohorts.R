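test_that("trial cohort recovers the target covariate moments at large n", {
  cfg <- dpp_sim_config(n = 100000, seed = 42)
  co <- simulate_trial_cohort(cfg)
  expect_equal(mean(co$age), 51, tolerance = 0.01)
  expect_equal(sd(co$age), 11, tolerance = 0.01)
  expect_equal(mean(co$bmi), 34, tolerance = 0.01)
  expect_equal(sd(co$bmi), 7, tolerance = 0.01)
  expect_equal(mean(co$fpg), 106, tolerance = 0.01)
  expect_equal(sd(co$fpg), 7, tolerance = 0.01)
  expect_equal(mean(co$hba1c), 5.78, tolerance = 0.01)
  # lognormal triglycerides: median and log-scale spread
  expect_equal(median(co$triglycerides), 144, tolerance = 0.02)
  expect_equal(mean(co$sex == "female"), 0.67, tolerance = 0.02)
  # schema invariants
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
  expect_false(anyDuplicated(co$id) > 0)
  expect_setequal(unique(co$arm), c("lifestyle", "metformin", "placebo"))
})

test_that("null-coefficient cohort matches the exponential closed form", {
  coefs <- dpp_generating_coefficients()
  coefs$hba1c <- coefs$triglycerides <- coefs$sex_female <- 0
  for (v in c("age", "fpg", "bmi")) coefs[[v]][] <- 0
  cfg <- dpp_sim_config(n = 20000, seed = 7, coefficients = coefs,
                        baseline_hazard = 0.1, admin_censor_years = 3,
                        dropout_rate = 0)
  co <- simulate_trial_cohort(cfg)
  frac3 <- mean(co$event)
  target <- 1 - exp(-0.3)
  # 3 binomial SEs of Monte-Carlo slack
  expect_lt(abs(frac3 - target), 3 * sqrt(target * (1 - target) / 20000))
  expect_true(all(co$time <= 3))
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- dpp_sim_config(n = 500, seed = 11,
                        missingness = c(fpg = 0.1, bmi = 0.05))
  expect_identical(simulate_trial_cohort(cfg), simulate_trial_cohort(cfg))
  cfg2 <- dpp_sim_config(n = 500, seed = 12,
                         missingness = c(fpg = 0.1, bmi = 0.05))
  expect_false(identical(simulate_trial_cohort(cfg),
                         simulate_trial_cohort(cfg2)))
})

test_that("Nelson-Aalen slope in a sex stratum matches the generating hazard", {
  coefs <- dpp_generating_coefficients()
  coefs$hba1c <- coefs$triglycerides <- 0
  for (v in c("age", "fpg", "bmi")) coefs[[v]][] <- 0
  coefs$sex_female <- log(1.5)
  h0 <- 0.08
  cfg <- dpp_sim_config(n = 100000, seed = 21, coefficients = coefs,
                        baseline_hazard = h0, admin_censor_years = 50,
                        dropout_rate = 0)
  co <- simulate_trial_cohort(cfg)
  na_slope <- function(d, at) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                            stype = 2, ctype = 1)
    -log(summary(sf, times = at)$surv) / at
  }
  expect_equal(na_slope(co[co$sex == "male", ], 2), h0, tolerance = 0.05)
  expect_equal(na_slope(co[co$sex == "female", ], 2), h0 * 1.5,
               tolerance = 0.05)
})

test_that("invalid configurations are rejected with diagnostics", {
  R <- default_correlation()
  R["age", "fpg"] <- R["fpg", "age"] <- 0.999
  R["age", "bmi"] <- R["bmi", "age"] <- 0.999
  R["fpg", "bmi"] <- R["bmi", "fpg"] <- -0.999
  expect_error(dpp_sim_config(n = 10, correlation = R),
               "positive definite")
  coefs <- dpp_generating_coefficients()
  coefs$fpg <- coefs$fpg[c("lifestyle", "placebo")]
  coefs$hba1c <- NULL
  cfg <- dpp_sim_config(n = 10, coefficients = coefs)
  expect_error(simulate_trial_cohort(cfg), "hba1c")
  expect_error(simulate_trial_cohort(cfg), "fpg:metformin")
  expect_error(
    sim_config(n = 10,
               allocation = c(lifestyle = 0.5, metformin = 0.5,
                              placebo = 0, none = 0)) |>
      simulate_trial_cohort(),
    "positive mass"
  )
  expect_error(sim_config(n = 0, allocation = c(lifestyle = 1, metformin = 0,
                                                placebo = 0, none = 0)),
               "positive integer")
})

test_that("observational cohort is untreated, uses placebo hazard, and is leaner", {
  cfg <- mesa_sim_config(n = 100000, seed = 13)
  co <- simulate_observational_cohort(cfg)
  expect_true(all(co$arm == "none"))
  expect_equal(mean(co$age), 64, tolerance = 0.01)
  expect_equal(mean(co$bmi), 30, tolerance = 0.01)
  expect_equal(mean(co$fpg), 101, tolerance = 0.015)
  expect_equal(mean(co$sex == "female"), 0.50, tolerance = 0.02)

  # with a near-null hazard everything is administratively censored
  cfg0 <- mesa_sim_config(n = 200, seed = 14, baseline_hazard = 1e-12)
  coefs <- cfg0$coefficients
  coefs$hba1c <- coefs$triglycerides <- coefs$sex_female <- 0
  for (v in c("age", "fpg", "bmi")) coefs[[v]][] <- 0
  cfg0$coefficients <- coefs
  cfg0$dropout_rate <- 0
  co0 <- simulate_observational_cohort(cfg0)
  expect_true(all(co0$event == 0))
  expect_true(all(co0$time == cfg0$admin_censor_years))

  expect_error(simulate_observational_cohort(dpp_sim_config(n = 10)),
               "entirely")
})

test_that("3-year incidence is materially lower in the observational population", {
  cal <- calibrated_config(n = 50000, seed = 3)
  obs_cfg <- mesa_sim_config(n = 50000, seed = 4,
                             baseline_hazard = cal$baseline_hazard,
                             coefficients = cal$coefficients)
  km3 <- function(co) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = co)
    1 - summary(sf, times = 3)$surv
  }
  trial <- simulate_trial_cohort(cal)
  placebo_inc <- km3(trial[trial$arm == "placebo", ])
  obs_inc <- km3(simulate_observational_cohort(obs_cfg))
  expect_lt(obs_inc, 0.8 * placebo_inc)
})

test_that("calibration recovers the closed-form baseline hazard when covariates are null", {
  coefs <- dpp_generating_coefficients()
  coefs$hba1c <- coefs$triglycerides <- coefs$sex_female <- 0
  for (v in c("age", "fpg", "bmi")) coefs[[v]][] <- 0
  cfg <- dpp_sim_config(n = 100, seed = 5, coefficients = coefs)
  cal <- calibrate_generating_model(0.227, 0.58, 0.31, cfg)
  expect_equal(cal$baseline_hazard, -log(1 - 0.227) / 3, tolerance = 1e-6)
  # zero requested reduction leaves the arm main effects at zero
  cal0 <- calibrate_generating_model(0.227, 0, 0, cfg)
  expect_equal(unname(cal0$coefficients$arm), c(0, 0), tolerance = 1e-6)
  expect_error(calibrate_generating_model(0.227, 1, 0.31, cfg), "reductions")
  expect_error(calibrate_generating_model(1.2, 0.5, 0.3, cfg),
               "target_placebo_risk")
})

test_that("calibrated simulation reproduces the marginal targets (fixed point)", {
  cal <- calibrated_config(n = 100000, seed = 6)
  co <- simulate_trial_cohort(cal)
  km3 <- function(d) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    1 - summary(sf, times = 3)$surv
  }
  inc <- vapply(split(co, co$arm), km3, numeric(1))
  expect_equal(unname(inc["placebo"]), 0.227, tolerance = 0.035)
  expect_equal(unname(inc["lifestyle"] / inc["placebo"]), 0.42,
               tolerance = 0.07)
  expect_equal(unname(inc["metformin"] / inc["placebo"]), 0.69,
               tolerance = 0.05)
})

test_that("missingness injection is MCAR, seeded, and restricted to predictors", {
  cfg <- dpp_sim_config(n = 10000, seed = 8)
  co <- simulate_trial_cohort(cfg)
  expect_identical(inject_missingness(co, c(fpg = 0), seed = 1), co)
  m1 <- inject_missingness(co, c(fpg = 0.1), seed = 1)
  n_na <- sum(is.na(m1$fpg))
  expect_gte(n_na, qbinom(0.005, 10000, 0.1))
  expect_lte(n_na, qbinom(0.995, 10000, 0.1))
  m2 <- inject_missingness(co, c(fpg = 0.1), seed = 1)
  expect_identical(which(is.na(m1$fpg)), which(is.na(m2$fpg)))
  expect_error(inject_missingness(co, c(time = 0.1), seed = 1),
               "predictor columns")
  expect_error(inject_missingness(co, c(event = 0.1), seed = 1),
               "predictor columns")
  expect_error(inject_missingness(co, c(arm = 0.1), seed = 1),
               "predictor columns")
})

test_that("cohort CSV writes the exact schema and round-trips missing cells", {
  co <- inject_missingness(simulate_trial_cohort(dpp_sim_config(n = 50,
                                                                seed = 9)),
                           c(bmi = 0.2), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  header <- readLines(path, n = 1)
  expect_identical(header,
    "id,age,sex,race_ethnicity,fpg,hba1c,bmi,triglycerides,arm,time,event")
  back <- read_cohort_csv(path)
  expect_equal(back$bmi, co$bmi)
  expect_equal(back$time, co$time, tolerance = 1e-12)
  expect_identical(which(is.na(back$bmi)), which(is.na(co$bmi)))
})

test_that("simulation config serializes and round-trips", {
  cfg <- dpp_sim_config(n = 123, seed = 99, missingness = c(fpg = 0.05))
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_identical(simulate_trial_cohort(back), simulate_trial_cohort(cfg))
})
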