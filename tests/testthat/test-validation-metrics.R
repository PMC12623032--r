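test_that("horizon labels implement the censoring conventions", {
  # no censoring before horizon: both schemes unit-weight and agree
  t1 <- c(1, 2, 4, 5)
  e1 <- c(1, 1, 0, 0)
  li <- horizon_labels(t1, e1, horizon = 3, scheme = "ipcw")
  le <- horizon_labels(t1, e1, horizon = 3, scheme = "exclude")
  expect_equal(li$weight, rep(1, 4))
  expect_identical(li$label, le$label)
  expect_identical(li$weight, le$weight)
  # censoring at exactly the horizon counts as event-free with weight 1
  t2 <- c(3, 3, 1, 2)
  e2 <- c(0, 0, 1, 1)
  l2 <- horizon_labels(t2, e2, horizon = 3)
  expect_identical(l2$status, c("event_free", "event_free", "event", "event"))
  expect_equal(l2$weight, rep(1, 4))
})

test_that("IPCW prevalence equals one minus Kaplan-Meier at the horizon", {
  # 10-subject fixture with censoring interleaved among events
  times <- c(0.5, 0.8, 1.0, 1.2, 1.5, 1.8, 2.0, 2.4, 2.7, 3.5)
  events <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  lab <- horizon_labels(times, events, horizon = 3)
  prev <- sum(lab$weight * lab$label) / length(times)
  expect_equal(prev, 1 - hand_km(times, events, 3), tolerance = 1e-12)
  # and with tied event/censoring times
  times2 <- c(1, 1, 1, 2, 2, 3.5, 3.5, 0.4, 2.6, 2.9)
  events2 <- c(1, 1, 0, 1, 0, 0, 0, 1, 1, 0)
  lab2 <- horizon_labels(times2, events2, horizon = 3)
  prev2 <- sum(lab2$weight * lab2$label) / length(times2)
  expect_equal(prev2, 1 - hand_km(times2, events2, 3), tolerance = 1e-12)
})

test_that("concordance handles separation, ties, and matches brute force", {
  lab <- plain_labels(c(1, 1, 0, 0, 0))
  expect_equal(concordance(c(.9, .8, .3, .2, .1), lab, n_boot = 0)$c_statistic,
               1)
  expect_equal(concordance(rep(.5, 5), lab, n_boot = 0)$c_statistic, 0.5)
  r5 <- c(.7, .2, .4, .4, .1)
  expect_equal(concordance(r5, lab, n_boot = 0)$c_statistic,
               bruteforce_concordance(r5, lab))
  # random weighted fixtures up to 50 subjects
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) next
      r <- round(runif(n), 2)  # force some ties
      w <- sample(c(0, 0.5, 1, 2), n, replace = TRUE)
      lab <- plain_labels(y, w)
      expect_equal(concordance(r, lab, n_boot = 0)$c_statistic,
                   bruteforce_concordance(r, lab), tolerance = 1e-12)
    }
  })
  expect_warning(
    out <- concordance(c(.1, .2), plain_labels(c(1, 1)), n_boot = 0),
    "undefined")
  expect_true(is.na(out$c_statistic))
  # bootstrap is reproducible from the seed
  y <- rbinom(60, 1, 0.3); r <- runif(60)
  c1 <- concordance(r, plain_labels(y), n_boot = 50, seed = 5)
  c2 <- concordance(r, plain_labels(y), n_boot = 50, seed = 5)
  expect_identical(c1, c2)
})

test_that("decile calibration detects induced miscalibration", {
  # single-bin hand fixture: 20 subjects, 8 events, no censoring
  times <- c(rep(1, 8), rep(4, 12))
  events <- c(rep(1, 8), rep(0, 12))
  cal <- calibration_by_decile(rep(0.4, 20), times, events, horizon = 3)
  expect_equal(nrow(cal), 1)
  expect_equal(cal$observed, 0.4)
  expect_false(cal$flagged)
  # a systematic +0.05 shift forces observed < predicted in every bin
  cfg <- calibrated_config(n = 8000, seed = 67)
  co <- simulate_trial_cohort(cfg)
  true_risk <- with(co, {
    lp <- ipirisk:::generating_lp(age, fpg, hba1c, bmi, triglycerides, sex,
                                  arm, cfg$coefficients, cfg$standardization)
    1 - exp(-3 * cfg$baseline_hazard * exp(lp))
  })
  shifted <- calibration_by_decile(pmin(true_risk + 0.05, 1), co$time,
                                   co$event, horizon = 3)
  expect_true(all(shifted$observed < shifted$mean_predicted))
  # bins partition the sample
  expect_equal(sum(shifted$n), nrow(co))
})

test_that("net benefit follows the threshold-odds formula and its boundaries", {
  # 100 screened: TP rate 0.08, FP rate 0.16 at threshold 0.20
  y <- c(rep(1, 8), rep(1, 2), rep(0, 16), rep(0, 74))
  r <- c(rep(0.9, 8), rep(0.05, 2), rep(0.9, 16), rep(0.05, 74))
  lab <- plain_labels(y)
  nb <- net_benefit(r, lab, 0.20)
  expect_equal(nb$tpr, 0.08)
  expect_equal(nb$fpr, 0.16)
  expect_equal(nb$net_benefit, 0.08 - 0.16 * 0.25)
  # threshold 1/2 has exchange rate exactly 1
  nb5 <- net_benefit(r, lab, 0.5)
  expect_equal(nb5$net_benefit, nb5$tpr - nb5$fpr)
  # classify-none scores 0; classify-all equals the treat-all reference
  expect_equal(net_benefit(rep(0, 100), lab, 0.2)$net_benefit, 0)
  all_nb <- net_benefit(rep(1, 100), lab, 0.2)
  expect_equal(all_nb$net_benefit, all_nb$treat_all)
  prev <- mean(y)
  expect_equal(all_nb$treat_all, prev - (1 - prev) * 0.25)
  # model NB never exceeds prevalence on the curve
  curve <- net_benefit_curve(r, lab)
  expect_true(all(curve$net_benefit <= prev + 1e-12))
  expect_error(net_benefit(r, lab, 0), "odds")
  expect_error(net_benefit(r, lab, 1), "odds")
})

test_that("NRI decomposes exactly and conserves reclassification counts", {
  lab <- plain_labels(c(rep(1, 10), rep(0, 20)))
  # cases: 2 up, 1 down; noncases: 3 down, 1 up (categories 0.1, 0.2)
  old_r <- c(rep(0.05, 10), rep(0.05, 20))
  new_r <- old_r
  new_r[1:2] <- 0.15     # cases up
  new_r[3] <- 0.05; old_r[3] <- 0.15  # case down
  old_r[11:13] <- 0.15; new_r[11:13] <- 0.05  # noncases down
  new_r[14] <- 0.25      # noncase up
  out <- nri(new_r, old_r, lab, n_boot = 0)
  expect_equal(out$event_nri, 0.1)
  expect_equal(out$nonevent_nri, 0.1)
  expect_equal(out$overall_nri, 0.2)
  expect_equal(sum(out$matrix_events), 10)
  expect_equal(sum(out$matrix_nonevents), 20)
  # identity comparison: zero NRI, diagonal matrices
  id <- nri(new_r, new_r, lab, n_boot = 0)
  expect_equal(id$overall_nri, 0)
  expect_equal(sum(id$matrix_events) - sum(diag(id$matrix_events)), 0)
  # overall always decomposes into event + nonevent parts
  expect_equal(out$overall_nri, out$event_nri + out$nonevent_nri)
  expect_error(nri(new_r, old_r, lab, categories = c(0.2, 0.1), n_boot = 0),
               "increasing")
  expect_error(nri(new_r, old_r, lab, categories = c(0, 0.2), n_boot = 0),
               "increasing|inside")
})

test_that("fairness gaps reduce to hand arithmetic on a two-group fixture", {
  # group A: TPR 0.8, FPR 0.1; group B: TPR 0.6, FPR 0.1
  mk <- function(n1, tp, n0, fp) {
    list(y = c(rep(1, n1), rep(0, n0)),
         r = c(rep(0.9, tp), rep(0.05, n1 - tp),
               rep(0.9, fp), rep(0.05, n0 - fp)))
  }
  A <- mk(10, 8, 20, 2)
  B <- mk(10, 6, 20, 2)
  y <- c(A$y, B$y); r <- c(A$r, B$r)
  g <- rep(c("A", "B"), each = 30)
  fm <- fairness_metrics(r, plain_labels(y), g, threshold = 0.2)
  expect_equal(fm$table$tpr, c(0.8, 0.6))
  expect_equal(fm$table$fpr, c(0.1, 0.1))
  expect_equal(fm$equal_opportunity_gap, 0.2)
  expect_equal(fm$equalized_odds_gap, 0.2)
  # single group: no pairs, zero gaps
  f1 <- fairness_metrics(r, plain_labels(y), rep("A", 60), threshold = 0.2)
  expect_equal(f1$equal_opportunity_gap, 0)
  # a group without cases is flagged and excluded
  g2 <- g; g2[y == 1 & g == "B"] <- "A"
  f2 <- fairness_metrics(r, plain_labels(y), g2, threshold = 0.2)
  expect_true("B" %in% f2$flagged)
})

test_that("Brier and IPA satisfy their defining identities", {
  y <- c(1, 0, 1, 0)
  expect_equal(brier_ipa(y, plain_labels(y))$brier, 0)
  expect_equal(brier_ipa(y, plain_labels(y))$ipa, 1)
  # constant-prevalence prediction has IPA exactly 0
  prev_pred <- rep(mean(y), 4)
  expect_equal(brier_ipa(prev_pred, plain_labels(y))$ipa, 0)
  # 4-subject hand fixture
  r <- c(0.8, 0.3, 0.6, 0.1)
  expect_equal(brier_ipa(r, plain_labels(y))$brier,
               mean((y - r)^2))
  expect_warning(brier_ipa(c(.1, .2), plain_labels(c(0, 0))), "undefined")
})

test_that("validation report assembles all components reproducibly", {
  cal <- calibrated_config(n = 1500, seed = 71)
  co <- simulate_trial_cohort(cal)
  m <- fit_risk_model(co, generating_spec())
  risks <- predict_risk(m, co, co$arm)
  rep1 <- validation_report(risks, co$time, co$event,
                            groupings = list(sex = co$sex), n_boot = 30,
                            seed = 4)
  rep2 <- validation_report(risks, co$time, co$event,
                            groupings = list(sex = co$sex), n_boot = 30,
                            seed = 4)
  expect_identical(rep1, rep2)
  expect_true(rep1$c_statistic$c_statistic > 0.5)
  expect_lte(rep1$net_benefit$net_benefit, rep1$prevalence)
  expect_named(rep1$fairness, "sex")
  expect_equal(nrow(rep1$net_benefit_curve), 50)
})
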