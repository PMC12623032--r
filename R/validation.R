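# Kaplan-Meier estimate of the censoring distribution G(t), with the
# convention that at tied times events precede censorings (required for the
# identity: IPCW-weighted prevalence at t = 1 - KM survival at t).
censoring_km <- function(times, events) {
  ct <- sort(unique(times[events == 0]))
  if (!length(ct)) {
    return(function(t) rep(1, length(t)))
  }
  # events at s precede censorings at s, so they leave the risk set first
  n_cens <- vapply(ct, function(s) sum(times == s & events == 0), numeric(1))
  n_at_risk <- vapply(ct, function(s) sum(times > s), numeric(1)) + n_cens
  G <- cumprod(1 - n_cens / n_at_risk)
  sf <- stats::stepfun(ct, c(1, G))
  function(t) sf(t)
}

# G(t-): the censoring survival just before t.
censoring_km_left <- function(times, events) {
  G <- censoring_km(times, events)
  eps <- 1e-10
  function(t) G(t * (1 - eps) - eps)
}

#' Binary labels and censoring weights at a fixed horizon
#'
#' Converts right-censored follow-up into horizon-fixed binary outcomes.
#' Subjects are `event` (event on or before the horizon), `event_free`
#' (followed to the horizon or beyond without an event by then; censoring at
#' exactly the horizon counts as event-free), or `censored` (lost before the
#' horizon). Under `scheme = "ipcw"`, events are weighted by
#' `1/G(t-)` and event-free subjects by `1/G(horizon-)`, where `G` is the
#' Kaplan-Meier estimate of the censoring distribution; censored-before-
#' horizon subjects get weight 0. Under `scheme = "exclude"`, weights are
#' unit and censored subjects are simply dropped (weight 0).
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param horizon Horizon in years, > 0.
#' @param scheme `"ipcw"` (default) or `"exclude"`.
#' @return A `horizon_labels` data frame with `status`, `label` (0/1), and
#'   `weight`; attributes record the scheme, horizon, and the number of
#'   subjects excluded because `G` vanished before their event time.
#' @export
horizon_labels <- function(times, events, horizon,
                           scheme = c("ipcw", "exclude")) {
  scheme <- match.arg(scheme)
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  status <- ifelse(events == 1 & times <= horizon, "event",
            ifelse(events == 0 & times < horizon, "censored", "event_free"))
  label <- as.numeric(status == "event")
  n_unweightable <- 0L
  if (scheme == "ipcw") {
    Gm <- censoring_km_left(times, events)
    w <- numeric(length(times))
    ev <- status == "event"
    ef <- status == "event_free"
    w[ev] <- 1 / Gm(times[ev])
    w[ef] <- 1 / Gm(horizon)
    bad <- !is.finite(w)
    n_unweightable <- sum(bad)
    if (n_unweightable > 0) {
      warning(n_unweightable, " subject(s) excluded: censoring survival ",
              "estimate is 0 at their event time", call. = FALSE)
      w[bad] <- 0
    }
  } else {
    w <- as.numeric(status != "censored")
  }
  structure(
    data.frame(status = status, label = label, weight = w,
               stringsAsFactors = FALSE),
    scheme = scheme, horizon = horizon, n_unweightable = n_unweightable,
    class = c("horizon_labels", "data.frame")
  )
}

weighted_prevalence <- function(labels) {
  sum(labels$weight * labels$label) / nrow(labels)
}

# Weighted concordance by a single sweep over risk-sorted subjects.
concordance_value <- function(risks, labels) {
  keep <- labels$weight > 0
  r <- risks[keep]
  y <- labels$label[keep]
  w <- labels$weight[keep]
  W1 <- sum(w[y == 1])
  W0 <- sum(w[y == 0])
  if (W1 <= 0 || W0 <= 0) return(NA_real_)
  ord <- order(r)
  r <- r[ord]; y <- y[ord]; w <- w[ord]
  grp <- cumsum(c(TRUE, diff(r) > 0))
  w0 <- w * (y == 0)
  w1 <- w * (y == 1)
  g_w0 <- rowsum(w0, grp)[, 1]
  g_w1 <- rowsum(w1, grp)[, 1]
  below0 <- c(0, cumsum(g_w0)[-length(g_w0)])
  num <- sum(g_w1 * (below0 + 0.5 * g_w0))
  num / (W1 * W0)
}

#' Concordance (C-statistic) with bootstrap confidence interval
#'
#' The weighted probability that a randomly chosen case carries a higher
#' predicted risk than a randomly chosen noncase, ties counted one half.
#' The CI is a seeded percentile bootstrap resampling subjects.
#'
#' @param risks Predicted risks.
#' @param labels A [horizon_labels()] result.
#' @param n_boot Bootstrap resamples (default 1000); 0 skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with `c_statistic`, `lower`, `upper`, `n_boot`.
#' @export
concordance <- function(risks, labels, n_boot = 1000L, seed = 1L,
                        conf = 0.95) {
  stopifnot(length(risks) == nrow(labels))
  C <- concordance_value(risks, labels)
  if (is.na(C)) {
    warning("concordance undefined: no weighted cases or no weighted noncases",
            call. = FALSE)
    return(list(c_statistic = NA_real_, lower = NA_real_, upper = NA_real_,
                n_boot = 0L))
  }
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    n <- length(risks)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        concordance_value(risks[idx], labels[idx, , drop = FALSE])
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(c_statistic = C, lower = lo, upper = hi, n_boot = as.integer(n_boot))
}

#' Calibration by deciles of predicted risk
#'
#' Bins subjects by deciles of predicted risk (values equal to an internal
#' quantile break fall in the lower bin) and, per bin, compares the mean
#' predicted risk with the observed risk, `1 -` the Kaplan-Meier survival at
#' the horizon within the bin, with a plain Greenwood confidence interval.
#' Bins whose follow-up does not reach the horizon are evaluated at the last
#' estimable time and flagged.
#'
#' @param risks Predicted risks.
#' @param times,events Follow-up data.
#' @param horizon Horizon in years.
#' @param n_bins Number of quantile bins (default 10).
#' @param conf Confidence level for the Greenwood interval.
#' @return Data frame: `bin`, `n`, `mean_predicted`, `observed`, `lower`,
#'   `upper`, `eval_time`, `flagged`.
#' @export
calibration_by_decile <- function(risks, times, events, horizon,
                                  n_bins = 10L, conf = 0.95) {
  n <- length(risks)
  if (n < 20) stop("calibration requires n >= 20", call. = FALSE)
  breaks <- unique(stats::quantile(risks, probs = seq(0, 1,
                                                      length.out = n_bins + 1),
                                   names = FALSE))
  bin <- findInterval(risks, breaks, left.open = TRUE)
  bin[bin == 0L] <- 1L  # the minimum lands in the first bin
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    sf <- survival::survfit(
      survival::Surv(times[sel], events[sel]) ~ 1,
      conf.type = "plain", conf.int = conf
    )
    eval_time <- min(horizon, max(times[sel]))
    flagged <- eval_time < horizon
    s <- summary(sf, times = eval_time, extend = TRUE)
    data.frame(
      bin = b, n = sum(sel), mean_predicted = mean(risks[sel]),
      observed = 1 - s$surv,
      lower = 1 - s$upper, upper = 1 - s$lower,
      eval_time = eval_time, flagged = flagged
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decision-curve net benefit at a threshold
#'
#' `NB = TPR - FPR * threshold / (1 - threshold)`, the true-positive rate
#' minus the false-positive rate discounted by the exchange rate (the odds of
#' the threshold probability). Rates are weighted counts per subject
#' screened, so `100 * NB` reads as true-positive cases identified per 100
#' screened. The treat-all and treat-none reference policies are returned
#' alongside.
#'
#' @param risks Predicted risks.
#' @param labels A [horizon_labels()] result.
#' @param threshold Decision threshold strictly inside (0, 1).
#' @return List: `threshold`, `net_benefit`, `treat_all`, `treat_none`,
#'   `tpr`, `fpr`, `prevalence`.
#' @export
net_benefit <- function(risks, labels, threshold) {
  stopifnot(length(risks) == nrow(labels))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1): the exchange rate is ",
         "the odds of the threshold", call. = FALSE)
  }
  n <- nrow(labels)
  w <- labels$weight
  y <- labels$label
  pos <- risks >= threshold
  tpr <- sum(w * y * pos) / n
  fpr <- sum(w * (1 - y) * pos) / n
  odds <- threshold / (1 - threshold)
  prev <- sum(w * y) / n
  nonprev <- sum(w * (1 - y)) / n
  list(threshold = threshold,
       net_benefit = tpr - fpr * odds,
       treat_all = prev - nonprev * odds,
       treat_none = 0,
       tpr = tpr, fpr = fpr, prevalence = prev)
}

#' @rdname net_benefit
#' @param thresholds Grid of thresholds for the decision curve.
#' @return `net_benefit_curve()` returns a data frame over the grid.
#' @export
net_benefit_curve <- function(risks, labels,
                              thresholds = seq(0.01, 0.50, by = 0.01)) {
  rows <- lapply(thresholds, function(th) {
    as.data.frame(net_benefit(risks, labels, th))
  })
  do.call(rbind, rows)
}

risk_categories <- function(risks, categories) {
  findInterval(risks, categories) + 1L
}

nri_components <- function(risks_new, risks_old, labels, categories) {
  K <- length(categories) + 1L
  cat_old <- risk_categories(risks_old, categories)
  cat_new <- risk_categories(risks_new, categories)
  w <- labels$weight
  y <- labels$label
  comp <- function(case) {
    sel <- if (case) y == 1 & w > 0 else y == 0 & w > 0
    W <- sum(w[sel])
    M <- matrix(0, K, K,
                dimnames = list(old = paste0("cat", seq_len(K)),
                                new = paste0("cat", seq_len(K))))
    if (W > 0) {
      tab <- rowsum(w[sel], interaction(cat_old[sel], cat_new[sel],
                                        drop = FALSE))
      idx <- do.call(rbind, lapply(strsplit(rownames(tab), "\\."),
                                   as.integer))
      M[idx] <- tab[, 1]
    }
    up <- sum(M[upper.tri(M)]) / W
    down <- sum(M[lower.tri(M)]) / W
    list(matrix = M, up = up, down = down, W = W)
  }
  cases <- comp(TRUE)
  noncases <- comp(FALSE)
  list(
    event_nri = cases$up - cases$down,
    nonevent_nri = noncases$down - noncases$up,
    overall_nri = (cases$up - cases$down) + (noncases$down - noncases$up),
    matrix_events = cases$matrix,
    matrix_nonevents = noncases$matrix
  )
}

#' Categorical net reclassification improvement
#'
#' Cross-classifies subjects into risk categories under an old (standard) and
#' new model, separately for cases and noncases, with censoring weights. The
#' event NRI is `P(up | case) - P(down | case)`, the nonevent NRI is
#' `P(down | noncase) - P(up | noncase)`, and the overall NRI is their sum.
#' The reclassification matrices are returned and a seeded percentile
#' bootstrap supplies the CI for the overall NRI.
#'
#' @param risks_new,risks_old Predicted risks for the same subjects under the
#'   new and standard model.
#' @param labels A [horizon_labels()] result.
#' @param categories Strictly increasing cut-points inside (0, 1);
#'   default `c(0.10, 0.20)`.
#' @param n_boot,seed,conf Bootstrap settings; `n_boot = 0` skips the CI.
#' @return List with the three NRI components, CI, and both matrices.
#' @export
nri <- function(risks_new, risks_old, labels, categories = c(0.10, 0.20),
                n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(length(risks_new) == nrow(labels),
            length(risks_old) == nrow(labels))
  if (!length(categories) || is.unsorted(categories, strictly = TRUE) ||
      any(categories <= 0 | categories >= 1)) {
    stop("`categories` must be strictly increasing and inside (0, 1)",
         call. = FALSE)
  }
  out <- nri_components(risks_new, risks_old, labels, categories)
  out$categories <- categories
  out$lower <- out$upper <- NA_real_
  if (n_boot > 0) {
    n <- nrow(labels)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        nri_components(risks_new[idx], risks_old[idx],
                       labels[idx, , drop = FALSE], categories)$overall_nri
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

#' Fairness of a thresholded classifier across subgroups
#'
#' Per-group true- and false-positive rates among that group's cases and
#' noncases at the decision threshold, the equal-opportunity gap (largest
#' pairwise TPR difference), and the equalized-odds gap (largest pairwise TPR
#' or FPR difference). Groups without weighted cases (or noncases) have an
#' undefined TPR (FPR) and are excluded from the corresponding gap with a
#' flag.
#'
#' @param risks Predicted risks.
#' @param labels A [horizon_labels()] result.
#' @param groups Group membership vector (e.g. race/ethnicity or sex).
#' @param threshold Decision threshold (default 0.20).
#' @return List: per-group `table` (n, TPR, FPR), `equal_opportunity_gap`,
#'   `equalized_odds_gap`, `flagged` group names.
#' @export
fairness_metrics <- function(risks, labels, groups, threshold = 0.20) {
  stopifnot(length(risks) == nrow(labels), length(groups) == nrow(labels))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  w <- labels$weight
  y <- labels$label
  pos <- risks >= threshold
  lv <- sort(unique(as.character(groups)))
  tab <- do.call(rbind, lapply(lv, function(g) {
    sel <- groups == g
    W1 <- sum(w[sel] * y[sel])
    W0 <- sum(w[sel] * (1 - y[sel]))
    data.frame(
      group = g, n = sum(sel),
      tpr = if (W1 > 0) sum(w[sel] * y[sel] * pos[sel]) / W1 else NA_real_,
      fpr = if (W0 > 0) sum(w[sel] * (1 - y[sel]) * pos[sel]) / W0 else
        NA_real_
    )
  }))
  flagged <- tab$group[is.na(tab$tpr) | is.na(tab$fpr)]
  gap <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else max(x) - min(x)
  }
  list(table = tab,
       equal_opportunity_gap = gap(tab$tpr),
       equalized_odds_gap = max(gap(tab$tpr), gap(tab$fpr)),
       threshold = threshold,
       flagged = flagged)
}

#' Brier score and index of prediction accuracy
#'
#' Weighted Brier score `mean(w * (label - risk)^2)` and
#' `IPA = 1 - Brier(model) / Brier(null)`, where the null model predicts the
#' weighted event prevalence for everyone.
#'
#' @param risks Predicted risks.
#' @param labels A [horizon_labels()] result.
#' @return List: `brier`, `brier_null`, `ipa`, `prevalence`.
#' @export
brier_ipa <- function(risks, labels) {
  stopifnot(length(risks) == nrow(labels))
  n <- nrow(labels)
  w <- labels$weight
  y <- labels$label
  brier <- sum(w * (y - risks)^2) / n
  prev <- if (sum(w) > 0) sum(w * y) / sum(w) else NA_real_
  brier_null <- sum(w * (y - prev)^2) / n
  ipa <- if (is.na(prev) || prev == 0 || brier_null == 0) {
    warning("IPA undefined at zero prevalence", call. = FALSE)
    NA_real_
  } else {
    1 - brier / brier_null
  }
  list(brier = brier, brier_null = brier_null, ipa = ipa, prevalence = prev)
}

#' Assemble a full validation report for one set of predictions
#'
#' Discrimination, decile calibration, decision-curve net benefit, fairness
#' by each supplied grouping, and Brier/IPA, all computed at the horizon
#' under the chosen censoring scheme.
#'
#' @param risks Predicted risks at the horizon.
#' @param times,events Follow-up data for the same subjects.
#' @param horizon Horizon in years.
#' @param groupings Named list of group vectors (e.g.
#'   `list(race_ethnicity = ..., sex = ...)`) for fairness and subgroup
#'   discrimination.
#' @param threshold Decision/fairness threshold (default 0.20).
#' @param scheme Censoring scheme for binary metrics.
#' @param n_boot,seed Bootstrap settings.
#' @param nb_thresholds Net-benefit curve grid.
#' @return A `validation_report` list.
#' @export
validation_report <- function(risks, times, events, horizon = 3,
                              groupings = list(),
                              threshold = 0.20,
                              scheme = c("ipcw", "exclude"),
                              n_boot = 1000L, seed = 1L,
                              nb_thresholds = seq(0.01, 0.50, by = 0.01)) {
  scheme <- match.arg(scheme)
  labels <- horizon_labels(times, events, horizon, scheme)
  conc <- concordance(risks, labels, n_boot = n_boot, seed = seed)
  fairness <- lapply(groupings, function(g) {
    fairness_metrics(risks, labels, g, threshold)
  })
  subgroup_c <- lapply(groupings, function(g) {
    do.call(rbind, lapply(sort(unique(as.character(g))), function(lv) {
      sel <- g == lv
      data.frame(group = lv, n = sum(sel),
                 c_statistic = concordance_value(risks[sel],
                                                 labels[sel, , drop = FALSE]))
    }))
  })
  structure(
    list(
      n = length(risks),
      horizon = horizon,
      scheme = scheme,
      c_statistic = conc,
      calibration = calibration_by_decile(risks, times, events, horizon),
      net_benefit = net_benefit(risks, labels, threshold),
      net_benefit_curve = net_benefit_curve(risks, labels, nb_thresholds),
      fairness = fairness,
      subgroup_c = subgroup_c,
      brier = brier_ipa(risks, labels),
      prevalence = weighted_prevalence(labels)
    ),
    class = "validation_report"
  )
}
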