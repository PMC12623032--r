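#' Define the Gower distance space over predictor columns
#'
#' Assigns each predictor a kind (continuous or categorical) and, for
#' continuous variables, the range (max - min) used to normalize absolute
#' differences. Ranges are computed from the reference cohort itself;
#' constant columns carry no distance information and are dropped with a
#' warning.
#'
#' @param cohort Reference cohort `data.frame`.
#' @param variables Predictor columns to include (default: the six model
#'   predictors). Outcome columns and `arm` are never distance variables.
#' @return A `gower_space` list with `kinds` and `ranges`.
#' @export
gower_space <- function(cohort, variables = predictor_columns()) {
  forbidden <- intersect(variables, c("time", "event", "arm", "id"))
  if (length(forbidden)) {
    stop("outcome/arm/id columns may not enter the Gower space: ",
         paste(forbidden, collapse = ", "), call. = FALSE)
  }
  kinds <- vapply(variables, function(v) {
    if (is.numeric(cohort[[v]])) "continuous" else "categorical"
  }, character(1))
  ranges <- vapply(variables, function(v) {
    if (kinds[[v]] != "continuous") return(NA_real_)
    obs <- cohort[[v]][!is.na(cohort[[v]])]
    if (!length(obs)) return(NA_real_)
    diff(range(obs))
  }, numeric(1))
  degenerate <- names(ranges)[kinds == "continuous" &
                                (is.na(ranges) | ranges <= 0)]
  if (length(degenerate)) {
    warning("constant or empty continuous column(s) excluded from Gower ",
            "distance: ", paste(degenerate, collapse = ", "), call. = FALSE)
    keep <- setdiff(variables, degenerate)
    kinds <- kinds[keep]
    ranges <- ranges[keep]
    variables <- keep
  }
  if (!length(variables)) {
    stop("no usable variables left in the Gower space", call. = FALSE)
  }
  structure(list(variables = variables, kinds = kinds, ranges = ranges),
            class = "gower_space")
}

#' Gower dissimilarity between two observations
#'
#' The mean, over variables observed on both sides, of the per-variable
#' dissimilarity: `|a - b| / range` for continuous variables and a 0/1
#' mismatch for categorical ones. Pairs with either side missing drop out of
#' both numerator and denominator, so the distance stays in `[0, 1]` under
#' arbitrary missingness.
#'
#' @param row_a,row_b Single-row `data.frame`s (or named lists) carrying the
#'   space's variables.
#' @param space A [gower_space()].
#' @return Distance in `[0, 1]`, or `NA` when no variable is
#'   pairwise-observed (such a neighbour is excluded by [impute_knn()]).
#' @export
gower_distance <- function(row_a, row_b, space) {
  stopifnot(inherits(space, "gower_space"))
  num <- 0
  den <- 0L
  for (v in space$variables) {
    a <- row_a[[v]]
    b <- row_b[[v]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) next
    d <- if (space$kinds[[v]] == "continuous") {
      abs(a - b) / space$ranges[[v]]
    } else {
      as.numeric(a != b)
    }
    num <- num + d
    den <- den + 1L
  }
  if (den == 0L) return(NA_real_)
  num / den
}

# Distances from one target row to every donor row, vectorized per variable.
gower_distances_to <- function(target, donors, space) {
  n <- nrow(donors)
  num <- numeric(n)
  den <- numeric(n)
  for (v in space$variables) {
    a <- target[[v]]
    if (is.na(a)) next
    b <- donors[[v]]
    ok <- !is.na(b)
    d <- if (space$kinds[[v]] == "continuous") {
      abs(a - b[ok]) / space$ranges[[v]]
    } else {
      as.numeric(a != b[ok])
    }
    num[ok] <- num[ok] + d
    den[ok] <- den[ok] + 1
  }
  out <- rep(NA_real_, n)
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

stat_mode <- function(x) {
  tab <- table(x)
  # ties broken toward the alphabetically lowest label
  names(tab)[which.max(tab == max(tab))]
}

#' Impute missing predictors by Gower k-nearest-neighbour aggregation
#'
#' Each missing cell is filled by aggregating the values of the `k` donors
#' nearest to its row under Gower distance: the mean for continuous variables
#' and the mode (ties toward the alphabetically lowest label) for categorical
#' ones. Only rows observing the variable are eligible donors, and donor
#' values are original observed values only (no chained imputation).
#' Equidistant donors are broken by subject-id order, so the result is
#' deterministic.
#'
#' @param cohort Cohort `data.frame`, possibly with `NA` predictor cells.
#' @param k Number of donors per cell (default 5).
#' @param space Optional [gower_space()]; defaults to one built from `donors`
#'   (or from `cohort` itself).
#' @param donors Optional reference cohort supplying donor rows and ranges,
#'   e.g. a training fold when imputing a held-out fold. Defaults to
#'   `cohort`, in which case a row never donates to itself.
#' @return The cohort with all missing predictor cells filled.
#' @export
impute_knn <- function(cohort, k = 5L, space = NULL, donors = NULL) {
  validate_cohort(cohort, allow_missing = TRUE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  self_donors <- is.null(donors)
  if (self_donors) donors <- cohort
  vars <- intersect(predictor_columns(), names(cohort))
  na_counts <- vapply(cohort[vars], function(x) sum(is.na(x)), integer(1))
  if (!any(na_counts > 0)) return(cohort)
  fully_missing <- vars[vapply(vars, function(v) all(is.na(donors[[v]])),
                               logical(1))]
  if (length(fully_missing)) {
    stop("variable(s) 100% missing among donors, cannot impute: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(space)) space <- gower_space(donors)
  kinds <- vapply(vars, function(v) {
    if (is.numeric(donors[[v]])) "continuous" else "categorical"
  }, character(1))
  donor_order <- order(donors$id)
  donors <- donors[donor_order, , drop = FALSE]
  short_cells <- character(0)
  rows_todo <- which(rowSums(is.na(cohort[vars])) > 0)
  for (i in rows_todo) {
    target <- cohort[i, ]
    dist <- gower_distances_to(target, donors, space)
    if (self_donors) dist[donors$id == target$id] <- NA
    for (v in vars[is.na(target[vars])]) {
      eligible <- which(!is.na(dist) & !is.na(donors[[v]]))
      if (!length(eligible)) {
        stop("no eligible donors for subject ", target$id, ", variable ", v,
             call. = FALSE)
      }
      if (length(eligible) < k) {
        short_cells <- c(short_cells, paste0("id ", target$id, "/", v, " (",
                                             length(eligible), " donors)"))
      }
      # stable ties: donors pre-sorted by id, order() is stable
      nearest <- eligible[order(dist[eligible])][seq_len(min(k,
                                                             length(eligible)))]
      vals <- donors[[v]][nearest]
      cohort[[v]][i] <- if (kinds[[v]] == "continuous") {
        mean(vals)
      } else {
        stat_mode(vals)
      }
    }
  }
  if (length(short_cells)) {
    warning("fewer than k = ", k, " eligible donors for: ",
            paste(short_cells, collapse = "; "), call. = FALSE)
  }
  cohort
}
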