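`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a config
# seed fully determines the output without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream-specific child seed from a base seed, staying inside the
# 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream) %% .Machine$integer.max)
}

trial_arms <- function() c("lifestyle", "metformin", "placebo")

all_arms <- function() c("lifestyle", "metformin", "placebo", "none")

predictor_columns <- function() {
  c("age", "sex", "fpg", "hba1c", "bmi", "triglycerides")
}

cohort_columns <- function() {
  c("id", "age", "sex", "race_ethnicity", "fpg", "hba1c", "bmi",
    "triglycerides", "arm", "time", "event")
}
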