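# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force implementation of the three written cleaning
# rules, deliberately structured differently from filter_trials: explicit
# per-rule subsets, no staged report bookkeeping.
brute_filter <- function(assessment, rt_min = 200, rt_max = 2000, sd_k = 2) {
  keep <- list()
  for (tt in c("congruent", "incongruent")) {
    sub <- assessment[assessment$congruency == tt, , drop = FALSE]
    sub <- sub[sub$correct, , drop = FALSE]
    sub <- sub[sub$rt_ms > rt_min & sub$rt_ms < rt_max, , drop = FALSE]
    if (nrow(sub) >= 2) {
      m <- sum(sub$rt_ms) / nrow(sub)
      s <- sqrt(sum((sub$rt_ms - m)^2) / (nrow(sub) - 1))
      sub <- sub[abs(sub$rt_ms - m) <= sd_k * s, , drop = FALSE]
    }
    keep[[tt]] <- sub
  }
  out <- rbind(keep$congruent, keep$incongruent)
  rownames(out) <- NULL
  out
}

# Random small assessment with contaminant RTs exercising every rule.
random_assessment <- function(n = 20) {
  congruency <- sample(c("congruent", "incongruent"), n, replace = TRUE)
  rt <- rnorm(n, 500, 150) + rexp(n, 1 / 100)
  contaminate <- runif(n)
  rt[contaminate < 0.1] <- runif(sum(contaminate < 0.1), 50, 199)
  rt[contaminate > 0.9] <- runif(sum(contaminate > 0.9), 2001, 4000)
  data.frame(
    congruency = congruency,
    correct = runif(n) > 0.1,
    rt_ms = pmax(rt, 1),
    stringsAsFactors = FALSE
  )
}

# Tiny but complete simulated study, shared by pipeline-level tests.
small_cohort <- function(n = 12, seed = 7, ...) {
  blocks <- rep(4L, n %/% 4L)
  simulate_cohort(cohort_config(
    n_participants = as.integer(n), block_sizes = blocks, seed = seed, ...
  ))
}

# Long questionnaire table drawn straight from the trajectory model, for
# inference tests that do not need trial-level simulation. Known truth:
# score = intercept_i + slope_i * t + N(0, resid_sd).
make_long_null <- function(n = 30, slope_mean = -5.9, slope_sd = 3,
                           intercept_mean = 70, intercept_sd = 15,
                           resid_sd = 7) {
  id <- sprintf("S%03d", seq_len(n))
  cond <- rep(c(0L, 1L), length.out = n)
  stim <- rep(c(0L, 0L, 1L, 1L), length.out = n)
  a <- rnorm(n, intercept_mean, intercept_sd)
  b <- rnorm(n, slope_mean, slope_sd)
  long <- expand.grid(participant_id = id, time = 0:3, stringsAsFactors = FALSE)
  i <- match(long$participant_id, id)
  long$condition <- cond[i]
  long$stimuli <- stim[i]
  long$score <- a[i] + b[i] * long$time + rnorm(nrow(long), 0, resid_sd)
  long
}
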