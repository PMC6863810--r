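make_trials <- function(congruency, rt, correct = TRUE) {
  data.frame(
    congruency = congruency, correct = correct, rt_ms = rt,
    stringsAsFactors = FALSE
  )
}

test_that("clean assessments pass through the filter untouched", {
  a <- make_trials(rep(c("congruent", "incongruent"), each = 5), 500)
  f <- filter_trials(a)
  expect_equal(nrow(f$retained), 10)
  expect_equal(sum(f$report$discarded_error + f$report$discarded_bounds +
    f$report$discarded_sd), 0)
  expect_equal(f$report$discard_fraction, c(0, 0))
})

test_that("the three discard stages fire in order with correct tallies", {
  # one error trial, one too-fast, one too-slow, seven tightly clustered
  a <- make_trials(
    rep("congruent", 10),
    c(500, 150, 2500, 510, 505, 495, 490, 500, 505, 498),
    correct = c(FALSE, rep(TRUE, 9))
  )
  a <- rbind(a, make_trials(rep("incongruent", 2), c(520, 530)))
  f <- filter_trials(a)
  con <- f$report[f$report$trial_type == "congruent", ]
  expect_equal(con$n_input, 10)
  expect_equal(con$discarded_error, 1)
  expect_equal(con$discarded_bounds, 2)
  # stage 3 operates on the 7 in-bounds survivors
  expect_equal(con$discarded_sd + con$retained, 7)
  # conservation
  expect_equal(con$n_input, con$discarded_error + con$discarded_bounds +
    con$discarded_sd + con$retained)
})

test_that("the SD trim matches the hand-computed boundary", {
  rts <- c(rep(500, 8), 900)
  a <- rbind(
    make_trials(rep("congruent", 9), rts),
    make_trials(rep("incongruent", 2), c(500, 510))
  )
  f <- filter_trials(a)
  m <- mean(rts)
  s <- sd(rts)
  should_drop <- abs(900 - m) > 2 * s
  kept_900 <- 900 %in% f$retained$rt_ms[f$retained$congruency == "congruent"]
  expect_equal(kept_900, !should_drop)
})

test_that("staged filter agrees with the brute-force oracle on random assessments", {
  set.seed(2024)
  for (i in 1:200) {
    a <- random_assessment(n = sample(4:30, 1))
    if (sum(a$congruency == "congruent") == 0 ||
      sum(a$congruency == "incongruent") == 0) {
      next
    }
    got <- suppressWarnings(filter_trials(a))
    want <- brute_filter(a)
    expect_equal(got$retained$rt_ms, want$rt_ms)
    expect_equal(got$retained$congruency, want$congruency)
    # conservation per type, always
    expect_equal(
      got$report$n_input,
      got$report$discarded_error + got$report$discarded_bounds +
        got$report$discarded_sd + got$report$retained
    )
  }
})

test_that("widening the bounds or raising the trim never loses trials", {
  set.seed(7)
  for (i in 1:30) {
    a <- random_assessment(25)
    base <- suppressWarnings(filter_trials(a, 200, 2000, 2))
    wider <- suppressWarnings(filter_trials(a, 100, 3000, 2))
    looser <- suppressWarnings(filter_trials(a, 200, 2000, 3))
    expect_gte(sum(wider$report$retained), sum(base$report$retained))
    expect_gte(sum(looser$report$retained), sum(base$report$retained))
  }
})

test_that("a trial type with fewer than two in-bounds survivors skips the SD stage", {
  a <- rbind(
    make_trials("congruent", 500),
    make_trials(rep("incongruent", 5), c(500, 505, 510, 495, 498))
  )
  f <- expect_silent(filter_trials(a))
  expect_match(paste(f$warnings, collapse = " "), "SD trim skipped")
  expect_equal(f$report$retained[f$report$trial_type == "congruent"], 1)
})

test_that("exclusion uses a strict 20% threshold per assessment and type", {
  clean <- data.frame(
    trial_type = c("congruent", "incongruent"), n_input = 40L,
    discarded_error = 0L, discarded_bounds = 0L, discarded_sd = 0L,
    retained = 40L, discard_fraction = 0
  )
  expect_false(exclusion_flag(clean, clean)$excluded)

  quarter <- clean
  quarter$discard_fraction[1] <- 0.25
  e <- exclusion_flag(quarter, clean)
  expect_true(e$excluded)
  expect_equal(e$reasons, "pre/congruent")

  boundary <- clean
  boundary$discard_fraction <- c(0.20, 0.20)
  expect_false(exclusion_flag(boundary, boundary)$excluded)
})

test_that("the bias index is incongruent minus congruent mean RT", {
  b <- bias_index(make_trials(
    c("congruent", "congruent", "incongruent", "incongruent"),
    c(500, 510, 520, 530)
  ))
  expect_equal(b$value, 20)
  expect_equal(b$n_congruent, 2)
  expect_equal(b$n_incongruent, 2)

  sym <- bias_index(make_trials(
    rep(c("congruent", "incongruent"), each = 3), rep(c(480, 500, 520), 2)
  ))
  expect_equal(sym$value, 0)

  neg <- bias_index(make_trials(c("congruent", "incongruent"), c(600, 580)))
  expect_equal(neg$value, -20)

  expect_error(bias_index(make_trials("congruent", 500)), "each type")
})

test_that("cohort-level cleaning flags and excludes lossy participants", {
  co <- small_cohort(n = 8, seed = 21, fast_guess_rate = 0, lapse_rate = 0, error_rate = 0)
  bt <- compute_bias_table(co$trials)
  expect_equal(nrow(bt$bias), 16)
  expect_true(all(c("pre", "post") %in% bt$bias$phase))
  # contamination-free cohort: only the SD trim fires, never near 20%
  expect_false(any(bt$bias$excluded))
  expect_true(all(bt$retained$phase %in% c("pre", "post")))
})

test_that("null cohorts yield bias indices centered at zero", {
  # 200 small cohorts with no true congruency effect; per-cohort t test of
  # the cleaned pre-training bias indices should reject at ~ the alpha level
  set.seed(314)
  sched <- generate_measurement_schedule(100, 0.2, seed = 60)$trials
  rejections <- 0L
  for (rep in 1:200) {
    bias <- vapply(1:50, function(i) {
      params <- data.frame(
        rt_mu = 450, rt_sigma = 50, rt_tau = 100, bias_delta = 0,
        error_rate = 0.04, fast_guess_rate = 0.02, lapse_rate = 0.02
      )
      resp <- simulate_responses(sched, params)
      f <- suppressWarnings(filter_trials(resp))
      bias_index(f$retained)$value
    }, numeric(1))
    if (t.test(bias)$p.value < 0.01) rejections <- rejections + 1L
  }
  # Binomial(200, 0.01): 8 or more rejections has probability ~1e-3
  expect_lte(rejections, 8L)
})
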