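test_that("Spearman-Brown has its fixed points, closed form and monotonicity", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(1 / 3), 0.5)
  expect_error(spearman_brown(-1), "must lie")

  grid <- seq(-0.95, 1, by = 0.05)
  vals <- spearman_brown(grid)
  expect_true(all(diff(vals) > 0))
})

test_that("noiseless heterogeneous participants give split-half reliability 1", {
  # each participant responds with constant RTs within type; their bias
  # differs across participants, so any split reproduces it exactly
  n <- 10
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      participant_id = sprintf("P%02d", i),
      congruency = rep(c("congruent", "incongruent"), each = 10),
      rt_ms = rep(c(500, 500 + 5 * i), each = 10),
      stringsAsFactors = FALSE
    )
  }))
  est <- splithalf_bias_reliability(trials, n_splits = 50, seed = 1)
  expect_equal(est$value, 1, tolerance = 1e-10)
  expect_equal(est$n_participants, n)
})

test_that("pure within-person noise drives the estimate toward zero", {
  # identical true bias for everyone, large trial noise: individual
  # differences in the half indices are noise, so r ~ 0 (possibly negative)
  set.seed(5)
  trials <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(
      participant_id = sprintf("P%02d", i),
      congruency = rep(c("congruent", "incongruent"), each = 20),
      rt_ms = 500 + rnorm(40, 0, 120),
      stringsAsFactors = FALSE
    )
  }))
  est <- splithalf_bias_reliability(trials, n_splits = 500, seed = 2)
  expect_lt(abs(est$value), 0.35)
})

test_that("the 5000-split estimate is stable across seeds", {
  # study-scale data: the split-resampling error of the 5000-split mean is
  # a few thousandths, so two seeds agree to 0.01
  co <- small_cohort(n = 96, seed = 31)
  bt <- compute_bias_table(co$trials)
  pre <- bt$retained[bt$retained$phase == "pre", ]
  e1 <- splithalf_bias_reliability(pre, n_splits = 5000, seed = 11)
  e2 <- splithalf_bias_reliability(pre, n_splits = 5000, seed = 97)
  expect_lt(abs(e1$value - e2$value), 0.01)
  # and exactly reproducible for a fixed seed
  e3 <- splithalf_bias_reliability(pre, n_splits = 5000, seed = 11)
  expect_identical(e1$value, e3$value)
})

test_that("the correction-order flag changes only the aggregation", {
  co <- small_cohort(n = 8, seed = 32)
  bt <- compute_bias_table(co$trials)
  pre <- bt$retained[bt$retained$phase == "pre", ]
  a <- splithalf_bias_reliability(pre, n_splits = 300, seed = 4, keep_splits = TRUE)
  b <- splithalf_bias_reliability(pre,
    n_splits = 300, seed = 4,
    order = "average-first", keep_splits = TRUE
  )
  expect_equal(a$value, mean(spearman_brown(b$per_split)))
  expect_equal(b$value, spearman_brown(mean(b$per_split)))
})

test_that("participants with too few trials are dropped; tiny samples error", {
  set.seed(3)
  trials <- data.frame(
    participant_id = rep(c("A", "B", "C", "D"), each = 8),
    congruency = rep(rep(c("congruent", "incongruent"), each = 4), 4),
    rt_ms = rnorm(32, 500, 50), stringsAsFactors = FALSE
  )
  # participant D keeps only one congruent trial
  is_d_con <- trials$participant_id == "D" & trials$congruency == "congruent"
  trials <- trials[!is_d_con | cumsum(is_d_con) <= 1, ]
  expect_warning(
    est <- splithalf_bias_reliability(trials, n_splits = 20, seed = 1),
    "dropped"
  )
  expect_equal(est$n_participants, 3)
  expect_equal(est$dropped, "D")

  two <- trials[trials$participant_id %in% c("A", "B"), ]
  expect_error(
    splithalf_bias_reliability(two, n_splits = 20, seed = 1),
    "at least 3"
  )
})

test_that("Cronbach's alpha matches its closed forms", {
  # identical items: perfect consistency
  x <- rnorm(20)
  expect_equal(cronbach_alpha(matrix(rep(x, 10), ncol = 10))$value, 1)

  # two items with equal sample variance: alpha = 2r / (1 + r)
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 3, 5, 4)
  stopifnot(isTRUE(all.equal(var(a), var(b))))
  r <- cor(a, b)
  expect_equal(cronbach_alpha(cbind(a, b))$value, 2 * r / (1 + r))

  # mutually independent items: alpha ~ 0 at large n
  set.seed(8)
  m <- matrix(rnorm(2000 * 10), ncol = 10)
  expect_lt(abs(cronbach_alpha(m)$value), 0.1)

  # incomplete rows are dropped and reported
  m2 <- matrix(rnorm(50), ncol = 5)
  m2[3, 2] <- NA
  est <- cronbach_alpha(m2)
  expect_equal(est$n_dropped_rows, 1)
  expect_equal(est$n_participants, 9)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)), "2 items")
})

test_that("split-half recovery of a known reliability from variance components", {
  # true bias varies across persons with SD sigma_b; each of the 2k trials
  # per type adds noise with SD sigma_e. The half-index error variance is
  # 2 sigma_e^2 / k, so the expected half-half correlation is
  # rho_half = sigma_b^2 / (sigma_b^2 + 2 sigma_e^2 / k), full-length
  # reliability = SB(rho_half).
  set.seed(99)
  sigma_b <- 30
  sigma_e <- 60
  k <- 20 # trials per type per half
  rho_half <- sigma_b^2 / (sigma_b^2 + 2 * sigma_e^2 / k)
  rho_full <- spearman_brown(rho_half)
  n <- 120
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    delta <- rnorm(1, 0, sigma_b)
    data.frame(
      participant_id = sprintf("P%03d", i),
      congruency = rep(c("congruent", "incongruent"), each = 2 * k),
      rt_ms = 500 + rep(c(-delta / 2, delta / 2), each = 2 * k) +
        rnorm(4 * k, 0, sigma_e),
      stringsAsFactors = FALSE
    )
  }))
  est <- splithalf_bias_reliability(trials, n_splits = 1000, seed = 12)
  expect_lt(abs(est$value - rho_full), 0.12)
})
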