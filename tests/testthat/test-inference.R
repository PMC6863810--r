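test_that("Pearson correlation matches the closed-form oracle", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 5)
  # hand formula: r = S_xy / sqrt(S_xx S_yy)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- correlate(x, y)
  expect_equal(got$r, r_hand)
  expect_equal(got$n, 3)

  expect_equal(correlate(1:10, 1:10)$r, 1)

  # pairwise deletion of missing values
  got2 <- correlate(c(x, NA), c(y, 3))
  expect_equal(got2$n, 3)
  expect_equal(got2$r, r_hand)

  expect_error(correlate(1:2, 2:3), "3 complete pairs")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("correlation p-values are calibrated under independence", {
  set.seed(42)
  p <- replicate(1000, correlate(rnorm(40), rnorm(40))$p)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("the mixed ANOVA uses the between/within strata correctly", {
  # a strong pre->post shift confined to one group must show up as both a
  # time effect and a time-by-group interaction
  set.seed(10)
  n_per <- 10
  groups <- rep(c("2D-mock", "2D-active", "3D-mock", "3D-active"), each = n_per)
  id <- sprintf("P%02d", seq_along(groups))
  pre <- rnorm(length(id), 0, 10)
  post <- pre + ifelse(groups == "2D-active", -60, 0) + rnorm(length(id), 0, 10)
  bias <- rbind(
    data.frame(participant_id = id, phase = "pre", bias_ms = pre, group = groups),
    data.frame(participant_id = id, phase = "post", bias_ms = post, group = groups)
  )
  out <- rm_anova_bias(bias)
  expect_setequal(out$effect, c("group", "time", "time:group"))
  expect_equal(out$df1, c(3, 1, 3))
  expect_equal(out$df2, c(36, 36, 36))
  expect_lt(out$p[out$effect == "time"], 0.01)
  expect_lt(out$p[out$effect == "time:group"], 0.01)

  # participants lacking a phase are dropped; excluded flags respected
  bias2 <- rbind(bias, data.frame(
    participant_id = "P99", phase = "pre",
    bias_ms = 0, group = "2D-mock"
  ))
  expect_equal(rm_anova_bias(bias2), out)

  # degenerate input is flagged rather than reported as a real F
  flat <- bias
  flat$bias_ms <- 5
  expect_true(all(rm_anova_bias(flat)$degenerate))

  expect_error(
    rm_anova_bias(bias[bias$group != "2D-mock" | bias$participant_id == "P01", ]),
    "at least 2"
  )
})

test_that("mixed ANOVA type-I error is near nominal under the null", {
  set.seed(77)
  groups <- rep(c("2D-mock", "2D-active", "3D-mock", "3D-active"), each = 10)
  id <- sprintf("P%02d", seq_along(groups))
  rej <- matrix(FALSE, 500, 3)
  for (r in 1:500) {
    subj <- rnorm(40, 0, 20) # participant-level variation
    bias <- rbind(
      data.frame(
        participant_id = id, phase = "pre",
        bias_ms = subj + rnorm(40, 0, 25), group = groups
      ),
      data.frame(
        participant_id = id, phase = "post",
        bias_ms = subj + rnorm(40, 0, 25), group = groups
      )
    )
    rej[r, ] <- rm_anova_bias(bias)$p < 0.05
  }
  rates <- colMeans(rej)
  for (rate in rates) expect_lt(abs(rate - 0.05), 0.03)
})

test_that("the model ladder obeys the AIC identity and nesting monotonicity", {
  set.seed(23)
  long <- make_long_null()
  fits <- fit_lmm_set(long)
  expect_s3_class(fits, "lmm_set")
  for (f in fits) {
    expect_true(is.null(f$error))
    expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
  }
  # output is AIC-ordered
  tab <- model_comparison(fits)
  expect_true(all(diff(tab$AIC) >= 0))
  # adding fixed effects never lowers the ML log-likelihood
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  nested_pairs <- list(
    c("null", "time"), c("time", "time_condition"),
    c("time_condition", "time_x_condition"), c("time", "time_stimuli"),
    c("time_condition", "additive"), c("additive", "full"),
    c("time_x_condition", "full"), c("time_x_stimuli", "full")
  )
  for (pr in nested_pairs) expect_gte(ll[[pr[2]]], ll[[pr[1]]])
})

test_that("the noiseless limit recovers the generating slope to numerical precision", {
  set.seed(1)
  n <- 20
  id <- sprintf("S%02d", 1:n)
  a <- rnorm(n, 70, 10)
  b <- rnorm(n, -5.9, 2)
  long <- expand.grid(participant_id = id, time = 0:3, stringsAsFactors = FALSE)
  i <- match(long$participant_id, id)
  long$condition <- rep(0:1, length.out = n)[i]
  long$stimuli <- 0L
  # residual noise at the numerical floor: the fitted mean slope must equal
  # the average generating slope
  long$score <- a[i] + b[i] * long$time + rnorm(nrow(long), 0, 1e-6)
  fits <- fit_lmm_set(long, ladder = list(time = score ~ time))
  est <- fits$time$fixed_effects
  expect_equal(est$estimate[est$term == "time"], mean(b), tolerance = 1e-5)
})

test_that("t-test degrees of freedom follow the containment pattern", {
  set.seed(31)
  long <- make_long_null(n = 92) # full follow-up: 92 x 4 rows
  fits <- fit_lmm_set(long, ladder = list(full = score ~ time * condition * stimuli))
  fe <- fits$full$fixed_effects
  # within-participant terms (those involving time) share one df; purely
  # between-participant terms another
  within_df <- unique(fe$df[grepl("time", fe$term) | fe$term == "(Intercept)"])
  between_df <- unique(fe$df[!grepl("time", fe$term) & fe$term != "(Intercept)"])
  expect_length(within_df, 1)
  expect_length(between_df, 1)
  expect_equal(within_df, 92 * 4 - 92 - 4) # N_obs - N_subj - within terms
  expect_equal(between_df, 92 - 4) # N_subj - between terms - intercept
})

test_that("likelihood-ratio tests match the log-likelihood oracle", {
  set.seed(5)
  long <- make_long_null()
  fits <- fit_lmm_set(long)
  lr <- likelihood_ratio(fits$time_x_condition, fits$full)
  expect_equal(lr$statistic, 2 * (fits$full$logLik - fits$time_x_condition$logLik))
  expect_equal(lr$df, fits$full$k - fits$time_x_condition$k)
  expect_equal(lr$df, 4) # stimuli, time:stimuli, condition:stimuli, 3-way
  expect_equal(lr$p, pchisq(lr$statistic, 4, lower.tail = FALSE))

  # identical models: zero statistic, p = 1
  same <- likelihood_ratio(fits$full, fits$full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # non-nested models are refused
  expect_error(
    likelihood_ratio(fits$time_x_stimuli, fits$time_x_condition),
    "not nested"
  )
})

test_that("participants with missing follow-ups are retained, not imputed", {
  set.seed(8)
  long <- make_long_null(n = 40)
  long$score[long$participant_id == "S001" & long$time >= 2] <- NA
  fits <- fit_lmm_set(long, ladder = list(time = score ~ time))
  expect_true(is.null(fits$time$error))
  expect_equal(nrow(fits$time$fit$data), 40 * 4 - 2)
})
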