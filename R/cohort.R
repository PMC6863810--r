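# Synthetic cohort simulation.
#
# Emulates a four-arm single-session ABM trial: blocked allocation to the
# 2D/3D x mock/active groups, a 100-trial pre measurement, two 190-trial
# training blocks per the group's variant, a 100-trial post measurement,
# and a 24-item x 2-subscale social anxiety questionnaire (total 0-144) at
# four timepoints with missing-completely-at-random dropout at follow-ups.
# Reaction times follow an ex-Gaussian with a congruency shift of
# +/- bias_delta/2, contaminated by fast guesses and attentional lapses so
# that every cleaning rule downstream is exercised.

GROUPS <- c("2D-mock", "2D-active", "3D-mock", "3D-active")

#' Configure a synthetic ABM cohort
#'
#' Population-level parameters for \code{\link{simulate_cohort}}. Individual
#' participants draw their own ex-Gaussian reaction-time parameters, true
#' congruency effect (\code{bias_delta}), contamination rates and
#' questionnaire trajectory from these means and SDs. Defaults reproduce the
#' reference trial's structure: 100 participants allocated in blocks of
#' 4/8/12, 100-trial measurements, 2 x 190-trial training, baseline anxiety
#' near 70 (SD ~19) on a 0--144 scale declining ~5.9 points per assessment,
#' and dropout probabilities 0.06 / 0.11 at the two follow-ups.
#'
#' @param n_participants cohort size.
#' @param block_sizes allocation block sizes (each divisible by 4, summing to
#'   \code{n_participants}).
#' @param rt_mu_mean,rt_mu_sd population mean/SD of the Gaussian RT component
#'   mean, ms.
#' @param rt_sigma_mean,rt_sigma_sd population mean/SD of the Gaussian SD, ms.
#' @param rt_tau_mean,rt_tau_sd population mean/SD of the exponential tail, ms.
#' @param bias_delta_mean,bias_delta_sd true incongruent-minus-congruent RT
#'   effect, ms (the quantity the bias index estimates).
#' @param error_rate,fast_guess_rate,lapse_rate contamination probabilities
#'   per trial.
#' @param lsas_intercept_mean,lsas_intercept_sd baseline questionnaire total.
#' @param lsas_slope_mean,lsas_slope_sd change in total per assessment.
#' @param lsas_resid_sd residual SD of the questionnaire total, points.
#' @param dropout_1wk,dropout_3mo probability a participant misses the 1-week
#'   / 3-month follow-up.
#' @param n_items number of item ratings summing to the total (24 items rated
#'   twice, each 0--3).
#' @param n_measurement_trials,measurement_filler_rate measurement task shape.
#' @param n_training_blocks,trials_per_training_block,training_filler_rate
#'   training task shape.
#' @param first_trial_loss emulate the recording fault in which the first
#'   trial of the first participant of each group is lost from the pre
#'   measurement.
#' @param seed integer seed governing every random draw.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_participants = 100L,
                          block_sizes = c(12L, 12L, 12L, 12L, 12L, 12L, 12L, 8L, 8L),
                          rt_mu_mean = 450, rt_mu_sd = 50,
                          rt_sigma_mean = 50, rt_sigma_sd = 10,
                          rt_tau_mean = 100, rt_tau_sd = 25,
                          bias_delta_mean = 0, bias_delta_sd = 10,
                          error_rate = 0.04,
                          fast_guess_rate = 0.02,
                          lapse_rate = 0.02,
                          lsas_intercept_mean = 69.7, lsas_intercept_sd = 19.3,
                          lsas_slope_mean = -5.9, lsas_slope_sd = 4,
                          lsas_resid_sd = 8,
                          dropout_1wk = 0.06, dropout_3mo = 0.11,
                          n_items = 48L,
                          n_measurement_trials = 100L,
                          measurement_filler_rate = 0.20,
                          n_training_blocks = 2L,
                          trials_per_training_block = 190L,
                          training_filler_rate = 0.20,
                          first_trial_loss = FALSE,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_participants >= 4, all(block_sizes %in% c(4L, 8L, 12L)),
    sum(block_sizes) == n_participants,
    error_rate >= 0, error_rate < 1,
    fast_guess_rate >= 0, lapse_rate >= 0, fast_guess_rate + lapse_rate < 1,
    dropout_1wk >= 0, dropout_1wk < 1, dropout_3mo >= 0, dropout_3mo < 1
  )
  structure(cfg, class = "cohort_config")
}

#' Allocate participants to groups in randomized blocks
#'
#' Emulates blocked slot randomization: consecutive allocation blocks each
#' contain the four groups in equal numbers, in a random order.
#'
#' @param n number of participants; must equal \code{sum(block_sizes)}.
#' @param block_sizes block sizes, each divisible by 4.
#' @param seed integer seed.
#' @return character vector of group labels of length \code{n}.
#' @examples
#' table(allocate_groups(8, c(8), seed = 1)) # each group exactly twice
#' @export
allocate_groups <- function(n, block_sizes, seed) {
  if (any(block_sizes %% 4L != 0L)) {
    stop("every allocation block must be divisible by 4", call. = FALSE)
  }
  if (sum(block_sizes) != n) {
    stop("block sizes must partition the cohort: sum(block_sizes) != n", call. = FALSE)
  }
  with_seed(seed, {
    unlist(lapply(block_sizes, function(b) {
      sample(rep(GROUPS, each = b %/% 4L))
    }), use.names = FALSE)
  })
}

# Draw one participant's ground-truth parameters from the population config.
# Rates are truncated to [0, 0.95]; scale parameters to a small positive floor.
draw_participant_params <- function(id, group, cfg) {
  pos <- function(x, lo = 1) max(x, lo)
  data.frame(
    id = id, group = group,
    rt_mu = pos(rnorm(1, cfg$rt_mu_mean, cfg$rt_mu_sd), 100),
    rt_sigma = pos(rnorm(1, cfg$rt_sigma_mean, cfg$rt_sigma_sd), 5),
    rt_tau = pos(rnorm(1, cfg$rt_tau_mean, cfg$rt_tau_sd), 5),
    bias_delta = rnorm(1, cfg$bias_delta_mean, cfg$bias_delta_sd),
    error_rate = cfg$error_rate,
    fast_guess_rate = cfg$fast_guess_rate,
    lapse_rate = cfg$lapse_rate,
    lsas_intercept = rnorm(1, cfg$lsas_intercept_mean, cfg$lsas_intercept_sd),
    lsas_slope = rnorm(1, cfg$lsas_slope_mean, cfg$lsas_slope_sd),
    dropout_1wk = runif(1) < cfg$dropout_1wk,
    dropout_3mo = runif(1) < cfg$dropout_3mo,
    stringsAsFactors = FALSE
  )
}

#' Simulate responses to a set of dot-probe trials
#'
#' Reaction times are ex-Gaussian: \code{rnorm(mu + c * bias_delta / 2,
#' sigma) + rexp(1 / tau)}, with congruency sign \code{c} = +1 for
#' incongruent, -1 for congruent and 0 for filler trials, so that the
#' expected incongruent-minus-congruent difference equals \code{bias_delta}.
#' With probability \code{fast_guess_rate} the RT is replaced by a fast guess
#' Uniform(50, 200) ms; with probability \code{lapse_rate} by an attentional
#' lapse Uniform(2000, 4000) ms. Each response is incorrect with probability
#' \code{error_rate}, in which case the reported letter is the wrong one.
#'
#' Draws from the current RNG state; seed via \code{set.seed} or call within
#' \code{\link{simulate_cohort}}.
#'
#' @param trials data frame of trials with columns \code{congruency} and
#'   \code{probe_letter} (e.g. \code{schedule$trials}).
#' @param params one row of participant parameters (\code{rt_mu},
#'   \code{rt_sigma}, \code{rt_tau}, \code{bias_delta}, \code{error_rate},
#'   \code{fast_guess_rate}, \code{lapse_rate}).
#' @return \code{trials} with added columns \code{response_letter},
#'   \code{correct} and \code{rt_ms}.
#' @export
simulate_responses <- function(trials, params) {
  n <- nrow(trials)
  shift <- ifelse(trials$congruency == "incongruent", 1,
    ifelse(trials$congruency == "congruent", -1, 0)
  )
  rt <- rnorm(n, params$rt_mu + shift * params$bias_delta / 2, params$rt_sigma) +
    rexp(n, rate = 1 / params$rt_tau)
  u <- runif(n)
  guess <- u < params$fast_guess_rate
  lapse <- !guess & u < params$fast_guess_rate + params$lapse_rate
  rt[guess] <- runif(sum(guess), 50, 200)
  rt[lapse] <- runif(sum(lapse), 2000, 4000)
  rt <- pmax(rt, 1) # RTs are strictly positive
  correct <- runif(n) >= params$error_rate
  trials$response_letter <- ifelse(correct, trials$probe_letter,
    ifelse(trials$probe_letter == "E", "F", "E")
  )
  trials$correct <- correct
  trials$rt_ms <- rt
  trials
}

#' Simulate one participant's questionnaire records
#'
#' The total follows a linear trajectory \code{intercept + slope * t} plus
#' Gaussian residual noise, rounded to the integer scale and clipped to
#' [0, 144]. Item scores (each 0--3) are generated by randomized allocation
#' of the total over the items, so items always sum exactly to the total.
#' Dropout flags remove the 1-week (t = 2) and/or 3-month (t = 3) records.
#'
#' Draws from the current RNG state.
#'
#' @param params one row of participant parameters.
#' @param config a \code{cohort_config} (supplies \code{lsas_resid_sd} and
#'   \code{n_items}).
#' @param timepoints integer codes 0 (baseline), 1 (post), 2 (1-week),
#'   3 (3-months).
#' @return data frame with columns \code{participant_id}, \code{instrument},
#'   \code{timepoint}, \code{total}, \code{item_1} .. \code{item_k}.
#' @export
simulate_lsas <- function(params, config, timepoints = 0:3) {
  keep <- !(timepoints == 2 & params$dropout_1wk) &
    !(timepoints == 3 & params$dropout_3mo)
  tps <- timepoints[keep]
  max_total <- 3L * config$n_items
  rows <- lapply(tps, function(t) {
    total <- params$lsas_intercept + params$lsas_slope * t +
      rnorm(1, 0, config$lsas_resid_sd)
    total <- as.integer(round(min(max(total, 0), min(144, max_total))))
    items <- allocate_items(total, config$n_items)
    rec <- data.frame(
      participant_id = params$id, instrument = "LSAS-SR",
      timepoint = t, total = total, stringsAsFactors = FALSE
    )
    rec[paste0("item_", seq_len(config$n_items))] <- as.list(items)
    rec
  })
  do.call(rbind, rows)
}

# Randomized-rounding allocation of `total` rating units over `k` items,
# each capped at 3. Spreads the total as evenly as chance allows.
allocate_items <- function(total, k) {
  items <- integer(k)
  remaining <- total
  while (remaining > 0L) {
    open <- which(items < 3L)
    take <- min(length(open), remaining)
    bump <- sample(open, take)
    items[bump] <- items[bump] + 1L
    remaining <- remaining - take
  }
  items
}

#' Simulate a complete ABM trial dataset
#'
#' For each participant: blocked group allocation, a pre measurement, two
#' training blocks per the group's variant (mock training is structurally a
#' measurement task; active training applies the contingency), a post
#' measurement, responses to every trial, and questionnaire records at four
#' timepoints with dropout. The ground-truth parameter table is retained so
#' recovery of the generating values can be tested. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return an object of class \code{abm_cohort}: list with elements
#'   \code{trials} (participant_id, phase in pre/training1/training2/post,
#'   trial attributes, response_letter, correct, rt_ms),
#'   \code{questionnaires}, \code{groups}, \code{ground_truth} and
#'   \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- allocate_groups(config$n_participants, config$block_sizes, config$seed)
  seeds <- derive_seeds(config$seed + 1L, 2L * config$n_participants + 1L)

  trial_parts <- vector("list", config$n_participants)
  quest_parts <- vector("list", config$n_participants)
  truth_parts <- vector("list", config$n_participants)
  first_of_group_seen <- character(0)

  for (i in seq_len(config$n_participants)) {
    id <- sprintf("P%03d", i)
    group <- groups[i]
    active <- grepl("active", group)
    mode3d <- grepl("3D", group)

    params <- with_seed(seeds[i], draw_participant_params(id, group, config))
    truth_parts[[i]] <- params

    phase_tables <- with_seed(seeds[config$n_participants + i], {
      pre <- generate_measurement_schedule(
        config$n_measurement_trials, config$measurement_filler_rate,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
      train <- generate_training_schedule(
        config$n_training_blocks, config$trials_per_training_block,
        active = active, stimuli_mode = if (mode3d) "3D" else "2D",
        filler_rate = config$training_filler_rate,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
      post <- generate_measurement_schedule(
        config$n_measurement_trials, config$measurement_filler_rate,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )

      pre_t <- simulate_responses(pre$trials, params)
      train_t <- simulate_responses(train$trials, params)
      post_t <- simulate_responses(post$trials, params)

      pre_t$phase <- "pre"
      train_t$phase <- ifelse(train_t$block == 1L, "training1", "training2")
      post_t$phase <- "post"

      quest <- simulate_lsas(params, config)
      list(trials = rbind(pre_t, train_t, post_t), quest = quest)
    })

    tab <- phase_tables$trials
    if (config$first_trial_loss && !(group %in% first_of_group_seen)) {
      first_of_group_seen <- c(first_of_group_seen, group)
      drop_row <- which(tab$phase == "pre" & tab$trial_index == 1L)
      if (length(drop_row)) tab <- tab[-drop_row[1L], , drop = FALSE]
    }
    tab$participant_id <- id
    trial_parts[[i]] <- tab
    quest_parts[[i]] <- phase_tables$quest
  }

  trials <- do.call(rbind, trial_parts)
  rownames(trials) <- NULL
  front <- c("participant_id", "phase")
  trials <- trials[, c(front, setdiff(names(trials), front))]

  structure(
    list(
      trials = trials,
      questionnaires = do.call(rbind, quest_parts),
      groups = data.frame(
        participant_id = sprintf("P%03d", seq_len(config$n_participants)),
        group = groups, stringsAsFactors = FALSE
      ),
      ground_truth = do.call(rbind, truth_parts),
      config = config
    ),
    class = "abm_cohort"
  )
}

#' @export
print.abm_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ABM cohort: %d participants, %d trials, %d questionnaire records\n",
    x$config$n_participants, nrow(x$trials), nrow(x$questionnaires)
  ))
  print(table(x$groups$group))
  invisible(x)
}

#' Export a cohort's tables as delimited text
#'
#' Writes \code{trials.csv}, \code{questionnaires.csv}, \code{groups.csv}
#' and \code{ground_truth.csv} into a directory.
#'
#' @param cohort an \code{abm_cohort}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$questionnaires, file.path(dir, "questionnaires.csv"),
    row.names = FALSE
  )
  utils::write.csv(cohort$groups, file.path(dir, "groups.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
    row.names = FALSE
  )
  invisible(dir)
}
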