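# Dot-probe trial schedules.
#
# A trial shows a vertically arranged face pair (threat-neutral or, on
# filler trials, neutral-neutral) for 500 ms after a 500 ms fixation cross,
# then a probe letter (E or F) at the location of one face. Congruent trials
# put the probe at the threat location, incongruent trials at the neutral
# location; filler trials have no congruency. Counterbalancing is enforced
# exactly within each block, then the trial order is shuffled.

SCHEDULE_COLUMNS <- c(
  "trial_index", "pair_type", "threat_position", "probe_position",
  "probe_letter", "congruency", "block",
  "fixation_ms", "faces_ms", "iti_ms"
)

# Build one exactly counterbalanced block. `contingency` is "balanced"
# (measurement / mock: equal congruent and incongruent) or "incongruent"
# (active training: probe always at the neutral location). Assumes the RNG
# is already seeded by the caller.
build_block <- function(n_trials, filler_rate, contingency) {
  n_filler <- n_trials * filler_rate
  if (abs(n_filler - round(n_filler)) > 1e-8) {
    stop(sprintf(
      "balance error: filler count %g = %d x %g is not an integer",
      n_filler, n_trials, filler_rate
    ), call. = FALSE)
  }
  n_filler <- as.integer(round(n_filler))
  n_scored <- n_trials - n_filler

  if (contingency == "balanced") {
    if (n_scored %% 4L != 0L) {
      stop(sprintf(
        paste0(
          "balance error: %d scored trials cannot be split evenly over ",
          "2 congruencies x 2 threat positions (must be divisible by 4)"
        ), n_scored
      ), call. = FALSE)
    }
    q <- n_scored %/% 4L
    congruency <- rep(c("congruent", "incongruent"), each = 2L * q)
    threat <- rep(rep(c("top", "bottom"), each = q), times = 2L)
  } else {
    if (n_scored %% 2L != 0L) {
      stop(sprintf(
        paste0(
          "balance error: %d scored trials cannot balance threat position ",
          "top/bottom (must be divisible by 2)"
        ), n_scored
      ), call. = FALSE)
    }
    congruency <- rep("incongruent", n_scored)
    threat <- rep(c("top", "bottom"), each = n_scored %/% 2L)
  }
  # congruent: probe at the threat location; incongruent: at the neutral one
  probe <- ifelse(congruency == "congruent", threat,
    ifelse(threat == "top", "bottom", "top")
  )

  # filler probe side balanced as evenly as possible; odd extra on a random side
  filler_probe <- character(0)
  if (n_filler > 0) {
    half <- n_filler %/% 2L
    filler_probe <- c(rep("top", half), rep("bottom", half))
    if (n_filler %% 2L == 1L) filler_probe <- c(filler_probe, sample(c("top", "bottom"), 1L))
  }

  block <- data.frame(
    pair_type = c(rep("threat-neutral", n_scored), rep("neutral-neutral", n_filler)),
    threat_position = c(threat, rep("none", n_filler)),
    probe_position = c(probe, filler_probe),
    congruency = c(congruency, rep("filler", n_filler)),
    stringsAsFactors = FALSE
  )

  # probe letter balanced across the whole block, independently of congruency
  half <- n_trials %/% 2L
  letters_pool <- c(rep("E", half), rep("F", half))
  if (n_trials %% 2L == 1L) letters_pool <- c(letters_pool, sample(c("E", "F"), 1L))
  block$probe_letter <- sample(letters_pool)

  block[sample.int(nrow(block)), , drop = FALSE]
}

finish_schedule <- function(blocks, variant, stimuli_mode,
                            fixation_ms, faces_ms, iti_ms) {
  sizes <- vapply(blocks, nrow, integer(1))
  trials <- do.call(rbind, blocks)
  trials$block <- rep(seq_along(blocks), sizes)
  trials$trial_index <- seq_len(nrow(trials))
  trials$fixation_ms <- fixation_ms
  trials$faces_ms <- faces_ms
  trials$iti_ms <- iti_ms
  rownames(trials) <- NULL
  trials <- trials[, SCHEDULE_COLUMNS]
  ends <- cumsum(sizes)
  structure(
    list(
      variant = variant,
      stimuli_mode = stimuli_mode,
      trials = trials,
      blocks = data.frame(block = seq_along(blocks), start = ends - sizes + 1L, end = ends)
    ),
    class = "abm_schedule"
  )
}

#' Generate a measurement dot-probe schedule
#'
#' Builds one exactly counterbalanced block for attentional bias measurement:
#' among threat-neutral (scored) trials, half are congruent and half
#' incongruent, with the threat face equally often on top and bottom within
#' each congruency; a proportion \code{filler_rate} of trials are
#' neutral-neutral fillers with the probe side balanced; the probe letter
#' (E/F) is balanced across all trials. The trial order is then shuffled.
#'
#' @param n_trials total number of trials (default 100).
#' @param filler_rate proportion of neutral-neutral filler trials
#'   (default 0.20). \code{n_trials * filler_rate} must be an integer and the
#'   remaining scored trials divisible by 4.
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @param stimuli_mode \code{"2D"} or \code{"3D"} (measurement is 2D in the
#'   reference design).
#' @param fixation_ms,faces_ms,iti_ms epoch durations in ms (defaults 500).
#' @return an object of class \code{abm_schedule}: a list with elements
#'   \code{variant}, \code{stimuli_mode}, \code{trials} (one row per trial)
#'   and \code{blocks} (start/end indices).
#' @examples
#' sch <- generate_measurement_schedule(100, 0.20, seed = 1)
#' table(sch$trials$congruency)
#' @export
generate_measurement_schedule <- function(n_trials = 100L, filler_rate = 0.20,
                                          seed, stimuli_mode = "2D",
                                          fixation_ms = 500, faces_ms = 500,
                                          iti_ms = 500) {
  stopifnot(n_trials >= 1, filler_rate >= 0, filler_rate < 1)
  stimuli_mode <- match.arg(stimuli_mode, c("2D", "3D"))
  with_seed(seed, {
    blk <- build_block(as.integer(n_trials), filler_rate, "balanced")
    finish_schedule(list(blk), "measurement", stimuli_mode,
      fixation_ms, faces_ms, iti_ms
    )
  })
}

#' Generate a training dot-probe schedule
#'
#' Builds a multi-block training session. With \code{active = TRUE} the
#' training contingency is applied: the probe always appears at the location
#' of the neutral face, so every threat-neutral trial is incongruent. With
#' \code{active = FALSE} (mock training) the schedule is identical in
#' structure to the measurement task: congruent and incongruent trials in
#' equal numbers. In both variants \code{filler_rate} of trials per block
#' are neutral-neutral fillers and the threat position is balanced within
#' each block.
#'
#' @param n_blocks number of blocks (default 2).
#' @param trials_per_block trials per block (default 190).
#' @param active logical; apply the training contingency?
#' @param stimuli_mode \code{"2D"} or \code{"3D"}.
#' @param filler_rate proportion of filler trials per block (default 0.20).
#' @param seed integer seed.
#' @param fixation_ms,faces_ms,iti_ms epoch durations in ms (defaults 500).
#' @return an \code{abm_schedule} with variant \code{"active"} or
#'   \code{"mock"}.
#' @examples
#' tr <- generate_training_schedule(2, 190, active = TRUE, seed = 3)
#' sum(tr$trials$congruency == "congruent") # 0: the contingency
#' @export
generate_training_schedule <- function(n_blocks = 2L, trials_per_block = 190L,
                                       active, stimuli_mode = "2D",
                                       filler_rate = 0.20, seed,
                                       fixation_ms = 500, faces_ms = 500,
                                       iti_ms = 500) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, is.logical(active))
  stimuli_mode <- match.arg(stimuli_mode, c("2D", "3D"))
  contingency <- if (active) "incongruent" else "balanced"
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      build_block(as.integer(trials_per_block), filler_rate, contingency)
    })
    finish_schedule(blocks, if (active) "active" else "mock", stimuli_mode,
      fixation_ms, faces_ms, iti_ms
    )
  })
}

violation <- function(constraint, block, observed, expected) {
  data.frame(
    constraint = constraint, block = block,
    observed = observed, expected = expected, stringsAsFactors = FALSE
  )
}

#' Validate counterbalancing and contingency constraints of a schedule
#'
#' Checks, per block, the structural invariants of the declared task variant:
#' filler consistency (neutral-neutral pairs have no threat position and no
#' congruency), the congruency/probe-position relation, equal congruent and
#' incongruent counts for measurement and mock schedules, zero congruent
#' trials for active schedules, threat-position balance among scored trials,
#' probe-letter balance (E/F within one of parity), and filler probe-side
#' balance. Violations are returned as data, not raised as errors.
#'
#' @param schedule an \code{abm_schedule}, or a data frame of trials plus a
#'   \code{variant} argument.
#' @param variant variant to validate against when \code{schedule} is a raw
#'   trial data frame.
#' @return a data frame of violations (\code{constraint}, \code{block},
#'   \code{observed}, \code{expected}); zero rows when the schedule is valid.
#' @export
validate_schedule <- function(schedule, variant = NULL) {
  if (inherits(schedule, "abm_schedule")) {
    trials <- schedule$trials
    variant <- schedule$variant
  } else {
    trials <- schedule
    if (is.null(variant)) stop("variant must be given for raw trial tables")
  }
  check_columns(trials, setdiff(SCHEDULE_COLUMNS, c("fixation_ms", "faces_ms", "iti_ms")),
    what = "trial table"
  )
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  bad_filler <- (trials$pair_type == "neutral-neutral") !=
    (trials$congruency == "filler") |
    (trials$pair_type == "neutral-neutral") != (trials$threat_position == "none")
  if (any(bad_filler)) {
    add(violation(
      "filler consistency", NA_integer_,
      sprintf("%d inconsistent trials", sum(bad_filler)),
      "pair_type, congruency and threat_position agree"
    ))
  }

  scored <- trials[trials$pair_type == "threat-neutral", , drop = FALSE]
  mis <- (scored$congruency == "congruent") !=
    (scored$probe_position == scored$threat_position)
  if (any(mis)) {
    add(violation(
      "congruency/probe relation", NA_integer_,
      sprintf("%d mislabelled trials", sum(mis)),
      "congruent iff probe at threat position"
    ))
  }

  for (b in sort(unique(trials$block))) {
    blk <- trials[trials$block == b, , drop = FALSE]
    sc <- blk[blk$pair_type == "threat-neutral", , drop = FALSE]
    n_con <- sum(sc$congruency == "congruent")
    n_inc <- sum(sc$congruency == "incongruent")

    if (variant == "active") {
      if (n_con != 0L) {
        add(violation(
          "contingency", b, sprintf("%d congruent trials", n_con),
          "0 congruent trials in active training"
        ))
      }
    } else {
      if (n_con != n_inc) {
        add(violation(
          "congruency balance", b, sprintf("%d congruent vs %d incongruent", n_con, n_inc),
          "equal congruent and incongruent counts"
        ))
      }
    }

    n_top <- sum(sc$threat_position == "top")
    n_bot <- sum(sc$threat_position == "bottom")
    if (n_top != n_bot) {
      add(violation(
        "threat position balance", b, sprintf("%d top vs %d bottom", n_top, n_bot),
        "threat face equally often top and bottom"
      ))
    }

    n_e <- sum(blk$probe_letter == "E")
    n_f <- sum(blk$probe_letter == "F")
    if (abs(n_e - n_f) > nrow(blk) %% 2L) {
      add(violation(
        "probe letter balance", b, sprintf("%d E vs %d F", n_e, n_f),
        "letters E and F with equal frequency"
      ))
    }

    fil <- blk[blk$congruency == "filler", , drop = FALSE]
    if (nrow(fil) > 0) {
      f_top <- sum(fil$probe_position == "top")
      f_bot <- sum(fil$probe_position == "bottom")
      if (abs(f_top - f_bot) > nrow(fil) %% 2L) {
        add(violation(
          "filler probe balance", b, sprintf("%d top vs %d bottom", f_top, f_bot),
          "filler probe side balanced"
        ))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      constraint = character(0), block = integer(0),
      observed = character(0), expected = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' @export
print.abm_schedule <- function(x, ...) {
  tab <- table(x$trials$congruency)
  cat(sprintf(
    "Dot-probe schedule: %s (%s stimuli), %d trials in %d block(s)\n",
    x$variant, x$stimuli_mode, nrow(x$trials), nrow(x$blocks)
  ))
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a schedule's trial table to a delimited text file
#'
#' @param schedule an \code{abm_schedule}.
#' @param path output file path (comma-separated, header row).
#' @return the path, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "abm_schedule"))
  cols <- setdiff(SCHEDULE_COLUMNS, c("fixation_ms", "faces_ms", "iti_ms"))
  utils::write.csv(schedule$trials[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schedule trial table written by \code{write_schedule}
#'
#' @param path file path.
#' @param variant task variant the file contains.
#' @param stimuli_mode \code{"2D"} or \code{"3D"}.
#' @return an \code{abm_schedule}.
#' @export
read_schedule <- function(path, variant, stimuli_mode = "2D") {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(trials,
    setdiff(SCHEDULE_COLUMNS, c("fixation_ms", "faces_ms", "iti_ms")),
    what = sprintf("schedule file '%s'", path)
  )
  trials$fixation_ms <- 500
  trials$faces_ms <- 500
  trials$iti_ms <- 500
  sizes <- as.integer(table(trials$block))
  ends <- cumsum(sizes)
  structure(
    list(
      variant = variant, stimuli_mode = stimuli_mode,
      trials = trials[, SCHEDULE_COLUMNS],
      blocks = data.frame(
        block = sort(unique(trials$block)),
        start = ends - sizes + 1L, end = ends
      )
    ),
    class = "abm_schedule"
  )
}
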