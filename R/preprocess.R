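# Reaction-time cleaning and the attentional bias index.
#
# Measurement-phase trials are cleaned in three stages applied in order:
# (1) error trials are discarded; (2) trials with RT < 200 ms or > 2000 ms
# are discarded; (3) within each trial type (congruent / incongruent),
# trials further than 2 SD from that type's mean RT among the survivors of
# stages 1-2 are discarded, in a single pass. A participant whose pre- or
# post-measurement loses more than 20% of either trial type is flagged for
# exclusion. The bias index is the mean incongruent RT minus the mean
# congruent RT on the retained trials; positive values indicate vigilance
# toward threat.

#' Apply the trial-discard rules to one assessment
#'
#' Stages, in order: drop incorrect responses; drop responses outside
#' (\code{rt_min}, \code{rt_max}) (strict inequalities); then, separately for
#' congruent and incongruent trials, drop responses more than \code{sd_k}
#' sample standard deviations from that type's mean among the survivors of
#' the first two stages (single pass, no re-iteration). Filler
#' (neutral-neutral) trials carry no congruency: they are dropped from the
#' retained output and do not enter any per-type statistic.
#'
#' @param assessment data frame of trial results with columns
#'   \code{congruency}, \code{correct} and \code{rt_ms}.
#' @param rt_min,rt_max absolute RT bounds in ms (defaults 200 and 2000).
#' @param sd_k SD multiplier for the per-type trim (default 2).
#' @return list with \code{retained} (data frame of surviving scored
#'   trials), \code{report} (per trial type: input, discarded at each stage,
#'   retained, and discard fraction relative to the type's input count) and
#'   \code{warnings} (e.g. a type with fewer than 2 survivors skips the SD
#'   stage).
#' @examples
#' trials <- data.frame(
#'   congruency = rep(c("congruent", "incongruent"), each = 5),
#'   correct = TRUE, rt_ms = 500
#' )
#' filter_trials(trials)$report
#' @export
filter_trials <- function(assessment, rt_min = 200, rt_max = 2000, sd_k = 2) {
  check_columns(assessment, c("congruency", "correct", "rt_ms"), "assessment")
  scored <- assessment[assessment$congruency %in% c("congruent", "incongruent"), ,
    drop = FALSE
  ]
  if (nrow(scored) == 0) stop("assessment contains no scored trials", call. = FALSE)

  warnings <- character(0)
  types <- c("congruent", "incongruent")
  report <- data.frame(
    trial_type = types, n_input = 0L, discarded_error = 0L,
    discarded_bounds = 0L, discarded_sd = 0L, retained = 0L,
    discard_fraction = 0, stringsAsFactors = FALSE
  )
  keep_parts <- list()

  for (ti in seq_along(types)) {
    tt <- types[ti]
    sub <- scored[scored$congruency == tt, , drop = FALSE]
    n_in <- nrow(sub)

    s1 <- sub[sub$correct, , drop = FALSE]
    d_err <- n_in - nrow(s1)

    in_bounds <- s1$rt_ms > rt_min & s1$rt_ms < rt_max
    s2 <- s1[in_bounds, , drop = FALSE]
    d_bounds <- nrow(s1) - nrow(s2)

    if (nrow(s2) >= 2) {
      m <- mean(s2$rt_ms)
      s <- stats::sd(s2$rt_ms)
      ok <- abs(s2$rt_ms - m) <= sd_k * s
      s3 <- s2[ok, , drop = FALSE]
    } else {
      if (nrow(s2) > 0 || n_in > 0) {
        warnings <- c(warnings, sprintf(
          "%s: %d survivor(s) after bounds stage; SD trim skipped", tt, nrow(s2)
        ))
      }
      s3 <- s2
    }
    d_sd <- nrow(s2) - nrow(s3)

    report$n_input[ti] <- n_in
    report$discarded_error[ti] <- d_err
    report$discarded_bounds[ti] <- d_bounds
    report$discarded_sd[ti] <- d_sd
    report$retained[ti] <- nrow(s3)
    report$discard_fraction[ti] <- if (n_in > 0) (n_in - nrow(s3)) / n_in else 0
    keep_parts[[tt]] <- s3
  }

  retained <- do.call(rbind, keep_parts)
  rownames(retained) <- NULL
  list(retained = retained, report = report, warnings = warnings)
}

#' Flag a participant for exclusion on excessive trial loss
#'
#' A participant is excluded when, in either the pre- or the post-training
#' measurement, strictly more than \code{threshold} of the trials of at
#' least one trial type were discarded.
#'
#' @param pre_report,post_report cleaning reports from
#'   \code{\link{filter_trials}} for the two measurement assessments.
#' @param threshold discard-fraction threshold (default 0.20, strict).
#' @return list with \code{excluded} (logical) and \code{reasons}
#'   (character vector like \code{"pre/congruent"}; empty when retained).
#' @export
exclusion_flag <- function(pre_report, post_report, threshold = 0.20) {
  cells <- rbind(
    data.frame(phase = "pre", pre_report, stringsAsFactors = FALSE),
    data.frame(phase = "post", post_report, stringsAsFactors = FALSE)
  )
  bad <- cells$discard_fraction > threshold
  list(
    excluded = any(bad),
    reasons = paste(cells$phase[bad], cells$trial_type[bad], sep = "/")
  )
}

#' Attentional bias index
#'
#' Mean retained incongruent RT minus mean retained congruent RT, in ms.
#' Positive values indicate faster responses to probes replacing the threat
#' face (vigilance); negative values faster responses at the neutral
#' location.
#'
#' @param retained data frame of retained scored trials (columns
#'   \code{congruency}, \code{rt_ms}), e.g. from \code{\link{filter_trials}}.
#' @return list of class \code{bias_index}: \code{value} (ms),
#'   \code{n_congruent}, \code{n_incongruent}.
#' @examples
#' bias_index(data.frame(
#'   congruency = c("congruent", "congruent", "incongruent", "incongruent"),
#'   rt_ms = c(500, 510, 520, 530)
#' ))$value # +20
#' @export
bias_index <- function(retained) {
  check_columns(retained, c("congruency", "rt_ms"), "retained trials")
  con <- retained$rt_ms[retained$congruency == "congruent"]
  inc <- retained$rt_ms[retained$congruency == "incongruent"]
  if (length(con) == 0 || length(inc) == 0) {
    stop("bias index undefined: need at least one retained trial of each type",
      call. = FALSE
    )
  }
  structure(
    list(
      value = mean(inc) - mean(con),
      n_congruent = length(con), n_incongruent = length(inc)
    ),
    class = "bias_index"
  )
}

#' @export
print.bias_index <- function(x, ...) {
  cat(sprintf(
    "Bias index: %+.2f ms (%d congruent, %d incongruent retained)\n",
    x$value, x$n_congruent, x$n_incongruent
  ))
  invisible(x)
}

#' Clean a cohort's measurement trials and tabulate bias indices
#'
#' Applies \code{\link{filter_trials}} to every participant's pre and post
#' measurement assessments, flags exclusions via
#' \code{\link{exclusion_flag}}, and computes the bias index per phase.
#' Training-phase trials are ignored: bias is only measured, and cleaned,
#' on the measurement phases.
#'
#' @param trials trial table in the cohort export schema (columns
#'   \code{participant_id}, \code{phase}, \code{congruency}, \code{correct},
#'   \code{rt_ms}; extra columns pass through).
#' @param rt_min,rt_max,sd_k cleaning parameters, see
#'   \code{\link{filter_trials}}.
#' @param exclude_threshold discard-fraction exclusion threshold
#'   (default 0.20).
#' @return list with \code{bias} (data frame: participant_id, phase,
#'   bias_ms, n_con, n_inc, excluded, reasons), \code{reports} (named list
#'   of per-participant cleaning reports) and \code{retained} (data frame of
#'   all retained measurement trials with participant_id and phase).
#' @export
compute_bias_table <- function(trials, rt_min = 200, rt_max = 2000, sd_k = 2,
                               exclude_threshold = 0.20) {
  check_columns(trials, c("participant_id", "phase", "congruency", "correct", "rt_ms"),
    what = "trial table"
  )
  meas <- trials[trials$phase %in% c("pre", "post"), , drop = FALSE]
  ids <- unique(meas$participant_id)

  bias_rows <- vector("list", length(ids))
  retained_rows <- vector("list", length(ids))
  reports <- vector("list", length(ids))
  names(reports) <- ids

  for (k in seq_along(ids)) {
    id <- ids[k]
    pre <- meas[meas$participant_id == id & meas$phase == "pre", , drop = FALSE]
    post <- meas[meas$participant_id == id & meas$phase == "post", , drop = FALSE]
    f_pre <- filter_trials(pre, rt_min, rt_max, sd_k)
    f_post <- filter_trials(post, rt_min, rt_max, sd_k)
    excl <- exclusion_flag(f_pre$report, f_post$report, exclude_threshold)

    phase_bias <- function(f, phase) {
      b <- bias_index(f$retained)
      data.frame(
        participant_id = id, phase = phase, bias_ms = b$value,
        n_con = b$n_congruent, n_inc = b$n_incongruent,
        excluded = excl$excluded,
        reasons = paste(excl$reasons, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
    bias_rows[[k]] <- rbind(phase_bias(f_pre, "pre"), phase_bias(f_post, "post"))
    retained_rows[[k]] <- rbind(f_pre$retained, f_post$retained)
    reports[[id]] <- list(pre = f_pre$report, post = f_post$report)
  }

  list(
    bias = do.call(rbind, bias_rows),
    reports = reports,
    retained = do.call(rbind, retained_rows)
  )
}
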