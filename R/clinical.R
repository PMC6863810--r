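# Jacobson-Truax reliable and clinically significant change.
#
# SE_M = SD_baseline * sqrt(1 - reliability); S_diff = sqrt(2 * SE_M^2);
# reliable change requires |change| >= 1.96 * S_diff ("at least": the
# boundary counts). Criterion A places the recovery cutoff at the
# dysfunctional sample's baseline mean minus 1.96 SD (for instruments where
# lower is better); scoring strictly below the cutoff plus reliable
# improvement classifies a participant as recovered.

#' Jacobson-Truax psychometric constants
#'
#' Computes SE_M, S_diff, the reliable-change threshold (1.96 * S_diff) and,
#' optionally, the criterion-A cutoff from a baseline sample and a
#' reliability estimate. The cutoff is reported both raw
#' (\code{mean - 1.96 * SD} when lower scores are better) and rounded to the
#' instrument's integer scale; classification uses the rounded value by
#' default.
#'
#' @param baseline_scores numeric vector of baseline scores (>= 2 values)
#'   or a precomputed summary \code{list(mean =, sd =, n =)} such as from
#'   \code{\link{pooled_moments}}.
#' @param reliability reliability coefficient < 1 (e.g. Cronbach's alpha or
#'   a split-half estimate).
#' @param with_cutoff compute the criterion-A cutoff?
#' @param lower_is_better do lower scores indicate improvement? (TRUE for
#'   both the social-anxiety total and the bias index).
#' @return object of class \code{jt_params}: \code{baseline_mean},
#'   \code{baseline_sd}, \code{n}, \code{reliability}, \code{se_m},
#'   \code{s_diff}, \code{rc_threshold}, \code{cutoff_raw},
#'   \code{cutoff} (rounded; NA when not requested), \code{lower_is_better}.
#' @examples
#' p <- jt_params(list(mean = 69.7, sd = 19.3, n = 95), reliability = 0.92)
#' round(p$s_diff, 1) # 7.7
#' @export
jt_params <- function(baseline_scores, reliability, with_cutoff = TRUE,
                      lower_is_better = TRUE) {
  if (reliability >= 1) stop("reliability must be < 1", call. = FALSE)
  if (is.list(baseline_scores)) {
    m <- baseline_scores$mean
    s <- baseline_scores$sd
    n <- baseline_scores$n
  } else {
    if (length(baseline_scores) < 2) {
      stop("need at least 2 baseline scores", call. = FALSE)
    }
    m <- mean(baseline_scores)
    s <- stats::sd(baseline_scores)
    n <- length(baseline_scores)
  }
  if (s == 0) stop("degenerate baseline: SD is zero", call. = FALSE)
  se_m <- s * sqrt(1 - reliability)
  s_diff <- sqrt(2 * se_m^2)
  cutoff_raw <- if (with_cutoff) {
    if (lower_is_better) m - 1.96 * s else m + 1.96 * s
  } else {
    NA_real_
  }
  structure(
    list(
      baseline_mean = m, baseline_sd = s, n = n, reliability = reliability,
      se_m = se_m, s_diff = s_diff, rc_threshold = 1.96 * s_diff,
      cutoff_raw = cutoff_raw, cutoff = round(cutoff_raw),
      lower_is_better = lower_is_better
    ),
    class = "jt_params"
  )
}

#' @export
print.jt_params <- function(x, ...) {
  cat(sprintf(
    "Jacobson-Truax constants (baseline n = %d, mean = %.2f, SD = %.2f, reliability = %.2f)\n",
    x$n, x$baseline_mean, x$baseline_sd, x$reliability
  ))
  cat(sprintf(
    "  SE_M = %.3f, S_diff = %.3f, reliable-change threshold = %.3f\n",
    x$se_m, x$s_diff, x$rc_threshold
  ))
  if (!is.na(x$cutoff_raw)) {
    cat(sprintf("  criterion-A cutoff = %.3f (rounded: %d)\n", x$cutoff_raw, x$cutoff))
  }
  invisible(x)
}

#' Reliable-change classification
#'
#' Classifies change scores against the reliable-change threshold. With
#' \code{lower_is_better}, a change of at least the threshold in the
#' negative direction is \code{"improved"}, in the positive direction
#' \code{"deteriorated"}, otherwise \code{"unchanged"}. The boundary is
#' inclusive ("at least 1.96 times the S_diff").
#'
#' @param change numeric vector of follow-up minus baseline scores.
#' @param rc_threshold reliable-change threshold (1.96 * S_diff).
#' @param lower_is_better direction of improvement.
#' @return character vector in \{improved, unchanged, deteriorated\}.
#' @export
rci_classify <- function(change, rc_threshold, lower_is_better = TRUE) {
  stopifnot(rc_threshold > 0)
  d <- if (lower_is_better) change else -change
  ifelse(d <= -rc_threshold, "improved",
    ifelse(d >= rc_threshold, "deteriorated", "unchanged")
  )
}

#' Five-category Jacobson-Truax classification
#'
#' Combines reliable change with the criterion-A cutoff: reliable
#' improvement and a follow-up score past the cutoff (strictly, "lower
#' than") is \code{"recovered"}; past the cutoff without reliable change is
#' \code{"non-reliably recovered"}; reliable improvement short of the cutoff
#' is \code{"improved"}; reliable change in the wrong direction is
#' \code{"deteriorated"}; anything else is \code{"unchanged"}.
#'
#' @param baseline,followup numeric vectors of scores (recycled to common
#'   length).
#' @param params a \code{\link{jt_params}} with a cutoff.
#' @param use_rounded_cutoff compare against the integer-rounded cutoff
#'   (default) or the raw value.
#' @return character vector of categories.
#' @examples
#' p <- jt_params(list(mean = 69.7, sd = 19.3, n = 95), 0.92)
#' jt_classify(71, 30, p) # recovered
#' @export
jt_classify <- function(baseline, followup, params, use_rounded_cutoff = TRUE) {
  stopifnot(inherits(params, "jt_params"))
  if (is.na(params$cutoff_raw)) {
    stop("jt_classify needs params computed with with_cutoff = TRUE", call. = FALSE)
  }
  cutoff <- if (use_rounded_cutoff) params$cutoff else params$cutoff_raw
  change <- followup - baseline
  rc <- rci_classify(change, params$rc_threshold, params$lower_is_better)
  below <- if (params$lower_is_better) followup < cutoff else followup > cutoff
  ifelse(rc == "improved" & below, "recovered",
    ifelse(rc == "unchanged" & below, "non-reliably recovered",
      ifelse(rc == "improved", "improved",
        ifelse(rc == "deteriorated", "deteriorated", "unchanged")
      )
    )
  )
}

JT_CATEGORIES <- c(
  "recovered", "non-reliably recovered", "improved", "unchanged", "deteriorated"
)

#' Classify every participant at every available follow-up
#'
#' Compares each follow-up timepoint against baseline (timepoint 0) with
#' \code{\link{jt_classify}}. Participants missing a follow-up contribute no
#' row at that timepoint; participants missing a baseline are skipped.
#'
#' @param scores long data frame with columns \code{participant_id},
#'   \code{timepoint} (0 = baseline) and \code{total}; an optional
#'   \code{group} column is carried into the counts.
#' @param params a \code{\link{jt_params}} with a cutoff.
#' @param timepoints follow-up timepoints to classify (default 1:3).
#' @param use_rounded_cutoff see \code{\link{jt_classify}}.
#' @return list with \code{classifications} (participant_id, timepoint,
#'   baseline, followup, change, category) and \code{counts} (category by
#'   timepoint, plus by group when available).
#' @export
classify_cohort <- function(scores, params, timepoints = 1:3,
                            use_rounded_cutoff = TRUE) {
  check_columns(scores, c("participant_id", "timepoint", "total"), "score table")
  base <- scores[scores$timepoint == 0, , drop = FALSE]
  baseline <- stats::setNames(base$total, base$participant_id)

  rows <- list()
  for (tp in timepoints) {
    fu <- scores[scores$timepoint == tp, , drop = FALSE]
    fu <- fu[fu$participant_id %in% names(baseline), , drop = FALSE]
    if (nrow(fu) == 0) next
    b <- baseline[fu$participant_id]
    cat_ <- jt_classify(b, fu$total, params, use_rounded_cutoff)
    row <- data.frame(
      participant_id = fu$participant_id, timepoint = tp,
      baseline = as.numeric(b), followup = fu$total,
      change = fu$total - as.numeric(b), category = cat_,
      stringsAsFactors = FALSE
    )
    if ("group" %in% names(fu)) row$group <- fu$group
    rows[[length(rows) + 1L]] <- row
  }
  cls <- do.call(rbind, rows)
  rownames(cls) <- NULL
  cls$category <- factor(cls$category, levels = JT_CATEGORIES)
  counts <- table(timepoint = cls$timepoint, category = cls$category)
  by_group <- if ("group" %in% names(cls)) {
    table(group = cls$group, timepoint = cls$timepoint, category = cls$category)
  } else {
    NULL
  }
  list(classifications = cls, counts = counts, counts_by_group = by_group)
}
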