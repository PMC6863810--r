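# End-to-end pipeline: cleaning -> psychometrics -> clinical change ->
# inference, with delimited-text I/O and a reproducibility manifest.

#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the analysis pipeline. Defaults equal
#' the reference analysis settings: RT bounds 200/2000 ms, 2 SD trim, 20%
#' exclusion threshold, 5000 reliability splits, 1.96 reliable-change
#' multiplier (implicit in the Jacobson-Truax constants).
#'
#' @param seed top-level integer seed; per-stage streams are derived from it.
#' @param rt_min,rt_max,sd_k trial cleaning parameters.
#' @param exclude_threshold participant exclusion threshold.
#' @param n_splits reliability splits.
#' @param correction_order Spearman-Brown order, see
#'   \code{\link{splithalf_bias_reliability}}.
#' @param jt_reliability reliability for the questionnaire Jacobson-Truax
#'   constants; \code{NULL} computes Cronbach's alpha from baseline items.
#' @param use_rounded_cutoff integer cutoff for classification?
#' @param out_dir optional directory for the output tables.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, rt_min = 200, rt_max = 2000, sd_k = 2,
                       exclude_threshold = 0.20, n_splits = 5000L,
                       correction_order = "correct-first",
                       jt_reliability = NULL, use_rounded_cutoff = TRUE,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(
    rt_min >= 0, rt_max > rt_min, sd_k > 0,
    exclude_threshold > 0, exclude_threshold < 1, n_splits >= 1
  )
  structure(cfg, class = "run_config")
}

#' Read a trial table exported by the cohort simulator (or real data in the
#' same schema)
#'
#' @param path comma-separated file with header.
#' @return data frame; errors name any missing required column.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "phase", "congruency", "correct", "rt_ms"),
    what = sprintf("trials file '%s'", path)
  )
  df
}

#' Read a questionnaire table (long format)
#'
#' @param path comma-separated file with header.
#' @return data frame; errors name any missing required column.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "timepoint", "total"),
    what = sprintf("scores file '%s'", path)
  )
  df
}

# Dummy-code group labels: condition (mock = 0 / active = 1) and stimuli
# (2D = 0 / 3D = 1).
group_dummies <- function(group) {
  data.frame(
    condition = as.integer(grepl("active", group)),
    stimuli = as.integer(grepl("3D", group))
  )
}

#' Build the long score table for the mixed-model ladder
#'
#' @param scores long questionnaire table (participant_id, timepoint,
#'   total).
#' @param groups data frame mapping participant_id to group label.
#' @return data frame with participant_id, time, condition, stimuli, score.
#' @export
make_long_scores <- function(scores, groups) {
  check_columns(scores, c("participant_id", "timepoint", "total"), "score table")
  check_columns(groups, c("participant_id", "group"), "group table")
  m <- merge(scores[, c("participant_id", "timepoint", "total")], groups,
    by = "participant_id"
  )
  cbind(
    data.frame(
      participant_id = m$participant_id, time = m$timepoint,
      score = m$total, stringsAsFactors = FALSE
    ),
    group_dummies(m$group)
  )
}

#' Run the full analysis pipeline
#'
#' Executes cleaning, psychometrics, clinical-change classification and the
#' inferential analyses on a trial table and questionnaire table (data
#' frames or file paths), mirroring the reference trial's analysis plan:
#' per-participant bias indices after the three-stage cleaning; split-half
#' reliability of the pre-training bias index; Cronbach's alpha of the
#' baseline questionnaire items; Jacobson-Truax constants and five-category
#' classification for the questionnaire, reliable-change-only
#' classification for the bias index; bias-anxiety correlations; the 2 x 4
#' mixed ANOVA on bias; and the mixed-model ladder with AIC ordering and a
#' likelihood-ratio test of the AIC-best model against the full model.
#'
#' @param config a \code{\link{run_config}}.
#' @param trials trial table or path (schema of \code{\link{read_trials}}).
#' @param scores questionnaire table or path; item columns
#'   (\code{item_1}...) are optional and only needed when
#'   \code{jt_reliability} is NULL.
#' @param groups data frame mapping participant_id to group; required for
#'   the ANOVA and mixed models.
#' @return list of class \code{abm_run} with elements \code{bias},
#'   \code{exclusions}, \code{reliability}, \code{alpha}, \code{jt_lsas}
#'   (params + classifications + counts), \code{jt_bias} (params +
#'   reliable-change table), \code{correlations}, \code{anova},
#'   \code{models}, \code{lrt}, \code{manifest}.
#' @export
run_pipeline <- function(config, trials, scores, groups) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(scores)) scores <- read_scores(scores)
  check_columns(groups, c("participant_id", "group"), "group table")
  seeds <- derive_seeds(config$seed, 2L)

  # --- preprocess ---
  cleaned <- compute_bias_table(trials,
    rt_min = config$rt_min, rt_max = config$rt_max, sd_k = config$sd_k,
    exclude_threshold = config$exclude_threshold
  )
  bias <- merge(cleaned$bias, groups, by = "participant_id")
  excluded_ids <- unique(bias$participant_id[bias$excluded])

  # --- psychometrics ---
  pre_retained <- cleaned$retained[cleaned$retained$phase == "pre" &
    !(cleaned$retained$participant_id %in% excluded_ids), , drop = FALSE]
  reliability <- splithalf_bias_reliability(pre_retained,
    n_splits = config$n_splits, seed = seeds[1],
    order = config$correction_order
  )

  item_cols <- grep("^item_", names(scores), value = TRUE)
  alpha <- NULL
  jt_rel <- config$jt_reliability
  if (is.null(jt_rel)) {
    if (length(item_cols) == 0) {
      stop("jt_reliability not given and score table has no item_* columns",
        call. = FALSE
      )
    }
    alpha <- cronbach_alpha(scores[scores$timepoint == 0, item_cols])
    jt_rel <- alpha$value
  }

  # --- clinical change: questionnaire (full Jacobson-Truax) ---
  base_scores <- scores$total[scores$timepoint == 0]
  params_lsas <- jt_params(base_scores, jt_rel,
    with_cutoff = TRUE, lower_is_better = TRUE
  )
  scores_g <- merge(scores, groups, by = "participant_id")
  jt_lsas <- classify_cohort(scores_g, params_lsas,
    timepoints = sort(unique(scores$timepoint[scores$timepoint > 0])),
    use_rounded_cutoff = config$use_rounded_cutoff
  )
  jt_lsas$params <- params_lsas

  # --- clinical change: bias (reliable-change part only) ---
  nonexcl <- bias[!bias$excluded, , drop = FALSE]
  pre_b <- nonexcl[nonexcl$phase == "pre", c("participant_id", "bias_ms")]
  post_b <- nonexcl[nonexcl$phase == "post", c("participant_id", "bias_ms")]
  bb <- merge(pre_b, post_b, by = "participant_id", suffixes = c("_pre", "_post"))
  params_bias <- jt_params(bb$bias_ms_pre, reliability$value,
    with_cutoff = FALSE, lower_is_better = TRUE
  )
  bias_change <- data.frame(
    participant_id = bb$participant_id,
    change = bb$bias_ms_post - bb$bias_ms_pre,
    stringsAsFactors = FALSE
  )
  bias_change$category <- rci_classify(bias_change$change, params_bias$rc_threshold)
  jt_bias <- list(
    params = params_bias, classifications = bias_change,
    counts = table(factor(bias_change$category,
      levels = c("improved", "unchanged", "deteriorated")
    ))
  )

  # --- inference ---
  lsas0 <- scores[scores$timepoint == 0, c("participant_id", "total")]
  lsas1 <- scores[scores$timepoint == 1, c("participant_id", "total")]
  ls <- merge(lsas0, lsas1, by = "participant_id", suffixes = c("_0", "_1"))
  cw <- merge(bb, ls, by = "participant_id")
  correlations <- list(
    pre = correlate(cw$bias_ms_pre, cw$total_0),
    post = correlate(cw$bias_ms_post, cw$total_1),
    change = correlate(
      cw$bias_ms_post - cw$bias_ms_pre,
      cw$total_1 - cw$total_0
    )
  )

  anova <- rm_anova_bias(bias)

  long <- make_long_scores(scores, groups)
  models <- fit_lmm_set(long)
  best <- models[[1]]
  lrt <- if (best$model_id != "full" && !is.null(models$full) &&
    is.null(models$full$error) && is.null(best$error)) {
    likelihood_ratio(best, models$full)
  } else {
    NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("abmprobe")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    n_participants = length(unique(trials$participant_id)),
    n_excluded = length(excluded_ids),
    excluded = excluded_ids,
    reliability_seed = seeds[1]
  )

  out <- structure(
    list(
      bias = bias, exclusions = excluded_ids, reliability = reliability,
      alpha = alpha, jt_lsas = jt_lsas, jt_bias = jt_bias,
      correlations = correlations, anova = anova, models = models,
      lrt = lrt, manifest = manifest
    ),
    class = "abm_run"
  )

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(bias, file.path(dir, "bias.csv"), row.names = FALSE)
    utils::write.csv(jt_lsas$classifications, file.path(dir, "jt_classifications.csv"),
      row.names = FALSE
    )
    utils::write.csv(model_comparison(models), file.path(dir, "model_comparison.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.abm_run <- function(x, ...) {
  cat("ABM dot-probe pipeline run\n")
  cat(sprintf(
    "  participants: %d (%d excluded for trial loss)\n",
    x$manifest$n_participants, x$manifest$n_excluded
  ))
  cat(sprintf(
    "  split-half reliability (pre): %.3f (%d splits)\n",
    x$reliability$value, x$reliability$n_splits
  ))
  if (!is.null(x$alpha)) {
    cat(sprintf("  Cronbach's alpha (baseline items): %.3f\n", x$alpha$value))
  }
  cat(sprintf(
    "  questionnaire S_diff: %.2f, cutoff: %d\n",
    x$jt_lsas$params$s_diff, x$jt_lsas$params$cutoff
  ))
  cat(sprintf("  bias S_diff: %.2f ms\n", x$jt_bias$params$s_diff))
  cat(sprintf("  AIC-best model: %s\n", x$models[[1]]$model_id))
  if (!is.null(x$lrt)) {
    cat(sprintf(
      "  LRT best vs full: chi2 = %.2f, df = %d, p = %.3f\n",
      x$lrt$statistic, x$lrt$df, x$lrt$p
    ))
  }
  invisible(x)
}
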