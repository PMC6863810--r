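# Inferential layer: Pearson correlations between bias and anxiety, the
# 2 x 4 mixed-design ANOVA on the bias index, and the dummy-coded linear
# mixed-effects model ladder compared by AIC and likelihood-ratio test.

#' Pearson correlation with pairwise deletion
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   are dropped.
#' @return list with \code{r}, \code{p} (two-sided), \code{n} (complete
#'   pairs).
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mixed-design ANOVA on pre/post bias indices
#'
#' The 2 (time: pre vs post, within subjects) x 4 (group, between subjects)
#' repeated-measures ANOVA. Group is tested against the between-participant
#' stratum; time and the time-by-group interaction against the
#' within-participant stratum. Only participants with both phases present
#' (and not flagged excluded) enter.
#'
#' @param bias data frame with columns \code{participant_id}, \code{phase}
#'   (\code{"pre"}/\code{"post"}), \code{bias_ms}, \code{group} and
#'   optionally \code{excluded}.
#' @return data frame with one row per effect (\code{group}, \code{time},
#'   \code{time:group}): \code{df1}, \code{df2}, \code{F}, \code{p},
#'   \code{degenerate} (TRUE when a residual stratum has zero variance and
#'   the F ratio is undefined).
#' @export
rm_anova_bias <- function(bias) {
  check_columns(bias, c("participant_id", "phase", "bias_ms", "group"), "bias table")
  if ("excluded" %in% names(bias)) bias <- bias[!bias$excluded, , drop = FALSE]
  wide_ok <- intersect(
    bias$participant_id[bias$phase == "pre"],
    bias$participant_id[bias$phase == "post"]
  )
  d <- bias[bias$participant_id %in% wide_ok & bias$phase %in% c("pre", "post"), ,
    drop = FALSE
  ]
  grp_n <- table(unique(d[, c("participant_id", "group")])$group)
  if (any(grp_n < 2)) {
    stop("every group needs at least 2 participants with complete pre/post data",
      call. = FALSE
    )
  }
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$time <- factor(d$phase, levels = c("pre", "post"))

  fit <- stats::aov(bias_ms ~ group * time + Error(participant_id), data = d)
  sm <- summary(fit)
  between <- sm[["Error: participant_id"]][[1]]
  within <- sm[["Error: Within"]][[1]]

  # residual variation indistinguishable from rounding error makes the F
  # ratio meaningless (e.g. all bias values identical)
  scale2 <- mean(d$bias_ms^2) + 1
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    res <- grep("Residuals", rownames(tab))
    f <- tab[i, "F value"]
    data.frame(
      effect = term, df1 = tab[i, "Df"], df2 = tab[res, "Df"],
      F = f, p = tab[i, "Pr(>F)"],
      degenerate = !is.finite(f) || tab[res, "Mean Sq"] < 1e-12 * scale2,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    pick(between, "group"),
    pick(within, "time"),
    pick(within, "group:time")
  )
  out$effect[out$effect == "group:time"] <- "time:group"
  rownames(out) <- NULL
  out
}

#' Default candidate model ladder
#'
#' The fixed-effect formulas fitted by \code{\link{fit_lmm_set}} when no
#' ladder is supplied: every additive and interactive combination of time,
#' training condition and stimulus dimensionality from the intercept-only
#' model to the full three-way interaction.
#'
#' @return named list of formulas in \code{score ~ ...} form.
#' @export
default_lmm_ladder <- function() {
  list(
    null = score ~ 1,
    time = score ~ time,
    time_condition = score ~ time + condition,
    time_x_condition = score ~ time * condition,
    time_stimuli = score ~ time + stimuli,
    time_x_stimuli = score ~ time * stimuli,
    additive = score ~ time + condition + stimuli,
    full = score ~ time * condition * stimuli
  )
}

#' Fit the longitudinal mixed-model ladder
#'
#' Fits a set of candidate linear mixed-effects models for the questionnaire
#' trajectory, from intercept-only up to the full three-way interaction of
#' time (coded 0--3), training condition (0 mock / 1 active) and stimulus
#' dimensionality (0 2D / 1 3D). Every model carries a random intercept and
#' a random time slope per participant and is fitted by maximum likelihood
#' (so AICs and likelihood-ratio tests across fixed-effect structures are
#' comparable). Participants with missing follow-ups contribute their
#' available rows; nothing is imputed. Degrees of freedom for the
#' fixed-effect t tests follow the containment method (within- vs
#' between-participant terms).
#'
#' @param long data frame with columns \code{participant_id}, \code{time}
#'   (integer 0--3), \code{condition} (0/1), \code{stimuli} (0/1) and
#'   \code{score}; rows with a missing score are dropped.
#' @param ladder named list of fixed-effect formulas in \code{score ~ ...}
#'   form; defaults to the eight-model ladder above.
#' @return object of class \code{lmm_set}: list of per-model fits (each with
#'   \code{model_id}, \code{k}, \code{logLik}, \code{AIC},
#'   \code{fixed_effects} table with Estimate/SE/DF/t/p, \code{fit} the
#'   underlying \code{nlme::lme} object, or \code{error} on convergence
#'   failure), ordered by AIC (failed fits last).
#' @export
fit_lmm_set <- function(long, ladder = default_lmm_ladder()) {
  check_columns(long, c("participant_id", "time", "score"), "long score table")
  needs_cond <- any(vapply(ladder, function(f) "condition" %in% all.vars(f), logical(1)))
  needs_stim <- any(vapply(ladder, function(f) "stimuli" %in% all.vars(f), logical(1)))
  if (needs_cond) check_columns(long, "condition", "long score table")
  if (needs_stim) check_columns(long, "stimuli", "long score table")
  long <- long[!is.na(long$score), , drop = FALSE]
  long$participant_id <- factor(long$participant_id)

  fits <- lapply(names(ladder), function(id) {
    fml <- ladder[[id]]
    res <- tryCatch(
      {
        fit <- tryCatch(
          nlme::lme(
            fixed = fml, random = ~ time | participant_id,
            data = long, method = "ML",
            control = nlme::lmeControl(maxIter = 200, msMaxIter = 200)
          ),
          # retry with the alternative optimizer before reporting failure
          error = function(e) {
            nlme::lme(
              fixed = fml, random = ~ time | participant_id,
              data = long, method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200)
            )
          }
        )
        tt <- summary(fit)$tTable
        fe <- data.frame(
          term = rownames(tt), estimate = tt[, "Value"],
          se = tt[, "Std.Error"], df = tt[, "DF"],
          t = tt[, "t-value"], p = tt[, "p-value"],
          stringsAsFactors = FALSE
        )
        rownames(fe) <- NULL
        ll <- stats::logLik(fit)
        list(
          model_id = id, formula = fml, k = attr(ll, "df"),
          logLik = as.numeric(ll), AIC = stats::AIC(fit),
          fixed_effects = fe, fit = fit, error = NULL
        )
      },
      error = function(e) {
        list(
          model_id = id, formula = fml, k = NA_integer_,
          logLik = NA_real_, AIC = NA_real_, fixed_effects = NULL,
          fit = NULL, error = conditionMessage(e)
        )
      }
    )
    res
  })
  names(fits) <- names(ladder)
  aics <- vapply(fits, function(f) ifelse(is.na(f$AIC), Inf, f$AIC), numeric(1))
  structure(fits[order(aics)], class = "lmm_set")
}

#' Model comparison table for a fitted ladder
#'
#' @param fits an \code{lmm_set} from \code{\link{fit_lmm_set}}.
#' @return data frame: \code{model_id}, \code{k}, \code{logLik}, \code{AIC},
#'   \code{dAIC} (difference from the best model), \code{converged}.
#' @export
model_comparison <- function(fits) {
  stopifnot(inherits(fits, "lmm_set"))
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      model_id = f$model_id, k = f$k, logLik = f$logLik, AIC = f$AIC,
      converged = is.null(f$error), stringsAsFactors = FALSE
    )
  }))
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  tab[, c("model_id", "k", "logLik", "AIC", "dAIC", "converged")]
}

#' @export
print.lmm_set <- function(x, ...) {
  cat("Linear mixed-model ladder (ML, random intercept + time slope):\n")
  print(model_comparison(x), digits = 6)
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' \code{statistic = 2 (logLik_full - logLik_nested)}, with degrees of
#' freedom equal to the difference in estimated parameter counts, referred
#' to a chi-square distribution. Both models must be ML fits with the same
#' random structure, and the nested model's fixed-effect terms must be a
#' subset of the full model's.
#'
#' @param nested,full elements of an \code{lmm_set} (or lists with
#'   \code{formula}, \code{k}, \code{logLik}).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
likelihood_ratio <- function(nested, full) {
  tn <- attr(stats::terms(nested$formula), "term.labels")
  tf <- attr(stats::terms(full$formula), "term.labels")
  if (!all(tn %in% tf)) {
    stop("models are not nested: nested model has terms absent from the full model",
      call. = FALSE
    )
  }
  df <- full$k - nested$k
  if (df < 0) stop("full model has fewer parameters than the nested model", call. = FALSE)
  stat <- 2 * (full$logLik - nested$logLik)
  p <- if (df == 0) as.numeric(stat <= 0) else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
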