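# Internal reliability: permutation split-half reliability of the bias
# index with Spearman-Brown correction, and Cronbach's alpha.

#' Spearman-Brown correction of a half-test correlation
#'
#' Projects the correlation between two test halves to the reliability of
#' the full-length test: \code{2 r / (1 + r)}. Applied as-is to negative
#' correlations (the formula is defined on (-1, 1]); no truncation at zero.
#'
#' @param r_half numeric vector of half-test correlations in (-1, 1].
#' @return corrected reliability, same length as \code{r_half}.
#' @examples
#' spearman_brown(1 / 3) # 0.5
#' @export
spearman_brown <- function(r_half) {
  if (any(r_half <= -1 | r_half > 1, na.rm = TRUE)) {
    stop("r_half must lie in (-1, 1]", call. = FALSE)
  }
  2 * r_half / (1 + r_half)
}

# Row-wise Pearson correlation of two n_splits x n_participants matrices.
row_pearson <- function(a, b) {
  am <- a - rowMeans(a)
  bm <- b - rowMeans(b)
  rowSums(am * bm) / sqrt(rowSums(am^2) * rowSums(bm^2))
}

# For one RT vector, draw `n_splits` random near-equal partitions and return
# the two half means as an n_splits x 2 matrix. Odd counts assign the extra
# trial to a random half per split. Vectorized: within-row ranks of a
# uniform key matrix pick each split's first half.
split_half_means <- function(x, n_splits) {
  n <- length(x)
  keys <- runif(n_splits * n)
  # within-row ranks via one global rank over row-offset keys
  keys <- keys + rep(seq_len(n_splits) - 1L, each = n)
  rk <- matrix(rank(keys), nrow = n_splits, byrow = TRUE) -
    (seq_len(n_splits) - 1L) * n
  k <- n %/% 2L + if (n %% 2L == 1L) stats::rbinom(n_splits, 1L, 0.5) else 0L
  half1 <- (rk <= k) %*% x
  total <- sum(x)
  cbind(half1 / k, (total - half1) / (n - k))
}

#' Split-half reliability of the bias index
#'
#' For each of \code{n_splits} random splits: every participant's retained
#' congruent trials are partitioned into two near-equal halves, likewise the
#' incongruent trials (splits stratify by trial type so both halves yield a
#' bias index); the two half bias indices are computed per participant; the
#' Pearson correlation of the half-1 versus half-2 indices across
#' participants is taken and Spearman-Brown corrected. The reported estimate
#' is the mean over splits (with \code{order = "average-first"}, the
#' correction is instead applied once to the mean correlation).
#'
#' @param trials data frame of cleaned, retained measurement trials with
#'   columns \code{participant_id}, \code{congruency}, \code{rt_ms}
#'   (typically the pre-training assessment).
#' @param n_splits number of random splits (default 5000).
#' @param seed integer seed.
#' @param order \code{"correct-first"} (Spearman-Brown per split, then
#'   average; the default) or \code{"average-first"}.
#' @param keep_splits retain the per-split corrected values?
#' @return object of class \code{reliability_estimate} with fields
#'   \code{method}, \code{value}, \code{n_splits}, \code{n_participants},
#'   \code{dropped} (participants with too few trials of a type) and
#'   optionally \code{per_split}.
#' @export
splithalf_bias_reliability <- function(trials, n_splits = 5000L, seed = 1L,
                                       order = c("correct-first", "average-first"),
                                       keep_splits = FALSE) {
  order <- match.arg(order)
  check_columns(trials, c("participant_id", "congruency", "rt_ms"), "trial table")
  scored <- trials[trials$congruency %in% c("congruent", "incongruent"), , drop = FALSE]
  ids <- unique(scored$participant_id)

  con <- split(scored$rt_ms[scored$congruency == "congruent"],
    scored$participant_id[scored$congruency == "congruent"]
  )
  inc <- split(scored$rt_ms[scored$congruency == "incongruent"],
    scored$participant_id[scored$congruency == "incongruent"]
  )
  usable <- ids[vapply(
    ids,
    function(id) length(con[[id]]) >= 2 && length(inc[[id]]) >= 2, logical(1)
  )]
  dropped <- setdiff(ids, usable)
  if (length(dropped) > 0) {
    warning(sprintf(
      "%d participant(s) dropped from splits (fewer than 2 trials of a type): %s",
      length(dropped), paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(usable) < 3) {
    stop("split-half reliability needs at least 3 contributing participants",
      call. = FALSE
    )
  }

  with_seed(seed, {
    b1 <- matrix(0, n_splits, length(usable))
    b2 <- matrix(0, n_splits, length(usable))
    for (j in seq_along(usable)) {
      id <- usable[j]
      mc <- split_half_means(con[[id]], n_splits)
      mi <- split_half_means(inc[[id]], n_splits)
      b1[, j] <- mi[, 1] - mc[, 1]
      b2[, j] <- mi[, 2] - mc[, 2]
    }
    r <- row_pearson(b1, b2)
    if (order == "correct-first") {
      per_split <- spearman_brown(r)
      value <- mean(per_split)
    } else {
      per_split <- r
      value <- spearman_brown(mean(r))
    }
    structure(
      list(
        method = "splithalf-SB", value = value, n_splits = n_splits,
        n_participants = length(usable), dropped = dropped,
        order = order, seed = seed,
        per_split = if (keep_splits) per_split else NULL
      ),
      class = "reliability_estimate"
    )
  })
}

#' Cronbach's alpha
#'
#' Internal consistency of a multi-item scale:
#' \code{alpha = k/(k-1) * (1 - sum(item variances) / variance(totals))},
#' with sample (n - 1) variances. Rows containing missing items are dropped
#' and reported.
#'
#' @param item_matrix numeric matrix or data frame, participants in rows,
#'   items in columns; at least 2 items and 3 complete rows.
#' @return object of class \code{reliability_estimate} with fields
#'   \code{method = "cronbach-alpha"}, \code{value}, \code{n_participants},
#'   \code{n_items}, \code{n_dropped_rows}.
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' cronbach_alpha(cbind(x + rnorm(50, 0, 0.3), x + rnorm(50, 0, 0.3)))
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("alpha needs at least 2 items", call. = FALSE)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) stop("alpha needs at least 3 complete rows", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("alpha undefined: zero variance of totals", call. = FALSE)
  item_var <- apply(m, 2, stats::var)
  structure(
    list(
      method = "cronbach-alpha",
      value = (k / (k - 1)) * (1 - sum(item_var) / total_var),
      n_participants = nrow(m), n_items = k, n_dropped_rows = n_dropped
    ),
    class = "reliability_estimate"
  )
}

#' @export
print.reliability_estimate <- function(x, ...) {
  if (x$method == "splithalf-SB") {
    cat(sprintf(
      "Split-half reliability (Spearman-Brown, %s): %.3f over %d splits, %d participants\n",
      x$order, x$value, x$n_splits, x$n_participants
    ))
    if (length(x$dropped)) {
      cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
    }
  } else {
    cat(sprintf(
      "Cronbach's alpha: %.3f (%d participants, %d items)\n",
      x$value, x$n_participants, x$n_items
    ))
  }
  invisible(x)
}
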