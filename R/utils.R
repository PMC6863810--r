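#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded at \code{seed},
#' then restores the caller's RNG state so that seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive independent sub-seeds from one top-level seed
#'
#' All randomness in the package flows from a single seed; each pipeline
#' stage receives its own derived stream so that changing, say, the number
#' of reliability splits does not shift the cohort simulation.
#'
#' @param seed top-level integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length \code{n}, each in [1, 2^31 - 2].
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stop with a message naming required columns missing from a data frame.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

#' Pool group-level summary statistics
#'
#' Recombines per-group sample sizes, means and standard deviations into the
#' mean and standard deviation of the combined sample, using the standard
#' combined-groups variance decomposition (within-group sum of squares plus
#' between-group dispersion about the pooled mean, with an n - 1 denominator).
#'
#' @param n integer vector of group sizes.
#' @param mean numeric vector of group means.
#' @param sd numeric vector of group standard deviations (sample, n - 1).
#' @return list with elements \code{n}, \code{mean}, \code{sd}.
#' @examples
#' pooled_moments(c(10, 10), c(0, 2), c(1, 1))
#' @export
pooled_moments <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd), all(n >= 1))
  N <- sum(n)
  m <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2) + sum(n * (mean - m)^2)
  list(n = N, mean = m, sd = sqrt(ss / (N - 1)))
}

#' Baseline group summaries of the reference ABM trial
#'
#' Group-level baseline sample sizes, means and standard deviations for the
#' social-anxiety score (LSAS-SR, 0--144) and the attentional bias index (ms)
#' in the published VR dot-probe ABM trial whose design this package's
#' defaults emulate (four groups crossing active/mock training with 2D/3D
#' stimuli, analysed n = 95). These published summaries are the inputs from
#' which the Jacobson--Truax constants are recomputed.
#'
#' @return data frame with columns \code{group}, \code{n}, \code{lsas_mean},
#'   \code{lsas_sd}, \code{bias_mean}, \code{bias_sd}.
#' @export
reference_baseline <- function() {
  path <- system.file("extdata", "reference_baseline.csv", package = "abmprobe")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
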