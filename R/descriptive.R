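#' Coefficient of variation with small-sample correction
#'
#' Computes the plain coefficient of variation `cv_hat = s / mean` (sample
#' standard deviation, n - 1 denominator) and the approximately unbiased
#' small-sample estimator `cv_star = (1 + 1/(4n)) * cv_hat`. The plain
#' estimator underestimates variability for small n, which matters for
#' short vocalization sequences; the corrected value is the one reported by
#' the dataset summaries.
#'
#' @param iois Numeric vector of IOIs (seconds), all > 0, length >= 2; an
#'   [ioi_sequence()] is also accepted.
#' @return A list of class `"cv_result"` with `cv_hat`, `cv_star`, `n`,
#'   `mean` and `sd`.
#' @examples
#' coefficient_of_variation(c(0.1, 0.2))
#' @export
coefficient_of_variation <- function(iois) {
  x <- as_iois(iois)
  n <- length(x)
  if (n < 2L) stop("need at least 2 IOIs for a coefficient of variation")
  if (any(x <= 0)) stop("all IOIs must be > 0")
  m <- mean(x)
  s <- stats::sd(x)
  cv_hat <- s / m
  structure(list(cv_hat = cv_hat, cv_star = (1 + 1 / (4 * n)) * cv_hat,
                 n = n, mean = m, sd = s),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV = %.4g (unbiased CV* = %.4g), n = %d, mean = %.4g s, sd = %.4g s\n",
              x$cv_hat, x$cv_star, x$n, x$mean, x$sd))
  invisible(x)
}

#' Normalized Pairwise Variability Index
#'
#' For each adjacent IOI pair the absolute difference is divided by the
#' pair mean; the nPVI is 100 times the average of these ratios. It is 0
#' for a perfectly isochronous sequence (all IOIs equal) and approaches
#' 200 for maximally alternating intervals. Values are scale invariant.
#'
#' @inheritParams coefficient_of_variation
#' @return The nPVI, a dimensionless value in `[0, 200)`.
#' @examples
#' npvi(c(0.1, 0.1, 0.1))  # 0
#' npvi(c(0.1, 0.3))       # 100
#' @export
npvi <- function(iois) {
  x <- as_iois(iois)
  m <- length(x)
  if (m < 2L) stop("need at least 2 IOIs for an nPVI")
  if (any(x <= 0)) stop("all IOIs must be > 0")
  a <- x[-m]
  b <- x[-1]
  100 * mean(abs(a - b) / ((a + b) / 2))
}

#' Exact beat frequency from the mean IOI
#'
#' The reciprocal of the mean IOI: a mean interval of 0.1 s corresponds to
#' a 10 Hz beat.
#'
#' @inheritParams coefficient_of_variation
#' @return Frequency in Hz.
#' @export
beat_from_mean_ioi <- function(iois) {
  x <- as_iois(iois)
  if (length(x) < 1L) stop("need at least 1 IOI")
  if (any(x <= 0)) stop("all IOIs must be > 0")
  1 / mean(x)
}

#' Summarize the IOI statistics of a dataset
#'
#' Computes the dataset-level descriptive table used as the first stage of
#' a rhythm analysis: pooled mean/SD/range of IOIs, the unbiased
#' coefficient of variation of all IOIs pooled (`cv_overall`), the mean of
#' per-sequence unbiased CVs (`cv_sequence_mean`), per-sequence and pooled
#' nPVI, and counts. The gap `cv_overall - cv_sequence_mean` indicates how
#' much variability lies between rather than within sequences, i.e. how
#' likely individual differences are.
#'
#' The pooled ("overall") nPVI skips adjacent pairs that straddle a
#' sequence boundary — those two IOIs are not adjacent in time. This choice
#' is recorded in the returned object (`overall_npvi_excludes_boundaries`).
#'
#' Sequences with fewer than 2 IOIs cannot contribute a CV or nPVI; they
#' are skipped with a warning and counted in `n_skipped`.
#'
#' @param ds A [rhythm_dataset()] (element sequences are converted to IOIs).
#' @return A list of class `"dataset_summary"`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "rhythm_dataset"))
  seqs <- lapply(ds$sequences, function(s)
    if (inherits(s, "element_sequence")) compute_iois(s) else s)
  lens <- vapply(seqs, function(s) length(s$iois), integer(1))
  skip <- lens < 2L
  if (any(skip))
    warning(sum(skip), " sequence(s) with < 2 IOIs skipped in dataset_summary")
  use <- seqs[!skip]
  if (length(use) == 0L) stop("no sequence has >= 2 IOIs")
  pooled <- unlist(lapply(use, `[[`, "iois"))
  cv_all <- coefficient_of_variation(pooled)
  per_cv <- vapply(use, function(s) coefficient_of_variation(s$iois)$cv_star,
                   numeric(1))
  per_npvi <- vapply(use, function(s) npvi(s$iois), numeric(1))
  # pooled nPVI with cross-boundary pairs excluded: weighted by pair counts
  pair_n <- vapply(use, function(s) length(s$iois) - 1L, integer(1))
  npvi_overall <- sum(per_npvi * pair_n) / sum(pair_n)
  structure(list(
    name = ds$name,
    mean_ioi = mean(pooled),
    sd_ioi = stats::sd(pooled),
    cv_overall = cv_all$cv_star,
    cv_sequence_mean = mean(per_cv),
    cv_gap = cv_all$cv_star - mean(per_cv),
    ioi_range = range(pooled),
    n_iois = length(pooled),
    npvi_per_sequence = per_npvi,
    npvi_mean = mean(per_npvi),
    npvi_range = range(per_npvi),
    npvi_overall = npvi_overall,
    overall_npvi_excludes_boundaries = TRUE,
    n_sequences = length(use),
    n_skipped = sum(skip),
    mean_ioi_per_sequence = vapply(use, function(s) mean(s$iois), numeric(1)),
    duration_per_sequence = vapply(use, function(s) sum(s$iois), numeric(1)),
    individual_per_sequence = vapply(use, `[[`, character(1), "individual_id")
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, digits = 3, ...) {
  cat(sprintf("IOI summary for '%s'\n", x$name))
  cat(sprintf("  %d IOIs in %d sequences (%d skipped)\n",
              x$n_iois, x$n_sequences, x$n_skipped))
  cat(sprintf("  mean IOI %.*g s, SD %.*g s, range %.*g-%.*g s\n",
              digits, x$mean_ioi, digits, x$sd_ioi,
              digits, x$ioi_range[1], digits, x$ioi_range[2]))
  cat(sprintf("  CV* overall %.*g, CV* sequence mean %.*g (gap %.*g)\n",
              digits, x$cv_overall, digits, x$cv_sequence_mean,
              digits, x$cv_gap))
  cat(sprintf("  nPVI per sequence: %.*g-%.*g, mean %.*g (pooled %.*g)\n",
              digits, x$npvi_range[1], digits, x$npvi_range[2],
              digits, x$npvi_mean, digits, x$npvi_overall))
  invisible(x)
}

#' @describeIn dataset_summary one-row data frame matching the summary
#'   table layout (mean IOI, SD, CVs, range, counts, nPVI).
#' @param x A `dataset_summary`.
#' @param ... Unused.
#' @export
as.data.frame.dataset_summary <- function(x, ...) {
  data.frame(dataset = x$name, mean_ioi_s = x$mean_ioi, sd_ioi_s = x$sd_ioi,
             cv_overall = x$cv_overall, cv_sequence_mean = x$cv_sequence_mean,
             ioi_min_s = x$ioi_range[1], ioi_max_s = x$ioi_range[2],
             n_iois = x$n_iois, npvi_min = x$npvi_range[1],
             npvi_max = x$npvi_range[2], npvi_mean = x$npvi_mean,
             n_sequences = x$n_sequences, stringsAsFactors = FALSE)
}
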