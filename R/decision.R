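#' Most prominent beat-frequency category
#'
#' Divides the analysis band (0-100 Hz by default) into bins of
#' `bin_width` Hz (half-open, `[k*w, (k+1)*w)`, with the top edge closed
#' so a beat exactly at the band limit is counted) and returns the bin
#' holding the largest share of per-sequence beats. Ties go to the lower
#' bin. A large share in one category is the descriptive signature of a
#' shared underlying beat.
#'
#' @param beats Numeric beat frequencies in Hz, within `[0, band_max]`.
#' @param bin_width Category width in Hz.
#' @param band_max Upper edge of the analysis band in Hz.
#' @return A list of class `"prominent_category"` with `category` (label
#'   such as `"20-30"`), `lower`, `upper`, `share` (percent) and `counts`
#'   (full per-bin table).
#' @export
prominent_category <- function(beats, bin_width = 10, band_max = 100) {
  beats <- as.numeric(beats)
  beats <- beats[is.finite(beats)]
  if (length(beats) < 1L) stop("need at least 1 beat frequency")
  if (any(beats < 0 | beats > band_max))
    stop("beats must lie within [0, ", band_max, "] Hz")
  edges <- seq(0, band_max, by = bin_width)
  bin <- findInterval(beats, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  best <- which.max(counts)  # ties -> lower bin (first maximum)
  structure(list(
    category = sprintf("%g-%g", edges[best], edges[best + 1]),
    lower = edges[best], upper = edges[best + 1],
    share = 100 * counts[best] / length(beats),
    counts = stats::setNames(counts, sprintf("%g-%g", edges[-length(edges)],
                                             edges[-1]))),
    class = "prominent_category")
}

#' @export
print.prominent_category <- function(x, ...) {
  cat(sprintf("Prominent category %s Hz holding %.1f%% of beats\n",
              x$category, x$share))
  invisible(x)
}

#' Default thresholds for the method-selection cascade
#'
#' The selection rules are heuristic and every threshold is a config key,
#' always echoed in the recommendation so results remain comparable across
#' studies. Defaults: `npvi_strict` 15 (an nPVI mean below this is treated
#' as directly indicating isochrony), `npvi_loose` 50 (between strict and
#' loose, isochrony is still inferred when the IOI distribution is
#' unimodal and per-sequence variability is modest), `cv_sequence_max`
#' 0.3, `cv_gap` 0.1 (a pooled-minus-per-sequence CV gap above this flags
#' likely individual differences), `fft_min_duration_s` 1 (sequences
#' shorter than this have too coarse a spectral bin width for reliable
#' beat detection), `tempo_slope_max` 0.3 (relative drift in the windowed
#' mean IOI beyond which a sequence is treated as changing tempo, which
#' rules out a single-frequency GAT fit).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of thresholds.
#' @export
decision_config <- function(...) {
  cfg <- list(npvi_strict = 15, npvi_loose = 50, cv_sequence_max = 0.3,
              cv_gap = 0.1, fft_min_duration_s = 1, tempo_slope_max = 0.3,
              unimodal_bins = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

# Internal: crude unimodality check — count kernel-density modes of the
# pooled IOIs, ignoring bumps under 10% of the main peak (a stand-in for
# visual assessment of the IOI histogram, not a formal dip test).
is_unimodal <- function(iois, n_bins = 20) {
  if (length(iois) < 8) return(NA)
  y <- stats::density(iois, n = 256)$y
  peak_idx <- which(diff(sign(diff(c(-Inf, y, -Inf)))) == -2)
  peaks <- sum(y[peak_idx] >= 0.1 * max(y))
  peaks <= 1
}

#' Recommend rhythm-analysis methods for a dataset
#'
#' Applies a rule cascade to the dataset's descriptive statistics:
#' (1) Is the dataset periodic? A unimodal IOI distribution with modest
#' per-sequence variability says yes. (2) Is it isochronous? A low mean
#' nPVI says yes directly; a moderate nPVI still permits isochrony when
#' the distribution is unimodal and per-sequence CVs are small. (3) Which
#' beat-estimation methods fit? A large gap between the pooled CV and the
#' mean per-sequence CV flags likely individual differences, for which the
#' per-sequence generate-and-test (GAT) search is preferred over the
#' oversimplifying IOI mean; sequences mostly shorter than the
#' FFT-adequacy duration are routed away from the FFT (coarse spectral
#' bins) and toward GAT; tempo-changing sequences are routed away from
#' GAT (a single fitted frequency cannot follow drift).
#'
#' "Unclear" verdicts are legal outputs; every fired rule and every
#' threshold used is recorded in the returned object.
#'
#' @param summary A [dataset_summary()], or a named list supplying at
#'   least `npvi_mean`, `cv_overall`, `cv_sequence_mean` and (optionally)
#'   pooled IOIs for the unimodality check as `iois`.
#' @param seq_durations Numeric vector of per-sequence durations in
#'   seconds (first to last onset). Defaults to
#'   `summary$duration_per_sequence` when present.
#' @param config Thresholds from [decision_config()].
#' @param tempo_changing Logical; whether sequences show systematic tempo
#'   drift (assessed externally or via [tempo_change_flag()]).
#' @param iois Optional pooled IOIs for the unimodality check.
#' @return A list of class `"method_recommendation"` with `periodic`,
#'   `isochronous`, `individual_differences_likely`,
#'   `recommended_methods`, `rationale` (character vector of fired rules)
#'   and `thresholds_used`.
#' @export
decide_method <- function(summary, seq_durations = NULL,
                          config = decision_config(),
                          tempo_changing = FALSE, iois = NULL) {
  s <- summary
  if (is.null(seq_durations) && !is.null(s$duration_per_sequence))
    seq_durations <- s$duration_per_sequence
  rationale <- character(0)
  note <- function(msg) rationale <<- c(rationale, msg)

  unimodal <- if (!is.null(iois)) {
    is_unimodal(iois, config$unimodal_bins)
  } else if (!is.null(s$iois)) {
    is_unimodal(s$iois, config$unimodal_bins)
  } else NA

  gap <- s$cv_overall - s$cv_sequence_mean

  # (1) periodic?
  if (s$npvi_mean > config$npvi_loose ||
      s$cv_sequence_mean > 2 * config$cv_sequence_max) {
    periodic <- "no"
    note(sprintf("aperiodic: nPVI mean %.3g and mean per-sequence CV* %.3g indicate no consistent interval structure (thresholds %g / %.3g)",
                 s$npvi_mean, s$cv_sequence_mean, config$npvi_loose,
                 2 * config$cv_sequence_max))
  } else if (identical(unimodal, FALSE)) {
    periodic <- "no"
    note(sprintf("aperiodic: multimodal IOI distribution (nPVI mean %.3g, mean per-sequence CV* %.3g)",
                 s$npvi_mean, s$cv_sequence_mean))
  } else if (isTRUE(unimodal)) {
    periodic <- "yes"
    note(sprintf("periodic: unimodal IOI distribution with nPVI mean %.3g <= %g and mean per-sequence CV* %.3g <= %.3g",
                 s$npvi_mean, config$npvi_loose, s$cv_sequence_mean,
                 2 * config$cv_sequence_max))
  } else if (s$cv_sequence_mean <= config$cv_sequence_max) {
    periodic <- "yes"
    note(sprintf("periodic: mean per-sequence CV* %.3g <= %.3g and nPVI mean %.3g <= %g (no IOI histogram available)",
                 s$cv_sequence_mean, config$cv_sequence_max, s$npvi_mean,
                 config$npvi_loose))
  } else {
    periodic <- "unclear"
    note("periodicity unclear without the IOI distribution")
  }

  # (2) isochronous?
  if (periodic == "no") {
    isochronous <- "no"
    note("not isochronous: dataset is aperiodic")
  } else if (s$npvi_mean <= config$npvi_strict) {
    isochronous <- "yes"
    note(sprintf("isochronous: nPVI mean %.3g <= strict threshold %g",
                 s$npvi_mean, config$npvi_strict))
  } else if (s$npvi_mean <= config$npvi_loose &&
             s$cv_sequence_mean <= config$cv_sequence_max) {
    isochronous <- "yes"
    note(sprintf("isochronous: nPVI mean %.3g in (%g, %g] but mean per-sequence CV* %.3g <= %.3g with a unimodal pattern",
                 s$npvi_mean, config$npvi_strict, config$npvi_loose,
                 s$cv_sequence_mean, config$cv_sequence_max))
  } else {
    isochronous <- "unclear"
    note(sprintf("isochrony unclear: nPVI mean %.3g, mean per-sequence CV* %.3g",
                 s$npvi_mean, s$cv_sequence_mean))
  }

  ind_diff <- is.finite(gap) && gap > config$cv_gap
  note(sprintf("CV* gap (overall - sequence mean) = %.3g: individual differences %s (threshold %g)",
               gap, if (ind_diff) "likely" else "not indicated", config$cv_gap))

  # (3) method routing
  methods <- character(0)
  if (periodic == "no") {
    note("no beat-estimation method recommended for an aperiodic dataset; recurrence plots may still reveal structure")
  } else {
    fft_ok <- !is.null(seq_durations) &&
      stats::median(seq_durations) >= config$fft_min_duration_s
    if (!is.null(seq_durations))
      note(sprintf("median sequence duration %.3g s %s the FFT-adequacy duration %g s",
                   stats::median(seq_durations),
                   if (fft_ok) "meets" else "is below",
                   config$fft_min_duration_s))
    if (tempo_changing) {
      note("tempo changes detected: GAT's single fitted frequency is unsuitable; recurrence plots recommended")
      methods <- if (fft_ok) c("IOI", "FFT", "recurrence") else "recurrence"
    } else if (ind_diff || !fft_ok) {
      methods <- "GAT"
      note(if (ind_diff)
        "per-sequence GAT recommended: individual differences likely and the IOI mean would oversimplify"
        else
        "GAT recommended: sequences too short for adequate spectral resolution")
    } else {
      methods <- c("IOI", "FFT")
      note("IOI and FFT recommended: strong shared pattern, adequate sequence length")
    }
  }

  structure(list(periodic = periodic, isochronous = isochronous,
                 individual_differences_likely = ind_diff,
                 recommended_methods = methods, rationale = rationale,
                 thresholds_used = config),
            class = "method_recommendation")
}

#' @export
print.method_recommendation <- function(x, ...) {
  cat("Method recommendation\n")
  cat(sprintf("  periodic: %s | isochronous: %s | individual differences likely: %s\n",
              x$periodic, x$isochronous, x$individual_differences_likely))
  cat(sprintf("  recommended: %s\n",
              if (length(x$recommended_methods))
                paste(x$recommended_methods, collapse = ", ") else "(none)"))
  cat("  rationale:\n")
  for (r in x$rationale) cat("   -", r, "\n")
  cat("  thresholds:",
      paste(sprintf("%s=%g", names(x$thresholds_used),
                    unlist(x$thresholds_used)), collapse = ", "), "\n")
  invisible(x)
}

#' Flag systematic tempo change in a sequence
#'
#' Splits the IOI series into windows, fits a line to the windowed mean
#' IOI against window index and flags the sequence when the fitted total
#' relative change exceeds `slope_max`. Descriptive only — it routes
#' tempo-drifting sequences away from single-frequency beat fits.
#'
#' @param iois Numeric IOIs (or an [ioi_sequence()] / [element_sequence()]).
#' @param n_windows Number of windows.
#' @param slope_max Maximum tolerated total relative change of the mean
#'   IOI across the sequence.
#' @return Logical.
#' @export
tempo_change_flag <- function(iois, n_windows = 4, slope_max = 0.3) {
  x <- as_iois(iois)
  if (length(x) < 2 * n_windows) return(FALSE)
  w <- cut(seq_along(x), n_windows, labels = FALSE)
  m <- tapply(x, w, mean)
  fit <- stats::lm(m ~ seq_along(m))
  total_change <- abs(stats::coef(fit)[2]) * (n_windows - 1) / mean(x)
  unname(total_change > slope_max)
}
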