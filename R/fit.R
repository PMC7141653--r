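#' Fit an isochronous beat to an onset sequence
#'
#' The central fitting function: estimates the exact beat frequency that
#' best describes one sequence of element onsets, by one of three methods.
#'
#' \describe{
#'   \item{`"ioi"`}{The reciprocal of the mean inter-onset interval, with
#'     the unbiased coefficient of variation as goodness of fit. Simple and
#'     robust, but blind to within-sequence structure.}
#'   \item{`"fft"`}{Spectral peak of the binarized point process
#'     ([binarize_onsets()], [fft_best_beat()]), with GOF and nGOF relative
#'     to the zero-bin internal reference. Resolution-limited for short
#'     sequences.}
#'   \item{`"gat"`}{Generate-and-test grid search ([gat_search()]) scored
#'     by FRMSD; finds the slowest beat whose grid the onsets sit on.}
#' }
#'
#' @param x Onsets in seconds (numeric vector), an [element_sequence()],
#'   or an [ioi_sequence()] (reconstructed to onsets starting at 0).
#' @param method `"ioi"`, `"fft"` or `"gat"`.
#' @param dt,f_max Binarization resolution (s) and search band (Hz) for
#'   the FFT method.
#' @param f_min,df GAT grid bounds/step (Hz); the GAT band is
#'   `[f_min, f_max]`.
#' @param ... Passed to the underlying method function.
#' @return An object of class `"beat_fit"`: a list with `frequency` (Hz),
#'   `gof` (named goodness-of-fit values of the method), `method`,
#'   `onsets`, `n_elements`, `duration`, and the full method result
#'   (`detail`).
#' @examples
#' fit <- beat_fit(gen_isochronous(0.1, 11), method = "gat")
#' coef(fit)
#' @export
beat_fit <- function(x, method = c("ioi", "fft", "gat"), dt = 0.005,
                     f_max = 100, f_min = 2, df = 0.01, ...) {
  method <- match.arg(method)
  onsets <- as_onsets(x)
  if (length(onsets) < 2L) stop("need at least 2 onsets to fit a beat")
  iois <- diff(onsets)
  res <- switch(method,
    ioi = {
      cv <- if (length(iois) >= 2) coefficient_of_variation(iois) else NULL
      list(frequency = beat_from_mean_ioi(iois),
           gof = c(cv_star = if (is.null(cv)) NA_real_ else cv$cv_star),
           detail = cv)
    },
    fft = {
      spec <- fft_best_beat(binarize_onsets(onsets, dt = dt), f_max = f_max, ...)
      list(frequency = spec$best_frequency,
           gof = c(gof = spec$gof, ngof = spec$ngof), detail = spec)
    },
    gat = {
      g <- gat_search(onsets, f_min = f_min, f_max = f_max, df = df, ...)
      list(frequency = g$best_frequency, gof = c(frmsd = g$best_frmsd),
           detail = g)
    })
  structure(list(frequency = res$frequency, gof = res$gof, method = method,
                 onsets = onsets, n_elements = length(onsets),
                 duration = diff(range(onsets)), detail = res$detail,
                 call = match.call()),
            class = "beat_fit")
}

#' @export
print.beat_fit <- function(x, ...) {
  cat(sprintf("Beat fit (%s method): %s\n", toupper(x$method),
              if (is.na(x$frequency)) "no beat detected"
              else sprintf("%.4g Hz", x$frequency)))
  if (length(x$gof))
    cat("  goodness of fit:",
        paste(sprintf("%s = %.4g", names(x$gof), x$gof), collapse = ", "), "\n")
  cat(sprintf("  %d elements over %.4g s\n", x$n_elements, x$duration))
  invisible(x)
}

#' @export
coef.beat_fit <- function(object, ...) {
  c(frequency_hz = object$frequency)
}

#' @export
summary.beat_fit <- function(object, ...) {
  iois <- diff(object$onsets)
  out <- list(fit = object,
              npvi = if (length(iois) >= 2) npvi(iois) else NA_real_,
              cv = if (length(iois) >= 2) coefficient_of_variation(iois)
                   else NULL,
              period = 1 / object$frequency)
  class(out) <- "summary.beat_fit"
  out
}

#' @export
print.summary.beat_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  implied period: %.4g s\n", x$period))
  if (!is.null(x$cv))
    cat(sprintf("  IOI mean %.4g s, CV* %.4g, nPVI %.4g\n",
                x$cv$mean, x$cv$cv_star, x$npvi))
  invisible(x)
}

#' Predicted beat-grid times for a fitted beat
#'
#' Returns the isochronous grid of the fitted frequency, anchored at the
#' first onset and spanning the observed sequence.
#'
#' @param object A `"beat_fit"`.
#' @param ... Unused.
#' @return Numeric vector of grid times in seconds.
#' @export
predict.beat_fit <- function(object, ...) {
  if (is.na(object$frequency)) return(numeric(0))
  p <- 1 / object$frequency
  t0 <- object$onsets[1]
  t0 + p * (0:floor((object$duration + p / 2) / p))
}

#' Residuals of a fitted beat
#'
#' Signed deviation of each onset from its nearest fitted beat-grid point
#' (seconds); the RMS of their absolute values is the RMSD the GAT method
#' minimizes.
#'
#' @param object A `"beat_fit"`.
#' @param ... Unused.
#' @export
residuals.beat_fit <- function(object, ...) {
  if (is.na(object$frequency)) return(rep(NA_real_, object$n_elements))
  p <- 1 / object$frequency
  ph <- (object$onsets - object$onsets[1]) %% p
  ifelse(ph <= p / 2, ph, ph - p)
}

#' Simulate onset sequences from a fitted beat
#'
#' Draws sequences on the fitted isochronous grid with Gaussian timing
#' noise matched to the fit's residual spread.
#'
#' @param object A `"beat_fit"`.
#' @param nsim Number of sequences.
#' @param seed Random seed (required for reproducibility).
#' @param ... Unused.
#' @return A list of numeric onset vectors.
#' @export
simulate.beat_fit <- function(object, nsim = 1, seed, ...) {
  if (is.na(object$frequency)) stop("cannot simulate from a no-beat fit")
  sd_res <- stats::sd(residuals(object))
  if (!is.finite(sd_res)) sd_res <- 0
  p <- 1 / object$frequency
  n <- object$n_elements
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      sort(p * (seq_len(n) - 1) + stats::rnorm(n, 0, sd_res)))
  })
}

#' @export
plot.beat_fit <- function(x, ...) {
  switch(x$method,
    gat = plot(x$detail, ...),
    fft = {
      graphics::plot(x$detail$frequencies, x$detail$amplitudes, type = "h",
                     xlab = "frequency [Hz]", ylab = "|X(f)|",
                     main = sprintf("Spectrum: best beat %.4g Hz",
                                    x$frequency), ...)
      graphics::abline(v = x$frequency, col = 2, lty = 2)
    },
    ioi = {
      graphics::hist(diff(x$onsets), breaks = "FD", xlab = "IOI [s]",
                     main = sprintf("IOIs: mean beat %.4g Hz", x$frequency),
                     ...)
    })
  invisible(x)
}

#' Run the full rhythm analysis on a dataset
#'
#' Orchestrates every analysis stage: the IOI summary, per-sequence beat
#' fits by all three methods with their goodness-of-fit values, prominent
#' beat categories per method, per-individual beat clustering, recurrence
#' matrices, and the method recommendation. The report is a pure function
#' of the dataset and configuration; the configuration used is embedded in
#' the result so every number is traceable.
#'
#' Sequences a method cannot handle (too few elements, too short for the
#' spectrum) are collected into the `qc` section rather than aborting the
#' run.
#'
#' @param ds A [rhythm_dataset()].
#' @param dt,f_max,f_min,df Method parameters, as in [beat_fit()].
#' @param cluster_threshold,cluster_normalize Passed to [cluster_beats()].
#' @param config Decision thresholds from [decision_config()].
#' @param methods Which beat methods to run.
#' @return A list of class `"rhythm_report"` with elements `summary`,
#'   `beats` (per-sequence data frame: sequence_id, individual, method,
#'   frequency_hz, gof columns), `prominent` (per-method
#'   [prominent_category()] results), `clusters` (a [cluster_report()] or
#'   NULL), `recurrence` (list of matrices), `recommendation`, `qc` and
#'   `config`.
#' @export
rhythm_analysis <- function(ds, dt = 0.005, f_max = 100, f_min = 2, df = 0.01,
                            cluster_threshold = 0.05,
                            cluster_normalize = FALSE,
                            config = decision_config(),
                            methods = c("ioi", "fft", "gat")) {
  stopifnot(inherits(ds, "rhythm_dataset"))
  summ <- dataset_summary(ds)
  qc <- character(0)
  rows <- list()
  recur <- list()
  tempo_flags <- logical(0)
  for (s in ds$sequences) {
    onsets <- tryCatch(as_onsets(s), error = function(e) NULL)
    sid <- s$sequence_id
    if (is.null(onsets) || length(onsets) < 2L) {
      qc <- c(qc, sprintf("%s: fewer than 2 onsets, skipped", sid))
      next
    }
    iois <- diff(onsets)
    if (length(iois) >= 2) {
      recur[[sid]] <- recurrence_matrix(iois)
      tempo_flags <- c(tempo_flags, tempo_change_flag(
        iois, slope_max = config$tempo_slope_max))
    }
    for (m in methods) {
      fit <- tryCatch(
        suppressWarnings(beat_fit(onsets, method = m, dt = dt, f_max = f_max,
                                  f_min = f_min, df = df)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        qc <- c(qc, sprintf("%s [%s]: %s", sid, m, conditionMessage(fit)))
        next
      }
      g <- fit$gof
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sid, individual = s$individual_id,
        species = s$species, method = toupper(m),
        frequency_hz = fit$frequency,
        gof = if ("gof" %in% names(g)) g[["gof"]] else NA_real_,
        ngof = if ("ngof" %in% names(g)) g[["ngof"]] else NA_real_,
        frmsd = if ("frmsd" %in% names(g)) g[["frmsd"]] else NA_real_,
        cv_star = if ("cv_star" %in% names(g)) g[["cv_star"]] else NA_real_,
        n_elements = fit$n_elements, duration_s = fit$duration,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no sequence could be analyzed")
  beats <- do.call(rbind, rows)
  prominent <- lapply(split(beats, beats$method), function(b) {
    f <- b$frequency_hz[is.finite(b$frequency_hz) & b$frequency_hz <= f_max]
    if (length(f)) prominent_category(f, band_max = f_max) else NULL
  })
  clusters <- NULL
  by_method <- lapply(split(beats, beats$method), function(b)
    data.frame(individual = b$individual, frequency = b$frequency_hz,
               stringsAsFactors = FALSE))
  clusters <- tryCatch(
    suppressWarnings(cluster_report(by_method, threshold = cluster_threshold,
                                    normalize = cluster_normalize)),
    error = function(e) { qc <<- c(qc, paste("clustering:",
                                             conditionMessage(e))); NULL })
  rec <- decide_method(
    summ, config = config,
    tempo_changing = length(tempo_flags) > 0 && mean(tempo_flags) > 0.5,
    iois = unlist(lapply(ds$sequences, function(s)
      tryCatch(as_iois(s), error = function(e) numeric(0)))))
  structure(list(summary = summ, beats = beats, prominent = prominent,
                 clusters = clusters, recurrence = recur,
                 recommendation = rec, qc = qc,
                 config = list(dt = dt, f_max = f_max, f_min = f_min, df = df,
                               cluster_threshold = cluster_threshold,
                               cluster_normalize = cluster_normalize,
                               decision = config)),
            class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat(sprintf("Rhythm analysis report for '%s'\n", x$summary$name))
  print(x$summary)
  cat("\nPer-method beat summary:\n")
  for (m in names(x$prominent)) {
    b <- x$beats[x$beats$method == m & is.finite(x$beats$frequency_hz), ]
    if (nrow(b) == 0) next
    cat(sprintf("  %s: %d sequences, beats %.3g-%.3g Hz; ", m, nrow(b),
                min(b$frequency_hz), max(b$frequency_hz)))
    if (!is.null(x$prominent[[m]]))
      cat(sprintf("prominent category %s Hz (%.1f%%)",
                  x$prominent[[m]]$category, x$prominent[[m]]$share))
    cat("\n")
  }
  cat("\n")
  print(x$recommendation)
  if (length(x$qc)) {
    cat("\nQC notes:\n")
    for (q in x$qc) cat("  -", q, "\n")
  }
  invisible(x)
}

#' Write the report tables of a rhythm analysis
#'
#' Writes `summary.csv` (dataset summary row), `beats.csv` (per-sequence
#' per-method beats with goodness of fit), `clusters.csv` (when
#' clustering succeeded) and `recommendation.json` into a directory.
#'
#' @param report A `"rhythm_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rhythm_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(report$summary),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$beats, file.path(dir, "beats.csv"),
                   row.names = FALSE)
  if (!is.null(report$clusters))
    utils::write.csv(as.data.frame(report$clusters),
                     file.path(dir, "clusters.csv"), row.names = FALSE)
  rec <- report$recommendation
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(periodic = rec$periodic, isochronous = rec$isochronous,
           individual_differences_likely = rec$individual_differences_likely,
           recommended_methods = rec$recommended_methods,
           rationale = rec$rationale, thresholds_used = rec$thresholds_used,
           config = report$config),
      file.path(dir, "recommendation.json"), auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(utils::capture.output(print(rec)),
               file.path(dir, "recommendation.txt"))
  }
  invisible(dir)
}
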