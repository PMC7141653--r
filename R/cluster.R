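#' Cluster beat frequencies within an individual
#'
#' Agglomerative hierarchical clustering of per-sequence beat frequencies
#' with group-average (UPGMA) linkage on Euclidean distances, cut at a
#' dissimilarity threshold. The share of sequences in the largest cluster
#' summarizes how strongly an individual "prefers" one beat.
#'
#' The default threshold of 0.05 is applied to the raw cophenetic distance
#' in Hz — a tight criterion at Hz scale. Set `normalize = TRUE` to divide
#' frequencies by their mean before clustering, which turns the threshold
#' into a relative (5%) criterion; both readings are legitimate and the
#' choice is recorded in the result.
#'
#' @param freqs Numeric beat frequencies in Hz, at least 1.
#' @param threshold Dissimilarity cutoff (merge heights <= threshold stay
#'   merged), > 0.
#' @param normalize Divide frequencies by their mean before clustering.
#' @return A list of class `"cluster_result"` with `labels` (cluster id
#'   per input), `n_clusters`, `largest_share`, `largest_cluster_range`
#'   (Hz range of the biggest cluster), `threshold`, `normalize` and
#'   `method_tag`.
#' @param method_tag Optional tag naming the beat method that produced the
#'   frequencies (e.g. "GAT", "FFT", "IOI").
#' @export
cluster_beats <- function(freqs, threshold = 0.05, normalize = FALSE,
                          method_tag = NA_character_) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 1L) stop("need at least 1 frequency")
  if (any(!is.finite(freqs))) stop("frequencies must be finite")
  if (threshold <= 0) stop("threshold must be > 0")
  if (length(freqs) == 1L) {
    warning("single frequency: trivially one cluster")
    labels <- 1L
  } else {
    v <- if (normalize) freqs / mean(freqs) else freqs
    hc <- stats::hclust(stats::dist(v), method = "average")
    labels <- stats::cutree(hc, h = threshold)
  }
  tab <- table(labels)
  big <- names(tab)[which.max(tab)]
  structure(list(labels = as.integer(labels),
                 n_clusters = length(tab),
                 largest_share = max(tab) / length(freqs),
                 largest_cluster_range = range(freqs[labels == as.integer(big)]),
                 largest_cluster_id = as.integer(big),
                 threshold = threshold, normalize = normalize,
                 method_tag = method_tag, freqs = freqs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result>%s %d frequencies -> %d cluster(s) at threshold %g%s; largest holds %.0f%% (%.3g-%.3g Hz)\n",
              if (is.na(x$method_tag)) "" else paste0(" [", x$method_tag, "]"),
              length(x$labels), x$n_clusters, x$threshold,
              if (x$normalize) " (mean-normalized)" else "",
              100 * x$largest_share,
              x$largest_cluster_range[1], x$largest_cluster_range[2]))
  invisible(x)
}

#' Per-individual beat-cluster report
#'
#' Runs [cluster_beats()] on each individual's per-sequence beat
#' frequencies, for one or several beat-estimation methods, and tabulates
#' the largest-cluster share per individual. Individuals with fewer than 2
#' sequences are excluded with a warning.
#'
#' @param beats_by_method Named list; each element is a data frame with
#'   columns `individual` and `frequency` (Hz), named by the method that
#'   produced it (e.g. `list(GAT = ..., FFT = ..., IOI = ...)`).
#' @inheritParams cluster_beats
#' @return A data frame of class `"cluster_report"` with columns
#'   `individual`, `method`, `n_sequences`, `n_clusters`, `largest_share`,
#'   `cluster_min_hz`, `cluster_max_hz`; the per-individual
#'   `cluster_result` objects are attached as attribute `"clusters"`.
#' @export
cluster_report <- function(beats_by_method, threshold = 0.05,
                           normalize = FALSE) {
  stopifnot(is.list(beats_by_method), length(beats_by_method) >= 1,
            !is.null(names(beats_by_method)))
  rows <- list()
  details <- list()
  for (method in names(beats_by_method)) {
    df <- beats_by_method[[method]]
    stopifnot(all(c("individual", "frequency") %in% names(df)))
    for (ind in unique(df$individual)) {
      f <- df$frequency[df$individual == ind]
      if (length(f) < 2L) {
        warning(sprintf("individual '%s' has < 2 sequences for method %s; excluded",
                        ind, method))
        next
      }
      cl <- cluster_beats(f, threshold = threshold, normalize = normalize,
                          method_tag = method)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, method = method, n_sequences = length(f),
        n_clusters = cl$n_clusters, largest_share = cl$largest_share,
        cluster_min_hz = cl$largest_cluster_range[1],
        cluster_max_hz = cl$largest_cluster_range[2],
        stringsAsFactors = FALSE)
      details[[paste(method, ind, sep = ":")]] <- cl
    }
  }
  if (length(rows) == 0L) stop("no individual had >= 2 sequences")
  out <- do.call(rbind, rows)
  attr(out, "clusters") <- details
  class(out) <- c("cluster_report", "data.frame")
  out
}

#' Dot plot of per-individual beat clusters
#'
#' One column per individual; every per-sequence beat frequency is drawn
#' as a dot, with members of the largest cluster highlighted and the
#' largest-cluster percentage printed under each column.
#'
#' @param x A `"cluster_report"`.
#' @param method Which method's clusters to draw (default: first present).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cluster_report <- function(x, method = NULL, ...) {
  details <- attr(x, "clusters")
  if (is.null(method)) method <- x$method[1]
  keys <- grep(paste0("^", method, ":"), names(details), value = TRUE)
  if (length(keys) == 0L) stop("no clusters for method ", method)
  inds <- sub("^[^:]*:", "", keys)
  all_f <- unlist(lapply(details[keys], `[[`, "freqs"))
  graphics::plot(NA, xlim = c(0.5, length(keys) + 0.5), ylim = range(all_f),
                 xaxt = "n", xlab = "individual",
                 ylab = "exact beat frequency [Hz]",
                 main = sprintf("Beat clusters per individual (%s)", method), ...)
  graphics::axis(1, at = seq_along(keys), labels = inds)
  for (i in seq_along(keys)) {
    cl <- details[[keys[i]]]
    in_big <- cl$labels == cl$largest_cluster_id
    graphics::points(rep(i, sum(!in_big)), cl$freqs[!in_big], pch = 16,
                     col = "grey40")
    graphics::points(rep(i, sum(in_big)), cl$freqs[in_big], pch = 16, col = 2)
    graphics::mtext(sprintf("%.0f%%", 100 * cl$largest_share), side = 1,
                    line = 2.5, at = i, cex = 0.8)
  }
  invisible(x)
}
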