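# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal route available (explicit sums, explicit
# grid enumeration, naive agglomeration) and share no code with the
# implementations they check.

# O(N^2) direct-sum discrete Fourier transform with 1/N normalization.
dft_oracle <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(n, function(k)
    sum(x * exp(-2i * pi * k * n / N)) / N, complex(1))
}

# FRMSD by explicit enumeration of the beat-grid points spanning the
# sequence: nearest-grid-point distance per onset, RMS, times frequency.
gat_oracle <- function(onsets, f) {
  t0 <- onsets[1]
  p <- 1 / f
  grid <- t0 + p * (0:ceiling((max(onsets) - t0) / p + 1))
  dev <- vapply(onsets, function(t) min(abs(t - grid)), numeric(1))
  rmsd <- sqrt(mean(dev^2))
  list(rmsd = rmsd, frmsd = rmsd * f)
}

# Naive UPGMA agglomeration: merge the pair of clusters with the smallest
# average inter-point distance until that minimum exceeds the threshold.
# Returns integer cluster labels.
upgma_oracle <- function(x, h) {
  clusters <- as.list(seq_along(x))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(abs(outer(x[clusters[[i]]], x[clusters[[j]]], "-")))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(length(x))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# Co-membership matrix for comparing partitions irrespective of label ids.
comembership <- function(labels) outer(labels, labels, "==")

# Brute-force nPVI: literal pairwise loop.
npvi_oracle <- function(iois) {
  m <- length(iois)
  acc <- 0
  for (k in 1:(m - 1))
    acc <- acc + abs(iois[k] - iois[k + 1]) / ((iois[k] + iois[k + 1]) / 2)
  100 * acc / (m - 1)
}

# Summary statistics as printed for the three study signal types
# (descriptive values only; used as inputs to the decision cascade).
printed_summary <- function(which) {
  p <- switch(which,
    carollia = list(mean_ioi = 0.043, cv_overall = 0.31,
                    cv_sequence_mean = 0.23, npvi_mean = 35.9,
                    n_iois = 195, n_sequences = 47),
    saccopteryx = list(mean_ioi = 0.078, cv_overall = 0.29,
                       cv_sequence_mean = 0.19, npvi_mean = 22.8,
                       n_iois = 646, n_sequences = 50),
    physeter = list(mean_ioi = 0.46, cv_overall = 0.22,
                    cv_sequence_mean = 0.14, npvi_mean = 5.2,
                    n_iois = 6913, n_sequences = 60))
  p$duration_per_sequence <- rep(p$mean_ioi * p$n_iois / p$n_sequences,
                                 p$n_sequences)
  p
}
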