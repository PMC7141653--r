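#' Deviation of onsets from an isochronous beat grid
#'
#' Overlays the observed onsets with a perfectly isochronous grid of
#' frequency `f` anchored at the first onset and measures how far each
#' onset lies from its nearest grid point. The root-mean-square of these
#' deviations (RMSD, seconds) is normalized to the beat period to give the
#' frequency-normalized RMSD (FRMSD), the average temporal deviation as a
#' fraction of a full cycle. Minimizing FRMSD over candidate frequencies
#' favours the slowest beat among harmonically equivalent fits.
#'
#' @param onsets Numeric onset times in seconds (or an
#'   [element_sequence()] / [ioi_sequence()]), at least 2 onsets.
#' @param f Candidate beat frequency in Hz, > 0. Vectorized over `f`.
#' @param convention `"rmsd_times_f"` (default; FRMSD = rmsd * f = rmsd /
#'   period, a fraction of a cycle) or `"rmsd_over_f"` (FRMSD = rmsd / f).
#'   Only the default makes FRMSD a cycle fraction and its minimum the
#'   slowest beat; the alternative is kept for comparison with other
#'   implementations.
#' @return A list with `rmsd` (seconds) and `frmsd` (dimensionless),
#'   each of length `length(f)`.
#' @export
beat_rmsd <- function(onsets, f, convention = c("rmsd_times_f", "rmsd_over_f")) {
  convention <- match.arg(convention)
  t <- as_onsets(onsets)
  if (length(t) < 2L) stop("need at least 2 onsets")
  if (any(f <= 0)) stop("beat frequency must be > 0")
  t <- t - t[1]
  period <- 1 / f
  # phase of each onset within the cycle; deviation to nearest grid point
  if (length(f) == 1L) {
    r <- t %% period
    dev <- pmin(r, period - r)
    rmsd <- sqrt(mean(dev^2))
  } else {
    r <- outer(t, period, "%%")
    dev <- pmin(r, rep(period, each = length(t)) - r)
    rmsd <- sqrt(colMeans(dev^2))
  }
  frmsd <- switch(convention,
                  rmsd_times_f = rmsd * f,
                  rmsd_over_f = rmsd / f)
  list(rmsd = rmsd, frmsd = frmsd)
}

#' Generate-and-test search for the best isochronous beat
#'
#' Scores every candidate frequency on an inclusive grid (default 2-100 Hz
#' in 0.01 Hz steps, 9801 candidates) with [beat_rmsd()] and returns the
#' frequency of minimal FRMSD. Ties — including the exact-fit case where a
#' fundamental and its harmonics all score 0 — are resolved toward the
#' slowest (lowest) frequency, so the fundamental is selected. The grid is
#' generated from integer indices to avoid cumulative floating-point step
#' drift.
#'
#' A fundamental whose exact frequency falls between grid points (e.g.
#' 10/3 Hz on a 0.01 Hz grid) can never score exactly 0, while one of its
#' harmonics that happens to lie on the grid can — which would defeat the
#' slowest-tie rule on near-perfect data. `gat_search` therefore applies a
#' harmonic disambiguation step: subharmonics `f*/k` of the minimizer are
#' accepted as ties when their FRMSD is within the grid-quantization floor
#' `span * df / (2 * sqrt(3))` of the minimum (the worst-case FRMSD a true
#' but off-grid beat accumulates from frequency rounding alone, with
#' `span` the sequence duration), and the slowest accepted candidate is
#' returned. Set `harmonic_rescue = FALSE` for the raw argmin.
#'
#' @inheritParams beat_rmsd
#' @param f_min,f_max,df Frequency window bounds and step, Hz.
#' @param max_grid Safety cap on the number of candidates.
#' @param harmonic_rescue Apply the subharmonic quantization-tie rule.
#' @return A list of class `"gat_result"` with `grid`, `frmsd_curve`,
#'   `rmsd_curve`, `best_frequency`, `best_frmsd`, `rmsd_at_best` and the
#'   search parameters.
#' @export
gat_search <- function(onsets, f_min = 2, f_max = 100, df = 0.01,
                       convention = c("rmsd_times_f", "rmsd_over_f"),
                       max_grid = 2e5, harmonic_rescue = TRUE) {
  convention <- match.arg(convention)
  t <- as_onsets(onsets)
  if (length(t) < 2L) stop("need at least 2 onsets")
  if (!(f_min < f_max) || df <= 0) stop("need f_min < f_max and df > 0")
  k <- round((f_max - f_min) / df)
  if (k + 1 > max_grid)
    stop("candidate grid of ", k + 1, " frequencies exceeds max_grid = ", max_grid)
  grid <- f_min + (0:k) * df
  sc <- beat_rmsd(t, grid, convention = convention)
  # slowest-tie rule: first index attaining the minimum (grid is increasing)
  best_i <- which(sc$frmsd <= min(sc$frmsd) + 1e-15)[1]
  if (harmonic_rescue && convention == "rmsd_times_f") {
    # an off-grid fundamental loses to an on-grid harmonic on near-perfect
    # data; accept the slowest subharmonic within the quantization floor
    span <- t[length(t)] - t[1]
    floor_q <- span * df / (2 * sqrt(3)) + 1e-12
    f_star <- grid[best_i]
    for (h in seq(floor(f_star / f_min), 2)) {
      if (h < 2) break
      i_sub <- round((f_star / h - f_min) / df) + 1L
      if (i_sub < 1L || i_sub > length(grid)) next
      if (sc$frmsd[i_sub] <= sc$frmsd[best_i] + floor_q) {
        best_i <- i_sub
        break
      }
    }
  }
  structure(list(grid = grid, frmsd_curve = sc$frmsd, rmsd_curve = sc$rmsd,
                 best_frequency = grid[best_i], best_frmsd = sc$frmsd[best_i],
                 rmsd_at_best = sc$rmsd[best_i],
                 f_min = f_min, f_max = f_max, df = df,
                 convention = convention, n_onsets = length(t)),
            class = "gat_result")
}

#' @export
print.gat_result <- function(x, ...) {
  cat(sprintf("<gat_result> best beat %.2f Hz (FRMSD %.4g) over %g-%g Hz in %g Hz steps\n",
              x$best_frequency, x$best_frmsd, x$f_min, x$f_max, x$df))
  invisible(x)
}

#' @export
plot.gat_result <- function(x, ...) {
  graphics::plot(x$grid, x$frmsd_curve, type = "l",
                 xlab = "candidate beat frequency [Hz]", ylab = "FRMSD",
                 main = sprintf("GAT: best beat %.2f Hz", x$best_frequency), ...)
  graphics::abline(v = x$best_frequency, col = 2, lty = 2)
  invisible(x)
}
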