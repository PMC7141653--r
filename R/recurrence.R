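#' Recurrence matrix of pairwise IOI differences
#'
#' Builds the matrix `M[i, j] = |IOI_i - IOI_j|` over all positions of an
#' IOI sequence. Rendered as an image it reveals higher-order temporal
#' structure — blocks of similar intervals, alternating patterns, tempo
#' drift — that scalar statistics miss. The matrix is symmetric with a
#' zero diagonal; a perfectly isochronous sequence gives an all-zero
#' (all-white) matrix.
#'
#' @param iois Numeric vector of IOIs in seconds (or an [ioi_sequence()] /
#'   [element_sequence()]), at least 2 IOIs.
#' @return A numeric matrix of class `"recurrence_matrix"` (seconds), with
#'   IOI indices as dimnames.
#' @export
recurrence_matrix <- function(iois) {
  x <- as_iois(iois)
  if (length(x) < 2L) stop("need at least 2 IOIs for a recurrence matrix")
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(seq_along(x), seq_along(x))
  class(m) <- c("recurrence_matrix", "matrix")
  m
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, max |IOI difference| %.4g s\n",
              nrow(x), ncol(x), max(x)))
  invisible(x)
}

#' Plot a recurrence matrix
#'
#' Grayscale rendering: white marks zero difference and darker cells mark
#' larger absolute IOI differences. By default the color scale spans this
#' matrix's own range, so the same shade does not represent the same
#' absolute difference across plots; pass `zlim` to share a scale between
#' plots when comparing sequences.
#'
#' @param x A `"recurrence_matrix"`.
#' @param zlim Numeric length-2 color-scale range in seconds; defaults to
#'   `c(0, max(x))` (per-plot scale).
#' @param n_gray Number of gray levels.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.recurrence_matrix <- function(x, zlim = NULL, n_gray = 64,
                                   main = "IOI recurrence plot", ...) {
  m <- unclass(x)
  if (is.null(zlim)) zlim <- c(0, max(m, 1e-12))
  pal <- grDevices::gray(seq(1, 0, length.out = n_gray))
  n <- nrow(m)
  # flip rows so index 1 is at the top-left, the conventional orientation
  graphics::image(x = seq_len(n), y = seq_len(n), z = t(m[n:1, , drop = FALSE]),
                  zlim = zlim, col = pal, xlab = "IOI index", ylab = "IOI index",
                  axes = FALSE, main = main, ...)
  at <- unique(round(pretty(seq_len(n))))
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at)
  graphics::axis(2, at = n + 1 - at, labels = at)
  graphics::box()
  graphics::mtext(sprintf("white = 0 s, black = %.3g s (scale is per plot)",
                          zlim[2]), side = 1, line = 3, cex = 0.7)
  invisible(x)
}

#' Render a recurrence matrix to a PNG file
#'
#' @param M A `"recurrence_matrix"`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @inheritParams plot.recurrence_matrix
#' @return The path, invisibly.
#' @export
render_recurrence <- function(M, path, width = 600, height = 600,
                              zlim = NULL, ...) {
  stopifnot(inherits(M, "recurrence_matrix"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": directory missing")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(M, zlim = zlim, ...)
  invisible(path)
}
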