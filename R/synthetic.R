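#' Generate a perfectly isochronous onset sequence
#'
#' Onsets at `0, ioi, 2*ioi, ...` — the ground-truth fixture for every
#' beat-detection method: nPVI and CV are exactly 0 and all methods should
#' recover the beat `1/ioi` Hz within their resolution limits.
#'
#' @param ioi Inter-onset interval in seconds, > 0.
#' @param n_elements Number of elements (onsets), >= 2.
#' @inheritParams element_sequence
#' @return An [element_sequence()].
#' @export
gen_isochronous <- function(ioi, n_elements, sequence_id = "iso",
                            individual_id = "synthetic", species = "synthetic") {
  stopifnot(ioi > 0, n_elements >= 2)
  element_sequence((seq_len(n_elements) - 1) * ioi, sequence_id = sequence_id,
                   individual_id = individual_id, species = species)
}

# Internal: run expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate an aperiodic control dataset with uniform IOIs
#'
#' IOIs drawn i.i.d. from Uniform(low, high); exact-zero draws (possible
#' in floating point when `low = 0`) are redrawn so every IOI is strictly
#' positive. This is the aperiodic control: no underlying beat exists, the
#' nPVI is far from 0 and beat detectors should report poor fits.
#'
#' @param n_sequences,n_elements Dataset dimensions; each sequence has
#'   `n_elements` onsets, i.e. `n_elements - 1` IOIs.
#' @param low,high Uniform bounds in seconds, `0 <= low < high`.
#' @param seed Random seed (required; generation is reproducible).
#' @return A [rhythm_dataset()] of [ioi_sequence()] objects.
#' @export
gen_uniform <- function(n_sequences = 10, n_elements = 100, low = 0, high = 1,
                        seed) {
  stopifnot(low < high, low >= 0, n_sequences >= 1, n_elements >= 2)
  with_seed(seed, {
    seqs <- lapply(seq_len(n_sequences), function(i) {
      x <- stats::runif(n_elements - 1, low, high)
      while (any(x <= 0)) x[x <= 0] <- stats::runif(sum(x <= 0), low, high)
      ioi_sequence(x, sequence_id = sprintf("unif_%02d", i),
                   individual_id = "synthetic", species = "uniform")
    })
    rhythm_dataset(seqs, name = "uniform")
  })
}

#' Generate a Gaussian-IOI dataset
#'
#' IOIs drawn i.i.d. from Normal(mean, sd), with any non-positive draw
#' rejected and redrawn until positive, so all IOIs are strictly positive
#' (this truncation biases the realized mean slightly upward when sd is
#' large relative to the mean). Emulates noisy-but-periodic sequences with
#' a true underlying beat of `1/mean` Hz.
#'
#' @param mean,sd Gaussian parameters in seconds, both > 0.
#' @inheritParams gen_uniform
#' @return A [rhythm_dataset()] of [ioi_sequence()] objects.
#' @export
gen_gaussian <- function(mean, sd, n_sequences = 10, n_elements = 100, seed) {
  stopifnot(mean > 0, sd > 0, n_sequences >= 1, n_elements >= 2)
  with_seed(seed, {
    seqs <- lapply(seq_len(n_sequences), function(i) {
      x <- stats::rnorm(n_elements - 1, mean, sd)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
      ioi_sequence(x, sequence_id = sprintf("gauss_%02d", i),
                   individual_id = "synthetic",
                   species = sprintf("gaussian_m%g_sd%g", mean, sd))
    })
    rhythm_dataset(seqs, name = sprintf("gaussian_m%g_sd%g", mean, sd))
  })
}

#' Generate a jittered isochronous comb
#'
#' IOIs are `base_ioi * (1 + u)` with `u ~ Uniform(-jitter_frac,
#' +jitter_frac)`. With `jitter_frac = 0` this is [gen_isochronous()];
#' increasing jitter degrades every goodness-of-fit measure monotonically
#' (nGOF falls, FRMSD rises), which makes the jittered comb the standard
#' fixture for validating goodness-of-fit behaviour.
#'
#' @param base_ioi Base interval in seconds, > 0.
#' @param jitter_frac Jitter half-width as a fraction of `base_ioi`, in
#'   `[0, 0.5)`.
#' @param n_elements Number of onsets, >= 2.
#' @param seed Random seed (required).
#' @inheritParams element_sequence
#' @return An [element_sequence()].
#' @export
gen_jittered_comb <- function(base_ioi, jitter_frac, n_elements, seed,
                              sequence_id = "comb") {
  stopifnot(base_ioi > 0, jitter_frac >= 0, jitter_frac < 0.5, n_elements >= 2)
  with_seed(seed, {
    u <- stats::runif(n_elements - 1, -jitter_frac, jitter_frac)
    iois <- base_ioi * (1 + u)
    element_sequence(c(0, cumsum(iois)), sequence_id = sequence_id,
                     individual_id = "synthetic", species = "jittered_comb")
  })
}

#' Synthetic stand-in datasets at the three study conditions
#'
#' Generates fully synthetic datasets emulating the headline properties of
#' the three kinds of acoustic signal the method suite targets: short
#' monosyllabic bat isolation-call bouts (Carollia perspicillata-like),
#' medium multisyllabic bat isolation calls (Saccopteryx bilineata-like),
#' and very long sperm whale (Physeter macrocephalus-like) echolocation
#' click trains. IOIs are Gaussian with rejection of non-positive draws;
#' per-sequence tempo offsets add between-individual variability. These
#' are synthetic emulations — sequence counts, element-count ranges and
#' IOI means/SDs match the published descriptive statistics of each signal
#' type, but the data are generated, not recorded.
#'
#' Conditions: `"carollia"` 47 sequences, 5 individuals, 3-11 elements,
#' IOI ~ N(0.043, 0.013); `"saccopteryx"` 50 sequences, 5 individuals,
#' 5-26 elements (mean 14, sd 3.5), IOI ~ N(0.078, 0.022); `"physeter"`
#' 60 sequences, 1 individual, 13-248 elements (mean 115, sd 48),
#' IOI ~ N(0.46, 0.10). All times in seconds.
#'
#' @param species One of `"carollia"`, `"saccopteryx"`, `"physeter"`.
#' @param seed Random seed (required).
#' @param between_sequence_cv Fraction of the mean IOI used as the SD of a
#'   per-sequence multiplicative tempo offset (creates the gap between the
#'   pooled CV and the mean per-sequence CV). Defaults per condition.
#' @return A [rhythm_dataset()] of [ioi_sequence()] objects.
#' @export
synth_study_dataset <- function(species = c("carollia", "saccopteryx",
                                            "physeter"),
                                seed, between_sequence_cv = NULL) {
  species <- match.arg(species)
  cfg <- switch(species,
    carollia = list(n_seq = 47, n_ind = 5, el_mean = 5.1, el_sd = 2,
                    el_min = 3, el_max = 11, ioi_mean = 0.043,
                    ioi_sd = 0.013, bscv = 0.12),
    saccopteryx = list(n_seq = 50, n_ind = 5, el_mean = 14, el_sd = 3.5,
                       el_min = 5, el_max = 26, ioi_mean = 0.078,
                       ioi_sd = 0.022, bscv = 0.10),
    physeter = list(n_seq = 60, n_ind = 1, el_mean = 115, el_sd = 48,
                    el_min = 13, el_max = 248, ioi_mean = 0.46,
                    ioi_sd = 0.10, bscv = 0.08))
  if (is.null(between_sequence_cv)) between_sequence_cv <- cfg$bscv
  with_seed(seed, {
    seqs <- lapply(seq_len(cfg$n_seq), function(i) {
      n_el <- round(stats::rnorm(1, cfg$el_mean, cfg$el_sd))
      n_el <- max(cfg$el_min, min(cfg$el_max, n_el))
      tempo <- exp(stats::rnorm(1, 0, between_sequence_cv))
      mu <- cfg$ioi_mean * tempo
      # within-sequence SD scaled so the pooled SD stays near the target
      sdw <- cfg$ioi_sd * sqrt(max(0.1, 1 - between_sequence_cv^2))
      x <- stats::rnorm(n_el - 1, mu, sdw)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sdw)
      ioi_sequence(x, sequence_id = sprintf("%s_%03d", species, i),
                   individual_id = sprintf("%s_ind%d", species,
                                           ((i - 1) %% cfg$n_ind) + 1),
                   species = paste0("synthetic_", species))
    })
    rhythm_dataset(seqs, name = paste0("synthetic_", species))
  })
}
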