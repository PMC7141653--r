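test_that("binarization maps onsets to the expected samples", {
  b <- binarize_onsets(c(0, 0.1, 0.2), dt = 0.005)
  expect_equal(b$n_samples, 41)
  expect_equal(which(b$values == 1) - 1, c(0, 20, 40))
  expect_equal(b$n_events, 3)
  expect_equal(b$values[1], 1L)
  expect_equal(b$values[b$n_samples], 1L)

  # first onset shifts to sample 0
  b2 <- binarize_onsets(c(0.05, 0.15), dt = 0.005)
  expect_equal(b2$n_samples, 21)
  expect_equal(which(b2$values == 1) - 1, c(0, 20))

  # collision: two onsets in one sample merge with a warning
  expect_warning(
    expect_warning(b3 <- binarize_onsets(c(0, 0.001, 0.1), dt = 0.005),
                   "collided"),
    "coarser")
  expect_equal(which(b3$values == 1) - 1, c(0, 20))
  expect_equal(b3$n_collisions, 1)

  # dt coarser than the smallest IOI warns
  expect_warning(binarize_onsets(c(0, 0.003, 0.1), dt = 0.005), "coarser")
})

test_that("the zero bin equals the time-domain mean and bounds the spectrum", {
  set.seed(5)
  for (i in 1:10) {
    on <- cumsum(runif(sample(3:15, 1), 0.02, 0.5))
    b <- suppressWarnings(binarize_onsets(on))
    sp <- suppressWarnings(fft_best_beat(b))
    expect_equal(sp$p0, b$n_events / b$n_samples, tolerance = 1e-12)
    expect_true(all(sp$amplitudes <= sp$p0 + 1e-12))
  }
})

test_that("spectrum agrees with a direct-sum transform oracle", {
  set.seed(6)
  for (i in 1:5) {
    on <- cumsum(runif(sample(4:12, 1), 0.05, 0.4))
    b <- suppressWarnings(binarize_onsets(on))
    if (b$n_samples > 512) next
    sp <- suppressWarnings(fft_best_beat(b))
    oracle <- Mod(dft_oracle(b$values))
    half <- seq_along(sp$amplitudes)
    expect_equal(sp$amplitudes, oracle[half], tolerance = 1e-9)
  }
})

test_that("a 10 Hz comb yields the comb's beat and the comb's p0", {
  on <- seq(0, 2, by = 0.1)  # 21 events, 401 samples at dt = 0.005
  sp <- fft_best_beat(binarize_onsets(on))
  expect_equal(sp$p0, 21 / 401, tolerance = 1e-12)
  expect_lte(abs(sp$best_frequency - 10), sp$freq_resolution)
  # beat detection is translation invariant
  sp2 <- fft_best_beat(binarize_onsets(on + 13.7))
  expect_equal(sp2$best_frequency, sp$best_frequency)
  expect_equal(sp2$amplitudes, sp$amplitudes, tolerance = 1e-12)
  expect_equal(sp2$gof, sp$gof, tolerance = 1e-12)
  expect_equal(sp2$ngof, sp$ngof, tolerance = 1e-12)
})

test_that("degenerate spectra are flagged and bad configs rejected", {
  # every sample an event: constant signal, no nonzero-frequency peak
  b <- binarize_onsets(seq(0, 0.1, by = 0.005), dt = 0.005)
  expect_true(all(b$values == 1))
  sp <- fft_best_beat(b)
  expect_true(sp$no_beat)
  expect_true(is.na(sp$best_frequency))

  expect_error(fft_best_beat(binarize_onsets(c(0, 0.1, 0.2)), f_max = 150),
               "Nyquist")
})

test_that("goodness of fit degrades with timing jitter", {
  perfect <- fft_best_beat(binarize_onsets(seq(0, 2, by = 0.1)))
  set.seed(8)
  iois <- 0.1 * (1 + runif(20, -0.2, 0.2))
  jit <- suppressWarnings(fft_best_beat(binarize_onsets(c(0, cumsum(iois)))))
  expect_gt(perfect$gof, jit$gof)
  expect_gt(perfect$ngof, jit$ngof)
  g <- goodness_of_fit(perfect)
  expect_equal(g$gof, perfect$gof)
  expect_equal(g$ngof, perfect$ngof)
})

test_that("nGOF length conventions differ by the expected factor", {
  b <- binarize_onsets(seq(0, 2, by = 0.1))
  s_samp <- fft_best_beat(b, length_unit = "samples")
  s_sec <- fft_best_beat(b, length_unit = "seconds")
  expect_equal(s_samp$ngof * b$n_samples, s_sec$ngof * b$duration,
               tolerance = 1e-12)
  expect_equal(s_samp$gof, s_sec$gof)
})

test_that("frequency resolution is the spectral bin spacing", {
  b <- binarize_onsets(c(0, 0.995), dt = 0.005)  # 200 samples, 1.0 s
  expect_equal(frequency_resolution(b), 1)
  b2 <- binarize_onsets(c(0, 2), dt = 0.005)     # 401 samples
  expect_equal(frequency_resolution(b2), 200 / 401, tolerance = 1e-12)
  b3 <- binarize_onsets(c(0, 0.495), dt = 0.005) # 100 samples, 0.5 s
  expect_warning(r <- frequency_resolution(b3), "coarse")
  expect_equal(r, 2)
})
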