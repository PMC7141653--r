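test_that("generators are deterministic under a seed and emit positive IOIs", {
  a <- gen_uniform(seed = 42)
  b <- gen_uniform(seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, gen_uniform(seed = 43)))

  g1 <- gen_gaussian(0.1, 0.05, seed = 7)
  g2 <- gen_gaussian(0.1, 0.05, seed = 7)
  expect_identical(g1, g2)

  for (ds in list(a, g1, gen_gaussian(1, 0.5, seed = 3, n_sequences = 2))) {
    iois <- unlist(lapply(ds$sequences, `[[`, "iois"))
    expect_true(all(iois > 0))
  }

  c1 <- gen_jittered_comb(0.1, 0.2, 30, seed = 5)
  expect_identical(c1, gen_jittered_comb(0.1, 0.2, 30, seed = 5))
  expect_true(all(diff(c1$onsets) > 0))

  # seeded generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(gen_uniform(seed = 1)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("uniform IOIs respect their range and aperiodicity", {
  ds <- gen_uniform(seed = 21)
  expect_length(ds, 10)
  iois <- unlist(lapply(ds$sequences, `[[`, "iois"))
  expect_length(iois, 10 * 99)
  expect_true(all(iois > 0 & iois < 1))
  # law of large numbers: mean within 3 standard errors of 0.5
  se <- sqrt(1 / 12) / sqrt(length(iois))
  expect_lt(abs(mean(iois) - 0.5), 3 * se)
  # aperiodic control: per-sequence nPVI far from 0
  npvis <- vapply(ds$sequences, function(s) npvi(s$iois), numeric(1))
  expect_true(all(npvis > 40))
})

test_that("gaussian rejection sampling truncates at zero and biases upward", {
  ds <- gen_gaussian(0.1, 0.05, seed = 8)
  iois <- unlist(lapply(ds$sequences, `[[`, "iois"))
  expect_true(all(iois > 0))

  # truncation at 0 lifts the realized mean above the nominal one; for
  # mean 0.2, sd 0.1 the truncated-normal mean is 0.2 + 0.1*phi(2)/Phi(2)
  ds2 <- gen_gaussian(0.2, 0.1, seed = 9, n_sequences = 30)
  iois2 <- unlist(lapply(ds2$sequences, `[[`, "iois"))
  expected <- 0.2 + 0.1 * dnorm(2) / pnorm(2)
  expect_equal(mean(iois2), expected, tolerance = 0.03)
  expect_gt(mean(iois2), 0.2)

  # slow sequences: per-sequence mean-IOI beat near 1 Hz
  ds3 <- gen_gaussian(1, 0.5, seed = 10)
  beats <- vapply(ds3$sequences, function(s) beat_from_mean_ioi(s$iois),
                  numeric(1))
  expect_equal(median(beats), 1 / (1 + 0.5 * dnorm(2) / pnorm(2)),
               tolerance = 0.1)
})

test_that("zero jitter reduces the comb to the isochronous generator", {
  c0 <- gen_jittered_comb(0.3, 0, 12, seed = 1)
  expect_equal(c0$onsets, gen_isochronous(0.3, 12)$onsets, tolerance = 1e-12)
})

test_that("isochronous sequences drive all methods to the truth", {
  # the three generating IOIs and the beats every method must recover
  cases <- data.frame(ioi = c(0.1, 0.3, 0.5), hz = c(10, 10 / 3, 2))
  for (k in seq_len(nrow(cases))) {
    s <- gen_isochronous(cases$ioi[k], 21)
    iois <- compute_iois(s)$iois
    expect_equal(npvi(iois), 0)
    expect_equal(coefficient_of_variation(iois)$cv_star, 0)
    expect_equal(beat_from_mean_ioi(iois), cases$hz[k], tolerance = 1e-12)
    g <- gat_search(s)
    expect_lte(abs(g$best_frequency - cases$hz[k]), 0.01)
    expect_lte(g$best_frmsd, 0.02)
    sp <- fft_best_beat(binarize_onsets(s))
    expect_lte(abs(sp$best_frequency - cases$hz[k]), sp$freq_resolution)
  }
})

test_that("jittered combs keep the underlying beat recoverable", {
  hits <- 0
  for (i in 1:20) {
    cb <- gen_jittered_comb(0.1, 0.1, 15, seed = 100 + i)
    if (abs(gat_search(cb)$best_frequency - 10) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("study-condition stand-ins reproduce their design parameters", {
  for (cfg in list(list(sp = "carollia", n = 47, el = c(3, 11), m = 0.043),
                   list(sp = "saccopteryx", n = 50, el = c(5, 26), m = 0.078),
                   list(sp = "physeter", n = 60, el = c(13, 248), m = 0.46))) {
    ds <- synth_study_dataset(cfg$sp, seed = 17)
    expect_identical(ds, synth_study_dataset(cfg$sp, seed = 17))
    expect_length(ds, cfg$n)
    lens <- vapply(ds$sequences, function(s) length(s$iois) + 1L, integer(1))
    expect_true(all(lens >= cfg$el[1] & lens <= cfg$el[2]))
    s <- dataset_summary(ds)
    expect_equal(s$mean_ioi, cfg$m, tolerance = 0.15)
    expect_true(all(unlist(lapply(ds$sequences, `[[`, "iois")) > 0))
  }
})
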