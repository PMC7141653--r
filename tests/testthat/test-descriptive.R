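test_that("coefficient of variation matches hand-computed values", {
  z <- coefficient_of_variation(c(0.1, 0.1, 0.1))
  expect_equal(z$cv_hat, 0)
  expect_equal(z$cv_star, 0)

  # n = 2: sd = 0.0707107, mean = 0.15
  z <- coefficient_of_variation(c(0.1, 0.2))
  expect_equal(z$cv_hat, sqrt(0.005) / 0.15, tolerance = 1e-12)
  expect_equal(z$cv_hat, 0.4714, tolerance = 1e-4)
  expect_equal(z$cv_star, (1 + 1 / 8) * z$cv_hat)
  expect_equal(z$cv_star, 0.5303, tolerance = 1e-4)

  expect_error(coefficient_of_variation(0.1), "at least 2")
})

test_that("the unbiased CV correction always increases the estimate", {
  set.seed(1)
  for (i in 1:25) {
    x <- runif(sample(2:40, 1), 0.01, 2)
    z <- coefficient_of_variation(x)
    expect_gte(z$cv_star, z$cv_hat)
    expect_equal(z$cv_star / z$cv_hat, 1 + 1 / (4 * length(x)),
                 tolerance = 1e-12)
  }
})

test_that("nPVI matches direct computation and its bounds", {
  # constant sequences give exactly 0, whatever the value or length
  set.seed(2)
  for (i in 1:10) {
    v <- runif(1, 0.001, 5)
    expect_identical(npvi(rep(v, sample(2:50, 1))), 0)
  }
  expect_equal(npvi(c(0.1, 0.3)), 100)
  expect_equal(npvi(c(1, 2, 1)), 200 / 3, tolerance = 1e-12)

  # brute-force oracle agreement and bounds on random sequences
  for (i in 1:25) {
    x <- runif(sample(2:40, 1), 0.01, 2)
    v <- npvi(x)
    expect_equal(v, npvi_oracle(x), tolerance = 1e-12)
    expect_gte(v, 0)
    expect_lt(v, 200)
  }
  expect_error(npvi(0.5), "at least 2")
})

test_that("mean-IOI beat conversion is the reciprocal mean", {
  expect_equal(beat_from_mean_ioi(rep(0.1, 7)), 10)
  expect_equal(beat_from_mean_ioi(c(0.2, 0.3)), 4)
  expect_equal(beat_from_mean_ioi(0.46), 1 / 0.46)
  expect_error(beat_from_mean_ioi(numeric(0)), "at least 1")
})

test_that("IOI statistics are scale invariant; beat scales inversely", {
  set.seed(3)
  x <- runif(20, 0.02, 0.5)
  for (c in c(0.1, 3, 1000)) {
    expect_equal(coefficient_of_variation(c * x)$cv_star,
                 coefficient_of_variation(x)$cv_star, tolerance = 1e-12)
    expect_equal(npvi(c * x), npvi(x), tolerance = 1e-12)
    expect_equal(beat_from_mean_ioi(c * x), beat_from_mean_ioi(x) / c,
                 tolerance = 1e-12)
  }
})

test_that("dataset summaries separate within- from between-sequence variation", {
  iso <- function(v, id) ioi_sequence(rep(v, 10), sequence_id = id)

  # identical isochronous sequences: everything zero
  ds <- rhythm_dataset(list(iso(0.1, "a"), iso(0.1, "b"), iso(0.1, "c")))
  s <- dataset_summary(ds)
  expect_equal(s$cv_overall, 0)
  expect_equal(s$cv_sequence_mean, 0)
  expect_equal(s$npvi_mean, 0)
  expect_equal(s$n_iois, 30)

  # internally isochronous but different tempi: only the pooled CV moves
  ds2 <- rhythm_dataset(list(iso(0.1, "a"), iso(0.3, "b")))
  s2 <- dataset_summary(ds2)
  expect_equal(s2$cv_sequence_mean, 0)
  expect_gt(s2$cv_overall, 0)
  expect_gt(s2$cv_gap, 0)

  # pooled nPVI skips the pair straddling the sequence boundary
  expect_equal(s2$npvi_overall, 0)
  expect_true(s2$overall_npvi_excludes_boundaries)

  # counts and range bracket every IOI
  set.seed(4)
  seqs <- lapply(1:5, function(i)
    ioi_sequence(runif(sample(3:12, 1), 0.01, 1), sequence_id = paste0("s", i)))
  s3 <- dataset_summary(rhythm_dataset(seqs))
  all_iois <- unlist(lapply(seqs, `[[`, "iois"))
  expect_equal(s3$n_iois, length(all_iois))
  expect_equal(s3$ioi_range, range(all_iois))
  expect_gte(s3$cv_overall, 0)
  expect_gte(s3$cv_sequence_mean, 0)

  # sequences with < 2 IOIs are skipped with a warning, not fatal
  ds4 <- rhythm_dataset(list(iso(0.1, "a"), ioi_sequence(0.2, sequence_id = "b")))
  expect_warning(s4 <- dataset_summary(ds4), "skipped")
  expect_equal(s4$n_sequences, 1)
  expect_equal(s4$n_skipped, 1)
})
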