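test_that("label files parse, sort leniently and error on bad rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0\t0.05\ta", "0.1\t0.15\tb", "0.2\t0.25\ta"), f)
  s <- read_label_file(f, species = "test")
  expect_s3_class(s, "element_sequence")
  expect_equal(s$onsets, c(0, 0.1, 0.2))
  expect_equal(s$labels, c("a", "b", "a"))

  # header line is skipped
  writeLines(c("onset\toffset", "0.0\t0.05", "0.1\t0.15"), f)
  expect_equal(read_label_file(f)$onsets, c(0, 0.1))

  # offset < onset names the row
  writeLines(c("0.0\t0.05", "0.1\t0.05"), f)
  expect_error(read_label_file(f), "row 2")

  # shuffled rows: lenient sorts with a warning, strict errors
  writeLines(c("0.2\t0.25", "0.0\t0.05", "0.1\t0.15"), f)
  expect_warning(s <- read_label_file(f), "sorted")
  expect_equal(s$onsets, c(0, 0.1, 0.2))
  expect_error(read_label_file(f, strict = TRUE), "increasing")

  # non-numeric field
  writeLines(c("0.0\t0.05", "oops\t0.15"), f)
  expect_error(read_label_file(f), "row 2")

  # millisecond input converts to seconds
  writeLines(c("0\t50", "100\t150"), f)
  expect_equal(read_label_file(f, unit = "ms")$onsets, c(0, 0.1))

  expect_error(read_label_file(file.path(tempdir(), "nope.txt")), "cannot read")
})

test_that("IOI tables read into grouped datasets and reject bad values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,individual,sequence_id,ioi_s",
               "batA,ind1,s1,0.1", "batA,ind1,s1,0.12",
               "batA,ind2,s2,0.2", "batA,ind2,s2,0.21"), f)
  ds <- read_ioi_table(f)
  expect_s3_class(ds, "rhythm_dataset")
  expect_length(ds, 2)
  expect_equal(ds$sequences[[1]]$iois, c(0.1, 0.12))
  expect_equal(ds$sequences[[2]]$individual_id, "ind2")

  # custom column mapping
  writeLines(c("sp,id,seq,interval", "x,a,1,0.5", "x,a,1,0.6"), f)
  ds2 <- read_ioi_table(f, columns = c(species = "sp", individual = "id",
                                       sequence = "seq", ioi = "interval"))
  expect_equal(ds2$sequences[[1]]$iois, c(0.5, 0.6))

  # missing column
  expect_error(read_ioi_table(f), "missing required column")

  # non-positive IOI lists the row
  writeLines(c("species,individual,sequence_id,ioi_s",
               "batA,ind1,s1,0.1", "batA,ind1,s1,-0.2"), f)
  expect_error(read_ioi_table(f), "rows: 2")
})

test_that("writing then reading an IOI table preserves values exactly", {
  set.seed(42)
  seqs <- lapply(1:3, function(i)
    ioi_sequence(runif(5, 0.01, 1), sequence_id = paste0("s", i),
                 individual_id = "ind1", species = "sp"))
  ds <- rhythm_dataset(seqs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ioi_table(ds, f)
  back <- read_ioi_table(f, columns = c(species = "species",
                                        individual = "individual",
                                        sequence = "sequence_id",
                                        ioi = "ioi_s"))
  for (i in 1:3)
    expect_equal(back$sequences[[i]]$iois, ds$sequences[[i]]$iois)
})

test_that("onsets and IOIs convert in both directions and round-trip", {
  s <- element_sequence(c(0, 0.1, 0.3))
  expect_equal(compute_iois(s)$iois, c(0.1, 0.2))
  expect_error(compute_iois(element_sequence(0)), "at least 2")

  expect_equal(onsets_from_iois(ioi_sequence(c(0.1, 0.2)))$onsets,
               c(0, 0.1, 0.3))
  expect_warning(o <- onsets_from_iois(structure(
    list(iois = numeric(0), sequence_id = "x", individual_id = "i",
         species = "s"), class = "ioi_sequence")), "single onset")
  expect_equal(o$onsets, 0)

  # round trip on random positive IOIs; onsets shifted to start at 0
  set.seed(7)
  for (i in 1:20) {
    x <- runif(sample(2:30, 1), 1e-3, 2)
    expect_equal(compute_iois(onsets_from_iois(ioi_sequence(x)))$iois, x)
    on <- cumsum(runif(5, 0.01, 1)) + 3
    s <- element_sequence(on)
    expect_equal(onsets_from_iois(compute_iois(s))$onsets, on - on[1])
  }
})

test_that("sequence containers enforce their invariants", {
  expect_error(element_sequence(c(0, 0, 0.1)), "strictly increasing")
  expect_error(element_sequence(c(0, 0.1), offsets = c(0.05)), "same length")
  expect_error(element_sequence(c(0, 0.1), offsets = c(0.05, 0.05)),
               "greater than its onset")
  expect_error(ioi_sequence(c(0.1, 0)), "> 0")
  s1 <- ioi_sequence(0.1, sequence_id = "a")
  expect_error(rhythm_dataset(list(s1, s1)), "unique")
})
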