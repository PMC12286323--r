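test_that("trial construction enforces metadata and marker invariants", {
  expect_error(make_trial(sas = 11L), "sas must be in 1..10")
  expect_error(make_trial(sas = 0L), "sas must be in 1..10")
  expect_s3_class(make_trial(sas = NA_integer_, mc_correct = NA), "nirs_trial")
  d <- matrix(rnorm(20), 2)
  expect_error(nirs_trial("t", "p", "OxyHb", d, 10, markers = c(5L, 5L)),
               "markers")
  expect_error(nirs_trial("t", "p", "OxyHb", d, 10, markers = c(0L, 10L)),
               "markers")
  d[1, 3] <- NA
  expect_error(nirs_trial("t", "p", "OxyHb", d, 10), "non-finite")
})

test_that("trial sets require consistent channels, fs and unique ids", {
  t1 <- make_trial(id = "A", n_channels = 3L)
  t2 <- make_trial(id = "B", n_channels = 3L, seed = 2L)
  expect_length(nirs_trial_set(list(t1, t2)), 2L)
  expect_error(nirs_trial_set(list(t1, make_trial(id = "B", n_channels = 4L))),
               "channel count")
  expect_error(nirs_trial_set(list(t1, make_trial(id = "A", seed = 3L))),
               "duplicate trial ids")
})

test_that("write_trials then read_trials round-trips matrices bit-for-bit", {
  set.seed(42)
  trials <- lapply(1:3, function(i)
    nirs_trial(sprintf("T%02d", i), "P01", "DeoxyHb",
               matrix(rnorm(4 * 37) * 10^sample(-6:6, 1), 4), fs = 10.1725,
               sas = sample(1:10, 1), mc_correct = sample(c(TRUE, FALSE), 1),
               markers = c(1L, 35L)))
  ts <- nirs_trial_set(trials)
  dir <- withr::local_tempdir()
  write_trials(ts, dir)
  back <- read_trials(dir)
  expect_length(back, 3L)
  for (id in names(ts$trials)) {
    expect_identical(back$trials[[id]]$data, ts$trials[[id]]$data)
    expect_identical(back$trials[[id]]$sas, ts$trials[[id]]$sas)
    expect_identical(back$trials[[id]]$mc_correct, ts$trials[[id]]$mc_correct)
    expect_identical(back$trials[[id]]$markers, ts$trials[[id]]$markers)
    expect_equal(back$trials[[id]]$fs, ts$trials[[id]]$fs)
  }
})

test_that("absent metadata survives a round trip as absent", {
  t1 <- make_trial(id = "T1", sas = NA_integer_, mc_correct = NA)
  dir <- withr::local_tempdir()
  write_trials(nirs_trial_set(list(t1)), dir)
  back <- read_trials(dir)
  expect_true(is.na(back$trials[["T1"]]$sas))
  expect_true(is.na(back$trials[["T1"]]$mc_correct))
})

test_that("an empty trial set writes a header-only metadata file", {
  dir <- withr::local_tempdir()
  write_trials(nirs_trial_set(list()), dir)
  lines <- readLines(file.path(dir, "metadata.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "^trial_id,participant_id,chromophore")
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  write_trials(nirs_trial_set(list(make_trial(id = "T1"))), dir)
  # metadata sas out of bounds
  meta <- read.csv(file.path(dir, "metadata.csv"))
  meta$sas <- 11
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE, na = "")
  expect_error(read_trials(dir), "sas must be in 1..10")
  write.csv(transform(meta, sas = 5), file.path(dir, "metadata.csv"),
            row.names = FALSE, na = "")
  # ragged matrix
  writeLines(c("1,2,3", "4,5"), file.path(dir, "T1.csv"))
  expect_error(read_trials(dir), "ragged")
  # non-numeric cell
  writeLines(c("1,2,3", "4,x,6"), file.path(dir, "T1.csv"))
  expect_error(read_trials(dir), "non-numeric cell in row 2")
  # orphan matrix file
  writeLines(c("1,2,3", "4,5,6"), file.path(dir, "T1.csv"))
  writeLines(c("1,2,3"), file.path(dir, "T9.csv"))
  expect_error(read_trials(dir), "without metadata")
  # matrix missing
  file.remove(file.path(dir, "T9.csv"), file.path(dir, "T1.csv"))
  expect_error(read_trials(dir), "without matrix")
})

test_that("total_hb is the elementwise sum with chromophore bookkeeping", {
  oxy <- make_trial(chromophore = "OxyHb", seed = 5L)
  deoxy <- make_trial(chromophore = "DeoxyHb", seed = 6L)
  tot <- total_hb(oxy, deoxy)
  expect_equal(tot$chromophore, "TotalHb")
  expect_identical(tot$data, oxy$data + deoxy$data)  # brute-force sum
  # additive identity and cancellation
  zero <- oxy; zero$data[] <- 0
  expect_identical(total_hb(zero, deoxy)$data, deoxy$data)
  neg <- deoxy; neg$data <- -oxy$data
  expect_true(all(total_hb(oxy, neg)$data == 0))
  # commutative in the data
  expect_identical(total_hb(oxy, deoxy)$data,
                   oxy$data + deoxy$data)
  # mismatches rejected
  expect_error(total_hb(deoxy, oxy), "expects \\(OxyHb, DeoxyHb\\)")
  other <- make_trial(id = "T99", chromophore = "DeoxyHb")
  expect_error(total_hb(oxy, other), "id mismatch")
  short <- make_trial(chromophore = "DeoxyHb", n_samples = 40L)
  expect_error(total_hb(oxy, short), "shape mismatch")
})
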