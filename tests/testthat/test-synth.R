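# a small, fast generator configuration used throughout these tests
small_cfg <- function(...) {
  synth_config(n_participants = 4L, trials_per_participant = 15L,
               n_channels = 4L, informative_channels = c(2L, 3L),
               length_range = c(120L, 160L), ...)
}

test_that("study-shaped preset matches the recording protocol", {
  ts <- study_shaped(seed = 5, n_channels = 4L,
                     informative_channels = c(2L, 3L),
                     length_range = c(60L, 80L))
  expect_length(ts, 450L)                        # 15 participants x 30 texts
  meta <- trial_metadata(ts)
  expect_equal(length(unique(meta$participant_id)), 15L)
  expect_true(all(meta$fs == 10.1725))
  full <- synth_config()
  expect_equal(full$n_channels, 20L)
  expect_equal(full$length_range, c(400L, 1300L))
  ts2 <- synth_generate(small_cfg(seed = 2))
  lens <- vapply(ts2$trials, function(t) ncol(t$data), 0L)
  expect_true(all(lens >= 120L & lens <= 160L))
  m <- trial_metadata(ts2)
  expect_true(all(m$s1 < m$s2 & m$s1 >= 0 & m$s2 < m$n_samples))
})

test_that("generation is deterministic under the seed", {
  a <- synth_generate(small_cfg(seed = 9))
  b <- synth_generate(small_cfg(seed = 9))
  expect_identical(a$trials, b$trials)
  expect_identical(attr(a, "true_class"), attr(b, "true_class"))
  c_ <- synth_generate(small_cfg(seed = 10))
  expect_false(identical(a$trials[[1]]$data, c_$trials[[1]]$data))
})

test_that("chromophores share metadata but carry opposite-signed responses", {
  deoxy <- synth_generate(small_cfg(seed = 4, effect_size = 0))
  oxy <- synth_generate(small_cfg(seed = 4, effect_size = 0,
                                  chromophore = "OxyHb"))
  md <- trial_metadata(deoxy)
  mo <- trial_metadata(oxy)
  expect_identical(md[setdiff(names(md), "chromophore")],
                   mo[setdiff(names(mo), "chromophore")])
  # evoked means have opposite signs (averaged over trials to beat noise)
  resp <- function(ts) mean(vapply(ts$trials, function(t) {
    i <- (t$markers[1] + 20):t$markers[2]
    mean(t$data[1, i]) - mean(t$data[1, 1:t$markers[1]])
  }, 0))
  expect_gt(resp(oxy), 0)
  expect_lt(resp(deoxy), 0)
})

test_that("zero effect size makes the classes exchangeable", {
  ts <- synth_generate(small_cfg(seed = 12, effect_size = 0))
  truth <- attr(ts, "true_class")
  amp <- vapply(ts$trials, function(t) mean(abs(t$data[2, ])), 0)
  p <- t.test(amp[truth == "understood"],
              amp[truth == "not_understood"])$p.value
  expect_gt(p, 0.01)
  # with a large effect the same statistic separates strongly
  ts2 <- synth_generate(small_cfg(seed = 12, effect_size = 3))
  truth2 <- attr(ts2, "true_class")
  amp2 <- vapply(ts2$trials, function(t) mean(abs(t$data[2, ])), 0)
  p2 <- t.test(amp2[truth2 == "understood"],
               amp2[truth2 == "not_understood"])$p.value
  expect_lt(p2, 1e-6)
})

test_that("sas_noise controls strategy-3 retention and bin coverage", {
  clean <- synth_generate(small_cfg(seed = 3, sas_noise = 0, blank_rate = 0))
  noisy <- synth_generate(small_cfg(seed = 3, sas_noise = 0.3, blank_rate = 0))
  n_clean <- nrow(label_strategy3(clean))
  n_noisy <- nrow(label_strategy3(noisy))
  expect_equal(n_clean, length(clean))           # all trials retained
  expect_lt(n_noisy, n_clean)
  # noisy SAS covers all three strategy-2 bins
  expect_equal(nlevels(droplevels(label_strategy2(noisy)$label)), 3L)
})

test_that("end-to-end accuracy is non-decreasing in effect size", {
  # Scaled-down pipeline with clean labels so the property isolates the
  # signal pathway; trials are kept long enough (~36-40 s) for the
  # class-coupled low-frequency component to complete several cycles.
  run_ca <- function(effect, seed) {
    ts <- synth_generate(synth_config(
      n_participants = 4L, trials_per_participant = 15L, n_channels = 4L,
      informative_channels = c(2L, 3L), length_range = c(360L, 400L),
      sas_noise = 0, blank_rate = 0, effect_size = effect, seed = seed))
    cfg <- run_config(strategy = 1, imf_index = 3, n_segments = 100L,
                      alphabet_size = 8L, channels = c(2L, 3L),
                      max_combo_size = 2L, n_runs = 1L,
                      features = c("skewness", "kurtosis", "std"),
                      k_range = c(1L, 5L, 9L), n_realizations = 10L,
                      select = "test_max", seed = seed)
    run_pipeline(ts, cfg)$summary$mean_ca
  }
  seeds <- 101:105
  ca0 <- mean(vapply(seeds, function(s) run_ca(0, s), 0))
  ca1 <- mean(vapply(seeds, function(s) run_ca(1.5, s), 0))
  ca2 <- mean(vapply(seeds, function(s) run_ca(3, s), 0))
  expect_lte(ca0, ca1 + 0.02)                    # small Monte-Carlo slack
  expect_lte(ca1, ca2 + 0.02)
  expect_gt(ca2, ca0)
})
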