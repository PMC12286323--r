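# Small in-code fixtures shared across test files.

# a minimal valid trial with reproducible random data
make_trial <- function(id = "T01", participant = "P01",
                       chromophore = "OxyHb", n_channels = 3L,
                       n_samples = 50L, fs = 10.1725, sas = 7L,
                       mc_correct = TRUE, seed = 1L) {
  set.seed(seed)
  nirs_trial(trial_id = id, participant_id = participant,
             chromophore = chromophore,
             data = matrix(rnorm(n_channels * n_samples), n_channels),
             fs = fs, sas = sas, mc_correct = mc_correct,
             markers = c(2L, n_samples - 3L))
}

# a trial set whose metadata (sas, mc_correct) is given per trial
make_metadata_set <- function(sas, mc_correct, n_channels = 2L,
                              n_samples = 30L) {
  stopifnot(length(sas) == length(mc_correct))
  trials <- lapply(seq_along(sas), function(i)
    make_trial(id = sprintf("T%03d", i),
               participant = sprintf("P%02d", (i - 1) %/% 30 + 1),
               n_channels = n_channels, n_samples = n_samples,
               sas = sas[i], mc_correct = mc_correct[i], seed = i))
  nirs_trial_set(trials)
}

# the study's printed confusion matrices (strategy 1, TotalHb IMF4 and
# strategy 3, DeoxyHb IMF3; five runs each), used as worked-example inputs
strategy1_counts <- data.frame(
  run = 1:5,
  tp = c(54, 54, 57, 59, 61), fn = c(20, 20, 17, 15, 13),
  tn = c(47, 47, 43, 41, 41), fp = c(14, 14, 18, 20, 20))

strategy3_counts <- data.frame(
  run = 1:5,
  tp = c(49, 47, 49, 50, 48), fn = c(3, 5, 3, 2, 4),
  tn = c(26, 25, 25, 23, 23), fp = c(4, 5, 5, 7, 7))
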