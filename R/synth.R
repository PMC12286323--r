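#' Synthetic fNIRS trial-set configuration
#'
#' Parameters of the synthetic reading-trial generator. Defaults emulate
#' the study conditions: 15 participants x 30 trials (450 trials), 20
#' channels at 10.1725 Hz, variable trial lengths up to 1300 samples.
#' Each trial is a hemodynamic-response-shaped component (canonical
#' difference-of-gammas kernel convolved with a boxcar spanning the
#' reading interval `[S1, S2)`), plus sinusoidal physiological components
#' (low-frequency oscillation and cardiac), a random-walk drift, and white
#' noise. On informative channels the response amplitude of `understood`
#' trials is scaled by `1 + effect_size`. OxyHb and DeoxyHb carry
#' opposite-signed responses (`oxy_gain`, `deoxy_gain`) with independent
#' noise, so TotalHb = OxyHb + DeoxyHb retains a net response.
#'
#' @param n_participants,trials_per_participant cohort shape
#' @param n_channels number of channels
#' @param fs sampling frequency, Hz
#' @param length_range `c(min, max)` trial lengths in samples
#' @param effect_size non-negative amplitude multiplier on informative
#'   channels for understood trials (0 = classes exchangeable)
#' @param informative_channels channel indices carrying the class effect
#' @param hrf_amplitude evoked-response amplitude (arbitrary
#'   concentration-change units)
#' @param oxy_gain,deoxy_gain chromophore response gains
#' @param osc_freqs,osc_amps physiological oscillation frequencies (Hz)
#'   and amplitudes
#' @param drift_sd per-sample standard deviation of the random-walk drift
#' @param noise_sd white-noise standard deviation
#' @param p_understood probability a trial is truly understood
#' @param sas_noise probability that the self-assessment score (and,
#'   independently, the multiple-choice outcome) disagrees with the true
#'   class
#' @param blank_rate probability the multiple-choice answer is left blank
#' @param chromophore `"DeoxyHb"`, `"OxyHb"`: which chromophore to emit
#' @param seed master seed
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_participants = 15L, trials_per_participant = 30L,
                         n_channels = 20L, fs = 10.1725,
                         length_range = c(400L, 1300L),
                         effect_size = 1, informative_channels = c(3L, 7L, 12L),
                         hrf_amplitude = 1, oxy_gain = 1, deoxy_gain = -0.4,
                         osc_freqs = c(0.1, 1.0), osc_amps = c(0.3, 0.15),
                         drift_sd = 0.02, noise_sd = 0.4,
                         p_understood = 0.55, sas_noise = 0.25,
                         blank_rate = 0.05,
                         chromophore = c("DeoxyHb", "OxyHb"), seed = 1L) {
  chromophore <- match.arg(chromophore)
  stopifnot(effect_size >= 0, all(informative_channels <= n_channels),
            length(length_range) == 2L, length_range[1] >= 4L,
            length_range[1] <= length_range[2],
            length(osc_freqs) == length(osc_amps),
            p_understood > 0, p_understood < 1,
            sas_noise >= 0, sas_noise <= 1, blank_rate >= 0, blank_rate < 1)
  structure(as.list(environment()), class = "synth_config")
}

# canonical double-gamma hemodynamic kernel sampled at fs, unit-area
hrf_kernel <- function(fs, duration = 30) {
  t <- seq(0, duration, by = 1 / fs)
  k <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  k / sum(k)
}

# ground-truth metadata drawn for one trial (class, sas, mc, length, markers)
draw_trial_meta <- function(cfg) {
  m <- if (cfg$length_range[1] == cfg$length_range[2]) cfg$length_range[1] else
    sample(cfg$length_range[1]:cfg$length_range[2], 1L)
  s1 <- sample(round(0.02 * m):round(0.06 * m), 1L)
  s2 <- m - 1L - sample(round(0.01 * m):round(0.05 * m), 1L)
  understood <- runif(1) < cfg$p_understood
  sas <- if (runif(1) < cfg$sas_noise) sample(1:10, 1L) else
    if (understood) sample(8:10, 1L) else sample(1:4, 1L)
  mc <- if (runif(1) < cfg$blank_rate) NA else
    xor(understood, runif(1) < cfg$sas_noise)
  list(m = m, s1 = s1, s2 = s2, understood = understood,
       sas = sas, mc_correct = mc)
}

# One channel's signal: evoked response + oscillations + drift + white noise.
# The class gain multiplies the evoked response and the task-linked
# low-frequency oscillation (the first osc component): neural engagement
# raises both the response and slow vasomotion power, so the class effect
# changes the shape of the evoked-to-noise mixture, not just its scale
# (a pure scale factor would be erased by the z-normalization downstream).
channel_signal <- function(cfg, meta, response, gain, informative) {
  m <- meta$m
  g <- if (informative && meta$understood) 1 + cfg$effect_size else 1
  x <- gain * cfg$hrf_amplitude * g * response
  tt <- (seq_len(m) - 1) / cfg$fs
  for (i in seq_along(cfg$osc_freqs)) {
    f <- cfg$osc_freqs[i] * exp(rnorm(1, 0, 0.03))
    a <- cfg$osc_amps[i] * (if (i == 1L) g else 1)
    x <- x + a * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  }
  x + cumsum(rnorm(m, 0, cfg$drift_sd)) + rnorm(m, 0, cfg$noise_sd)
}

#' Generate a synthetic trial set
#'
#' Deterministic under `cfg$seed`; every trial and channel draws from its
#' own counter-derived sub-seed, so the set is reproducible regardless of
#' evaluation order, and regenerating with the other chromophore yields
#' paired trials sharing metadata, markers and the underlying class.
#'
#' @param cfg a [synth_config()]
#' @return a [nirs_trial_set()] with per-trial `sas` and `mc_correct`; the
#'   ground-truth class of every trial is recorded in the
#'   `"true_class"` attribute (named character vector)
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  kern <- hrf_kernel(cfg$fs)
  gain <- if (cfg$chromophore == "OxyHb") cfg$oxy_gain else cfg$deoxy_gain
  trials <- list()
  truth <- character()
  for (p in seq_len(cfg$n_participants)) {
    for (tr in seq_len(cfg$trials_per_participant)) {
      meta <- with_seed(derive_seed(cfg$seed, p, tr, "meta"),
                        function() draw_trial_meta(cfg))
      u <- numeric(meta$m)
      u[(meta$s1 + 1):(meta$s2)] <- 1      # boxcar over the reading interval
      response <- convolve(u, rev(kern), type = "open")[seq_len(meta$m)]
      data <- matrix(0, cfg$n_channels, meta$m)
      for (ch in seq_len(cfg$n_channels)) {
        data[ch, ] <- with_seed(
          derive_seed(cfg$seed, p, tr, ch, cfg$chromophore),
          function() channel_signal(cfg, meta, response, gain,
                                    ch %in% cfg$informative_channels))
      }
      id <- sprintf("P%02dT%02d", p, tr)
      trials[[id]] <- nirs_trial(
        trial_id = id, participant_id = sprintf("P%02d", p),
        chromophore = cfg$chromophore, data = data, fs = cfg$fs,
        sas = meta$sas, mc_correct = meta$mc_correct,
        markers = c(meta$s1, meta$s2))
      truth[id] <- if (meta$understood) "understood" else "not_understood"
    }
  }
  out <- nirs_trial_set(trials)
  attr(out, "true_class") <- truth
  out
}

#' Study-shaped synthetic trial set
#'
#' Convenience preset matching the study's recording shape: 15
#' participants x 30 trials = 450 trials, 20 channels at 10.1725 Hz,
#' trial lengths up to 1300 samples.
#'
#' @param seed master seed
#' @param ... overrides passed to [synth_config()]
#' @return a [nirs_trial_set()] of 450 trials
#' @export
study_shaped <- function(seed, ...) {
  synth_generate(synth_config(seed = seed, ...))
}
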