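#' EMD sifting configuration
#'
#' Controls the empirical mode decomposition core: the Cauchy-type sifting
#' stop (`sum((h_prev - h_new)^2) / sum(h_prev^2) < sift_tolerance`, the
#' classical default 0.2), a sifting cap, mirrored boundary extrema, and
#' cubic-spline envelopes.
#'
#' @param max_siftings maximum sifting iterations per mode
#' @param sift_tolerance Cauchy stopping threshold (> 0)
#' @param boundary boundary rule; only `"mirror"` is implemented
#' @param envelope envelope interpolant; only `"cubic_spline"`
#' @return list of class `emd_config`
#' @export
emd_config <- function(max_siftings = 100L, sift_tolerance = 0.2,
                       boundary = "mirror", envelope = "cubic_spline") {
  stopifnot(sift_tolerance > 0, max_siftings >= 1)
  boundary <- match.arg(boundary, "mirror")
  envelope <- match.arg(envelope, "cubic_spline")
  structure(list(max_siftings = as.integer(max_siftings),
                 sift_tolerance = sift_tolerance,
                 boundary = boundary, envelope = envelope),
            class = "emd_config")
}

#' ICEEMDAN configuration
#'
#' Defaults follow the reference parameterization for biomedical signals:
#' noise amplitude constant `epsilon0 = 0.2` (the target noise-to-signal
#' ratio) and `n_realizations = 100` Gaussian noise sequences. `max_imfs`
#' defaults to 8 so that the fifth mode exists for signals around 1300
#' samples.
#'
#' @param epsilon0 desired signal-to-added-noise constant (> 0)
#' @param n_realizations number of noise realizations L
#' @param max_imfs maximum number of modes to extract (>= 1)
#' @param seed integer seed for the noise realizations
#' @param emd an [emd_config()] for the sifting core
#' @return list of class `iceemdan_config`
#' @export
iceemdan_config <- function(epsilon0 = 0.2, n_realizations = 100L,
                            max_imfs = 8L, seed = 1L, emd = emd_config()) {
  stopifnot(epsilon0 > 0, n_realizations >= 1)
  if (max_imfs < 1) stop("max_imfs must be >= 1")
  structure(list(epsilon0 = epsilon0,
                 n_realizations = as.integer(n_realizations),
                 max_imfs = as.integer(max_imfs),
                 seed = as.integer(seed), emd = emd),
            class = "iceemdan_config")
}

#' Local mean of a signal
#'
#' Mean of the upper and lower cubic-spline envelopes through the interior
#' local maxima and minima, with two extrema mirrored beyond each boundary.
#' A signal without both an interior maximum and an interior minimum is its
#' own trend and is returned unchanged.
#'
#' @param x numeric vector
#' @return numeric vector of the same length
#' @export
local_mean <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  .local_mean_cpp(as.double(x))
}

imf_set <- function(imfs, residue, n) {
  structure(list(imfs = imfs, residue = residue, source_len = n),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue, %d samples\n",
              nrow(x$imfs), x$source_len))
  invisible(x)
}

#' Classical empirical mode decomposition
#'
#' Repeated sifting (`h <- h - local_mean(h)`) extracts oscillatory modes
#' fast-to-slow until the residue has fewer than 3 extrema or `k_max` modes
#' were produced. The k-th extracted mode defines the mode operator `E_k`
#' used inside ICEEMDAN.
#'
#' @param x numeric vector, finite
#' @param cfg an [emd_config()]
#' @param k_max maximum number of modes
#' @return an `imf_set`: `imfs` (matrix, one row per mode), `residue`,
#'   `source_len`; the rows plus the residue sum to `x` exactly up to
#'   floating-point error
#' @export
emd <- function(x, cfg = emd_config(), k_max = 12L) {
  stopifnot(is.numeric(x), all(is.finite(x)), k_max >= 1)
  out <- .emd_cpp(as.double(x), as.integer(k_max),
                  cfg$sift_tolerance, cfg$max_siftings)
  imf_set(out$imfs, out$residue, length(x))
}

#' ICEEMDAN decomposition
#'
#' Improved complete ensemble EMD with adaptive noise. Each residue is
#' estimated as the average local mean over noise-perturbed copies of the
#' previous residue:
#' \deqn{r_1 = \mathrm{mean}_i\, M(x + \beta_0 E_1(w^{(i)})),\quad
#'       IMF_1 = x - r_1}
#' \deqn{r_j = \mathrm{mean}_i\, M(r_{j-1} + \beta_{j-1} E_j(w^{(i)})),\quad
#'       IMF_j = r_{j-1} - r_j}
#' with \eqn{\beta_0 = \epsilon_0\, sd(x) / sd(E_1(w^{(i)}))} computed per
#' realization and \eqn{\beta_j = \epsilon_0\, sd(r_j)} for later stages.
#' The same L seeded noise sequences are reused across stages, with the EMD
#' mode operator `E_j` applied per stage, so the modes telescope exactly:
#' `x = sum(IMFs) + residue`. Extraction stops when the residue has fewer
#' than 3 extrema or `max_imfs` is reached.
#'
#' @param x numeric vector, finite
#' @param cfg an [iceemdan_config()]
#' @return an `imf_set`
#' @export
iceemdan <- function(x, cfg = iceemdan_config()) {
  stopifnot(inherits(cfg, "iceemdan_config"), is.numeric(x), all(is.finite(x)))
  n <- length(x)
  noise <- with_seed(cfg$seed, function()
    matrix(rnorm(cfg$n_realizations * n), nrow = cfg$n_realizations))
  out <- .iceemdan_cpp(as.double(x), noise, cfg$epsilon0, cfg$max_imfs,
                       cfg$emd$sift_tolerance, cfg$emd$max_siftings)
  imf_set(out$imfs, out$residue, n)
}

#' Select one intrinsic mode function
#'
#' Returns the j-th IMF. If the decomposition produced fewer than `j`
#' modes, a zero sequence of the source length is returned with a warning
#' (fail-soft so that batch runs over many channels survive short
#' decompositions).
#'
#' @param s an `imf_set`
#' @param j 1-based mode index
#' @return numeric vector of length `s$source_len`
#' @export
select_imf <- function(s, j) {
  stopifnot(inherits(s, "imf_set"), j >= 1)
  if (j > nrow(s$imfs)) {
    warning("requested IMF ", j, " but only ", nrow(s$imfs),
            " modes extracted; returning zeros")
    return(numeric(s$source_len))
  }
  s$imfs[j, ]
}
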