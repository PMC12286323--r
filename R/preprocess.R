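#' Linearly resample a sequence to a target length
#'
#' Maps the index range `[0, m-1]` uniformly onto `[0, target_len-1]` and
#' evaluates the piecewise-linear interpolant of `x` at the new grid.
#' Endpoints are pinned: the first and last output samples equal the first
#' and last input samples. Used to standardize variable-length trials to a
#' common sample count before decomposition.
#'
#' @param x numeric vector, length >= 2
#' @param target_len integer >= 2
#' @return numeric vector of length `target_len`
#' @export
interpolate_to_length <- function(x, target_len) {
  m <- length(x)
  if (m < 2L) stop("need at least 2 samples to interpolate, got ", m)
  target_len <- as.integer(target_len)
  if (target_len < 2L) stop("target_len must be >= 2")
  if (m == target_len) return(x)
  pos <- seq(0, m - 1, length.out = target_len)
  approx(x = seq_len(m) - 1, y = x, xout = pos, method = "linear")$y
}

#' Standardize a trial set to a common length
#'
#' Every channel of every trial is interpolated independently to
#' `target_len` samples. The default target is the maximum sample count
#' observed in the set (the study convention: no signal is ever truncated);
#' scaled-down analyses can override it.
#'
#' @param ts a [nirs_trial_set()]
#' @param target_len common length; default `NULL` means the set-wide
#'   maximum sample count
#' @return a [nirs_trial_set()] whose trials all have `target_len` samples;
#'   markers are rescaled onto the new grid
#' @export
standardize_set <- function(ts, target_len = NULL) {
  stopifnot(inherits(ts, "nirs_trial_set"))
  lens <- vapply(ts$trials, function(t) ncol(t$data), 0L)
  if (is.null(target_len)) target_len <- max(lens)
  target_len <- as.integer(target_len)
  trials <- lapply(ts$trials, function(t) {
    m <- ncol(t$data)
    if (m != target_len) {
      t$data <- t(apply(t$data, 1L, interpolate_to_length, target_len))
      scale <- (target_len - 1) / (m - 1)
      t$markers <- as.integer(c(floor(t$markers[1] * scale),
                                min(round(t$markers[2] * scale), target_len - 1L)))
      if (t$markers[1] >= t$markers[2]) t$markers <- c(0L, target_len - 1L)
    }
    t
  })
  nirs_trial_set(trials, ts$channel_names)
}
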