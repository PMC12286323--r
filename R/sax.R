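#' SAX configuration
#'
#' Word length (`n_segments`) and alphabet size for symbolic aggregate
#' approximation. The study grid uses 100, 650 or 1300 segments of a
#' 1300-sample signal and alphabets of 5 to 8 symbols.
#'
#' @param n_segments number of PAA segments (word length)
#' @param alphabet_size integer in 2..26
#' @param znorm_epsilon standard-deviation floor below which a sequence is
#'   treated as constant and z-normalized to all zeros
#' @return list of class `sax_config`
#' @export
sax_config <- function(n_segments = 1300L, alphabet_size = 8L,
                       znorm_epsilon = 1e-12) {
  stopifnot(n_segments >= 1, alphabet_size >= 2, alphabet_size <= 26,
            znorm_epsilon > 0)
  structure(list(n_segments = as.integer(n_segments),
                 alphabet_size = as.integer(alphabet_size),
                 znorm_epsilon = znorm_epsilon), class = "sax_config")
}

#' Z-normalize a sequence
#'
#' `(y - mean) / sd` with the population (1/n) standard deviation, the
#' classical SAX convention. Sequences with sd below `epsilon` return all
#' zeros (constant-signal guard).
#'
#' @param y numeric vector
#' @param epsilon constant-signal guard threshold
#' @return numeric vector with mean 0 and population sd 1 (or all zeros)
#' @export
znorm <- function(y, epsilon = 1e-12) {
  mu <- mean(y)
  sigma <- sqrt(mean((y - mu)^2))
  if (!is.finite(sigma) || sigma < epsilon) return(numeric(length(y)))
  (y - mu) / sigma
}

#' Piecewise aggregate approximation
#'
#' Reduces a length-n sequence to w segment means. When w divides n each
#' output is the mean of a consecutive block of n/w samples; otherwise a
#' sample straddling a segment boundary contributes to both segments in
#' proportion to the overlap (fractional-boundary PAA).
#'
#' @param y numeric vector of length n
#' @param w number of segments, `1 <= w <= n`
#' @return numeric vector of length w
#' @export
paa <- function(y, w) {
  n <- length(y)
  w <- as.integer(w)
  if (w > n) stop("w (", w, ") exceeds sequence length (", n, ")")
  if (w == n) return(y)
  if (n %% w == 0L)
    return(colMeans(matrix(y, nrow = n %/% w)))
  # fractional boundaries: segment k covers [k*n/w, (k+1)*n/w) in sample units
  out <- numeric(w)
  seg_len <- n / w
  for (k in seq_len(w)) {
    lo <- (k - 1) * seg_len
    hi <- k * seg_len
    i0 <- floor(lo) + 1
    i1 <- ceiling(hi)
    acc <- 0
    for (i in i0:i1) {
      wgt <- min(i, hi) - max(i - 1, lo)
      if (wgt > 0) acc <- acc + wgt * y[i]
    }
    out[k] <- acc / seg_len
  }
  out
}

#' Gaussian-equiprobable breakpoints
#'
#' The a-1 breakpoints that cut the standard Gaussian into `a` equal-mass
#' bins: `qnorm(i/a)` for i = 1..a-1. Computed from the inverse CDF rather
#' than a lookup table; agrees with the tabulated values at table
#' precision, and is antisymmetric about zero.
#'
#' @param a alphabet size >= 2
#' @return strictly increasing numeric vector of length a-1
#' @export
breakpoints <- function(a) {
  a <- as.integer(a)
  if (a < 2L) stop("alphabet size must be >= 2")
  qnorm(seq_len(a - 1L) / a)
}

#' Symbolize a sequence with SAX
#'
#' z-normalization, PAA to `cfg$n_segments`, then discretization against
#' the Gaussian-equiprobable breakpoints: symbol k+1 where the PAA value
#' falls in the right-closed bin `(beta_k, beta_{k+1}]`. Symbols are the
#' letters A, B, C, ... with the numeric encoding A=1, B=2, ...
#'
#' @param y numeric vector
#' @param cfg a [sax_config()]
#' @return object of class `symbolic_series`: `symbols` (character vector),
#'   `numeric` (integer vector), `config`
#' @export
symbolize <- function(y, cfg = sax_config()) {
  stopifnot(inherits(cfg, "sax_config"))
  z <- znorm(y, cfg$znorm_epsilon)
  p <- paa(z, cfg$n_segments)
  beta <- breakpoints(cfg$alphabet_size)
  # right-closed bins: value in (beta_k, beta_{k+1}] -> symbol k+1
  num <- findInterval(p, beta, left.open = TRUE) + 1L
  structure(list(symbols = LETTERS[num], numeric = num, config = cfg),
            class = "symbolic_series")
}

#' @export
print.symbolic_series <- function(x, ...) {
  word <- paste(x$symbols, collapse = "")
  if (nchar(word) > 60) word <- paste0(substr(word, 1, 60), "...")
  cat(sprintf("<symbolic_series> w=%d a=%d: %s\n",
              x$config$n_segments, x$config$alphabet_size, word))
  invisible(x)
}

#' Triple window shifting
#'
#' Augmentation that takes three equal-length windows of the numeric symbol
#' sequence at offsets 0, `stride`, and `2*stride`. In `"augment"` mode the
#' windows become three instances that inherit the trial's label; in
#' `"concat"` mode they are concatenated into one longer sequence.
#'
#' @param s a `symbolic_series` or an integer/numeric sequence
#' @param mode `"augment"` (default) or `"concat"`
#' @param stride window offset in symbols; default `floor(len/10)` giving
#'   three 80%-length windows
#' @return `"augment"`: list of three sequences; `"concat"`: list of one
#'   concatenated sequence
#' @export
triple_window_shift <- function(s, mode = c("augment", "concat"),
                                stride = NULL) {
  mode <- match.arg(mode)
  x <- if (inherits(s, "symbolic_series")) s$numeric else s
  len <- length(x)
  if (is.null(stride)) stride <- len %/% 10L
  stride <- as.integer(stride)
  if (stride < 0L) stop("stride must be >= 0")
  wlen <- len - 2L * stride
  if (wlen < 1L) stop("stride ", stride, " too large for length ", len)
  windows <- lapply(0:2, function(k) x[(k * stride + 1L):(k * stride + wlen)])
  if (mode == "concat") list(do.call(c, windows)) else windows
}
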