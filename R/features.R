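FEATURE_MENU <- c("mean", "variance", "skewness", "kurtosis", "std")

#' Statistical features of a numeric symbol sequence
#'
#' Population moments of the sequence `z`:
#' mean, variance `(1/n) sum (z - zbar)^2`, std (its square root),
#' skewness `(1/n) sum (z - zbar)^3 / variance^(3/2)`, and non-excess
#' kurtosis `(1/n) sum (z - zbar)^4 / std^4` (about 3 for Gaussian data).
#' For a constant sequence, skewness and kurtosis are defined as 0 and the
#' other features are computed normally.
#'
#' @param z numeric vector, length >= 2
#' @param menu character vector: subset of
#'   `c("mean", "variance", "skewness", "kurtosis", "std")`, returned in
#'   the order given
#' @return named numeric vector over `menu`
#' @export
stat_features <- function(z, menu = FEATURE_MENU) {
  n <- length(z)
  if (n < 2L) stop("need at least 2 samples, got ", n)
  bad <- setdiff(menu, FEATURE_MENU)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  mu <- mean(z)
  d <- z - mu
  v <- mean(d^2)
  s <- sqrt(v)
  if (v > 0) {
    skw <- mean(d^3) / v^1.5
    krt <- mean(d^4) / v^2
  } else {
    skw <- 0
    krt <- 0
  }
  all <- c(mean = mu, variance = v, skewness = skw, kurtosis = krt, std = s)
  all[menu]
}

#' Feature matrix for a set of sequences
#'
#' @param seqs list of numeric sequences
#' @param menu features to compute (see [stat_features()])
#' @return matrix, one row per sequence, one column per feature
#' @export
feature_matrix <- function(seqs, menu = FEATURE_MENU) {
  out <- t(vapply(seqs, stat_features, numeric(length(menu)), menu = menu))
  colnames(out) <- menu
  out
}

#' Sequential forward feature selection
#'
#' Classical wrapper SFS: starting from the empty menu, repeatedly add the
#' feature whose inclusion maximizes the evaluator's cross-validated
#' accuracy; stop when no addition strictly improves it. Ties are broken
#' by menu order, so the selection is deterministic. Accuracy along the
#' accepted path is non-decreasing by construction.
#'
#' @param x feature matrix whose columns are tagged by `feature_names`
#'   (several columns may share a tag, e.g. one per channel)
#' @param y class labels (factor, >= 2 classes present)
#' @param feature_names character vector, one tag per column of `x`
#' @param menu candidate features in tie-break order
#' @param evaluator `function(x_sub, y) -> accuracy in [0,1]`; default:
#'   5-fold stratified cross-validated k-NN accuracy (k = 5), the same
#'   classifier used downstream
#' @param seed seed for the evaluator's fold assignment
#' @return character vector: the selected features, in selection order
#' @export
sfs_select <- function(x, y, feature_names = colnames(x),
                       menu = intersect(FEATURE_MENU, unique(feature_names)),
                       evaluator = NULL, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("sequential forward selection needs at least 2 classes")
  stopifnot(ncol(x) == length(feature_names))
  if (is.null(evaluator))
    evaluator <- function(xs, ys) cv_knn_accuracy(xs, ys, k = 5L, seed = seed)
  selected <- character()
  best_acc <- -Inf
  repeat {
    cand <- setdiff(menu, selected)
    if (!length(cand)) break
    accs <- vapply(cand, function(f) {
      cols <- feature_names %in% c(selected, f)
      evaluator(x[, cols, drop = FALSE], y)
    }, 0)
    i <- which.max(accs)  # first max = menu-order tie-break
    if (accs[i] > best_acc) {
      selected <- c(selected, cand[i])
      best_acc <- accs[i]
    } else break
  }
  selected
}
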