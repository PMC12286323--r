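#' Stratified 70/30 train/test split
#'
#' Splits trials into training and test sets preserving per-class
#' proportions within rounding: each class contributes
#' `round(train_frac * n_class)` trials to training. For the study's
#' strategy-3 class sizes (174 understood / 100 not understood) this
#' reproduces the printed marginals 122/52 and 70/30.
#'
#' @param labeled data frame with columns `trial_id`, `label` (e.g. from
#'   [label_trials()])
#' @param seed integer seed driving the randomization
#' @param train_frac training fraction (default 0.70)
#' @return list of class `split_plan`: `train_ids`, `test_ids`,
#'   `train_frac`, `seed`
#' @export
make_split <- function(labeled, seed, train_frac = 0.7) {
  stopifnot(all(c("trial_id", "label") %in% names(labeled)))
  y <- droplevels(as.factor(labeled$label))
  sizes <- table(y)
  if (any(sizes < 2L))
    stop("every class needs >= 2 trials; got ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  train_ids <- character()
  with_seed(seed, function() {
    for (cl in levels(y)) {
      ids <- labeled$trial_id[y == cl]
      n_train <- round(train_frac * length(ids))
      n_train <- max(1L, min(n_train, length(ids) - 1L))
      train_ids <<- c(train_ids, sample(ids, n_train))
    }
  })
  structure(list(train_ids = sort(train_ids),
                 test_ids = sort(setdiff(labeled$trial_id, train_ids)),
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "split_plan")
}

# squared Euclidean distances between rows of a and rows of b
dist_sq <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# majority vote with deterministic tie-breaking: ties go to the tied class
# with the smaller summed neighbor distance, then to the earlier factor
# level (for binary tasks the negative class is level 1)
vote <- function(neigh_labels, neigh_dists, levels) {
  counts <- tabulate(neigh_labels, nbins = length(levels))
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    sums <- vapply(top, function(l) sum(neigh_dists[neigh_labels == l]), 0)
    top <- top[sums == min(sums)][1]
  }
  top[1]
}

#' Fit a k-nearest-neighbor model
#'
#' Stores the training points; prediction is by majority vote among the k
#' nearest neighbors under Euclidean distance. Distance ties are broken by
#' training-point insertion order, vote ties by the smaller summed neighbor
#' distance and then toward the negative class.
#'
#' @param x numeric training matrix (rows = instances)
#' @param y labels (factor or coercible)
#' @param k number of neighbors, `1 <= k <= nrow(x)`
#' @param positive label of the positive class (used for ROC scores);
#'   default: the last factor level
#' @return object of class `knn_model`
#' @export
knn_fit <- function(x, y, k = 5L, positive = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y))
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) stop("k must be in 1..n_train")
  if (is.null(positive)) positive <- levels(y)[nlevels(y)]
  stopifnot(positive %in% levels(y))
  structure(list(x = x, y = y, k = k, positive = positive),
            class = "knn_model")
}

#' Predict with a k-NN model
#'
#' @param object a `knn_model`
#' @param newdata numeric matrix of query rows (a single query may be a
#'   vector)
#' @param ... unused
#' @return data frame with columns `label` (factor prediction) and `score`
#'   (fraction of the k neighbors belonging to the positive class)
#' @export
predict.knn_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("query dimension ", ncol(newdata), " does not match training dimension ",
         ncol(object$x))
  d <- dist_sq(newdata, object$x)
  yi <- as.integer(object$y)
  pos <- which(levels(object$y) == object$positive)
  k <- object$k
  lab <- integer(nrow(newdata))
  score <- numeric(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    ord <- order(d[i, ])[seq_len(k)]    # stable: ties by insertion order
    nl <- yi[ord]
    lab[i] <- vote(nl, sqrt(d[i, ord]), levels(object$y))
    score[i] <- mean(nl == pos)
  }
  data.frame(label = factor(levels(object$y)[lab], levels = levels(object$y)),
             score = score)
}

# stratified fold assignment at the trial level, expanded to instance
# rows, so augmented windows of one trial never straddle a fold boundary
trial_folds <- function(trial_ids, labels, n_folds, seed) {
  first <- !duplicated(trial_ids)
  fold_by_trial <- make_folds(labels[first], n_folds, seed)
  names(fold_by_trial) <- trial_ids[first]
  unname(fold_by_trial[trial_ids])
}

# stratified fold assignment: integer fold id per instance
make_folds <- function(y, n_folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, function() {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <<- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

# cross-validated accuracy for each k in `ks`, sharing one distance matrix
knn_cv_accs <- function(x, y, ks, n_folds = 5L, seed = 1L, fold = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(fold)) fold <- make_folds(y, n_folds, seed)
  yi <- as.integer(y)
  lv <- levels(y)
  correct <- setNames(numeric(length(ks)), ks)
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    d <- dist_sq(x[te, , drop = FALSE], x[tr, , drop = FALSE])
    for (i in seq_along(te)) {
      ord <- order(d[i, ])
      nl <- yi[tr][ord]
      nd <- sqrt(d[i, ord])
      for (j in seq_along(ks)) {
        k <- min(ks[j], length(tr))
        pred <- vote(nl[seq_len(k)], nd[seq_len(k)], lv)
        if (pred == yi[te[i]]) correct[j] <- correct[j] + 1
      }
    }
  }
  correct / length(y)
}

# single-k convenience used as the default SFS evaluator
cv_knn_accuracy <- function(x, y, k = 5L, n_folds = 5L, seed = 1L) {
  unname(knn_cv_accs(x, y, ks = k, n_folds = n_folds, seed = seed))
}

#' Choose k by cross-validation
#'
#' Maximizes 5-fold stratified cross-validated accuracy on the training
#' data over `k_range`; ties are resolved toward the smallest k.
#'
#' @param x training feature matrix
#' @param y training labels
#' @param k_range candidate neighbor counts (default 1..25)
#' @param seed seed for the fold assignment
#' @return the selected k (integer), with the CV accuracy as attribute
#'   `"cv_accuracy"`
#' @export
tune_k <- function(x, y, k_range = 1:25, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  accs <- knn_cv_accs(x, y, ks = k_range, seed = seed)
  best <- which.max(accs)          # first max = smallest k on ties
  structure(k_range[best], cv_accuracy = unname(accs[best]))
}

#' Enumerate channel combinations
#'
#' All channel subsets of sizes 1..`max_size` in deterministic order:
#' increasing size, lexicographic within size. For 20 channels and
#' `max_size = 4` this yields the study's 6195 combinations.
#'
#' @param n_channels number of channels
#' @param max_size largest subset size
#' @return list of integer vectors
#' @export
enumerate_channel_combos <- function(n_channels, max_size) {
  stopifnot(max_size >= 1, max_size <= n_channels)
  out <- list()
  for (s in seq_len(max_size))
    out <- c(out, combn(n_channels, s, simplify = FALSE))
  out
}

# z-score columns by training statistics; constant columns pass through
scale_by_train <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdv, "/"))
}

# majority over a trial's augmented window instances; scores averaged
aggregate_by_trial <- function(trial_ids, pred, lv) {
  ids <- unique(trial_ids)
  lab <- integer(length(ids))
  score <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- trial_ids == ids[i]
    counts <- tabulate(as.integer(pred$label[sel]), nbins = length(lv))
    top <- which(counts == max(counts))
    lab[i] <- top[1]
    score[i] <- mean(pred$score[sel])
  }
  data.frame(trial_id = ids, label = factor(lv[lab], levels = lv),
             score = score, stringsAsFactors = FALSE)
}

#' Exhaustive channel-combination search
#'
#' For every channel combination: assemble the per-channel features,
#' z-score them by training statistics, tune k by cross-validation on the
#' training trials, classify the test trials (augmented window instances
#' are voted per trial), and record the confusion counts and test accuracy.
#' Rows are sorted by test accuracy (descending), matching how the study
#' reports the best combination of each run.
#'
#' @param channel_features list (one element per channel) of numeric
#'   feature matrices with identical row order
#' @param instances data frame describing the feature rows, with columns
#'   `trial_id` and `label`
#' @param split a `split_plan` from [make_split()]
#' @param combos list of channel index vectors (default: all subsets of up
#'   to 4 channels)
#' @param k_range candidate k values (default 1..25)
#' @param positive positive-class label (default: last factor level)
#' @param seed seed for fold assignments
#' @return data frame, one row per combination: `combo`, `size`, `k`,
#'   `cv_accuracy`, `test_ca`, and the confusion counts `tp`, `fn`, `tn`,
#'   `fp` (binary tasks; NA otherwise), sorted by `test_ca` descending.
#'   Per-trial test predictions for each combination are attached as the
#'   `"predictions"` attribute (a list keyed by combo string).
#' @export
combo_search <- function(channel_features, instances, split,
                         combos = enumerate_channel_combos(
                           length(channel_features),
                           min(4L, length(channel_features))),
                         k_range = 1:25, positive = NULL, seed = 1L) {
  stopifnot(inherits(split, "split_plan"))
  y <- droplevels(as.factor(instances$label))
  lv <- levels(y)
  if (is.null(positive)) positive <- lv[length(lv)]
  tr <- instances$trial_id %in% split$train_ids
  te <- instances$trial_id %in% split$test_ids
  # trial-level truth for the test side
  te_truth <- unique(data.frame(trial_id = instances$trial_id[te],
                                label = y[te], stringsAsFactors = FALSE))
  fold <- trial_folds(instances$trial_id[tr], y[tr], 5L,
                      derive_seed(seed, "folds"))
  rows <- vector("list", length(combos))
  preds <- list()
  for (ci in seq_along(combos)) {
    combo <- combos[[ci]]
    x <- do.call(cbind, channel_features[combo])
    sc <- scale_by_train(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    accs <- knn_cv_accs(sc$train, y[tr], ks = k_range, fold = fold)
    k <- k_range[which.max(accs)]
    model <- knn_fit(sc$train, y[tr], k = k, positive = positive)
    pred <- predict(model, sc$test)
    agg <- aggregate_by_trial(instances$trial_id[te], pred, lv)
    truth <- te_truth$label[match(agg$trial_id, te_truth$trial_id)]
    agg$truth <- truth
    key <- paste(combo, collapse = "+")
    preds[[key]] <- agg
    ca <- mean(agg$label == truth)
    if (length(lv) == 2L) {
      cm <- confusion(truth, agg$label, positive = positive)
      rows[[ci]] <- data.frame(combo = key, size = length(combo), k = k,
                               cv_accuracy = max(accs), test_ca = ca,
                               tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
                               stringsAsFactors = FALSE)
    } else {
      rows[[ci]] <- data.frame(combo = key, size = length(combo), k = k,
                               cv_accuracy = max(accs), test_ca = ca,
                               tp = NA_integer_, fn = NA_integer_,
                               tn = NA_integer_, fp = NA_integer_,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$test_ca, out$combo, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  out
}
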