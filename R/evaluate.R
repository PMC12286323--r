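#' Confusion matrix for a binary task
#'
#' Counts true/false positives and negatives, with `positive` naming the
#' positive class (in the reading-comprehension task, `understood`).
#'
#' @param truth,predicted vectors of equal length over two classes
#' @param positive the positive-class label
#' @return object of class `confusion_matrix`: integers `tp`, `fn`, `tn`,
#'   `fp`
#' @export
confusion <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ: ",
         length(truth), " vs ", length(predicted))
  t_pos <- truth == positive
  p_pos <- predicted == positive
  structure(list(tp = sum(t_pos & p_pos), fn = sum(t_pos & !p_pos),
                 tn = sum(!t_pos & !p_pos), fp = sum(!t_pos & p_pos)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param tp,fn,tn,fp non-negative counts, not all zero
#' @return object of class `confusion_matrix`
#' @export
confusion_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d TN=%d FP=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' The six ratio metrics of a binary confusion matrix:
#' accuracy `CA = (TP+TN)/total`, sensitivity `SE = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)`, Jaccard index `J = TP/(TP+FP+FN)`,
#' F-measure `FM = 2TP/(2TP+FP+FN)`, and precision `TP/(TP+FP)`.
#' A metric whose denominator is zero is reported as 0 with a warning.
#'
#' @param cm a `confusion_matrix`
#' @return named list: `ca`, `se`, `sp`, `j`, `fm`, `precision`, all in
#'   `[0, 1]`
#' @export
basic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den, what) {
    if (den <= 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  with(cm, list(
    ca = ratio(tp + tn, tp + tn + fp + fn, "CA"),
    se = ratio(tp, tp + fn, "SE"),
    sp = ratio(tn, tn + fp, "SP"),
    j = ratio(tp, tp + fp + fn, "J"),
    fm = ratio(2 * tp, 2 * tp + fp + fn, "FM"),
    precision = ratio(tp, tp + fp, "precision")))
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under the ROC traced over score thresholds, computed
#' through the rank (Mann-Whitney) equivalence so that tied scores
#' contribute 1/2. Hard 0/1 scores therefore give the single-operating-
#' point area `(SE + SP)/2`.
#'
#' @param scores numeric scores, larger = more positive
#' @param labels binary labels
#' @param positive the positive-class label
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs both classes present (", n1, " positive, ", n0, " negative)")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exact full-hexagon area (side 1): 6 * sqrt(3)/4; the literature prints
# the rounded 2.59807
HEXAGON_AREA <- 6 * sqrt(3) / 4

#' Polygon area metric
#'
#' The six metrics CA, SE, SP, AUC, J, FM are placed on the spokes of a
#' regular hexagon (in that cyclic order). Adjacent spokes subtend 60
#' degrees, so the enclosed polygon area is
#' `RA = sqrt(3)/4 * sum_i a_i * b_i` over the six adjacent pairs, and the
#' score is normalized by the full hexagon area `6*sqrt(3)/4 = 2.59808`:
#' `PAM = RA / 2.59808`. PAM is 1 exactly when all six metrics are 1, and
#' is non-decreasing in each metric.
#'
#' @param ca,se,sp,auc,j,fm the six constituent metrics, each in `[0, 1]`;
#'   alternatively pass a single named list/vector as `ca`
#' @return PAM in `[0, 1]`
#' @export
pam <- function(ca, se, sp, auc, j, fm) {
  if (missing(se) && (is.list(ca) || length(ca) > 1)) {
    m <- ca
    ca <- m[["ca"]]; se <- m[["se"]]; sp <- m[["sp"]]
    auc <- m[["auc"]]; j <- m[["j"]]; fm <- m[["fm"]]
  }
  spokes <- c(ca = ca, se = se, sp = sp, auc = auc, j = j, fm = fm)
  if (any(!is.finite(spokes)) || any(spokes < 0) || any(spokes > 1))
    stop("all six PAM constituents must lie in [0, 1]")
  ra <- sqrt(3) / 4 * sum(spokes * spokes[c(2:6, 1)])
  ra / HEXAGON_AREA
}

#' Full evaluation report for binary predictions
#'
#' Confusion-matrix metrics, ROC AUC from the scores, and PAM.
#'
#' @param truth true labels
#' @param predicted predicted labels
#' @param scores positive-class scores (for ROC); if `NULL`, hard 0/1
#'   scores derived from `predicted` are used (AUC then equals
#'   `(SE+SP)/2`)
#' @param positive the positive-class label
#' @return object of class `eval_report`: `cm`, `ca`, `se`, `sp`, `j`,
#'   `fm`, `precision`, `auc`, `pam`
#' @export
eval_report <- function(truth, predicted, scores = NULL, positive) {
  cm <- confusion(truth, predicted, positive)
  m <- basic_metrics(cm)
  if (is.null(scores)) scores <- as.numeric(predicted == positive)
  m$auc <- roc_auc(scores, truth, positive)
  m$pam <- pam(m$ca, m$se, m$sp, m$auc, m$j, m$fm)
  structure(c(list(cm = cm), m), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> PAM=%.2f%%  CA=%.2f%%  SE=%.2f%%  ",
                     "SP=%.2f%%  AUC=%.4f  J=%.4f  FM=%.4f  prec=%.2f%%\n"),
              100 * x$pam, 100 * x$ca, 100 * x$se, 100 * x$sp,
              x$auc, x$j, x$fm, 100 * x$precision))
  print(x$cm)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_eval_report <- function(report, path) {
  out <- list(confusion = report$cm[c("tp", "fn", "tn", "fp")],
              metrics = report[c("ca", "se", "sp", "auc", "j", "fm",
                                 "precision", "pam")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
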