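# Classification metrics, stratified cross-validation, ROC and
# mature-region localization distance.

#' Confusion-matrix metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/n`. A ratio with a zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param truth logical vector of true class labels.
#' @param calls logical vector of predicted labels, same length.
#' @return list of class `"metric_report"` with `tp`, `fp`, `tn`, `fn`,
#'   `sen`, `spe`, `acc`.
#' @export
confusion_metrics <- function(truth, calls) {
  stopifnot(is.logical(truth), is.logical(calls))
  if (length(truth) != length(calls)) stop("truth and calls differ in length")
  if (!length(truth)) stop("empty input")
  tp <- sum(truth & calls); fn <- sum(truth & !calls)
  tn <- sum(!truth & !calls); fp <- sum(!truth & calls)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sen = ratio(tp, tp + fn), spe = ratio(tn, tn + fp),
                 acc = ratio(tp + tn, length(truth))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> tp %d fp %d tn %d fn %d | sen %s spe %s acc %s\n",
              x$tp, x$fp, x$tn, x$fn,
              format(x$sen, digits = 4), format(x$spe, digits = 4),
              format(x$acc, digits = 4)))
  invisible(x)
}

#' Stratified k-fold cross-validation of the predictor
#'
#' Shuffles each class with the given seed into `k` near-equal folds
#' (stratified by class, fold sizes within one record of each other); for
#' each fold, trains the full pipeline on the remainder and predicts the
#' held-out records at the fold's own chosen threshold.
#'
#' @param positives,negatives lists of [hairpin_record()]s; each class must
#'   have at least `k` records.
#' @param k number of folds (>= 2).
#' @param cfg a [fom_config()].
#' @param coeffs [feature_coefficients()].
#' @param seed integer seed for the fold assignment.
#' @return list with `folds` (per-fold metric data frame), `mean` and `sd`
#'   of sensitivity/specificity/accuracy across folds, and the fold
#'   `assignments`.
#' @export
kfold_cv <- function(positives, negatives, k = 5L, cfg = fom_config(),
                     coeffs = feature_coefficients(), seed = NULL) {
  stopifnot(k >= 2L)
  np <- length(positives); nn <- length(negatives)
  if (np < k || nn < k)
    stop(sprintf("each class needs >= %d records (got %d positives, %d negatives)",
                 k, np, nn))
  if (!is.null(seed)) set.seed(seed)
  fold_pos <- sample(rep_len(seq_len(k), np))
  fold_neg <- sample(rep_len(seq_len(k), nn))
  per_fold <- lapply(seq_len(k), function(f) {
    model <- train_pipeline(positives[fold_pos != f], negatives[fold_neg != f],
                            cfg, coeffs)
    held <- c(positives[fold_pos == f], negatives[fold_neg == f])
    truth <- c(rep(TRUE, sum(fold_pos == f)), rep(FALSE, sum(fold_neg == f)))
    pred <- predict_hairpins(model, held)
    pred <- pred[!duplicated(pred$id), , drop = FALSE]   # one row per record
    ok <- pred$status == "ok"
    if (any(!ok))
      warning(sprintf("fold %d: %d record(s) could not be predicted", f, sum(!ok)))
    m <- confusion_metrics(truth[ok], pred$is_mirna[ok])
    data.frame(fold = f, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               sen = m$sen, spe = m$spe, acc = m$acc)
  })
  folds <- do.call(rbind, per_fold)
  list(folds = folds,
       mean = colMeans(folds[, c("sen", "spe", "acc")], na.rm = TRUE),
       sd = vapply(folds[, c("sen", "spe", "acc")], stats::sd,
                   numeric(1), na.rm = TRUE),
       assignments = list(pos = fold_pos, neg = fold_neg))
}

#' ROC curve and AUC
#'
#' True/false positive rates at every distinct score cut, with trapezoidal
#' AUC (computed via \pkg{pROC}; equal to the Mann-Whitney pair statistic
#' with ties counted 1/2).
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth logical class labels; both classes must be present.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(is.numeric(scores), is.logical(truth),
            length(scores) == length(truth))
  if (!any(truth) || all(truth))
    stop("roc_curve needs at least one record of each class")
  r <- pROC::roc(response = factor(truth, levels = c(FALSE, TRUE)),
                 predictor = scores, levels = c("FALSE", "TRUE"),
                 direction = "<", quiet = TRUE)
  list(points = data.frame(threshold = r$thresholds,
                           fpr = 1 - r$specificities,
                           tpr = r$sensitivities),
       auc = as.numeric(pROC::auc(r)))
}

#' Localization distance between mature intervals
#'
#' Distance in nucleotides between the annotated and the predicted mature
#' region on the same precursor coordinate line. The default is the
#' start-offset distance `|pred_start - true_start|`; midpoint distance is
#' available as an alternative.
#'
#' @param true_interval,predicted_interval numeric `c(start, end)` intervals
#'   (1-based inclusive).
#' @param method `"start"` or `"midpoint"`.
#' @return non-negative distance in nt.
#' @export
localization_distance <- function(true_interval, predicted_interval,
                                  method = c("start", "midpoint")) {
  method <- match.arg(method)
  chk <- function(x) {
    x <- as.numeric(x)
    if (length(x) != 2L || x[1] > x[2]) stop("intervals must be c(start, end)")
    x
  }
  a <- chk(true_interval); b <- chk(predicted_interval)
  switch(method,
         start = abs(b[1] - a[1]),
         midpoint = abs(mean(b) - mean(a)))
}

#' Bookkeeping of the original human training/test split
#'
#' The predictor was originally calibrated on human data: of 1046 human
#' miRNA precursors (miRBase release 16), 809 were drawn for positive
#' training; of 8494 pseudo-hairpins and 754 other ncRNAs (microPred),
#' 5890 and 551 respectively were drawn for negative training. This helper
#' applies that split arithmetic, returning the derived set sizes.
#'
#' @param pos_total,pos_train human precursor totals and positive training
#'   draw.
#' @param pseudo_total,pseudo_train pseudo-hairpin totals and training draw.
#' @param ncrna_total,ncrna_train other-ncRNA totals and training draw.
#' @return list with `pos_train`, `pos_test`, `neg_train`, `neg_test`, plus
#'   the input totals `pos_total` and `neg_total`.
#' @export
training_split_counts <- function(pos_total = 1046L, pos_train = 809L,
                                  pseudo_total = 8494L, pseudo_train = 5890L,
                                  ncrna_total = 754L, ncrna_train = 551L) {
  stopifnot(pos_train <= pos_total, pseudo_train <= pseudo_total,
            ncrna_train <= ncrna_total)
  list(pos_total = pos_total, pos_train = pos_train,
       pos_test = pos_total - pos_train,
       neg_total = pseudo_total + ncrna_total,
       neg_train = pseudo_train + ncrna_train,
       neg_test = (pseudo_total - pseudo_train) + (ncrna_total - ncrna_train))
}
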