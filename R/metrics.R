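# Confusion-matrix bookkeeping and evaluation measures, with the abnormal
# class as positive throughout: TP = abnormal called abnormal, TN = normal
# called normal. All measures are reported in percent.

#' Tally a confusion matrix
#'
#' @param pred,truth Equal-length label vectors in \{+1, -1\}
#'   (+1 = abnormal = positive class).
#' @return An object of class `confusion_counts` with fields `TP`, `FN`,
#'   `TN`, `FP`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.numeric(pred)
  truth <- as.numeric(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  if (length(pred) < 1L) stop("need at least one prediction", call. = FALSE)
  if (!all(pred %in% c(-1, 1)) || !all(truth %in% c(-1, 1))) {
    stop("labels must be +1 or -1", call. = FALSE)
  }
  structure(
    list(TP = sum(pred == 1 & truth == 1),
         FN = sum(pred == -1 & truth == 1),
         TN = sum(pred == -1 & truth == -1),
         FP = sum(pred == 1 & truth == -1)),
    class = "confusion_counts"
  )
}

#' Evaluation measures from a confusion matrix
#'
#' Computes, in percent: accuracy (TP+TN)/n, sensitivity (= recall)
#' TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), and the F1
#' score, the harmonic mean of recall and precision. A measure whose
#' denominator is zero is undefined and raises an error naming the measure
#' (silent zeros would corrupt model selection).
#'
#' @param counts A [confusion()] result, or a list with fields TP/FN/TN/FP.
#' @return An object of class `metric_report`: a named list with entries
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`, each in
#'   \[0, 100\].
#' @export
metric_report <- function(counts) {
  for (f in c("TP", "FN", "TN", "FP")) {
    v <- counts[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("invalid confusion count '%s'", f), call. = FALSE)
    }
  }
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  n <- TP + FN + TN + FP
  if (n == 0) stop("undefined metric 'accuracy': no samples", call. = FALSE)
  if (TP + FN == 0) {
    stop("undefined metric 'sensitivity': no positive (abnormal) samples",
         call. = FALSE)
  }
  if (TN + FP == 0) {
    stop("undefined metric 'specificity': no negative (normal) samples",
         call. = FALSE)
  }
  if (TP + FP == 0) {
    stop("undefined metric 'precision': no positive predictions", call. = FALSE)
  }
  recall <- TP / (TP + FN) * 100
  precision <- TP / (TP + FP) * 100
  if (recall + precision == 0) {
    stop("undefined metric 'f1': recall and precision are both zero",
         call. = FALSE)
  }
  structure(
    list(accuracy = (TP + TN) / n * 100,
         sensitivity = recall,
         specificity = TN / (TN + FP) * 100,
         precision = precision,
         f1 = 2 * recall * precision / (recall + precision)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  precision %.1f%%  F1 %.1f%%\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Format metric reports as a table
#'
#' One row per named report, mirroring the usual
#' classifier-by-feature-set comparison layout.
#'
#' @param reports Named list of `metric_report`s.
#' @return A data.frame with one row per report.
#' @export
report_table <- function(reports) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(run = nm, accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity, precision = r$precision,
               f1 = r$f1, stringsAsFactors = FALSE)
  }))
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin so fold sizes differ by at most one per class.
stratified_folds <- function(y, folds, seed) {
  assign_out <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        stop(sprintf(
          "stratification infeasible: class %s has %d members for %d folds",
          format(cls), length(idx), folds), call. = FALSE)
      }
      idx <- sample(idx)
      assign_out[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_out
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' Splits the training set into `folds` stratified folds (fixed by `seed`),
#' evaluates every grid row by mean validation accuracy, and returns the
#' best row (ties broken by grid order) together with the per-fold reports
#' at that row.
#'
#' @param X Feature matrix; `y` labels in \{+1, -1\}.
#' @param y Labels.
#' @param folds Number of folds (>= 2); default 10.
#' @param hyper_grid Data frame with columns `c1`, `c2`, `sigma1`, `sigma2`;
#'   default is the single point c = sigma = 3.5.
#' @param seed Integer seed for the fold assignment.
#' @param kernel Kernel passed to [twsvm_fit()].
#' @return A list with `best` (the winning grid row), `mean_accuracy`
#'   (vector over grid rows), `fold_accuracy` (folds x grid matrix),
#'   `fold_reports` (per-fold `metric_report`s at the best row; a fold whose
#'   report has an undefined measure carries only its accuracy) and
#'   `fold_assignments`.
#' @export
cross_validate <- function(X, y, folds = 10L,
                           hyper_grid = data.frame(c1 = 3.5, c2 = 3.5,
                                                   sigma1 = 3.5, sigma2 = 3.5),
                           seed = 1L, kernel = "gaussian") {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  needed <- c("c1", "c2", "sigma1", "sigma2")
  if (!all(needed %in% names(hyper_grid))) {
    stop("`hyper_grid` needs columns c1, c2, sigma1, sigma2", call. = FALSE)
  }
  fold_id <- stratified_folds(y, folds, seed)

  fold_acc <- matrix(NA_real_, nrow = folds, ncol = nrow(hyper_grid))
  for (gi in seq_len(nrow(hyper_grid))) {
    hp <- hyper_grid[gi, ]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      model <- twsvm_fit(X[tr, , drop = FALSE], y[tr],
                         c1 = hp$c1, c2 = hp$c2,
                         sigma1 = hp$sigma1, sigma2 = hp$sigma2,
                         kernel = kernel)
      pred <- predict(model, X[!tr, , drop = FALSE])
      fold_acc[f, gi] <- mean(pred == y[!tr]) * 100
    }
  }
  mean_acc <- colMeans(fold_acc)
  best_i <- which.max(mean_acc)  # first maximum wins ties

  hp <- hyper_grid[best_i, ]
  fold_reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- twsvm_fit(X[tr, , drop = FALSE], y[tr],
                       c1 = hp$c1, c2 = hp$c2,
                       sigma1 = hp$sigma1, sigma2 = hp$sigma2,
                       kernel = kernel)
    pred <- predict(model, X[!tr, , drop = FALSE])
    cm <- confusion(pred, y[!tr])
    fold_reports[[f]] <- tryCatch(
      metric_report(cm),
      error = function(e) list(accuracy = (cm$TP + cm$TN) /
                                 (cm$TP + cm$TN + cm$FP + cm$FN) * 100,
                               note = conditionMessage(e))
    )
  }
  list(best = hp, best_index = best_i, mean_accuracy = mean_acc,
       fold_accuracy = fold_acc, fold_reports = fold_reports,
       fold_assignments = fold_id)
}
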