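# Evaluation: confusion matrix, macro-averaged metrics, one-vs-rest ROC/AUC
# and the channel-combination experiment runner.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of records with true class `i` predicted as
#' class `j`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param classes Class ordering; defaults to the sorted union of labels.
#' @return Object of class `confusion_matrix`: the integer count matrix with
#'   a `classes` attribute.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, classes = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (!length(true_labels) || length(true_labels) != length(predicted_labels)) {
    stop_gaitdx("label vectors must be nonempty and of equal length",
                class = "gaitdx_parameter_error")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(true_labels, predicted_labels)))
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(unknown)) {
    stop_gaitdx("unknown label(s): ", paste(unknown, collapse = ", "),
                class = "gaitdx_parameter_error")
  }
  counts <- table(factor(true_labels, classes), factor(predicted_labels, classes))
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = list(true = classes, predicted = classes))
  structure(m, classes = classes, class = c("confusion_matrix", "matrix"))
}

# One-vs-rest TP/TN/FP/FN per class.
ovr_counts <- function(cm) {
  n <- sum(cm)
  t(vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    c(TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn)
  }, numeric(4)))
}

#' Macro-averaged classification metrics
#'
#' Per class one-vs-rest: sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' F1 `2TP/(2TP+FP+FN)`; macro values are the unweighted class means and
#' accuracy is `trace/total`. All reported as percentages. An empty class
#' (`TP + FN = 0`) gets sensitivity 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `eval_report`: list with `accuracy`, `precision`,
#'   `sensitivity`, `f1` (percent), `per_class` (data frame) and `confusion`.
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) {
    stop_gaitdx("empty confusion matrix", class = "gaitdx_parameter_error")
  }
  oc <- ovr_counts(cm)
  classes <- attr(cm, "classes")
  sens <- ifelse(oc[, "TP"] + oc[, "FN"] > 0,
                 oc[, "TP"] / (oc[, "TP"] + oc[, "FN"]), 0)
  if (any(oc[, "TP"] + oc[, "FN"] == 0)) {
    warning("class(es) with no true records: sensitivity set to 0 for ",
            paste(classes[oc[, "TP"] + oc[, "FN"] == 0], collapse = ", "))
  }
  prec <- ifelse(oc[, "TP"] + oc[, "FP"] > 0,
                 oc[, "TP"] / (oc[, "TP"] + oc[, "FP"]), 0)
  f1 <- ifelse(2 * oc[, "TP"] + oc[, "FP"] + oc[, "FN"] > 0,
               2 * oc[, "TP"] / (2 * oc[, "TP"] + oc[, "FP"] + oc[, "FN"]), 0)
  structure(list(
    accuracy = 100 * sum(diag(cm)) / sum(cm),
    precision = 100 * mean(prec),
    sensitivity = 100 * mean(sens),
    f1 = 100 * mean(f1),
    per_class = data.frame(class = classes, TP = oc[, "TP"], FP = oc[, "FP"],
                           FN = oc[, "FN"], TN = oc[, "TN"],
                           sensitivity = 100 * sens, precision = 100 * prec,
                           f1 = 100 * f1, row.names = NULL),
    confusion = cm
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("Pooled evaluation: accuracy %.2f%%, macro precision ",
                     "%.2f%%, macro sensitivity %.2f%%, macro F1 %.2f%%"),
              x$accuracy, x$precision, x$sensitivity, x$f1))
  if (!is.null(x$auc)) cat(sprintf(", macro AUC %.3f", x$auc))
  cat("\n\nConfusion matrix (rows = true):\n")
  m <- x$confusion
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

# Rank-based (Mann-Whitney) AUC; equals the trapezoidal ROC area with
# tie-aware thresholds.
binary_auc <- function(pos, score) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest ROC AUC
#'
#' AUC per class from thresholding that class's score column (rank form,
#' equivalent to the trapezoidal rule with tie handling); the macro value is
#' the unweighted class mean. Constant score columns yield AUC 0.5 with a
#' degenerate-score warning.
#'
#' @param true_labels Label vector.
#' @param class_scores Numeric matrix, one column per class (rows sum to 1).
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_macro <- function(true_labels, class_scores) {
  true_labels <- as.character(true_labels)
  classes <- colnames(class_scores)
  stopifnot(!is.null(classes), nrow(class_scores) == length(true_labels))
  auc <- vapply(classes, function(cl) {
    s <- class_scores[, cl]
    if (max(s) - min(s) < 1e-15) {
      warning("degenerate (constant) scores for class ", cl,
              ": AUC set to 0.5")
      return(0.5)
    }
    binary_auc(true_labels == cl, s)
  }, numeric(1))
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' One-vs-rest ROC curve points
#'
#' Full (FPR, TPR) staircase for one class's score column, for plotting or
#' export.
#'
#' @param true_labels Label vector.
#' @param score Numeric score for the positive class.
#' @param positive The positive class label.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(true_labels, score, positive) {
  pos <- as.character(true_labels) == positive
  th <- c(Inf, sort(unique(score), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(score[!pos] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(score[pos] >= t), numeric(1))
  )
}

#' Channel-combination experiment grid
#'
#' Reproduces the one/two/three-channel experiment structure: for every
#' channel combination (all singles, pairs, and the triple of the supplied
#' per-channel feature tables) and every requested ranking method, the
#' pipeline prunes correlated features, ranks, runs the incremental top-k
#' search under subject-wise CV, and reports the best configuration.
#'
#' @param tables Named list `channel -> feature table` (each with
#'   `subject_id`, `label`, feature columns; rows aligned across channels).
#' @param rankers Ranking methods to run.
#' @param folds Fold assignment shared by every cell.
#' @param config A [knn_config()].
#' @param combos Optional list of character vectors naming the combinations;
#'   default all 7 (3 singles + 3 pairs + 1 triple).
#' @param prune_threshold Correlation-pruning threshold.
#' @param max_k Cap on the incremental search depth.
#' @param smote,seed Passed to the CV stage.
#' @return List with `grid` (one row per combo-ranker cell: `channels`,
#'   `ranker`, `top_k`, `accuracy`, `precision`, `sensitivity`, `f1`, `auc`)
#'   and `reports` (the matching `eval_report`s).
#' @export
channel_experiment <- function(tables,
                               rankers = c("chi2", "mrmr", "relieff", "nca"),
                               folds = NULL, config = knn_config(),
                               combos = NULL, prune_threshold = 0.9,
                               max_k = NULL, smote = TRUE, seed = 1L) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  rankers <- match.arg(rankers, several.ok = TRUE)
  chans <- names(tables)
  if (is.null(combos)) {
    combos <- c(as.list(chans),
                utils::combn(chans, 2, simplify = FALSE),
                if (length(chans) >= 3) utils::combn(chans, 3, simplify = FALSE))
  }
  meta_cols <- intersect(c("subject_id", "label", "cycle"), names(tables[[1]]))
  if (is.null(folds)) {
    subj <- tapply(as.character(tables[[1]]$label),
                   as.character(tables[[1]]$subject_id), `[`, 1)
    folds <- subject_wise_folds(as.list(subj), seed = seed)
  }
  rows <- list()
  reports <- list()
  for (combo in combos) {
    missing <- setdiff(combo, chans)
    if (length(missing)) {
      stop_gaitdx("no feature table for channel(s): ",
                  paste(missing, collapse = ", "),
                  class = "gaitdx_parameter_error")
    }
    tab <- tables[[combo[1]]][meta_cols]
    for (ch in combo) {
      tab <- cbind(tab, tables[[ch]][setdiff(names(tables[[ch]]), meta_cols)])
    }
    pruned <- drop_correlated(tab, prune_threshold)
    for (rk in rankers) {
      ranked <- rank_features(pruned$table, pruned$table$label, rk)
      search <- incremental_feature_search(ranked, pruned$table, folds,
                                           config, max_k = max_k,
                                           smote = smote, seed = seed)
      rep <- search$best_report
      key <- paste(paste(combo, collapse = "-"), rk, sep = "_")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(
        channels = paste(combo, collapse = "-"), ranker = rk,
        top_k = search$best_k,
        accuracy = round(rep$accuracy, 2), precision = round(rep$precision, 2),
        sensitivity = round(rep$sensitivity, 2), f1 = round(rep$f1, 2),
        auc = round(rep$auc, 2))
    }
  }
  list(grid = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}
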