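# Classification stage: SMOTE augmentation of training folds, the tuned
# distance-weighted KNN, subject-wise cross-validation and the incremental
# top-k feature search.

#' KNN classifier configuration
#'
#' Defaults are the tuned optimum shipped with the pipeline: 1 neighbour,
#' Euclidean distance, squared-inverse distance weighting (weight `1/d^2`).
#'
#' @param n_neighbors Number of neighbours.
#' @param metric `"euclidean"` or `"cityblock"`.
#' @param weighting `"uniform"`, `"inverse"` or `"squared_inverse"`.
#' @return Object of class `knn_config`.
#' @export
knn_config <- function(n_neighbors = 1,
                       metric = c("euclidean", "cityblock"),
                       weighting = c("squared_inverse", "inverse", "uniform")) {
  structure(list(n_neighbors = check_count(n_neighbors, "n_neighbors"),
                 metric = match.arg(metric),
                 weighting = match.arg(weighting)),
            class = "knn_config")
}

pairwise_distances <- function(test_X, train_X, metric) {
  if (metric == "euclidean") {
    cross <- tcrossprod(test_X, train_X)
    d2 <- outer(rowSums(test_X^2), rowSums(train_X^2), "+") - 2 * cross
    sqrt(pmax(d2, 0))
  } else {
    t(apply(test_X, 1, function(v) {
      colSums(abs(t(train_X) - v))
    }))
  }
}

#' Distance-weighted k-nearest-neighbour prediction
#'
#' For every test point the `k` nearest training points vote with weight 1
#' (`uniform`), `1/d` (`inverse`) or `1/d^2` (`squared_inverse`); an
#' exact-match neighbour (distance 0) wins outright. `class_scores` are the
#' normalized weighted votes. With `n_neighbors = 1` the scores are instead
#' built from the distance to the nearest training point of *each* class
#' (normalized squared-inverse), so ROC curves remain non-degenerate.
#'
#' @param train_X,train_y Training feature matrix and labels.
#' @param test_X Test feature matrix (same columns).
#' @param config A [knn_config()].
#' @param classes Class ordering for the score columns; defaults to the
#'   sorted unique training labels.
#' @return List with `labels` (predicted) and `class_scores` (matrix, rows
#'   sum to 1).
#' @export
knn_predict <- function(train_X, train_y, test_X, config = knn_config(),
                        classes = NULL) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  train_y <- as.character(train_y)
  k <- config$n_neighbors
  if (k > nrow(train_X)) {
    stop_gaitdx("n_neighbors = ", k, " exceeds training size ",
                nrow(train_X), class = "gaitdx_parameter_error")
  }
  if (ncol(train_X) != ncol(test_X)) {
    stop_gaitdx("train/test feature dimensions differ",
                class = "gaitdx_parameter_error")
  }
  if (is.null(classes)) classes <- sort(unique(train_y))
  D <- pairwise_distances(test_X, train_X, config$metric)
  nte <- nrow(test_X)
  scores <- matrix(0, nte, length(classes),
                   dimnames = list(NULL, classes))
  wfun <- switch(config$weighting,
                 uniform = function(d) rep(1, length(d)),
                 inverse = function(d) 1 / d,
                 squared_inverse = function(d) 1 / d^2)
  for (i in seq_len(nte)) {
    d <- D[i, ]
    nb <- order(d)[seq_len(k)]
    if (any(d[nb] == 0)) {
      zl <- train_y[nb][d[nb] == 0]
      for (cl in zl) scores[i, cl] <- scores[i, cl] + 1
    } else {
      w <- wfun(d[nb])
      for (j in seq_len(k)) {
        scores[i, train_y[nb[j]]] <- scores[i, train_y[nb[j]]] + w[j]
      }
    }
    if (k == 1) {
      # per-class nearest distances -> graded scores for ROC
      dc <- vapply(classes, function(cl) min(d[train_y == cl]), numeric(1))
      if (any(dc == 0)) {
        scores[i, ] <- as.numeric(dc == 0)
      } else {
        scores[i, ] <- 1 / dc^2
      }
    }
    scores[i, ] <- scores[i, ] / sum(scores[i, ])
  }
  if (k == 1) {
    # the predicted label is still the strict nearest neighbour's label
    labels <- train_y[apply(D, 1, which.min)]
  } else {
    labels <- classes[apply(scores, 1, which.max)]
  }
  list(labels = labels, class_scores = scores)
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: each minority class is up-sampled to the
#' majority count with points `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`,
#' where `x_nn` is one of the `k` nearest same-class neighbours of a
#' randomly chosen class member. Apply to training folds only.
#'
#' @param X Feature matrix or data frame.
#' @param y Class labels.
#' @param k Neighbourhood size (clamped with a warning to class size minus 1).
#' @param seed Seed for the synthesis stream.
#' @return List with augmented `X` (matrix) and `y`; original rows first.
#' @export
smote_augment <- function(X, y, k = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2)) {
    stop_gaitdx("SMOTE cannot up-sample the singleton class ",
                names(counts)[counts < 2][1], class = "gaitdx_parameter_error")
  }
  target <- max(counts)
  add_X <- NULL
  add_y <- character(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      kk <- min(k, length(idx) - 1L)
      if (kk < k) {
        warning("SMOTE: k clamped to ", kk, " for class ", cl)
      }
      Xc <- X[idx, , drop = FALSE]
      Dc <- as.matrix(stats::dist(Xc))
      diag(Dc) <- Inf
      nn <- t(apply(Dc, 1, function(d) order(d)[seq_len(kk)]))
      base <- sample(seq_along(idx), need, replace = TRUE)
      pick <- vapply(base, function(b) nn[b, sample.int(kk, 1)], integer(1))
      u <- stats::runif(need)
      syn <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      add_X <- rbind(add_X, syn)
      add_y <- c(add_y, rep(cl, need))
    }
  })
  list(X = rbind(X, add_X), y = c(y, add_y))
}

#' Subject-wise fold assignment
#'
#' Class-stratified grouping: subjects are shuffled within class (seeded) and
#' dealt round-robin to folds, the deal continuing across classes so fold
#' sizes stay balanced. All records of a subject share its fold.
#'
#' @param subjects Named character vector or list mapping
#'   `subject_id -> class label` (one entry per subject).
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return Named integer vector `subject_id -> fold` in `0:(n_folds - 1)`,
#'   class `subject_folds`.
#' @export
subject_wise_folds <- function(subjects, n_folds = 5, seed = 1L) {
  labs <- unlist(subjects)
  ids <- names(labs)
  if (length(ids) < n_folds) {
    stop_gaitdx("fewer subjects (", length(ids), ") than folds (", n_folds,
                ")", class = "gaitdx_parameter_error")
  }
  assign <- integer(0)
  with_seed(seed, {
    cursor <- 0L
    for (cl in unique(labs)) {
      cl_ids <- sample(ids[labs == cl])
      f <- (cursor + seq_along(cl_ids) - 1L) %% n_folds
      assign <- c(assign, stats::setNames(f, cl_ids))
      cursor <- cursor + length(cl_ids)
    }
  })
  structure(assign[ids], names = ids, class = "subject_folds")
}

#' Record-wise fold assignment
#'
#' Ignores subject grouping: records are shuffled and dealt round-robin,
#' stratified by class. Provided to quantify the identity-confounding
#' (leakage) inflation that subject-wise splitting prevents.
#'
#' @param labels Class label per record.
#' @param n_folds Number of folds.
#' @param seed Shuffle seed.
#' @return Integer vector of fold indices in `0:(n_folds - 1)`, one per
#'   record.
#' @export
record_wise_folds <- function(labels, n_folds = 5, seed = 1L) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    cursor <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- (cursor + seq_along(idx) - 1L) %% n_folds
      cursor <- cursor + length(idx)
    }
  })
  folds
}

record_fold_vector <- function(folds, subject_ids) {
  if (inherits(folds, "subject_folds")) {
    missing <- setdiff(unique(subject_ids), names(folds))
    if (length(missing)) {
      stop_gaitdx("no fold assignment for subject(s): ",
                  paste(missing, collapse = ", "),
                  class = "gaitdx_parameter_error")
    }
    unname(folds[subject_ids])
  } else {
    as.integer(folds)
  }
}

#' Cross-validated KNN run with per-fold SMOTE
#'
#' For every fold: standardize features on the training records, SMOTE the
#' training set to class balance, fit/predict with the distance-weighted
#' KNN, and pool all held-out predictions into one confusion matrix scored
#' by [macro_metrics()] and [roc_auc_macro()]. When `folds` is a subject
#' map, a machine-checked no-leakage assertion verifies that no test
#' subject's records ever enter training (or SMOTE).
#'
#' @param table Feature table (data frame with `subject_id`, `label` and
#'   feature columns) or a bare feature matrix.
#' @param folds A `subject_folds` map from [subject_wise_folds()] or an
#'   integer fold vector per record (record-wise CV).
#' @param labels,subject_ids Only needed when `table` is a bare matrix.
#' @param config A [knn_config()].
#' @param smote Balance training folds with SMOTE (default TRUE).
#' @param seed Seed driving the per-fold SMOTE streams.
#' @param subject_wise Enforce the no-leakage assertion (no subject's
#'   records on both sides of any split). `NULL` (default) enforces it
#'   whenever `folds` is a subject map; pass `TRUE` to demand it for a
#'   record-level fold vector too, in which case a vector that splits a
#'   subject raises a leakage error.
#' @return An `eval_report` (see [macro_metrics()]) with elements
#'   `confusion`, `accuracy`, `precision`, `sensitivity`, `f1` (percent),
#'   `auc`, `per_class`, and `predictions`.
#' @export
cross_validated_run <- function(table, folds, labels = NULL,
                                subject_ids = NULL, config = knn_config(),
                                smote = TRUE, seed = 1L,
                                subject_wise = NULL) {
  if (is.data.frame(table)) {
    labels <- as.character(table$label)
    subject_ids <- as.character(table$subject_id)
    X <- feature_matrix(table)
  } else {
    X <- as.matrix(table)
    labels <- as.character(labels)
  }
  fold_of <- record_fold_vector(folds, subject_ids)
  classes <- sort(unique(labels))
  if (is.null(subject_wise)) {
    subject_wise <- inherits(folds, "subject_folds")
  }
  pred <- character(length(labels))
  scores <- matrix(NA_real_, length(labels), length(classes),
                   dimnames = list(NULL, classes))
  for (f in sort(unique(fold_of))) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    if (!length(te)) {
      stop_gaitdx("empty test fold ", f, class = "gaitdx_parameter_error")
    }
    if (subject_wise) {
      leak <- intersect(subject_ids[tr], subject_ids[te])
      if (length(leak)) {
        stop_gaitdx("subject leakage across fold ", f, ": ",
                    paste(leak, collapse = ", "),
                    class = "gaitdx_leakage_error")
      }
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
    Xte <- scale(X[te, , drop = FALSE], mu, sdv)
    ytr <- labels[tr]
    if (smote) {
      aug <- smote_augment(Xtr, ytr, seed = seed + f)
      Xtr <- aug$X
      ytr <- aug$y
    }
    out <- knn_predict(Xtr, ytr, Xte, config, classes = classes)
    pred[te] <- out$labels
    scores[te, ] <- out$class_scores
  }
  cm <- confusion_matrix(labels, pred, classes)
  rep <- macro_metrics(cm)
  rep$auc <- roc_auc_macro(labels, scores)$macro
  rep$predictions <- data.frame(subject_id = if (is.null(subject_ids))
    NA_character_ else subject_ids, truth = labels, predicted = pred)
  rep$class_scores <- scores
  rep
}

#' Incremental top-k forward feature search
#'
#' Runs [cross_validated_run()] on the top-1, top-2, ... top-`max_k` columns
#' of a ranked feature list and returns the metric trace plus the best `k`
#' (smallest `k` attaining the maximal pooled accuracy).
#'
#' @param ranked A `ranked_features` object.
#' @param table Feature table containing at least the ranked columns plus
#'   `subject_id` and `label`.
#' @param folds Fold assignment (see [cross_validated_run()]).
#' @param config A [knn_config()].
#' @param max_k Largest `k` to try; default the full ranked length.
#' @param smote,seed Passed to [cross_validated_run()].
#' @return List with `trace` (data frame `k`, `accuracy`, `precision`,
#'   `sensitivity`, `f1`, `auc`), `best_k`, and `best_report`.
#' @export
incremental_feature_search <- function(ranked, table, folds,
                                       config = knn_config(),
                                       max_k = NULL, smote = TRUE,
                                       seed = 1L) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (!length(ranked$names)) {
    stop_gaitdx("empty ranked feature list", class = "gaitdx_parameter_error")
  }
  if (is.null(max_k)) max_k <- length(ranked$names)
  max_k <- min(max_k, length(ranked$names))
  meta <- intersect(c("subject_id", "label", "cycle"), names(table))
  reports <- vector("list", max_k)
  rows <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    sub <- table[c(meta, ranked$names[seq_len(k)])]
    rep <- cross_validated_run(sub, folds, config = config, smote = smote,
                               seed = seed)
    reports[[k]] <- rep
    rows[[k]] <- data.frame(k = k, accuracy = rep$accuracy,
                            precision = rep$precision,
                            sensitivity = rep$sensitivity, f1 = rep$f1,
                            auc = rep$auc)
  }
  trace <- do.call(rbind, rows)
  best_k <- trace$k[which.max(trace$accuracy)]  # smallest argmax (stable)
  list(trace = trace, best_k = best_k, best_report = reports[[best_k]])
}

#' Small-grid KNN hyperparameter search
#'
#' Deterministic grid search over neighbour count, metric and weighting,
#' selected by pooled subject-wise CV accuracy. The shipped default
#' configuration (1 neighbour, Euclidean, squared-inverse) is the tuned
#' optimum; this function re-derives it from data.
#'
#' @param table Feature table.
#' @param folds Fold assignment.
#' @param n_neighbors_grid,metrics,weightings Search space.
#' @param smote,seed Passed to [cross_validated_run()].
#' @return List with `best` (a [knn_config()]) and `grid` (data frame of all
#'   configurations and accuracies).
#' @export
tune_knn <- function(table, folds, n_neighbors_grid = c(1, 3, 5, 7, 9),
                     metrics = c("euclidean", "cityblock"),
                     weightings = c("uniform", "inverse", "squared_inverse"),
                     smote = TRUE, seed = 1L) {
  grid <- expand.grid(n_neighbors = n_neighbors_grid, metric = metrics,
                      weighting = weightings, stringsAsFactors = FALSE)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- knn_config(grid$n_neighbors[i], grid$metric[i], grid$weighting[i])
    rep <- cross_validated_run(table, folds, config = cfg, smote = smote,
                               seed = seed)
    grid$accuracy[i] <- rep$accuracy
  }
  best <- grid[which.max(grid$accuracy), ]
  list(best = knn_config(best$n_neighbors, best$metric, best$weighting),
       grid = grid)
}
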