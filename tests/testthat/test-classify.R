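test_that("SMOTE leaves balanced data untouched, balances imbalanced data,
           and synthesizes only on same-class segments", {
  set.seed(500)
  Xb <- matrix(rnorm(90 * 2), ncol = 2)
  yb <- rep(c("a", "b", "c"), each = 30)
  out <- smote_augment(Xb, yb, seed = 1)
  expect_identical(dim(out$X), dim(Xb))
  expect_identical(out$y, yb)

  Xi <- matrix(rnorm(42 * 3), ncol = 3)
  yi <- rep(c("a", "b", "c"), c(12, 12, 18))
  aug <- smote_augment(Xi, yi, seed = 2)
  expect_true(all(table(aug$y) == 18))
  expect_identical(aug$X[seq_len(42), ], Xi)  # originals preserved, first
  # convexity: every synthetic point lies on a segment between two
  # same-class originals
  syn_idx <- seq(43, nrow(aug$X))
  for (i in syn_idx) {
    cl <- aug$y[i]
    orig <- Xi[yi == cl, , drop = FALSE]
    p <- aug$X[i, ]
    on_segment <- any(apply(orig, 1, function(u) {
      any(apply(orig, 1, function(v) {
        dv <- v - u
        if (sum(dv^2) < 1e-24) return(all(abs(p - u) < 1e-8))
        t <- sum((p - u) * dv) / sum(dv^2)
        t >= -1e-8 && t <= 1 + 1e-8 &&
          sqrt(sum((p - (u + t * dv))^2)) < 1e-8
      }))
    }))
    expect_true(on_segment)
  }
  expect_error(smote_augment(Xi[c(1, 13:42), ], yi[c(1, 13:42)]),
               class = "gaitdx_parameter_error")
  expect_identical(smote_augment(Xi, yi, seed = 2)$X, aug$X)
})

test_that("KNN matches trivial nearest-neighbour facts and the
           exhaustive-distance oracle", {
  set.seed(510)
  tr <- matrix(rnorm(60 * 4), ncol = 4)
  ytr <- sample(c("a", "b", "c"), 60, replace = TRUE)
  # exact match wins outright
  out <- knn_predict(tr, ytr, tr[7, , drop = FALSE], knn_config(1))
  expect_identical(out$labels, ytr[7])
  # self-prediction is perfect at k = 1
  self <- knn_predict(tr, ytr, tr, knn_config(1))
  expect_identical(self$labels, ytr)
  # oracle equivalence on 200 random points, several configurations
  te <- matrix(rnorm(200 * 4), ncol = 4)
  for (k in c(1, 5)) {
    for (m in c("euclidean", "cityblock")) {
      cfg <- knn_config(k, m, "squared_inverse")
      expect_identical(knn_predict(tr, ytr, te, cfg)$labels,
                       unname(oracle_knn(tr, ytr, te, k, m)))
    }
  }
  # with one neighbour the weighting function is inert
  p1 <- knn_predict(tr, ytr, te, knn_config(1, weighting = "uniform"))
  p2 <- knn_predict(tr, ytr, te, knn_config(1, weighting = "squared_inverse"))
  expect_identical(p1$labels, p2$labels)
  expect_error(knn_predict(tr, ytr, te, knn_config(100)),
               class = "gaitdx_parameter_error")
  # scores are proper distributions
  sc <- knn_predict(tr, ytr, te, knn_config(3))$class_scores
  expect_equal(unname(rowSums(sc)), rep(1, 200))
})

test_that("subject-wise folds partition subjects class-stratified with no
           subject spanning folds", {
  subj <- c(setNames(rep("control", 6), paste0("C", 1:6)),
            setNames(rep("DN", 6), paste0("N", 1:6)),
            setNames(rep("DFU", 9), paste0("U", 1:9)))
  f <- subject_wise_folds(as.list(subj), seed = 3)
  expect_length(f, 21)
  expect_true(all(table(f) %in% 4:5))
  # records of a subject inherit one fold; train/test subject sets disjoint
  recs <- rep(names(subj), each = 7)
  rf <- gaitdx:::record_fold_vector(f, recs)
  for (k in 0:4) {
    expect_length(intersect(recs[rf == k], recs[rf != k]), 0)
  }
  expect_error(subject_wise_folds(as.list(subj[1:3]), n_folds = 5),
               class = "gaitdx_parameter_error")
})

test_that("cross-validated KNN is deterministic, perfect on separable
           classes, and at chance on shuffled labels", {
  set.seed(520)
  n_sub <- 15
  subj_ids <- rep(sprintf("S%02d", 1:n_sub), each = 8)
  labels <- rep(rep(c("a", "b", "c"), each = 5)[1:n_sub], each = 8)
  centers <- rep(c(a = -6, b = 0, c = 6)[rep(c("a", "b", "c"),
                                             each = 5)[1:n_sub]], each = 8)
  X <- cbind(rnorm(length(centers), centers, 0.5),
             rnorm(length(centers), centers, 0.5))
  tab <- data.frame(subject_id = subj_ids, label = labels,
                    f1 = X[, 1], f2 = X[, 2])
  folds <- subject_wise_folds(subject_label_map(tab), seed = 1)
  rep1 <- cross_validated_run(tab, folds, seed = 1)
  expect_equal(rep1$accuracy, 100)
  expect_identical(cross_validated_run(tab, folds, seed = 1)$predictions,
                   rep1$predictions)

  accs <- vapply(1:20, function(s) {
    set.seed(600 + s)
    perm <- as.character(sample(unique(subj_ids)))
    lab_of <- setNames(labels[match(unique(subj_ids), subj_ids)], perm)
    shuf <- tab
    shuf$label <- unname(lab_of[shuf$subject_id])
    f <- subject_wise_folds(subject_label_map(shuf), seed = s)
    cross_validated_run(shuf, f, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 5)
})

test_that("the incremental search returns the smallest argmax depth and a
           trace consistent with independent re-runs", {
  set.seed(530)
  subj_ids <- rep(sprintf("S%02d", 1:12), each = 6)
  labels <- rep(rep(c("a", "b", "c"), each = 4), each = 6)
  good <- rnorm(72, c(a = -4, b = 0, c = 4)[labels], 0.5)
  tab <- data.frame(subject_id = subj_ids, label = labels,
                    good = good, n1 = rnorm(72), n2 = rnorm(72))
  folds <- subject_wise_folds(subject_label_map(tab), seed = 2)
  ranked <- rank_chi2(tab, tab$label)
  sr <- incremental_feature_search(ranked, tab, folds, seed = 5)
  expect_identical(nrow(sr$trace), 3L)
  for (k in 1:3) {
    sub <- tab[c("subject_id", "label", ranked$names[seq_len(k)])]
    again <- cross_validated_run(sub, folds, seed = 5)
    expect_equal(sr$trace$accuracy[k], again$accuracy)
  }
  expect_identical(sr$best_k,
                   sr$trace$k[which.max(sr$trace$accuracy)])
  one <- incremental_feature_search(
    gaitdx:::ranked_features("chi2", "good", 1), tab, folds, seed = 5)
  expect_identical(one$best_k, 1L)
})

test_that("median pipeline accuracy is monotone in the class-effect size", {
  run_at <- function(scale, seeds = 1:3) {
    vapply(seeds, function(s) {
      cfg <- cohort_config(cycles_per_subject = 4,
                           dn_peak_delay = 0.06 * scale,
                           dfu_peak_delay = 0.10 * scale,
                           second_peak_reduction = 0.15 * scale,
                           seed = 100 * s)
      co <- generate_cohort(cfg)
      ft <- extract_features(co, channels = "GRFz", grf_sets = "td")
      run_pipeline(ft, ranker = "chi2", max_k = 6,
                   seed = s)$report$accuracy
    }, numeric(1))
  }
  med <- vapply(c(0, 0.5, 1), function(sc) median(run_at(sc)), numeric(1))
  expect_true(all(diff(med) >= 0))
})
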