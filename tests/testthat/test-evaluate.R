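test_that("confusion matrix counts match a brute-force tally and reject
           malformed input", {
  set.seed(700)
  cls <- c("control", "DN", "DFU")
  tr <- sample(cls, 200, replace = TRUE)
  pr <- sample(cls, 200, replace = TRUE)
  cm <- confusion_matrix(tr, pr, cls)
  for (i in cls) for (j in cls) {
    expect_identical(cm[i, j], sum(tr == i & pr == j))
  }
  expect_identical(sum(cm), 200L)
  all_right <- confusion_matrix(tr, tr, cls)
  expect_true(all(all_right[upper.tri(all_right) | lower.tri(all_right)] == 0))
  expect_error(confusion_matrix(character(0), character(0)),
               class = "gaitdx_parameter_error")
  expect_error(confusion_matrix("a", "zz", classes = c("a", "b")),
               class = "gaitdx_parameter_error")
})

test_that("macro metrics reproduce the binary worked example and the
           one-vs-rest decomposition to 1e-12 on random matrices", {
  # binary case: TP=40 (pos->pos), FN=10, FP=20, TN=30
  cm <- confusion_matrix(
    rep(c("pos", "neg"), c(50, 50)),
    c(rep("pos", 40), rep("neg", 10), rep("pos", 20), rep("neg", 30)),
    c("neg", "pos"))
  mm <- macro_metrics(cm)
  pos_row <- mm$per_class[mm$per_class$class == "pos", ]
  expect_equal(mm$accuracy, 70)
  expect_equal(pos_row$sensitivity, 80)
  expect_equal(pos_row$precision, 200 / 3, tolerance = 1e-10)
  expect_equal(pos_row$f1, 800 / 11, tolerance = 1e-10)

  perfect <- confusion_matrix(rep(c("a", "b", "c"), 5),
                              rep(c("a", "b", "c"), 5))
  mp <- macro_metrics(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$f1, 100)

  set.seed(701)
  for (rep_i in 1:1000) {
    m <- matrix(rpois(9, 5), 3, 3,
                dimnames = list(true = c("a", "b", "c"),
                                predicted = c("a", "b", "c")))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    cm3 <- structure(m, classes = c("a", "b", "c"),
                     class = c("confusion_matrix", "matrix"))
    got <- macro_metrics(cm3)
    want <- oracle_macro(m)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_true(all(got$per_class$f1 + 1e-12 >=
                      pmin(got$per_class$precision,
                           got$per_class$sensitivity) - 1e-9))
  }
})

test_that("macro AUC matches the trapezoidal oracle (and pROC), has the
           trivial endpoints, a 0.5 null, and monotone-transform
           invariance", {
  y <- rep(c("a", "b"), each = 50)
  s_perfect <- cbind(a = c(runif(50, 0.6, 1), runif(50, 0, 0.4)))
  s_perfect <- cbind(s_perfect, b = 1 - s_perfect[, "a"])
  expect_equal(roc_auc_macro(y, s_perfect)$per_class[["a"]], 1)
  inverted <- s_perfect
  inverted[, "a"] <- 1 - s_perfect[, "a"]
  inverted[, "b"] <- 1 - s_perfect[, "b"]
  expect_equal(roc_auc_macro(y, inverted)$per_class[["a"]], 0)

  set.seed(710)
  n <- 2000
  yr <- sample(c("a", "b"), n, replace = TRUE)
  sr <- runif(n)
  S <- cbind(a = sr, b = 1 - sr)
  got <- roc_auc_macro(yr, S)
  expect_lt(abs(got$per_class[["a"]] - 0.5), 0.03)
  expect_equal(got$per_class[["a"]], oracle_auc(yr == "a", sr),
               tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = yr, predictor = sr, levels = c("b", "a"),
      direction = "<", quiet = TRUE)))
    expect_equal(got$per_class[["a"]], proc_auc, tolerance = 1e-12)
  }
  # strictly monotone transform leaves AUC unchanged
  S2 <- cbind(a = exp(3 * sr), b = 1 - sr)
  expect_equal(roc_auc_macro(yr, S2)$per_class[["a"]],
               got$per_class[["a"]], tolerance = 1e-12)
  expect_warning(
    const_auc <- roc_auc_macro(yr, cbind(a = sr, b = rep(0.5, n))),
    "degenerate")
  expect_equal(const_auc$per_class[["b"]], 0.5)
})

test_that("the channel experiment emits one row per combo-ranker cell with
           reproducible numbers", {
  set.seed(720)
  n_sub <- 12
  subj <- rep(sprintf("S%02d", 1:n_sub), each = 12)
  lab <- rep(rep(c("a", "b", "c"), each = 4), each = 12)
  mk_table <- function(shift) {
    data.frame(subject_id = subj, label = lab,
               f_info = rnorm(length(subj),
                              shift * c(a = -2, b = 0, c = 2)[lab], 1),
               f_noise = rnorm(length(subj)))
  }
  tables <- list(ch1 = mk_table(1), ch2 = mk_table(0.5), ch3 = mk_table(0))
  names(tables$ch1)[3:4] <- c("ch1_info", "ch1_noise")
  names(tables$ch2)[3:4] <- c("ch2_info", "ch2_noise")
  names(tables$ch3)[3:4] <- c("ch3_info", "ch3_noise")
  ex <- channel_experiment(tables, rankers = c("chi2", "mrmr", "relieff",
                                               "nca"),
                           max_k = 2, seed = 4)
  expect_identical(nrow(ex$grid), 7L * 4L)
  expect_identical(sort(unique(ex$grid$channels)),
                   sort(c("ch1", "ch2", "ch3", "ch1-ch2", "ch1-ch3",
                          "ch2-ch3", "ch1-ch2-ch3")))
  ex2 <- channel_experiment(tables, rankers = c("chi2", "mrmr", "relieff",
                                                "nca"),
                            max_k = 2, seed = 4)
  expect_identical(ex$grid, ex2$grid)
  expect_error(channel_experiment(tables, combos = list("nope"), max_k = 1),
               class = "gaitdx_parameter_error")
})
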