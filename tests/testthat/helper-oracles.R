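# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities from first principles and
# must stay independent of the package implementations they check.

# Exhaustive-distance KNN with squared-inverse weighting.
oracle_knn <- function(train_X, train_y, test_X, k = 1,
                       metric = c("euclidean", "cityblock"),
                       weighting = c("squared_inverse", "uniform", "inverse")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  apply(test_X, 1, function(v) {
    d <- apply(train_X, 1, function(u) {
      if (metric == "euclidean") sqrt(sum((u - v)^2)) else sum(abs(u - v))
    })
    nb <- order(d)[seq_len(k)]
    if (any(d[nb] == 0)) {
      votes <- table(train_y[nb][d[nb] == 0])
    } else {
      w <- switch(weighting,
                  uniform = rep(1, k),
                  inverse = 1 / d[nb],
                  squared_inverse = 1 / d[nb]^2)
      votes <- tapply(w, train_y[nb], sum)
    }
    names(votes)[which.max(votes)]
  })
}

# Per-class one-vs-rest metrics computed longhand from a count matrix.
oracle_macro <- function(m) {
  n <- sum(m)
  cls <- seq_len(nrow(m))
  sens <- prec <- f1 <- numeric(length(cls))
  for (i in cls) {
    tp <- m[i, i]
    fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[i] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  list(accuracy = 100 * sum(diag(m)) / n, precision = 100 * mean(prec),
       sensitivity = 100 * mean(sens), f1 = 100 * mean(f1))
}

# Trapezoidal AUC from an explicit threshold sweep over unique scores.
oracle_auc <- function(pos, score) {
  th <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  fpr <- vapply(th, function(t) mean(score[!pos] >= t), numeric(1))
  tpr <- vapply(th, function(t) mean(score[pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Mutual information (nats) from entropies: I = H(a) + H(b) - H(a, b).
oracle_mi <- function(a, b) {
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  H(as.numeric(table(a)) / length(a)) +
    H(as.numeric(table(b)) / length(b)) -
    H(as.numeric(table(paste(a, b))) / length(a))
}

# Levinson-Durbin solution of the Yule-Walker equations, written longhand.
oracle_yule_walker <- function(x, order = 4) {
  x <- x - mean(x)
  n <- length(x)
  r <- vapply(0:order, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
  a <- numeric(0)
  e <- r[1]
  for (m in seq_len(order)) {
    k <- if (m == 1) r[2] / e else (r[m + 1] - sum(a * r[seq(m, 2)])) / e
    a <- c(a - k * rev(a), k)
    e <- e * (1 - k^2)
  }
  a
}

# Small, fast synthetic cohort for integration-style tests.
make_test_cohort <- function(seed = 1, cycles = 3, ...) {
  generate_cohort(cohort_config(cycles_per_subject = cycles, seed = seed, ...))
}

# Planted-separating-feature dataset: one informative column among noise.
make_planted <- function(seed, n_per = 40, p_noise = 20, sep = 1, sd0 = 0.3) {
  set.seed(seed)
  y <- rep(c("a", "b", "c"), each = n_per)
  f <- stats::rnorm(3 * n_per, rep(c(-sep, 0, sep), each = n_per), sd0)
  X <- cbind(planted = f,
             matrix(stats::rnorm(3 * n_per * p_noise), ncol = p_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(X = as.data.frame(X), y = y)
}

subject_label_map <- function(table) {
  as.list(tapply(as.character(table$label), as.character(table$subject_id),
                 `[`, 1))
}
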