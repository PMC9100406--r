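# Feature selection: correlation-based pruning and the four filter-type
# ranking algorithms (chi-square, mRMR, ReliefF, NCA). Rankers consume a
# numeric feature matrix / data frame and a class-label vector and return a
# `ranked_features` object: ordered names with aligned scores.

ranked_features <- function(method, names, scores) {
  structure(list(method = method, names = names,
                 scores = as.numeric(scores)),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat("Ranked features (", x$method, "), top ",
      min(10L, length(x$names)), " of ", length(x$names), ":\n", sep = "")
  print(utils::head(data.frame(feature = x$names, score = x$scores), 10))
  invisible(x)
}

feature_matrix <- function(table) {
  meta <- intersect(c("subject_id", "label", "cycle"), names(table))
  as.matrix(table[setdiff(names(table), meta)])
}

check_labels <- function(y) {
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    stop_gaitdx("feature ranking needs at least 2 classes",
                class = "gaitdx_ranking_error")
  }
  y
}

# Equal-frequency discretization into at most n_bins bins.
equal_freq_bins <- function(x, n_bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

chi2_stat <- function(bins, y) {
  O <- table(bins, y)
  if (nrow(O) < 2) return(0)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Mutual information (nats) between two discrete vectors.
mutual_information <- function(a, b) {
  J <- table(a, b) / length(a)
  pa <- rowSums(J)
  pb <- colSums(J)
  E <- outer(pa, pb)
  idx <- J > 0
  sum(J[idx] * log(J[idx] / E[idx]))
}

#' Drop highly correlated features
#'
#' Scans column pairs `(i < j)` in input order; whenever the absolute Pearson
#' correlation exceeds `threshold` and neither column is already dropped, the
#' later column `j` is dropped. Zero-variance columns are never dropped (they
#' correlate with nothing) but are flagged. Deterministic and idempotent.
#'
#' @param table Data frame of numeric feature columns (metadata columns
#'   `subject_id`, `label`, `cycle` are carried through untouched).
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return List with `table` (surviving columns), `dropped` (names, in drop
#'   order) and `flagged` (zero-variance column names).
#' @export
drop_correlated <- function(table, threshold = 0.9) {
  meta <- intersect(c("subject_id", "label", "cycle"), names(table))
  X <- feature_matrix(table)
  if (nrow(X) < 2) {
    stop_gaitdx("correlation pruning needs at least 2 rows",
                class = "gaitdx_config_error")
  }
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  flagged <- colnames(X)[sds == 0]
  keep <- rep(TRUE, p)
  cm <- suppressWarnings(abs(stats::cor(X)))
  cm[is.na(cm)] <- 0
  for (i in seq_len(p - 1)) {
    if (!keep[i]) next
    for (j in seq((i + 1), p)) {
      if (keep[j] && cm[i, j] > threshold) keep[j] <- FALSE
    }
  }
  dropped <- colnames(X)[!keep]
  list(table = table[c(meta, colnames(X)[keep])],
       dropped = dropped, flagged = flagged)
}

#' Chi-square feature ranking
#'
#' Each feature is discretized into `n_bins` equal-frequency bins and scored
#' by the chi-square statistic of the bin-by-class contingency table
#' (independence test between feature occupancy and class). Features are
#' returned in descending score order, ties broken by input column order.
#'
#' @param X Feature data frame or matrix (metadata columns ignored).
#' @param y Class labels.
#' @param n_bins Number of equal-frequency bins.
#' @return A `ranked_features` object.
#' @export
rank_chi2 <- function(X, y, n_bins = 10) {
  X <- feature_matrix(as.data.frame(X))
  y <- check_labels(y)
  scores <- apply(X, 2, function(col) chi2_stat(equal_freq_bins(col, n_bins), y))
  ord <- order(-scores)  # stable: ties keep input order
  ranked_features("chi2", colnames(X)[ord], scores[ord])
}

#' Minimum-redundancy maximum-relevance (mRMR) ranking
#'
#' Greedy forward ranking under the MID criterion: at each step the feature
#' maximizing `I(f; y) - mean(I(f; s))` over already-selected features `s` is
#' appended, with mutual information estimated from equal-frequency binning.
#' The full ordering is returned; scores are the criterion value at each
#' selection step (not necessarily monotone).
#'
#' @inheritParams rank_chi2
#' @return A `ranked_features` object.
#' @export
rank_mrmr <- function(X, y, n_bins = 10) {
  X <- feature_matrix(as.data.frame(X))
  y <- check_labels(y)
  p <- ncol(X)
  B <- apply(X, 2, equal_freq_bins, n_bins = n_bins)
  rel <- apply(B, 2, mutual_information, b = y)
  red <- matrix(NA_real_, p, p)  # filled lazily
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    crit <- vapply(remaining, function(j) {
      if (!length(selected)) return(rel[j])
      for (s in selected) {
        if (is.na(red[s, j])) {
          red[s, j] <<- red[j, s] <<- mutual_information(B[, j], B[, s])
        }
      }
      rel[j] - mean(red[selected, j])
    }, numeric(1))
    best <- remaining[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, best)
  }
  ranked_features("mrmr", colnames(X)[selected], scores)
}

#' ReliefF feature ranking
#'
#' Standard multi-class ReliefF: every sample contributes its `k` nearest
#' same-class hits and, for each other class, `k` nearest misses weighted by
#' the class prior; per-feature value differences are scaled by the feature
#' range and averaged over all samples. Distances are Manhattan on
#' range-normalized features.
#'
#' @inheritParams rank_chi2
#' @param k Number of nearest hits/misses per class (default 10); every
#'   class must have more than `k` members.
#' @return A `ranked_features` object.
#' @export
rank_relieff <- function(X, y, k = 10) {
  X <- feature_matrix(as.data.frame(X))
  y <- check_labels(y)
  n <- nrow(X)
  counts <- table(y)
  small <- names(counts)[counts <= k]
  if (length(small)) {
    stop_gaitdx("class ", small[1], " has <= k = ", k, " members",
                class = "gaitdx_parameter_error")
  }
  rng <- apply(X, 2, function(col) max(col) - min(col))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  priors <- counts / n
  W <- numeric(ncol(X))
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  for (i in seq_len(n)) {
    di <- D[i, ]
    di[i] <- Inf
    hits <- which(y == y[i])
    hits <- hits[order(di[hits])][seq_len(k)]
    hit_term <- colMeans(abs(Xn[hits, , drop = FALSE] -
                             matrix(Xn[i, ], k, ncol(X), byrow = TRUE)))
    miss_term <- numeric(ncol(X))
    for (cl in setdiff(names(counts), y[i])) {
      mi <- which(y == cl)
      mi <- mi[order(di[mi])][seq_len(k)]
      wc <- priors[[cl]] / (1 - priors[[y[i]]])
      miss_term <- miss_term +
        wc * colMeans(abs(Xn[mi, , drop = FALSE] -
                          matrix(Xn[i, ], k, ncol(X), byrow = TRUE)))
    }
    W <- W + (miss_term - hit_term) / n
  }
  ord <- order(-W)
  ranked_features("relieff", colnames(X)[ord], W[ord])
}

#' Neighborhood component analysis (NCA) feature ranking
#'
#' Learns nonnegative per-feature weights `w` by projected full-batch
#' gradient ascent on the expected leave-one-out accuracy of a soft
#' (exponential-kernel) nearest-neighbour rule with weighted distance
#' `d_w(i, j) = sum_r w_r^2 |x_ir - x_jr|`, minus the ridge penalty
#' `lambda * sum(w^2)`. Features are standardized internally; the descending
#' weight order is the ranking.
#'
#' @inheritParams rank_chi2
#' @param lambda Regularization strength; default `1 / n`.
#' @param max_iter Maximum gradient iterations (default 100).
#' @param step Initial step size for the adaptive (halving) line search.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Unused entropy anchor kept for interface stability; the
#'   full-batch ascent is deterministic.
#' @return A `ranked_features` object with attribute `converged`.
#' @export
rank_nca <- function(X, y, lambda = NULL, max_iter = 100, step = 1,
                     tol = 1e-6, seed = 1L) {
  X <- feature_matrix(as.data.frame(X))
  y <- check_labels(y)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / n
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)

  # |x_ir - x_jr| flattened to an (n*n) x p matrix, built once.
  A <- matrix(0, n * n, p)
  for (r in seq_len(p)) {
    A[, r] <- abs(outer(Xs[, r], Xs[, r], "-"))
  }
  same <- as.numeric(outer(y, y, "=="))
  diag_idx <- (seq_len(n) - 1) * n + seq_len(n)

  objective_grad <- function(w) {
    d <- matrix(A %*% (w^2), n, n)
    # softmax over j != i, numerically stabilized per row
    nd <- -d
    nd[diag_idx] <- -Inf
    mx <- apply(nd, 1, max)
    P <- exp(nd - mx)
    P <- P / rowSums(P)
    pi_i <- rowSums(P * matrix(same, n, n))
    f <- mean(pi_i) - lambda * sum(w^2)
    C <- P * (pi_i - matrix(same, n, n))   # c_ij = p_ij (p_i - hit_ij)
    g <- (2 * w) * as.numeric(crossprod(A, as.numeric(C))) / n -
      2 * lambda * w
    list(f = f, g = g)
  }

  w <- rep(1, p)
  og <- objective_grad(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- step
    repeat {
      w_new <- pmax(w + st * og$g, 0)
      og_new <- objective_grad(w_new)
      if (og_new$f >= og$f || st < 1e-10) break
      st <- st / 2
    }
    if (abs(og_new$f - og$f) < tol * max(1, abs(og$f))) {
      w <- w_new
      og <- og_new
      converged <- TRUE
      break
    }
    w <- w_new
    og <- og_new
    step <- st * 1.2
  }
  if (!converged) {
    warning("NCA did not converge after ", max_iter,
            " iterations; returning current weights")
  }
  ord <- order(-w)
  out <- ranked_features("nca", colnames(X)[ord], w[ord])
  attr(out, "converged") <- converged
  out
}

#' Rank features by one of the four methods
#'
#' Dispatcher over [rank_chi2()], [rank_mrmr()], [rank_relieff()] and
#' [rank_nca()].
#'
#' @param X Feature data frame or matrix.
#' @param y Class labels.
#' @param method One of `"chi2"`, `"mrmr"`, `"relieff"`, `"nca"`.
#' @param ... Passed to the method.
#' @return A `ranked_features` object.
#' @export
rank_features <- function(X, y, method = c("chi2", "mrmr", "relieff", "nca"),
                          ...) {
  method <- match.arg(method)
  switch(method,
         chi2 = rank_chi2(X, y, ...),
         mrmr = rank_mrmr(X, y, ...),
         relieff = rank_relieff(X, y, ...),
         nca = rank_nca(X, y, ...))
}
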