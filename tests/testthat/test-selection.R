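test_that("correlation pruning drops the later of each collinear pair, keeps
           orthogonal and zero-variance columns, and is idempotent", {
  set.seed(400)
  n <- 100
  a <- rnorm(n)
  b <- 0.95 * scale(a)[, 1] + sqrt(1 - 0.95^2) * rnorm(n)  # r ~ 0.95
  tab <- data.frame(label = rep(c("x", "y"), n / 2),
                    f1 = a, f2 = a * 2 + 3, f3 = b, f4 = rnorm(n),
                    f5 = rep(1, n))
  out <- drop_correlated(tab)
  expect_true(all(c("f2", "f3") %in% out$dropped))
  expect_true(all(c("f1", "f4", "f5") %in% names(out$table)))
  expect_identical(out$flagged, "f5")
  expect_gt(abs(cor(a, b)), 0.9)  # construction sanity
  twice <- drop_correlated(out$table)
  expect_identical(names(twice$table), names(out$table))
  expect_length(twice$dropped, 0)
  # orthogonal constructed columns survive
  orth <- data.frame(g1 = rep(c(1, -1, 1, -1), 10),
                     g2 = rep(c(1, 1, -1, -1), 10))
  expect_length(drop_correlated(orth)$dropped, 0)
})

test_that("chi-square ranking scores a hand-computed contingency table,
           zeroes constants, and tops an injective class encoding", {
  y <- rep(c("a", "b"), each = 10)
  f <- c(1:10, 21:30)  # 2 equal-frequency bins = perfect split
  r <- rank_chi2(data.frame(f = f), y, n_bins = 2)
  expect_equal(r$scores[1], 20)  # 2x2 table (10,0 / 0,10)
  r2 <- rank_chi2(data.frame(konst = rep(7, 20), f = f), y, n_bins = 2)
  expect_equal(r2$scores[r2$names == "konst"], 0)
  wins <- sum(vapply(1:50, function(s) {
    d <- make_planted(s)
    rank_chi2(d$X, d$y)$names[1] == "planted"
  }, logical(1)))
  expect_gte(wins, 49)
  expect_error(rank_chi2(data.frame(f = f), rep("a", 20)),
               class = "gaitdx_ranking_error")
})

test_that("mRMR penalizes redundancy and agrees with the exhaustive greedy
           oracle on small tables", {
  set.seed(410)
  n <- 300
  y <- rep(c("a", "b"), each = n / 2)
  strong <- rnorm(n, ifelse(y == "a", -1, 1), 0.4)
  weak <- rnorm(n, ifelse(y == "a", -0.5, 0.5), 0.9)
  X <- data.frame(strong = strong, dup = strong, weak = weak)
  r <- rank_mrmr(X, y)
  expect_identical(r$names[1], "strong")
  # the exact duplicate is penalized below the weaker complementary feature
  expect_gt(match("dup", r$names), match("weak", r$names))

  # exhaustive oracle: recompute the greedy MID ordering longhand
  Xo <- data.frame(a = rnorm(n), b = rnorm(n, ifelse(y == "a", 0, 1)),
                   c = rnorm(n), d = strong, e = weak)
  r5 <- rank_mrmr(Xo, y, n_bins = 5)
  bins <- lapply(Xo, function(col) {
    br <- unique(quantile(col, seq(0, 1, length.out = 6)))
    as.integer(cut(col, br, include.lowest = TRUE))
  })
  rel <- vapply(bins, oracle_mi, b = y, numeric(1))
  sel <- character(0)
  rest <- names(Xo)
  while (length(rest)) {
    crit <- vapply(rest, function(f) {
      if (!length(sel)) return(rel[[f]])
      rel[[f]] - mean(vapply(sel, function(s)
        oracle_mi(bins[[f]], bins[[s]]), numeric(1)))
    }, numeric(1))
    sel <- c(sel, rest[which.max(crit)])
    rest <- setdiff(rest, sel)
  }
  expect_identical(r5$names, sel)
  expect_identical(rank_mrmr(data.frame(only = rnorm(50)),
                             rep(c("a", "b"), 25))$names, "only")
})

test_that("ReliefF scores duplicates identically, hovers near zero under a
           shuffled-label null, and finds planted structure", {
  set.seed(420)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  f <- rnorm(n, ifelse(y == "a", -1, 1), 0.3)
  X <- data.frame(f1 = f, f2 = f, noise = rnorm(n))
  r <- rank_relieff(X, y)
  expect_equal(r$scores[r$names == "f1"], r$scores[r$names == "f2"],
               tolerance = 1e-12)
  expect_true(all(match(c("f1", "f2"), r$names) < match("noise", r$names)))

  null_scores <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    Xn <- data.frame(a = rnorm(n))
    yn <- sample(y)
    rank_relieff(Xn, yn)$scores[1]
  }, numeric(1))
  se <- sd(null_scores) / sqrt(length(null_scores))
  expect_lt(abs(mean(null_scores)), 3 * se + 1e-3)

  wins <- sum(vapply(1:50, function(s) {
    d <- make_planted(s)
    rank_relieff(d$X, d$y)$names[1] == "planted"
  }, logical(1)))
  expect_gte(wins, 49)
  small <- data.frame(a = rnorm(12))
  expect_error(rank_relieff(small, rep(c("a", "b"), each = 6), k = 10),
               class = "gaitdx_parameter_error")
})

test_that("NCA weights collapse under heavy regularization and promote a
           planted separating feature (including a duplicated one)", {
  d <- make_planted(1, n_per = 30, p_noise = 8)
  r_big <- rank_nca(d$X, d$y, lambda = 1e4, max_iter = 50)
  expect_true(all(r_big$scores < 1e-3))
  wins <- sum(vapply(1:20, function(s) {
    dd <- make_planted(s, n_per = 30, p_noise = 10)
    rank_nca(dd$X, dd$y)$names[1] == "planted"
  }, logical(1)))
  expect_gte(wins, 20)
  # duplicated informative feature: one copy stays rank 1, both beat noise
  dd <- make_planted(5, n_per = 30, p_noise = 6)
  dd$X$planted2 <- dd$X$planted
  rr <- rank_nca(dd$X, dd$y)
  expect_true(rr$names[1] %in% c("planted", "planted2"))
  pos <- match(c("planted", "planted2"), rr$names)
  first_noise <- min(match(grep("^noise", rr$names, value = TRUE), rr$names))
  expect_true(all(pos < first_noise))
})

test_that("rankers are invariant to row order and produce monotone scores
           (sort-based methods)", {
  d <- make_planted(7, n_per = 25, p_noise = 6)
  perm <- sample(length(d$y))
  for (m in c("chi2", "relieff")) {
    r1 <- rank_features(d$X, d$y, m)
    r2 <- rank_features(d$X[perm, ], d$y[perm], m)
    expect_identical(r1$names, r2$names)
    expect_equal(r1$scores, r2$scores, tolerance = 1e-10)
    expect_true(all(diff(r1$scores) <= 1e-12))
  }
  r1 <- rank_mrmr(d$X, d$y)
  r2 <- rank_mrmr(d$X[perm, ], d$y[perm])
  expect_identical(r1$names, r2$names)
  n1 <- rank_nca(d$X, d$y)
  n2 <- rank_nca(d$X[perm, ], d$y[perm])
  expect_identical(n1$names, n2$names)
  expect_equal(n1$scores, n2$scores, tolerance = 1e-6)
})
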