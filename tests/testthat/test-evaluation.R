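# Cross-validation partitioning, metrics, selection rules, the performance
# frontier, the forecasting baseline and latent standardization.

test_that("contiguous folds partition the series exhaustively", {
  f <- contiguous_kfold(100, 5)
  expect_equal(sapply(f, function(x) length(x$test)), rep(20, 5))
  f2 <- contiguous_kfold(103, 5)
  expect_equal(sapply(f2, function(x) length(x$test)), c(21, 21, 21, 20, 20))
  all_test <- sort(unlist(lapply(f2, `[[`, "test")))
  expect_equal(all_test, 1:103)                       # exhaustive
  expect_equal(anyDuplicated(all_test), 0L)           # disjoint
  for (k in 1:5) {
    expect_equal(sort(c(f2[[k]]$train, f2[[k]]$test)), 1:103)
    expect_equal(diff(range(f2[[k]]$test)), length(f2[[k]]$test) - 1)
  }
  expect_error(contiguous_kfold(3, 5), "shorter")
})

test_that("mean CC matches the Pearson formula and its edge conventions", {
  a <- matrix(1:4, 4, 1)
  expect_equal(mean_cc(a, a), 1)
  expect_equal(mean_cc(a, -a), -1)
  expect_equal(mean_cc(a, matrix(c(1, 1, 2, 2))), 0.894, tolerance = 1e-3)
  # direct formula oracle on random multivariate data
  set.seed(1)
  A <- matrix(rnorm(60), 20, 3)
  P <- matrix(rnorm(60), 20, 3)
  oracle <- mean(sapply(1:3, function(j) {
    num <- sum((A[, j] - mean(A[, j])) * (P[, j] - mean(P[, j])))
    num / sqrt(sum((A[, j] - mean(A[, j]))^2) * sum((P[, j] - mean(P[, j]))^2))
  }))
  expect_equal(mean_cc(A, P), oracle, tolerance = 1e-12)
  # constant predicted dimension scores zero
  P0 <- P
  P0[, 2] <- 3.14
  expect_equal(mean_cc(A, P0),
               mean(c(cor(A[, 1], P[, 1]), 0, cor(A[, 3], P[, 3]))),
               tolerance = 1e-12)
  # constant actual dimension is excluded with a warning
  A0 <- A
  A0[, 1] <- 0
  expect_warning(v <- mean_cc(A0, P), "constant")
  expect_equal(v, mean(sapply(2:3, function(j) cor(A[, j], P[, j]))),
               tolerance = 1e-12)
})

test_that("mean CC is invariant to positive affine rescaling of predictions", {
  set.seed(2)
  A <- matrix(rnorm(40), 20, 2)
  P <- matrix(rnorm(40), 20, 2)
  P2 <- sweep(sweep(P, 2, c(2.5, 0.3), "*"), 2, c(-1, 7), "+")
  expect_equal(mean_cc(A, P), mean_cc(A, P2), tolerance = 1e-12)
})

test_that("multiclass AUC hits the chance and perfect anchors", {
  set.seed(3)
  lab <- sample.int(4, 200, TRUE)
  # constant uniform classifier: chance level 0.5
  expect_equal(multiclass_auc(lab, matrix(0.25, 200, 4)), 0.5)
  # one-hot correct classifier: perfect level 1
  onehot <- matrix(0, 200, 4)
  onehot[cbind(1:200, lab)] <- 1
  expect_equal(multiclass_auc(lab, onehot), 1)
})

test_that("multiclass AUC equals the rank-statistic oracle", {
  lab <- c(1L, 2L, 3L, 1L, 2L, 3L)
  set.seed(4)
  pr <- matrix(runif(18), 6, 3)
  pr <- pr / rowSums(pr)
  # pairwise-comparison (Mann-Whitney) oracle per class, one vs rest
  oracle <- mean(sapply(1:3, function(cl) {
    pos <- pr[lab == cl, cl]
    neg <- pr[lab != cl, cl]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }))
  expect_equal(multiclass_auc(lab, pr), oracle, tolerance = 1e-12)
  expect_warning(multiclass_auc(c(1L, 1L, 2L, 2L), matrix(0.5, 4, 3)),
                 "absent")
})

test_that("signed-rank test matches the exact distribution", {
  # ten strictly positive, untied differences: exact one-sided p = 1/2^10
  expect_equal(paired_signed_rank(1:10 + 0.1 * (1:10), 1:10 * 1.0), 1 / 1024,
               tolerance = 1e-12)
  expect_equal(paired_signed_rank(rep(1, 6), rep(1, 6)), 1)
  # exact-enumeration oracle for n = 6: p = P(T+ >= observed) over all
  # 2^6 sign assignments of the ranked |differences|
  set.seed(5)
  a <- rnorm(6)
  b <- rnorm(6)
  d <- a - b
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  t_all <- as.matrix(signs) %*% rk
  p_oracle <- mean(t_all >= t_obs)
  expect_equal(paired_signed_rank(a, b, "greater"), p_oracle,
               tolerance = 1e-12)
})

test_that("the frontier rule reproduces hand-enumerated tables", {
  # model 1 dominates model 2 in both metrics (consistently, 8 folds)
  d <- rbind(m1 = 1:8 / 10 + 0.2, m2 = 1:8 / 10)
  s <- rbind(m1 = 1:8 / 10 + 0.2, m2 = 1:8 / 10)
  expect_equal(unname(performance_frontier(d, s)), c(TRUE, FALSE))
  # each model wins one metric: both are on the frontier
  d2 <- rbind(m1 = 1:8 / 10 + 0.2, m2 = 1:8 / 10)
  s2 <- rbind(m1 = 1:8 / 10, m2 = 1:8 / 10 + 0.2)
  expect_equal(unname(performance_frontier(d2, s2)), c(TRUE, TRUE))
  # identical samples: no significant difference, both on the frontier
  expect_equal(unname(performance_frontier(rbind(d[1, ], d[1, ]),
                                           rbind(s[1, ], s[1, ]))),
               c(TRUE, TRUE))
  # sub-1% relative mean difference is not significant even if consistent
  d3 <- rbind(m1 = rep(1.000, 8) + (1:8) * 1e-5, m2 = rep(1.0, 8))
  expect_equal(unname(performance_frontier(d3, d3)), c(TRUE, TRUE))
})

test_that("frontier reduces to Pareto dominance when all gaps are large", {
  set.seed(6)
  base <- seq(0.3, 0.44, by = 0.02)
  dec <- rbind(a = base + 0.30, b = base + 0.20, c = base + 0.10)
  sp <- rbind(a = base + 0.10, b = base + 0.30, c = base + 0.05)
  # a and b trade off; c is dominated by both
  expect_equal(unname(performance_frontier(dec, sp)),
               c(TRUE, TRUE, FALSE))
})

test_that("dimension selection follows the peak rules", {
  sweep_df <- data.frame(
    fold = 1, dim = c(1, 2, 4),
    split = "train",
    decoding = c(0.2, 0.5, 0.5),
    selfpred = c(0.1, 0.2, 0.3))
  expect_equal(select_dimension(sweep_df, "decoding_peak")$dim, 2)
  # decoding peaks at 4, self-prediction at 64: joint picks the larger
  sweep_df2 <- data.frame(
    fold = 1, dim = c(4, 16, 64), split = "train",
    decoding = c(0.6, 0.5, 0.5), selfpred = c(0.2, 0.3, 0.4))
  expect_equal(select_dimension(sweep_df2, "joint_peak")$dim, 64)
  # exhaustive-scan oracle on random curves
  set.seed(7)
  for (rep in 1:20) {
    dims <- c(1, 2, 4, 8)
    dec <- round(runif(4), 2)
    sp <- round(runif(4), 2)
    df <- data.frame(fold = 1, dim = dims, split = "train",
                     decoding = dec, selfpred = sp)
    o_dec <- dims[min(which(dec == max(dec)))]
    o_sp <- dims[min(which(sp == max(sp)))]
    expect_equal(select_dimension(df, "decoding_peak")$dim, o_dec)
    expect_equal(select_dimension(df, "joint_peak")$dim, max(o_dec, o_sp))
  }
})

test_that("the naive hold baseline behaves as arithmetic dictates", {
  Yc <- matrix(5, 10, 1)
  nb <- naive_forecast_baseline(Yc, 3)
  expect_true(all(nb$y_hat[4:10, ] == 5))  # constant series: zero error
  ramp <- matrix(1:20, 20, 1)
  for (m in 1:4) {
    err <- abs(naive_forecast_baseline(ramp, m)$y_hat - ramp)
    expect_true(all(err[!is.na(err)] == m))  # error grows linearly with m
  }
  Y <- matrix(rnorm(10), 10, 1)
  nb1 <- naive_forecast_baseline(Y, 1)
  expect_equal(nb1$y_hat[2:10, ], Y[1:9, ])  # one-step = shift by one
})

test_that("2-D latent standardization normalizes, rotates and orients", {
  set.seed(8)
  th <- seq(0, 3 * pi / 2, length.out = 40)
  # clockwise ellipse, offset and scaled, plus noisy trials
  base <- cbind(3 + 2 * cos(-th + 0.8), -1 + 0.5 * sin(-th + 0.8))
  trajs <- list(
    cond1 = lapply(1:4, function(i) base + 0.05 * matrix(rnorm(80), 40, 2)),
    cond2 = lapply(1:4, function(i) 0.7 * base + 0.05 * matrix(rnorm(80), 40, 2))
  )
  out <- standardize_2d_latents(trajs)
  pts <- do.call(rbind, unlist(out$trajectories, recursive = FALSE))
  # z-scored before the (variance-mixing) rotation: zero mean, and the
  # rotation preserves the total variance of the two unit-variance dims
  expect_equal(colMeans(pts), c(0, 0), tolerance = 1e-10)
  expect_equal(sum(apply(pts, 2, var)), 2, tolerance = 0.05)
  m1 <- out$means$cond1
  expect_lt(abs(atan2(m1[1, 2], m1[1, 1])), 1e-6)  # starts at angle 0
  n <- nrow(m1)
  area2 <- sum(m1[-n, 1] * m1[-1, 2] - m1[-1, 1] * m1[-n, 2])
  expect_gt(area2, 0)  # counterclockwise after reflection
  expect_error(standardize_2d_latents(list(a = matrix(0, 5, 3))), "2-D")
})

test_that("the evaluation pipeline never touches the test fold", {
  dat <- quick_world(seed = 31, Tn = 600)
  folds <- contiguous_kfold(600, 3)
  te <- folds[[2]]$test
  Y_test_hash <- digest_series(dat$Y[te, ])
  Z_test_hash <- digest_series(dat$Z[te, ])
  spec <- dpad_spec(3, 2, n_x = 2, n_1 = 2)
  sw <- dimension_sweep(dat$Y, dat$Z, spec, quick_cfg(max_epochs = 5),
                        dims = c(1, 2), folds = 3)
  sel <- select_dimension(sw, "joint_peak")
  expect_identical(digest_series(dat$Y[te, ]), Y_test_hash)
  expect_identical(digest_series(dat$Z[te, ]), Z_test_hash)
  expect_equal(nrow(sel), 3)
  expect_true(all(sel$dim %in% c(1, 2)))
  expect_equal(nrow(sw), 12)  # 3 folds x 2 dims x 2 splits
})
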