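# Loss definitions, the behavior of the four optimization steps, masking,
# and residual covariance estimation.

test_that("Gaussian loss is the masked sum of squared errors", {
  expect_equal(loss_gaussian(matrix(c(1, 2)), matrix(c(1, 2))), 0)
  expect_equal(loss_gaussian(matrix(c(1, 2)), matrix(c(0, 0))), 5)
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  p <- matrix(rnorm(30), 10, 3)
  msk <- rbinom(10, 1, 0.6) > 0
  msk[1] <- TRUE
  # brute-force summation oracle
  tot <- 0
  for (i in 1:10) if (msk[i]) for (j in 1:3) tot <- tot + (a[i, j] - p[i, j])^2
  expect_equal(loss_gaussian(a, p, msk), tot)
  expect_error(loss_gaussian(a, p, rep(FALSE, 10)), "empty objective")
  # doubling all errors quadruples the loss (isotropic Gaussian NLL shape)
  expect_equal(loss_gaussian(a, a + 2 * (p - a)), 4 * loss_gaussian(a, p))
})

test_that("categorical loss is the masked NLL of the true class", {
  lab <- matrix(c(1L, 2L), 2, 1)
  p <- array(0, c(2, 1, 4))
  p[1, 1, ] <- c(1, 0, 0, 0)
  p[2, 1, ] <- c(0, 1, 0, 0)
  expect_equal(loss_categorical(lab, p), 0)
  pu <- array(0.25, c(1, 1, 4))
  expect_equal(loss_categorical(matrix(3L), pu), log(4))
  set.seed(2)
  lab <- matrix(sample.int(3, 12, TRUE), 6, 2)
  pr <- array(runif(6 * 2 * 3), c(6, 2, 3))
  pr <- pr / as.vector(apply(pr, c(1, 2), sum))
  msk <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  tot <- 0
  for (i in which(msk)) for (m in 1:2) tot <- tot - log(pr[i, m, lab[i, m]])
  expect_equal(loss_categorical(lab, pr, msk), tot)
})

test_that("linear static fits equal the ordinary least-squares solution", {
  set.seed(3)
  X <- matrix(rnorm(200), 4, 50)
  W_true <- matrix(rnorm(8), 2, 4)
  Yt <- W_true %*% X + 0.05 * matrix(rnorm(100), 2, 50)
  W_hat <- dpad:::ols_map(X, Yt, rep(1, 50))
  # closed-form OLS oracle computed independently per output row
  for (r in 1:2) {
    beta <- solve(X %*% t(X), X %*% Yt[r, ])
    expect_equal(drop(W_hat[r, ]), drop(beta), tolerance = 1e-6)
  }
  # realizable regression recovers the generating map
  W_exact <- dpad:::ols_map(X, W_true %*% X, rep(1, 50))
  expect_equal(W_exact, W_true, tolerance = 1e-7)
  # target independent of the regressors: fit approaches zero map
  # (centered data), i.e. the per-channel mean of centered targets
  Yind <- matrix(rnorm(2000), 2, 1000)
  Wn <- dpad:::ols_map(matrix(rnorm(4000), 4, 1000), Yind, rep(1, 1000))
  expect_lt(max(abs(Wn)), 0.15)
})

test_that("corrupting masked-out behavior changes nothing that is learned", {
  dat <- quick_world(seed = 21)
  Tn <- nrow(dat$Y)
  set.seed(99)
  mask <- intermittent_mask(Tn, 0.6)
  spec <- dpad_spec(n_y = 3, n_z = 2, n_x = 3, n_1 = 2)
  cfg <- quick_cfg()
  f1 <- fit_dpad(dat$Y, dat$Z, spec, cfg, mask = mask)
  Zc <- dat$Z
  Zc[!mask, ] <- 1e6  # arbitrary garbage at unobserved samples
  f2 <- fit_dpad(dat$Y, Zc, spec, cfg, mask = mask)
  expect_identical(dpad:::section_params(f1$sec1),
                   dpad:::section_params(f2$sec1))
  p1 <- predict(f1, dat$Y)
  p2 <- predict(f2, dat$Y)
  expect_identical(p1$z_hat, p2$z_hat)
})

test_that("later steps never alter the weights learned in earlier steps", {
  dat <- quick_world(seed = 22)
  cfg <- quick_cfg()
  fit_a <- fit_dpad(dat$Y, dat$Z, dpad_spec(3, 2, n_x = 2, n_1 = 2), cfg)
  fit_b <- fit_dpad(dat$Y, dat$Z, dpad_spec(3, 2, n_x = 5, n_1 = 2), cfg)
  # same seed, same data: step 1 and step 2 results must be identical
  # whether or not steps 3-4 run afterwards
  expect_identical(dpad:::section_params(fit_a$sec1),
                   dpad:::section_params(fit_b$sec1))
  expect_identical(fit_a$Cy1$W, fit_b$Cy1$W)
})

test_that("step-3 objective equals the Gaussian loss on explicit residuals", {
  dat <- quick_world(seed = 23)
  cfg <- quick_cfg()
  fit <- fit_dpad(dat$Y, dat$Z, dpad_spec(3, 2, n_x = 4, n_1 = 2), cfg)
  # reconstruct the aggregate neural loss from the fitted model pieces
  Ys <- dpad:::apply_scaler(dat$Y, fit$scalers$y)
  st <- filter_states(fit, dat$Y)
  yhat1 <- t(dpad:::pm_forward(fit$Cy1, t(st$x1))$out)
  yhat2 <- t(dpad:::pm_forward(fit$sec2$read, t(st$x2))$out)
  resid <- Ys - yhat1
  expect_equal(loss_gaussian(resid, yhat2),
               loss_gaussian(Ys, yhat1 + yhat2), tolerance = 1e-10)
})

test_that("the NDM path (n_1 = 0) decodes behavior through step 4", {
  # high-SNR handcrafted world: rotational 2-state dynamics observed in
  # four neural channels; behavior reads the states almost noiselessly
  th <- 0.5
  gt <- structure(list(
    A = 0.92 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
    Cy = matrix(c(1, 0, 0.5, 1, 0, 1, -0.6, 0.4), 4, 2),
    Cz = diag(2), Q = diag(0.3, 2), R = diag(0.05, 4),
    noise = list(A = diag(0, 4), Q = diag(1e-8, 4), H = matrix(0, 2, 4)),
    n_x = 2, n_1 = 2, n_y = 4, n_z = 2), class = "linear_ssm")
  set.seed(24)
  dat <- generate_data(gt, 2500)
  fit <- fit_dpad(dat$Y, dat$Z, dpad_spec(4, 2, n_x = 2, n_1 = 0),
                  quick_cfg(max_epochs = 80))
  expect_null(fit$sec1)
  expect_false(is.null(fit$unified_Cz))
  ev <- evaluate_model(fit, dat$Y, dat$Z)
  expect_gt(ev$decoding, 0.4)  # behavior is decodable only via step 4
})

test_that("prioritized fitting approaches the ideal predictor on easy data", {
  set.seed(25)
  mdl <- random_linear_model(n_x = 4, n_1 = 2, n_y = 4, n_z = 3)
  tr <- generate_data(mdl, 4000)
  te <- generate_data(mdl, 2000)
  ip <- predict(ideal_predictor(mdl), te$Y)
  cfg <- fit_config(max_epochs = 120, patience = 5, lr = 0.01,
                    batch_size = 8, seed = 5)
  fit <- fit_dpad(tr$Y, tr$Z, dpad_spec(4, 3, n_x = 4, n_1 = 2), cfg)
  ev <- evaluate_model(fit, te$Y, te$Z)
  expect_gt(ev$decoding, mean_cc(te$Z, ip$z_hat) - 0.1)
  expect_gt(ev$selfpred, mean_cc(te$Y, ip$y_hat) - 0.1)
})

test_that("residual covariances match the textbook sample covariance", {
  dat <- quick_world(seed = 26)
  cfg <- quick_cfg()
  fit <- fit_dpad(dat$Y, dat$Z, dpad_spec(3, 2, n_x = 3, n_1 = 2), cfg)
  pr <- predict(fit, dat$Y)
  expect_equal(fit$Sigma_e, stats::cov(dat$Y - pr$y_hat), tolerance = 1e-12)
  expect_equal(fit$Sigma_eps, stats::cov(dat$Z - pr$z_hat),
               tolerance = 1e-12)
  # symmetric positive semidefinite
  expect_equal(fit$Sigma_e, t(fit$Sigma_e))
  expect_true(all(eigen(fit$Sigma_e, only.values = TRUE)$values > -1e-10))
  # a model predicting its targets perfectly has zero residual covariance
  m <- scalar_model(a = 0, k = 0, cy = 1, cz = 1)
  Y0 <- matrix(0, 50, 1)
  m2 <- suppressWarnings(estimate_noise_covariances(m, Y0, Y0))
  expect_equal(m2$Sigma_e, matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("categorical behavior is fitted and scored end to end", {
  set.seed(27)
  mdl <- random_linear_model(n_x = 2, n_1 = 2, n_y = 4, n_z = 1)
  dat <- generate_data(mdl, 2500)
  lab <- matrix(as.integer(cut(dat$Z[, 1],
                               breaks = quantile(dat$Z, 0:3 / 3),
                               include.lowest = TRUE)), ncol = 1)
  spec <- dpad_spec(n_y = 4, n_z = 1, n_x = 2, n_1 = 2,
                    behavior_mode = "categorical", n_c = 3)
  fit <- fit_dpad(dat$Y, lab, spec, quick_cfg(max_epochs = 40))
  pr <- predict(fit, dat$Y)
  sums <- apply(pr$z_hat, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  auc <- multiclass_auc(lab[, 1], pr$z_hat[, 1, ])
  expect_gt(auc, 0.6)  # well above chance on its own training data
})

test_that("training reports divergence instead of returning garbage", {
  dat <- quick_world(seed = 28, Tn = 400)
  cfg <- quick_cfg(lr = 1e6, max_epochs = 3)  # absurd step size
  expect_error(fit_dpad(dat$Y, dat$Z, dpad_spec(3, 2, 2, 2), cfg),
               "diverged|finite")
})
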