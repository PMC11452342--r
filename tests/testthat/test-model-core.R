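# Model construction, causal filtering, readouts, forecasting and
# serialization.

test_that("section presence follows the latent dimension split", {
  m <- build_model(dpad_spec(n_y = 3, n_z = 2, n_x = 4, n_1 = 4))
  expect_null(m$sec2)
  expect_false(is.null(m$sec1))

  m0 <- build_model(dpad_spec(n_y = 3, n_z = 2, n_x = 4, n_1 = 0))
  expect_null(m0$sec1)
  expect_false(is.null(m0$sec2))

  mb <- build_model(dpad_spec(n_y = 3, n_z = 2, n_x = 6, n_1 = 2))
  expect_equal(mb$sec1$n, 2)
  expect_equal(mb$sec2$n, 4)
  # section 2's input map sees the neural observation and the updated
  # section-1 state
  expect_equal(mb$sec2$d_u, 3 + 2)
})

test_that("state stepping follows the scalar recursion arithmetic", {
  m <- scalar_model(a = 0.5, k = 1, cy = 1, cz = 1)
  s1 <- step_state(m, x1 = 0, x2 = NULL, y = 1)
  expect_equal(s1$x1, 1)               # 0.5*0 + 1*1
  s2 <- step_state(m, x1 = s1$x1, x2 = NULL, y = 1)
  expect_equal(s2$x1, 1.5)             # 0.5*1 + 1*1
  expect_error(step_state(m, 0, NULL, NaN), "finite")
})

test_that("identity recursion with zero input holds the state constant", {
  m <- scalar_model(a = 1, k = 0, cy = 1, cz = 1)
  x <- 0.7
  for (y in rnorm(5)) x <- step_state(m, x, NULL, y)$x1
  expect_equal(x, 0.7)
})

test_that("filtering is causal and starts from the zero fixed point", {
  set.seed(4)
  m <- matrix_model(A = matrix(c(0.5, 0, 0.2, 0.3), 2, 2),
                    K = matrix(rnorm(6), 2, 3),
                    Cy = matrix(rnorm(6), 3, 2),
                    Cz = matrix(rnorm(2), 1, 2))
  expect_true(all(filter_states(m, matrix(0, 20, 3))$x1 == 0))

  Y <- matrix(rnorm(60), 20, 3)
  st <- filter_states(m, Y)
  Y2 <- Y
  Y2[11:20, ] <- Y2[sample(11:20), ] + rnorm(30)  # permute + corrupt future
  st2 <- filter_states(m, Y2)
  expect_identical(st$x1[1:11, ], st2$x1[1:11, ])  # x_k uses y_1..y_{k-1}
  expect_false(isTRUE(all.equal(st$x1[13:20, ], st2$x1[13:20, ])))
})

test_that("linear filtering equals an independent dense matrix recursion", {
  set.seed(5)
  A <- matrix(rnorm(4, sd = 0.3), 2, 2)
  K <- matrix(rnorm(6), 2, 3)
  Cy <- matrix(rnorm(6), 3, 2)
  Cz <- matrix(rnorm(4), 2, 2)
  m <- matrix_model(A, K, Cy, Cz)
  Y <- matrix(rnorm(90), 30, 3)
  st <- filter_states(m, Y)
  # oracle: direct matrix recursion x_{k+1} = A x_k + K y_k
  x <- c(0, 0)
  Xo <- matrix(0, 30, 2)
  for (k in 1:30) {
    Xo[k, ] <- x
    x <- drop(A %*% x + K %*% Y[k, ])
  }
  expect_equal(st$x1, Xo, tolerance = 1e-12)
  pr <- predict(m, Y)
  expect_equal(pr$y_hat, Xo %*% t(Cy), tolerance = 1e-12)
  expect_equal(pr$z_hat, Xo %*% t(Cz), tolerance = 1e-12)
})

test_that("section-1 states ignore section-2 weights entirely", {
  set.seed(6)
  spec <- dpad_spec(n_y = 2, n_z = 1, n_x = 5, n_1 = 2)
  m <- build_model(spec)
  Y <- matrix(rnorm(40), 20, 2)
  x1_before <- filter_states(m, Y)$x1
  p2 <- lapply(dpad:::section_params(m$sec2), function(p) p + rnorm(length(p)))
  m$sec2 <- dpad:::section_set_params(m$sec2, p2)
  expect_identical(filter_states(m, Y)$x1, x1_before)
})

test_that("categorical readout produces normalized probabilities", {
  spec <- dpad_spec(n_y = 2, n_z = 2, n_x = 3, n_1 = 3,
                    behavior_mode = "categorical", n_c = 4)
  m <- build_model(spec)
  # zero logits: all classes 1/4
  m$sec1$read$W <- matrix(0, 8, 3)
  st <- list(x1 = matrix(rnorm(15), 5, 3))
  pr <- predict_from_states(m, st)
  expect_equal(as.vector(pr$z_hat), rep(0.25, 40))

  set.seed(7)
  m$sec1$read$W <- matrix(rnorm(24), 8, 3)
  pr <- predict_from_states(m, st)
  sums <- apply(pr$z_hat, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # elementwise oracle: exp / normalize of the raw logits
  logits <- st$x1 %*% t(m$sec1$read$W)
  p11 <- exp(logits[1, 1:4]) / sum(exp(logits[1, 1:4]))
  expect_equal(pr$z_hat[1, 1, ], unname(p11), tolerance = 1e-12)
})

test_that("softmax matches its defining formula on random logits", {
  set.seed(8)
  l <- matrix(rnorm(12), 3, 4)
  p <- softmax(l)
  expect_equal(p, apply(l, 2, function(c_) exp(c_) / sum(exp(c_))),
               tolerance = 1e-12)
  expect_equal(colSums(p), rep(1, 4))
})

test_that("forecasting at horizon 1 reproduces one-step prediction", {
  set.seed(9)
  m <- scalar_model(a = 0.6, k = 0.5, cy = 1.2, cz = 0.8)
  Y <- matrix(rnorm(25), 25, 1)
  expect_equal(forecast(m, Y, 1)$z_hat, predict(m, Y)$z_hat)
})

test_that("multistep forecasts follow the closed-form feedback recursion", {
  a <- 0.6; k <- 0.5; cy <- 1.2; cz <- 0.8
  m <- scalar_model(a, k, cy, cz)
  set.seed(10)
  Y <- matrix(rnorm(30), 30, 1)
  # closed form: feeding y_hat = cy*x back gives x' = (a + k*cy) x
  x <- 0; xs <- numeric(30)
  for (t in 1:30) { xs[t] <- x; x <- a * x + k * Y[t, 1] }
  for (m_h in 2:3) {
    fc <- forecast(m, Y, m_h)
    expect_true(all(is.na(fc$y_hat[1:(m_h - 1), ])))
    pred_oracle <- cy * (a + k * cy)^(m_h - 1) * xs
    expect_equal(fc$y_hat[m_h:30, 1], pred_oracle[1:(30 - m_h + 1)],
                 tolerance = 1e-12)
  }
})

test_that("with zero input gain forecasts evolve autonomously", {
  m <- scalar_model(a = 0.9, k = 0, cy = 1, cz = 1)
  Y <- matrix(rnorm(10), 10, 1)
  for (m_h in 1:3) {
    fc <- forecast(m, Y, m_h)
    expect_true(all(fc$y_hat[!is.na(fc$y_hat)] == 0))  # x stays at 0
  }
})

test_that("serialization round-trips predictions bit-exactly", {
  dat <- quick_world()
  spec <- dpad_spec(n_y = 3, n_z = 2, n_x = 4, n_1 = 2)
  fit <- fit_dpad(dat$Y, dat$Z, spec, quick_cfg())
  path <- tempfile(fileext = ".rds")
  save_dpad(fit, path)
  fit2 <- load_dpad(path)
  p1 <- predict(fit, dat$Y)
  p2 <- predict(fit2, dat$Y)
  expect_identical(p1$y_hat, p2$y_hat)
  expect_identical(p1$z_hat, p2$z_hat)
  expect_identical(fit$Sigma_e, fit2$Sigma_e)
})
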