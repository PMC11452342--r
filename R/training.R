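# Four-step prioritized optimization.
#
# Step 1 trains section 1 (A'(1), K(1), C_z(1)) end to end to predict
# behavior from filtered states: the behaviorally relevant dynamics are
# learned first, with priority, uncontaminated by the neural objective.
# Step 2 regresses neural activity on the (now frozen) section-1 states to
# learn C_y(1). Step 3 trains section 2 (A'(2), K(2), C_y(2)) on the yet
# unpredicted part of the neural activity. Step 4 (used when n_1 = 0, or on
# request) learns a unified behavior readout from both state blocks.
# Steps never revisit earlier steps' weights.

#' Fit configuration
#'
#' @param max_epochs maximum training epochs per optimization step
#' @param patience epochs without strict improvement of the training
#'   objective before stopping
#' @param lr Adam step size
#' @param batch_size minibatch size, in sequences, for recursion training
#' @param static_batch minibatch size, in samples, for static readout fits
#' @param seq_length truncated-backpropagation sequence length; continuous
#'   recordings are cut into sequences of this length with the state reset
#'   to zero at sequence starts
#' @param lr_drops number of times the step size is reduced (by
#'   `lr_drop_factor`, restarting from the best weights) when the
#'   objective plateaus, before training stops; 0 reproduces plain early
#'   stopping
#' @param lr_drop_factor multiplicative step-size reduction on plateau
#' @param seed master seed: weight initialization and batch shuffling all
#'   derive from it, making fits bit-reproducible on one machine
#' @param scale_inputs z-score neural and continuous behavior series with
#'   training statistics (inverted at prediction time)
#' @param l2 optional ridge penalty weight on network weights (config hook;
#'   0, the default, everywhere in this package's analyses)
#' @return list of class `dpad_fit_config`
#' @export
fit_config <- function(max_epochs = 2500, patience = 3, lr = 0.01,
                       batch_size = 8, static_batch = 512,
                       seq_length = 128, lr_drops = 0,
                       lr_drop_factor = 0.3, seed = 1,
                       scale_inputs = TRUE, l2 = 0) {
  stopifnot(max_epochs >= 1, patience >= 1, lr > 0, seq_length >= 2,
            lr_drops >= 0, lr_drop_factor > 0, lr_drop_factor < 1)
  structure(list(max_epochs = max_epochs, patience = patience, lr = lr,
                 batch_size = batch_size, static_batch = static_batch,
                 seq_length = seq_length, lr_drops = lr_drops,
                 lr_drop_factor = lr_drop_factor, seed = seed,
                 scale_inputs = scale_inputs, l2 = l2),
            class = "dpad_fit_config")
}

#' Cut a continuous multivariate series into equal-length sequences
#'
#' @return list(arr = (d x B x L) array, w = (B x L) 0/1 validity weights)
#' @keywords internal
chunk_series <- function(X, L, w = NULL) {
  X <- as.matrix(X)
  Tn <- nrow(X); d <- ncol(X)
  B <- ceiling(Tn / L)
  pad <- B * L - Tn
  Xp <- rbind(X, matrix(0, pad, d))
  wv <- if (is.null(w)) rep(1, Tn) else as.numeric(w)
  wp <- c(wv, rep(0, pad))
  # sequence-major layout: arr[, b, l] = sample (b-1)*L + l
  arr <- array(0, c(d, B, L))
  wm <- matrix(0, B, L)
  for (b in seq_len(B)) {
    idx <- ((b - 1) * L + 1):(b * L)
    arr[, b, ] <- t(Xp[idx, , drop = FALSE])
    wm[b, ] <- wp[idx]
  }
  list(arr = arr, w = wm)
}

#' Fit the two-section model with the prioritized multistep optimization
#'
#' Runs steps 1-2 when n_1 > 0 and steps 3-4 when n_1 < n_x. When both
#' sections are present (0 < n_1 < n_x) the unified behavior readout of
#' step 4 is skipped by default and behavior is predicted from the
#' section-1 states alone; when n_1 = 0 the model reduces to unsupervised
#' neural dynamical modeling (NDM) and step 4 provides the behavior
#' readout. Finishes by estimating the residual noise covariances.
#'
#' @param Y (T x n_y) neural series
#' @param Z (T x n_z) behavior series (continuous), or integer class labels
#'   in 1..n_c (categorical)
#' @param spec a [dpad_spec()]
#' @param cfg a [fit_config()]
#' @param mask optional logical length-T vector, TRUE where behavior was
#'   observed (intermittent sampling); the behavior loss is computed only
#'   at observed samples
#' @param force_step4 learn the unified behavior readout even when
#'   0 < n_1 < n_x
#' @param unified_Cy also learn a unified neural readout from both state
#'   blocks (optional final refinement)
#' @return a fitted `dpad_model`
#' @export
fit_dpad <- function(Y, Z, spec, cfg = fit_config(), mask = NULL,
                     force_step4 = FALSE, unified_Cy = FALSE) {
  stopifnot(inherits(spec, "dpad_spec"))
  Y <- as.matrix(Y)
  Z <- as.matrix(Z)
  Tn <- nrow(Y)
  stopifnot(nrow(Z) == Tn, ncol(Y) == spec$n_y, ncol(Z) == spec$n_z)
  if (is.null(mask)) mask <- rep(TRUE, Tn)
  if (!any(mask)) stop("empty objective: mask excludes all behavior samples")
  categorical <- spec$behavior_mode == "categorical"
  if (categorical) {
    if (any(Z[mask, ] < 1 | Z[mask, ] > spec$n_c)) {
      stop("categorical labels must be integers in 1..n_c")
    }
    storage.mode(Z) <- "integer"
  }
  set.seed(cfg$seed)

  model <- build_model(spec)
  # scaling statistics from training data only (observed behavior samples)
  if (cfg$scale_inputs) {
    model$scalers <- list(
      y = make_scaler(Y),
      z = if (!categorical) make_scaler(Z, rows = mask) else NULL
    )
  }
  Ys <- apply_scaler(Y, model$scalers$y)
  Zs <- if (categorical) Z else apply_scaler(Z, model$scalers$z)
  # corrupted/unobserved behavior values must never touch the objective
  if (!categorical) Zs[!mask, ] <- 0 else Zs[!mask, ] <- 1L
  loss_z <- if (categorical) "categorical" else "gaussian"

  L <- min(cfg$seq_length, Tn)
  ych <- chunk_series(Ys, L)
  zch <- chunk_series(Zs, L, w = as.numeric(mask))
  if (categorical) {
    zch$arr <- array(as.integer(zch$arr), dim(zch$arr))
    # padding positions carry weight 0 but must still be valid class
    # indices for the loss bookkeeping
    zch$arr[zch$arr < 1L] <- 1L
  }

  x1 <- NULL
  if (spec$n_1 > 0) {
    # -- step 1: behaviorally relevant recursion + behavior readout --------
    # each step draws from its own seed stream so that the presence or
    # length of later steps can never perturb earlier ones
    set.seed(cfg$seed + 1L)
    st1 <- train_rnn_section(model$sec1, ych$arr, zch$arr, zch$w,
                             loss_z, cfg, n_c = spec$n_c)
    model$sec1 <- st1$sec
    model$log$step1 <- st1$history
    # states from continuous filtering of the full series
    x1 <- filter_states(model, Y)$x1

    # -- step 2: neural readout from frozen section-1 states ---------------
    set.seed(cfg$seed + 2L)
    if (model$Cy1$form == "linear") {
      model$Cy1$W <- ols_map(t(x1), t(Ys), rep(1, Tn))
    } else {
      model$Cy1 <- train_static_map(model$Cy1, t(x1), t(Ys), rep(1, Tn),
                                    "gaussian", cfg)
    }
  }

  x2 <- NULL
  if (spec$n_2 > 0) {
    # -- step 3: remaining neural dynamics on the neural residual ----------
    resid <- Ys
    if (!is.null(x1)) {
      resid <- Ys - t(pm_forward(model$Cy1, t(x1))$out)
    }
    if (!is.null(x1)) {
      # x_{k+1}^(1) for k = 1..T-1 is x1[k+1]; for k = T it takes one more
      # state update from x1[T] and y_T
      x1next <- rbind(x1[-1, , drop = FALSE], x1[Tn, , drop = FALSE] * 0)
      lastY <- apply_scaler(Y[Tn, , drop = FALSE], model$scalers$y)
      s1 <- sec_step(model$sec1, matrix(x1[Tn, ], , 1), t(lastY))
      x1next[Tn, ] <- drop(s1$x)
      U2 <- cbind(Ys, x1next)
    } else {
      U2 <- Ys
    }
    u2ch <- chunk_series(U2, L)
    rch <- chunk_series(resid, L)
    set.seed(cfg$seed + 3L)
    st3 <- train_rnn_section(model$sec2, u2ch$arr, rch$arr, rch$w,
                             "gaussian", cfg)
    model$sec2 <- st3$sec
    model$log$step3 <- st3$history
    x2 <- filter_states(model, Y)$x2
  }

  # -- step 4: unified behavior readout (NDM path or on request) -----------
  if (spec$n_2 > 0 && (spec$n_1 == 0 || force_step4)) {
    set.seed(cfg$seed + 4L)
    xall <- t(cbind(x1, x2))
    d_z <- if (categorical) spec$n_z * spec$n_c else spec$n_z
    fmCz <- form_to_pm(spec$forms$Cz)
    if (fmCz == "linear" && !categorical) {
      cz <- pm_linear(spec$n_x, d_z)
      cz$W <- ols_map(xall, t(Zs), as.numeric(mask))
      model$unified_Cz <- cz
    } else {
      cz <- if (fmCz == "linear") pm_linear(spec$n_x, d_z)
            else pm_mlp(spec$n_x, d_z, spec$hidden)
      model$unified_Cz <- train_static_map(cz, xall, t(Zs),
                                           as.numeric(mask), loss_z, cfg,
                                           n_c = spec$n_c)
    }
  }
  if (unified_Cy && spec$n_1 > 0 && spec$n_2 > 0) {
    xall <- t(cbind(x1, x2))
    fmCy <- form_to_pm(spec$forms$Cy)
    if (fmCy == "linear") {
      cy <- pm_linear(spec$n_x, spec$n_y)
      cy$W <- ols_map(xall, t(Ys), rep(1, Tn))
      model$unified_Cy <- cy
    } else {
      cy <- pm_mlp(spec$n_x, spec$n_y, spec$hidden)
      model$unified_Cy <- train_static_map(cy, xall, t(Ys), rep(1, Tn),
                                           "gaussian", cfg)
    }
  }

  model <- estimate_noise_covariances(model, Y, Z, mask)
  model
}

#' Estimate residual noise covariances
#'
#' Sample covariances of the one-step-ahead neural and behavior residuals
#' on the training data (original units); symmetric positive semidefinite
#' by construction. For categorical behavior only the neural covariance is
#' estimated.
#'
#' @param model fitted `dpad_model`
#' @param Y,Z training series
#' @param mask behavior observation mask
#' @return the model with `Sigma_e` and `Sigma_eps` filled in
#' @export
estimate_noise_covariances <- function(model, Y, Z, mask = NULL) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (is.null(mask)) mask <- rep(TRUE, nrow(Y))
  pr <- predict(model, Y)
  e <- Y - pr$y_hat
  if (nrow(e) <= ncol(e)) {
    warning("fewer samples than neural dimensions: covariance rank deficient")
  }
  model$Sigma_e <- stats::cov(e)
  if (model$spec$behavior_mode == "continuous") {
    eps <- (Z - pr$z_hat)[mask, , drop = FALSE]
    if (nrow(eps) <= ncol(eps)) {
      warning("fewer samples than behavior dimensions: covariance rank deficient")
    }
    model$Sigma_eps <- stats::cov(eps)
  }
  model
}
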