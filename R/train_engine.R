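# Gradient training loops: minibatch Adam over sequence batches with
# strict early stopping on the full training-set objective.

#' Loss head: evaluate readout on states, return loss, readout grads and
#' the gradient flowing back into the states.
#'
#' @param pm readout map
#' @param Xmat (n x N) states
#' @param target (d x N) matrix (gaussian) or (n_z x N) integer labels
#' @param w length-N 0/1 sample weights (observation mask and padding)
#' @param loss_type "gaussian" or "categorical"
#' @param n_c class count (categorical)
#' @keywords internal
readout_loss_grad <- function(pm, Xmat, target, w, loss_type, n_c = NULL,
                              grad = TRUE) {
  fw <- pm_forward(pm, Xmat)
  out <- fw$out
  nv <- sum(w)
  if (nv == 0) stop("empty objective: no observed samples in batch")
  if (loss_type == "gaussian") {
    resid <- out - target
    if (any(w == 0)) resid[, w == 0] <- 0
    loss <- sum(resid * resid) / nv
    if (!grad) return(list(loss = loss))
    dOut <- 2 * resid / nv
  } else {
    n_z <- nrow(target)
    N <- ncol(Xmat)
    loss <- 0
    dOut <- matrix(0, nrow(out), N)
    nvz <- nv * n_z
    for (m in seq_len(n_z)) {
      rows <- ((m - 1L) * n_c + 1L):(m * n_c)
      P <- softmax(out[rows, , drop = FALSE])
      idx <- cbind(target[m, ], seq_len(N))
      lp <- log(pmax(P[idx], 1e-7)) * w
      loss <- loss - sum(lp) / nvz
      if (grad) {
        G <- P
        G[idx] <- G[idx] - 1
        G <- sweep(G, 2, w, "*") / nvz
        dOut[rows, ] <- G
      }
    }
    if (!grad) return(list(loss = loss))
  }
  bk <- pm_backward(pm, fw$cache, dOut)
  gR <- bk$grads
  names(gR) <- paste0("read.", names(gR))
  list(loss = loss, grads = gR, dX = bk$dU)
}

#' Objective of a section on the full (batched) training data
#' @keywords internal
section_objective <- function(sec, U_arr, target, w_mat, loss_type, n_c) {
  fwd <- section_rnn_forward(sec, U_arr)
  n <- sec$n; B <- fwd$B; L <- fwd$L
  Xmat <- matrix(fwd$X, n, B * L)
  tg <- if (loss_type == "gaussian") matrix(target, , B * L)
        else matrix(target, , B * L)
  readout_loss_grad(sec$read, Xmat, tg, as.vector(w_mat), loss_type, n_c,
                    grad = FALSE)$loss
}

#' Train one RNN section end to end with truncated BPTT
#'
#' Minimizes the mean masked readout loss by Adam over minibatches of
#' sequences. Early stopping: the full training objective is evaluated
#' after every epoch; training stops once it has failed to improve
#' strictly for `patience` consecutive epochs, and the best-scoring
#' weights are restored.
#'
#' @param sec section created by [make_section()] (with a `read` map)
#' @param U_arr (d_u x B x L) inputs
#' @param target (d x B x L) array or (n_z x B x L) integer labels
#' @param w_mat (B x L) 0/1 weights (mask and padding)
#' @param loss_type "gaussian" or "categorical"
#' @param cfg fit configuration list (lr, max_epochs, patience, batch_size)
#' @return list(sec, history, objective)
#' @keywords internal
train_rnn_section <- function(sec, U_arr, target, w_mat, loss_type, cfg,
                              n_c = NULL) {
  B <- dim(U_arr)[2]; L <- dim(U_arr)[3]; n <- sec$n
  params <- section_params(sec)
  opt <- adam_init(params)
  batch_size <- min(cfg$batch_size, B)
  best <- list(loss = Inf, params = params)
  bad <- 0L
  lr_now <- cfg$lr
  drops_left <- if (is.null(cfg$lr_drops)) 0L else cfg$lr_drops
  history <- numeric(0)
  td <- dim(target)[1]

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(B)
    starts <- seq(1L, B, by = batch_size)
    for (s in starts) {
      ids <- ord[s:min(s + batch_size - 1L, B)]
      Ub <- U_arr[, ids, , drop = FALSE]
      tb <- target[, ids, , drop = FALSE]
      wb <- w_mat[ids, , drop = FALSE]
      if (sum(wb) == 0) next
      fwd <- section_rnn_forward(sec, Ub)
      Nb <- length(ids) * L
      head <- readout_loss_grad(sec$read, matrix(fwd$X, n, Nb),
                                matrix(tb, td, Nb), as.vector(wb),
                                loss_type, n_c)
      if (!is.finite(head$loss)) {
        stop("training diverged: non-finite objective (epoch ", epoch, ")")
      }
      dX_ext <- array(head$dX, c(n, length(ids), L))
      grads <- c(section_rnn_backward(sec, fwd, dX_ext), head$grads)
      if (!is.null(cfg$l2) && cfg$l2 > 0) {
        for (nm in names(params)) {
          grads[[nm]] <- grads[[nm]] + 2 * cfg$l2 * params[[nm]]
        }
      }
      upd <- adam_update(params, grads[names(params)], opt, lr = lr_now)
      params <- upd$params
      opt <- upd$state
      sec <- section_set_params(sec, params)
    }
    obj <- section_objective(sec, U_arr, target, w_mat, loss_type, n_c)
    if (!is.finite(obj)) stop("training diverged: non-finite objective")
    history <- c(history, obj)
    if (obj < best$loss) {
      best <- list(loss = obj, params = params)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) {
        if (drops_left > 0L) {
          # plateau: restart from the best weights with a smaller step
          drops_left <- drops_left - 1L
          lr_now <- lr_now * cfg$lr_drop_factor
          params <- best$params
          sec <- section_set_params(sec, params)
          opt <- adam_init(params)
          bad <- 0L
        } else {
          break
        }
      }
    }
  }
  sec <- section_set_params(sec, best$params)
  list(sec = sec, history = history, objective = best$loss)
}

#' Train a static (state-to-observation) map by minibatch Adam
#' @keywords internal
train_static_map <- function(pm, Umat, target, w, loss_type, cfg,
                             n_c = NULL) {
  N <- ncol(Umat)
  params <- pm_params(pm)
  opt <- adam_init(params)
  bs <- min(cfg$static_batch, N)
  best <- list(loss = Inf, params = params)
  bad <- 0L
  lr_now <- cfg$lr
  drops_left <- if (is.null(cfg$lr_drops)) 0L else cfg$lr_drops
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(N)
    for (s in seq(1L, N, by = bs)) {
      ids <- ord[s:min(s + bs - 1L, N)]
      if (sum(w[ids]) == 0) next
      head <- readout_loss_grad(pm, Umat[, ids, drop = FALSE],
                                target[, ids, drop = FALSE], w[ids],
                                loss_type, n_c)
      gR <- head$grads
      names(gR) <- substring(names(gR), 6L)  # strip "read."
      upd <- adam_update(params, gR[names(params)], opt, lr = lr_now)
      params <- upd$params
      opt <- upd$state
      pm <- pm_set_params(pm, params)
    }
    obj <- readout_loss_grad(pm, Umat, target, w, loss_type, n_c,
                             grad = FALSE)$loss
    if (!is.finite(obj)) stop("training diverged: non-finite objective")
    if (obj < best$loss) {
      best <- list(loss = obj, params = params)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) {
        if (drops_left > 0L) {
          drops_left <- drops_left - 1L
          lr_now <- lr_now * cfg$lr_drop_factor
          params <- best$params
          pm <- pm_set_params(pm, params)
          opt <- adam_init(params)
          bad <- 0L
        } else {
          break
        }
      }
    }
  }
  pm_set_params(pm, best$params)
}

#' Weighted ordinary least squares for a linear map (no bias)
#'
#' Exact minimizer of the masked Gaussian loss for a linear readout.
#' @keywords internal
ols_map <- function(Umat, target, w) {
  keep <- w > 0
  U <- Umat[, keep, drop = FALSE]
  Y <- target[, keep, drop = FALSE]
  G <- tcrossprod(U)
  # tiny ridge guards rank deficiency without visibly biasing the fit
  diag(G) <- diag(G) + 1e-10 * max(diag(G), 1)
  W <- Y %*% t(U) %*% solve(G)
  W
}
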