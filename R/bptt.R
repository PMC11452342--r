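# Backpropagation-through-time engine for one RNN section.
#
# A "section" bundles the recursion map A', the neural-input map K (or the
# joint map A'' when both recursion and input are nonlinear), and the
# readout trained alongside the recursion (the behavior readout in the
# prioritized step, the neural readout in the residual step).
#
# Batched layout: sequences of equal length L are stacked so inputs are
# (d_u x B x L) arrays; every time step is a single matrix product across
# the batch. The recursion loop is the only per-step R-level iteration;
# input and readout maps are evaluated vectorized over all B*L samples.
# Timing convention: x_1 = x_0 (default 0); predictions at step l use x_l;
# x_{l+1} = A'(x_l) + K(u_l), so x_l depends on inputs u_1..u_{l-1} only.

#' @keywords internal
make_section <- function(n, d_u, forms, hidden = NULL, d_read = NULL,
                         read_form = "linear") {
  # forms: list(A = "linear"/"mlp"/"lstm", K = "linear"/"mlp")
  joint <- identical(forms$A, "mlp") && identical(forms$K, "mlp")
  sec <- list(n = n, d_u = d_u, joint = joint,
              lstm = identical(forms$A, "lstm"))
  if (joint) {
    sec$AK <- pm_mlp(n + d_u, n, hidden)
    # keep the initial recursion near-contractive: shrink the output layer
    nl <- length(sec$AK$W)
    sec$AK$W[[nl]] <- sec$AK$W[[nl]] * 0.1
  } else {
    sec$A <- switch(forms$A,
      linear = pm_linear(n, n),
      mlp = pm_mlp(n, n, hidden),
      lstm = pm_lstm(n, n)
    )
    if (forms$A == "linear") {
      # rescale to spectral radius 0.5 so the initial filter is stable
      sr <- max(Mod(eigen(sec$A$W, only.values = TRUE)$values))
      if (sr > 0) sec$A$W <- sec$A$W * (0.5 / sr)
    } else if (forms$A == "mlp") {
      nl <- length(sec$A$W)
      sec$A$W[[nl]] <- sec$A$W[[nl]] * 0.1
    }
    sec$K <- switch(forms$K,
      linear = pm_linear(d_u, n),
      mlp = pm_mlp(d_u, n, hidden)
    )
  }
  if (!is.null(d_read)) {
    sec$read <- switch(read_form,
      linear = pm_linear(n, d_read),
      mlp = pm_mlp(n, d_read, hidden)
    )
  }
  sec
}

#' Flatten section weights into one named list (prefix.name)
#' @keywords internal
section_params <- function(sec, include_read = TRUE) {
  out <- list()
  for (piece in c("A", "K", "AK", if (include_read) "read")) {
    if (!is.null(sec[[piece]])) {
      p <- pm_params(sec[[piece]])
      names(p) <- paste0(piece, ".", names(p))
      out <- c(out, p)
    }
  }
  out
}

#' @keywords internal
section_set_params <- function(sec, params) {
  for (piece in c("A", "K", "AK", "read")) {
    if (!is.null(sec[[piece]])) {
      pref <- paste0(piece, ".")
      sel <- startsWith(names(params), pref)
      if (!any(sel)) next
      p <- params[sel]
      names(p) <- substring(names(p), nchar(pref) + 1L)
      sec[[piece]] <- pm_set_params(sec[[piece]], p)
    }
  }
  sec
}

#' Run the section recursion over a batch of sequences
#'
#' @param sec section
#' @param U_arr (d_u x B x L) input array
#' @param x0 (n x B) initial state (default zeros)
#' @return list with X (n x B x L) filtered states (X[,,l] = x_l), caches
#'   needed for the backward pass, and x_last (n x B) = x_{L+1}
#' @keywords internal
section_rnn_forward <- function(sec, U_arr, x0 = NULL) {
  d_u <- dim(U_arr)[1]; B <- dim(U_arr)[2]; L <- dim(U_arr)[3]
  n <- sec$n
  x <- if (is.null(x0)) matrix(0, n, B) else x0
  X <- array(0, c(n, B, L))
  fwd <- list(B = B, L = L)

  if (!sec$joint) {
    # input map is state-independent: evaluate once over all samples
    Umat <- matrix(U_arr, d_u, B * L)
    kf <- pm_forward(sec$K, Umat)
    fwd$kcache <- kf$cache
    Kout <- array(kf$out, c(n, B, L))
  }

  if (sec$lstm) {
    c_ <- matrix(0, n, B)
    caches <- vector("list", L)
    for (l in seq_len(L)) {
      X[, , l] <- x
      st <- lstm_step(sec$A, x, c_, matrix(Kout[, , l], n, B))
      caches[[l]] <- st$cache
      x <- st$h; c_ <- st$c
    }
    fwd$lstm_caches <- caches
  } else if (sec$joint) {
    nl <- length(sec$AK$W)
    dims <- c(n + d_u, sec$AK$hidden, n)
    acts <- lapply(dims, function(d) array(0, c(d, B, L)))
    for (l in seq_len(L)) {
      X[, , l] <- x
      a <- rbind(x, matrix(U_arr[, , l], d_u, B))
      acts[[1L]][, , l] <- a
      for (i in seq_len(nl)) {
        z <- sec$AK$W[[i]] %*% a + sec$AK$b[[i]]
        if (i < nl) z[z < 0] <- 0
        acts[[i + 1L]][, , l] <- z
        a <- z
      }
      x <- a
    }
    fwd$acts <- acts
  } else if (sec$A$form == "linear") {
    W <- sec$A$W
    for (l in seq_len(L)) {
      X[, , l] <- x
      x <- W %*% x + matrix(Kout[, , l], n, B)
      if (!is.null(sec$A$b)) x <- x + sec$A$b
    }
  } else {  # mlp recursion, additive input
    nl <- length(sec$A$W)
    dims <- c(n, sec$A$hidden, n)
    acts <- lapply(dims, function(d) array(0, c(d, B, L)))
    for (l in seq_len(L)) {
      X[, , l] <- x
      a <- x
      acts[[1L]][, , l] <- a
      for (i in seq_len(nl)) {
        z <- sec$A$W[[i]] %*% a + sec$A$b[[i]]
        if (i < nl) z[z < 0] <- 0
        acts[[i + 1L]][, , l] <- z
        a <- z
      }
      x <- a + matrix(Kout[, , l], n, B)
    }
    fwd$acts <- acts
  }
  fwd$X <- X
  fwd$x_last <- x
  fwd
}

#' Backward pass through the section recursion
#'
#' @param dX_ext (n x B x L) gradient of the loss with respect to each
#'   filtered state from everything outside the recursion (the readout).
#' @return list(grads = named flat list over A/K or AK weights)
#' @keywords internal
section_rnn_backward <- function(sec, fwd, dX_ext) {
  B <- fwd$B; L <- fwd$L; n <- sec$n
  dx <- matrix(0, n, B)          # dL/d x_{l+1}
  Dnext <- array(0, c(n, B, L))  # upstream gradient at the input-map output
  grads <- list()

  if (sec$lstm) {
    dc <- matrix(0, n, B)
    gA <- NULL
    for (l in L:1) {
      bk <- lstm_step_backward(sec$A, fwd$lstm_caches[[l]], dx, dc)
      gA <- add_grads(gA, bk$grads)
      Dnext[, , l] <- bk$dU
      dx <- bk$dh_prev + matrix(dX_ext[, , l], n, B)
      dc <- bk$dc_prev
    }
    names(gA) <- paste0("A.", names(gA))
    grads <- c(grads, gA)
  } else if (sec$joint) {
    nl <- length(sec$AK$W)
    acts <- fwd$acts
    deltas <- lapply(sec$AK$W, function(W) array(0, c(nrow(W), B, dim(fwd$X)[3])))
    for (l in L:1) {
      d <- dx
      for (i in nl:1) {
        if (i < nl) d <- d * (matrix(acts[[i + 1L]][, , l], , B) > 0)
        deltas[[i]][, , l] <- d
        d <- crossprod(sec$AK$W[[i]], d)
      }
      dx <- d[seq_len(n), , drop = FALSE] + matrix(dX_ext[, , l], n, B)
    }
    for (i in seq_len(nl)) {
      dm <- matrix(deltas[[i]], , B * L)
      am <- matrix(acts[[i]], , B * L)
      grads[[paste0("AK.W", i)]] <- dm %*% t(am)
      grads[[paste0("AK.b", i)]] <- rowSums(dm)
    }
  } else if (sec$A$form == "linear") {
    W <- sec$A$W
    for (l in L:1) {
      Dnext[, , l] <- dx
      dx <- crossprod(W, dx) + matrix(dX_ext[, , l], n, B)
    }
    Dm <- matrix(Dnext, n, B * L)
    grads[["A.W"]] <- Dm %*% t(matrix(fwd$X, n, B * L))
    if (!is.null(sec$A$b)) grads[["A.b"]] <- rowSums(Dm)
  } else {  # mlp recursion
    nl <- length(sec$A$W)
    acts <- fwd$acts
    deltas <- lapply(sec$A$W, function(W) array(0, c(nrow(W), B, L)))
    for (l in L:1) {
      Dnext[, , l] <- dx
      d <- dx
      for (i in nl:1) {
        if (i < nl) d <- d * (matrix(acts[[i + 1L]][, , l], , B) > 0)
        deltas[[i]][, , l] <- d
        d <- crossprod(sec$A$W[[i]], d)
      }
      dx <- d + matrix(dX_ext[, , l], n, B)
    }
    for (i in seq_len(nl)) {
      dm <- matrix(deltas[[i]], , B * L)
      am <- matrix(acts[[i]], , B * L)
      grads[[paste0("A.W", i)]] <- dm %*% t(am)
      grads[[paste0("A.b", i)]] <- rowSums(dm)
    }
  }

  if (!sec$joint) {
    kb <- pm_backward(sec$K, fwd$kcache, matrix(Dnext, n, B * L))
    gK <- kb$grads
    names(gK) <- paste0("K.", names(gK))
    grads <- c(grads, gK)
  }
  grads
}
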