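# Parameter maps: the building blocks of the two-section RNN.
#
# Every model parameter (recursion A', neural input K, neural readout C_y,
# behavior readout C_z) is a trainable map that can be a plain matrix
# multiplication, a multilayer feed-forward network with ReLU hidden layers,
# or (recursion only) an LSTM cell.  All maps operate on column-major
# batches: inputs are (d_in x N) matrices, outputs (d_out x N).
#
# Each map carries its weights as plain numeric arrays so that the Adam
# optimizer and the backpropagation-through-time engine can treat them
# uniformly (a flat list of arrays plus matching gradient arrays).

#' @keywords internal
glorot_mat <- function(d_out, d_in) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_out * d_in, -lim, lim), d_out, d_in)
}

#' Create a linear parameter map
#'
#' A linear map is exactly a matrix multiplication; by convention it carries
#' no bias unless requested (matching the linear state-space convention where
#' signals are centered before fitting).
#'
#' @param d_in,d_out input/output dimension
#' @param bias include an additive bias term
#' @keywords internal
pm_linear <- function(d_in, d_out, bias = FALSE) {
  pm <- list(
    form = "linear", d_in = d_in, d_out = d_out,
    W = glorot_mat(d_out, d_in),
    b = if (bias) numeric(d_out) else NULL
  )
  class(pm) <- c("dpad_pm_linear", "dpad_pm")
  pm
}

#' Create a feed-forward (multilayer perceptron) parameter map
#'
#' Hidden layers use rectified-linear activations; the output layer is
#' linear. Hidden layers and the output carry additive biases.
#'
#' @param d_in,d_out input/output dimension
#' @param hidden integer vector of hidden layer widths (length 1 or 2)
#' @keywords internal
pm_mlp <- function(d_in, d_out, hidden) {
  stopifnot(length(hidden) >= 1)
  dims <- c(d_in, hidden, d_out)
  nl <- length(dims) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (i in seq_len(nl)) {
    W[[i]] <- glorot_mat(dims[i + 1L], dims[i])
    b[[i]] <- numeric(dims[i + 1L])
  }
  pm <- list(form = "mlp", d_in = d_in, d_out = d_out, hidden = hidden,
             W = W, b = b)
  class(pm) <- c("dpad_pm_mlp", "dpad_pm")
  pm
}

#' Create an LSTM parameter map (recursion only)
#'
#' The LSTM's hidden state is the section's declared latent state; the cell
#' state is internal extra memory. The cell consumes the (possibly mapped)
#' neural input as its input vector. Gate order in the stacked weight
#' matrices is input, forget, candidate, output; the forget-gate bias is
#' initialized to 1.
#'
#' @param d_in input dimension (dimension of the neural-input map's output)
#' @param n hidden state dimension (the section's latent dimension)
#' @keywords internal
pm_lstm <- function(d_in, n) {
  b <- numeric(4 * n)
  b[(n + 1):(2 * n)] <- 1  # forget gate bias
  pm <- list(
    form = "lstm", d_in = d_in, d_out = n, n = n,
    Wx = glorot_mat(4 * n, d_in),
    Wh = glorot_mat(4 * n, n),
    b = b
  )
  class(pm) <- c("dpad_pm_lstm", "dpad_pm")
  pm
}

# ---- flat parameter access (for Adam and serialization) --------------------

#' @keywords internal
pm_params <- function(pm) {
  switch(pm$form,
    linear = if (is.null(pm$b)) list(W = pm$W) else list(W = pm$W, b = pm$b),
    mlp = {
      out <- list()
      for (i in seq_along(pm$W)) {
        out[[paste0("W", i)]] <- pm$W[[i]]
        out[[paste0("b", i)]] <- pm$b[[i]]
      }
      out
    },
    lstm = list(Wx = pm$Wx, Wh = pm$Wh, b = pm$b)
  )
}

#' @keywords internal
pm_set_params <- function(pm, params) {
  switch(pm$form,
    linear = {
      pm$W <- params$W
      if (!is.null(pm$b)) pm$b <- params$b
    },
    mlp = {
      for (i in seq_along(pm$W)) {
        pm$W[[i]] <- params[[paste0("W", i)]]
        pm$b[[i]] <- params[[paste0("b", i)]]
      }
    },
    lstm = {
      pm$Wx <- params$Wx
      pm$Wh <- params$Wh
      pm$b <- params$b
    }
  )
  pm
}

# ---- stateless forward / backward ------------------------------------------

#' Evaluate a stateless parameter map on a batch
#'
#' @param pm map (linear or mlp; LSTM is stateful, see [lstm_step()])
#' @param U (d_in x N) input batch
#' @return list(out = (d_out x N), cache) where cache supports pm_backward
#' @keywords internal
pm_forward <- function(pm, U) {
  switch(pm$form,
    linear = {
      out <- pm$W %*% U
      if (!is.null(pm$b)) out <- out + pm$b
      list(out = out, cache = list(U = U))
    },
    mlp = {
      nl <- length(pm$W)
      acts <- vector("list", nl + 1L)
      acts[[1L]] <- U
      for (i in seq_len(nl)) {
        z <- pm$W[[i]] %*% acts[[i]] + pm$b[[i]]
        if (i < nl) z[z < 0] <- 0  # ReLU on hidden layers only
        acts[[i + 1L]] <- z
      }
      list(out = acts[[nl + 1L]], cache = list(acts = acts))
    },
    stop("pm_forward is for stateless maps; use lstm_step for lstm")
  )
}

#' Backpropagate through a stateless parameter map
#'
#' @param pm map
#' @param cache forward cache
#' @param dY (d_out x N) upstream gradient
#' @return list(grads = named list matching pm_params, dU = (d_in x N))
#' @keywords internal
pm_backward <- function(pm, cache, dY) {
  switch(pm$form,
    linear = {
      grads <- list(W = dY %*% t(cache$U))
      if (!is.null(pm$b)) grads$b <- rowSums(dY)
      list(grads = grads, dU = crossprod(pm$W, dY))
    },
    mlp = {
      nl <- length(pm$W)
      acts <- cache$acts
      grads <- list()
      d <- dY
      for (i in nl:1) {
        if (i < nl) d <- d * (acts[[i + 1L]] > 0)  # through ReLU
        grads[[paste0("W", i)]] <- d %*% t(acts[[i]])
        grads[[paste0("b", i)]] <- rowSums(d)
        d <- crossprod(pm$W[[i]], d)
      }
      list(grads = grads, dU = d)
    },
    stop("pm_backward is for stateless maps; use lstm_step_backward for lstm")
  )
}

# ---- LSTM cell -------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM step on a batch
#'
#' @param pm lstm map
#' @param h (n x N) hidden state, c_ (n x N) cell state, U (d_in x N) input
#' @return list(h, c, cache)
#' @keywords internal
lstm_step <- function(pm, h, c_, U) {
  n <- pm$n
  z <- pm$Wx %*% U + pm$Wh %*% h + pm$b
  i <- sigmoid(z[1:n, , drop = FALSE])
  f <- sigmoid(z[(n + 1):(2 * n), , drop = FALSE])
  g <- tanh(z[(2 * n + 1):(3 * n), , drop = FALSE])
  o <- sigmoid(z[(3 * n + 1):(4 * n), , drop = FALSE])
  c_new <- f * c_ + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(h = h_new, c = c_new,
       cache = list(U = U, h = h, c = c_, i = i, f = f, g = g, o = o,
                    c_new = c_new, tc = tc))
}

#' Backpropagate one LSTM step
#'
#' @param dh,dc upstream gradients for the new hidden/cell states
#' @return list(grads, dh_prev, dc_prev, dU)
#' @keywords internal
lstm_step_backward <- function(pm, cache, dh, dc) {
  with(cache, {
    do_ <- dh * tc
    dcn <- dc + dh * o * (1 - tc^2)
    di <- dcn * g
    df <- dcn * c
    dg <- dcn * i
    dc_prev <- dcn * f
    dz <- rbind(
      di * i * (1 - i),
      df * f * (1 - f),
      dg * (1 - g^2),
      do_ * o * (1 - o)
    )
    grads <- list(Wx = dz %*% t(U), Wh = dz %*% t(h), b = rowSums(dz))
    list(grads = grads,
         dh_prev = crossprod(pm$Wh, dz),
         dc_prev = dc_prev,
         dU = crossprod(pm$Wx, dz))
  })
}
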