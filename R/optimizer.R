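# Adam optimizer over flat lists of named numeric arrays.

#' @keywords internal
adam_init <- function(params) {
  # moments mirror each parameter's structure (vector vs matrix) exactly
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update
#'
#' @param params named list of arrays
#' @param grads matching gradients
#' @param state optimizer state from [adam_init()]
#' @param lr step size; beta1, beta2, eps standard Adam constants
#' @return list(params, state)
#' @keywords internal
adam_update <- function(params, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' @keywords internal
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' @keywords internal
scale_grads <- function(g, s) lapply(g, function(x) x * s)
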