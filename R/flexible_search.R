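# Flexible nonlinearity: candidate architecture enumeration, inner
# cross-validated scoring within the training data, and selection by the
# decoding-focused or self-prediction-focused criterion.

#' Enumerate the candidate nonlinearity architectures
#'
#' Each of the four parameters (A', K, C_y, C_z) is independently linear or
#' nonlinear; nonlinear parameters share one feed-forward shape per
#' candidate (1 or 2 hidden layers of 64 or 128 units), giving
#' 15 x 4 + 1 = 61 candidates including the single fully linear model.
#' Additionally the recursion A' can be an LSTM with the other three
#' parameters again linear/nonlinear in the same four shapes:
#' 7 x 4 + 1 = 29 more, for 90 candidates in total.
#'
#' @return data.frame of class `dpad_grid` with columns id, A, K, Cy, Cz,
#'   hidden_layers, hidden_units, n_nonlinear
#' @export
enumerate_architectures <- function() {
  shapes <- expand.grid(hidden_layers = 1:2, hidden_units = c(64, 128))
  rows <- list()
  add <- function(A, K, Cy, Cz, hl, hu) {
    rows[[length(rows) + 1L]] <<- data.frame(
      A = A, K = K, Cy = Cy, Cz = Cz,
      hidden_layers = hl, hidden_units = hu,
      stringsAsFactors = FALSE)
  }
  # feed-forward family: every subset of the four parameters nonlinear
  for (mask in 0:15) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    forms <- ifelse(bits, "nonlinear", "linear")
    if (mask == 0) {
      add(forms[1], forms[2], forms[3], forms[4], 1, 64)  # fully linear
    } else {
      for (s in seq_len(nrow(shapes))) {
        add(forms[1], forms[2], forms[3], forms[4],
            shapes$hidden_layers[s], shapes$hidden_units[s])
      }
    }
  }
  # LSTM-recursion family over the other three parameters
  for (mask in 0:7) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    forms <- ifelse(bits, "nonlinear", "linear")
    if (mask == 0) {
      add("lstm", forms[1], forms[2], forms[3], 1, 64)
    } else {
      for (s in seq_len(nrow(shapes))) {
        add("lstm", forms[1], forms[2], forms[3],
            shapes$hidden_layers[s], shapes$hidden_units[s])
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$n_nonlinear <- rowSums(grid[, c("A", "K", "Cy", "Cz")] != "linear")
  grid <- cbind(id = seq_len(nrow(grid)), grid)
  class(grid) <- c("dpad_grid", class(grid))
  grid
}

#' @keywords internal
spec_from_candidate <- function(cand, n_y, n_z, n_x, n_1,
                                behavior_mode = "continuous", n_c = NULL) {
  dpad_spec(n_y = n_y, n_z = n_z, n_x = n_x, n_1 = n_1,
            A = cand$A, K = cand$K, Cy = cand$Cy, Cz = cand$Cz,
            hidden_layers = cand$hidden_layers,
            hidden_units = cand$hidden_units,
            behavior_mode = behavior_mode, n_c = n_c)
}

#' Score one candidate architecture by inner cross-validation
#'
#' Two contiguous inner folds are formed within the training data; the
#' candidate is fitted on each fold's complement and scored on the held-out
#' half. Returns means and standard errors (s.e.m. over the two folds:
#' sample standard deviation divided by sqrt(2)) of behavior decoding and
#' neural self-prediction. The outer test fold is never touched.
#'
#' @param Y,Z training-fold series
#' @param spec a `dpad_spec` describing this candidate
#' @param cfg fit configuration
#' @param inner_folds number of inner folds (default 2)
#' @param mask behavior observation mask for the training fold
#' @return list(decoding, selfpred, decoding_sem, selfpred_sem)
#' @export
inner_cv_score <- function(Y, Z, spec, cfg = fit_config(), inner_folds = 2,
                           mask = NULL) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (is.null(mask)) mask <- rep(TRUE, nrow(Y))
  idx <- contiguous_kfold(nrow(Y), inner_folds)
  dec <- sp <- numeric(0)
  for (f in seq_along(idx)) {
    tr <- idx[[f]]$train; te <- idx[[f]]$test
    fit <- fit_dpad(Y[tr, , drop = FALSE], Z[tr, , drop = FALSE], spec,
                    cfg, mask = mask[tr])
    ev <- evaluate_model(fit, Y[te, , drop = FALSE], Z[te, , drop = FALSE],
                         mask[te])
    dec <- c(dec, ev$decoding)
    sp <- c(sp, ev$selfpred)
  }
  list(decoding = mean(dec), selfpred = mean(sp),
       decoding_sem = stats::sd(dec) / sqrt(length(dec)),
       selfpred_sem = stats::sd(sp) / sqrt(length(sp)))
}

#' Run the architecture search on training data
#'
#' @param Y,Z training-fold series
#' @param n_x,n_1 latent dimensions for every candidate
#' @param cfg fit configuration
#' @param grid candidate grid (default [enumerate_architectures()]); pass a
#'   subset for smoke-scale searches
#' @param mask behavior observation mask
#' @return data.frame of class `dpad_search`: the grid plus score columns;
#'   failed candidates are dropped with a warning
#' @export
search_architectures <- function(Y, Z, n_x, n_1, cfg = fit_config(),
                                 grid = enumerate_architectures(),
                                 mask = NULL) {
  res <- list()
  for (i in seq_len(nrow(grid))) {
    cand <- grid[i, ]
    spec <- spec_from_candidate(cand, n_y = ncol(as.matrix(Y)),
                                n_z = ncol(as.matrix(Z)),
                                n_x = n_x, n_1 = n_1)
    sc <- try(inner_cv_score(Y, Z, spec, cfg, mask = mask), silent = TRUE)
    if (inherits(sc, "try-error")) {
      warning("candidate ", cand$id, " failed to train and was excluded: ",
              attr(sc, "condition")$message)
      next
    }
    res[[length(res) + 1L]] <- cbind(cand, as.data.frame(sc))
  }
  if (length(res) == 0) stop("no candidate could be scored")
  out <- do.call(rbind, res)
  class(out) <- c("dpad_search", class(out))
  out
}

#' Select an architecture from candidate scores
#'
#' decoding_focused: among candidates within one s.e.m. of the best
#' behavior decoding, pick the best neural self-prediction.
#' self_prediction_focused: among candidates within one s.e.m. of the best
#' self-prediction, pick the best decoding. Ties on the maximized metric
#' are broken by parsimony: fewer nonlinear parameters, then fewer hidden
#' units, then fewer hidden layers, then candidate order.
#'
#' @param scores a `dpad_search` data.frame (columns decoding, selfpred,
#'   decoding_sem, selfpred_sem)
#' @param criterion "decoding_focused" or "self_prediction_focused"
#' @return the selected row of `scores`
#' @export
select_architecture <- function(scores,
                                criterion = c("decoding_focused",
                                              "self_prediction_focused")) {
  criterion <- match.arg(criterion)
  if (nrow(scores) == 0) stop("empty score set")
  if (criterion == "decoding_focused") {
    thr_metric <- scores$decoding; thr_sem <- scores$decoding_sem
    max_metric <- scores$selfpred
  } else {
    thr_metric <- scores$selfpred; thr_sem <- scores$selfpred_sem
    max_metric <- scores$decoding
  }
  best <- max(thr_metric)
  sem_at_best <- thr_sem[which.max(thr_metric)]
  eligible <- thr_metric >= best - sem_at_best
  cand <- scores[eligible, , drop = FALSE]
  mm <- max_metric[eligible]
  top <- which(mm == max(mm))
  if (length(top) > 1) {
    ord <- order(cand$n_nonlinear[top], cand$hidden_units[top],
                 cand$hidden_layers[top], top)
    top <- top[ord[1]]
  }
  cand[top, , drop = FALSE]
}
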