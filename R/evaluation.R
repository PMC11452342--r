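# Evaluation machinery: contiguous cross-validation, decoding and
# self-prediction metrics, state-dimension sweeps and selection rules,
# the joint neural-behavioral performance frontier, forecasting baseline,
# and 2-D latent standardization for visualization.

#' Contiguous K-fold partition of a time series
#'
#' Cuts 1..Tn into K equal contiguous segments (the remainder is given to
#' the earliest folds), used as test segments one at a time with the
#' complement as training data. Contiguity respects the serial dependence
#' of time series: random-sample CV would leak information across the
#' train/test boundary at every sample.
#'
#' @param Tn series length
#' @param K number of folds
#' @return list of K lists with `train` and `test` integer index vectors
#' @export
contiguous_kfold <- function(Tn, K) {
  if (Tn < K) stop("series shorter than the number of folds")
  base <- Tn %/% K
  extra <- Tn %% K
  sizes <- rep(base, K) + c(rep(1, extra), rep(0, K - extra))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_len(K), function(k) {
    test <- starts[k]:ends[k]
    list(train = setdiff(seq_len(Tn), test), test = test)
  })
}

#' Mean correlation coefficient across dimensions
#'
#' Pearson correlation between actual and predicted, per dimension,
#' averaged. A dimension with constant actual values has no defined CC and
#' is excluded with a warning; a constant predicted dimension carries no
#' signal and scores 0.
#'
#' @param actual,predicted (T x d) matrices
#' @return scalar mean CC
#' @export
mean_cc <- function(actual, predicted) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  stopifnot(all(dim(actual) == dim(predicted)))
  ok <- stats::complete.cases(cbind(actual, predicted))
  ccs <- vapply(seq_len(ncol(actual)), function(j) {
    a <- actual[ok, j]; p <- predicted[ok, j]
    if (stats::sd(a) < 1e-12) return(NA_real_)
    if (stats::sd(p) < 1e-12) return(0)
    stats::cor(a, p)
  }, numeric(1))
  if (anyNA(ccs)) {
    warning("constant actual dimension(s) excluded from mean CC")
    ccs <- ccs[!is.na(ccs)]
  }
  mean(ccs)
}

#' One-vs-rest multiclass AUC
#'
#' Area under the ROC curve of each class's predicted probability against
#' the binary indicator of that class, macro-averaged over classes. 1 is
#' perfect classification; 0.5 is chance. Classes absent from the labels
#' are excluded with a warning.
#'
#' @param labels integer class labels (1..n_c), length T
#' @param probabilities (T x n_c) matrix or (T x 1 x n_c) array of class
#'   probabilities
#' @return scalar macro AUC
#' @export
multiclass_auc <- function(labels, probabilities) {
  if (length(dim(probabilities)) == 3) {
    stopifnot(dim(probabilities)[2] == 1)
    probabilities <- matrix(probabilities[, 1, ],
                            dim(probabilities)[1], dim(probabilities)[3])
  }
  n_c <- ncol(probabilities)
  aucs <- numeric(0)
  for (cl in seq_len(n_c)) {
    ind <- labels == cl
    if (!any(ind) || all(ind)) {
      warning("class ", cl, " absent from labels (or labels constant); excluded")
      next
    }
    r <- pROC::roc(response = ind, predictor = probabilities[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  mean(aucs)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' One-sided paired signed-rank p-value (exact where available). By
#' convention p = 1 when all differences are zero.
#'
#' @param a,b paired samples
#' @param side "greater" tests a > b; "less" tests a < b
#' @return p-value
#' @export
paired_signed_rank <- function(a, b, side = c("greater", "less")) {
  side <- match.arg(side)
  stopifnot(length(a) == length(b))
  d <- a - b
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = side)$p.value
  )
}

#' Joint neural-behavioral performance frontier
#'
#' A model is on the frontier if, against every alternative, it is either
#' significantly better in at least one of the two measures (behavior
#' decoding, neural self-prediction) or not significantly worse in both.
#' A difference counts as significant only when the one-sided signed-rank
#' test gives p <= alpha AND the relative difference of the mean
#' performances is at least `min_rel` (guarding against minimal
#' differences reaching significance).
#'
#' @param decoding (M x S) matrix: per-model paired decoding samples
#'   (e.g., session-folds); rows are models
#' @param selfpred (M x S) matrix of paired self-prediction samples
#' @param alpha significance level (default 0.05)
#' @param min_rel minimum relative mean difference (default 0.01)
#' @return logical vector of frontier membership, named by rownames
#' @export
performance_frontier <- function(decoding, selfpred, alpha = 0.05,
                                 min_rel = 0.01) {
  decoding <- as.matrix(decoding); selfpred <- as.matrix(selfpred)
  stopifnot(all(dim(decoding) == dim(selfpred)), nrow(decoding) >= 2)
  M <- nrow(decoding)
  sig_better <- function(x, y) {
    p <- paired_signed_rank(x, y, "greater")
    rel <- (mean(x) - mean(y)) / max(abs(mean(y)), 1e-12)
    p <= alpha && rel >= min_rel
  }
  on_frontier <- rep(TRUE, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      a_dec <- sig_better(decoding[i, ], decoding[j, ])
      a_sp <- sig_better(selfpred[i, ], selfpred[j, ])
      b_dec <- sig_better(decoding[j, ], decoding[i, ])
      b_sp <- sig_better(selfpred[j, ], selfpred[i, ])
      better_somewhere <- a_dec || a_sp
      comparable_both <- !b_dec && !b_sp
      if (!(better_somewhere || comparable_both)) {
        on_frontier[i] <- FALSE
        break
      }
    }
  }
  names(on_frontier) <- rownames(decoding)
  on_frontier
}

#' Evaluate decoding and self-prediction of a fitted model
#'
#' @param model fitted `dpad_model`
#' @param Y,Z held-out neural and behavior series
#' @param mask optional behavior-observation mask for the evaluation data
#' @return list(decoding, selfpred) mean CC values (for categorical
#'   behavior, decoding is the macro one-vs-rest AUC)
#' @export
evaluate_model <- function(model, Y, Z, mask = NULL) {
  pr <- predict(model, Y)
  Z <- as.matrix(Z)
  if (is.null(mask)) mask <- rep(TRUE, nrow(Z))
  if (model$spec$behavior_mode == "categorical") {
    dec <- mean(vapply(seq_len(ncol(Z)), function(m) {
      multiclass_auc(Z[mask, m], pr$z_hat[mask, m, ])
    }, numeric(1)))
  } else {
    dec <- mean_cc(Z[mask, , drop = FALSE],
                   pr$z_hat[mask, , drop = FALSE])
  }
  list(decoding = dec, selfpred = mean_cc(as.matrix(Y), pr$y_hat))
}

#' Sweep latent state dimensions under outer cross-validation
#'
#' For each outer fold and each state dimension, fits a model and records
#' decoding and self-prediction on both the training fold (used by
#' dimension-selection rules) and the test fold (reported). Unless
#' overridden, the first min(16, n_x) state dimensions are learned with the
#' prioritized steps (n_1 = min(16, n_x)) and the remainder by the residual
#' steps.
#'
#' @param Y,Z full series
#' @param dims state dimensions to fit (default powers of 2 up to 128)
#' @param spec_template a `dpad_spec` whose dimensions are overridden
#' @param cfg fit configuration
#' @param folds number of outer folds (default 5)
#' @param n_1 override for the behaviorally relevant dimension rule
#' @param mask behavior observation mask
#' @return data.frame (fold, dim, split, decoding, selfpred) of class
#'   `dpad_sweep`
#' @export
dimension_sweep <- function(Y, Z, spec_template, cfg = fit_config(),
                            dims = 2^(0:7), folds = 5, n_1 = NULL,
                            mask = NULL) {
  stopifnot(!is.unsorted(dims))
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (is.null(mask)) mask <- rep(TRUE, nrow(Y))
  fold_idx <- contiguous_kfold(nrow(Y), folds)
  out <- list()
  for (f in seq_along(fold_idx)) {
    tr <- fold_idx[[f]]$train; te <- fold_idx[[f]]$test
    for (d in dims) {
      n1 <- if (is.null(n_1)) min(16, d) else min(n_1, d)
      spec <- dpad_spec(n_y = spec_template$n_y, n_z = spec_template$n_z,
                        n_x = d, n_1 = n1,
                        A = spec_template$forms$A, K = spec_template$forms$K,
                        Cy = spec_template$forms$Cy,
                        Cz = spec_template$forms$Cz,
                        hidden_layers = length(spec_template$hidden),
                        hidden_units = spec_template$hidden[1],
                        behavior_mode = spec_template$behavior_mode,
                        n_c = spec_template$n_c)
      fit <- try(fit_dpad(Y[tr, , drop = FALSE], Z[tr, , drop = FALSE],
                          spec, cfg, mask = mask[tr]), silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning("fit failed for fold ", f, ", dim ", d, ": ",
                attr(fit, "condition")$message)
        next
      }
      for (split in c("train", "test")) {
        idx <- if (split == "train") tr else te
        ev <- evaluate_model(fit, Y[idx, , drop = FALSE],
                             Z[idx, , drop = FALSE], mask[idx])
        out[[length(out) + 1L]] <- data.frame(
          fold = f, dim = d, split = split,
          decoding = ev$decoding, selfpred = ev$selfpred)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("dpad_sweep", class(res))
  res
}

#' Select a state dimension from training-data metric curves
#'
#' `decoding_peak`: the smallest dimension attaining the training-fold
#' decoding maximum. `joint_peak`: the larger of (smallest dimension at the
#' training self-prediction peak, smallest dimension at the training
#' decoding peak) so the chosen model explains both signals well.
#'
#' @param sweep a `dpad_sweep` (or compatible data.frame)
#' @param rule "decoding_peak" or "joint_peak"
#' @param tol peaks are compared with this absolute tolerance
#' @return data.frame (fold, dim)
#' @export
select_dimension <- function(sweep, rule = c("decoding_peak", "joint_peak"),
                             tol = 0) {
  rule <- match.arg(rule)
  tr <- sweep[sweep$split == "train", ]
  if (nrow(tr) == 0) stop("no training-split rows in sweep")
  smallest_at_peak <- function(dimv, val) {
    mx <- max(val)
    min(dimv[val >= mx - tol])
  }
  folds <- sort(unique(tr$fold))
  picks <- vapply(folds, function(f) {
    cur <- tr[tr$fold == f, ]
    cur <- cur[order(cur$dim), ]
    d_dec <- smallest_at_peak(cur$dim, cur$decoding)
    if (rule == "decoding_peak") return(d_dec)
    d_sp <- smallest_at_peak(cur$dim, cur$selfpred)
    max(d_dec, d_sp)
  }, numeric(1))
  data.frame(fold = folds, dim = picks)
}

#' Naive multistep forecasting baseline
#'
#' Model-free m-step-ahead prediction holding the last observed value:
#' y_hat_k = y_{k-m}. Reflects how predictable the series is purely from
#' its smoothness. The first m rows are NA (no observation precedes them).
#'
#' @param Y (T x d) series
#' @param m horizon (>= 1)
#' @return list(y_hat, horizon)
#' @export
naive_forecast_baseline <- function(Y, m) {
  if (m < 1) stop("horizon m must be >= 1")
  Y <- as.matrix(Y)
  Tn <- nrow(Y)
  y_hat <- matrix(NA_real_, Tn, ncol(Y))
  if (m < Tn) y_hat[(m + 1):Tn, ] <- Y[1:(Tn - m), , drop = FALSE]
  list(y_hat = y_hat, horizon = m)
}

#' Standardize 2-D behaviorally relevant latent trajectories
#'
#' For visualization of condition-averaged 2-D latent trajectories: z-score
#' both state dimensions over all trajectories, rotate so the first
#' condition's mean trajectory starts at polar angle 0, and reflect (negate
#' the second dimension) if that trajectory runs clockwise, so it runs
#' counterclockwise. One transform, estimated from the first condition's
#' mean trajectory only, is applied to every condition.
#'
#' @param trajectories named list: per condition, a list of (T x 2) trial
#'   trajectories or a single (T x 2) matrix
#' @return list with `trajectories` (same structure, transformed) and
#'   `means` (per-condition mean trajectories)
#' @export
standardize_2d_latents <- function(trajectories) {
  norm_cond <- function(x) if (is.matrix(x)) list(x) else x
  trajs <- lapply(trajectories, norm_cond)
  all_pts <- do.call(rbind, unlist(trajs, recursive = FALSE))
  if (ncol(all_pts) != 2) stop("latent trajectories must be 2-D")
  mu <- colMeans(all_pts)
  sd_ <- apply(all_pts, 2, stats::sd)
  zs <- function(x) sweep(sweep(x, 2, mu, "-"), 2, sd_, "/")
  trajs <- lapply(trajs, function(tr) lapply(tr, zs))
  cond_mean <- function(tr) Reduce("+", tr) / length(tr)
  m1 <- cond_mean(trajs[[1]])
  # rotate the start of the first condition's mean trajectory to angle 0
  th <- atan2(m1[1, 2], m1[1, 1])
  Rr <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
  rot <- function(x) x %*% t(Rr)
  trajs <- lapply(trajs, function(tr) lapply(tr, rot))
  m1 <- rot(m1)
  # reflect if the trajectory runs clockwise (negative signed area)
  n <- nrow(m1)
  area2 <- sum(m1[-n, 1] * m1[-1, 2] - m1[-1, 1] * m1[-n, 2])
  if (area2 < 0) {
    refl <- function(x) { x[, 2] <- -x[, 2]; x }
    trajs <- lapply(trajs, function(tr) lapply(tr, refl))
  }
  means <- lapply(trajs, cond_mean)
  out_trajs <- Map(function(orig, tr) if (is.matrix(orig)) tr[[1]] else tr,
                   trajectories, trajs)
  list(trajectories = out_trajs, means = means)
}
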