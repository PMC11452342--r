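# Prediction losses used by the prioritized optimization steps.

#' Sum-of-squares (Gaussian) prediction loss
#'
#' Sum over observed samples of the squared two-norm of the prediction
#' error. Proportional to the negative log-likelihood under isotropic
#' Gaussian residuals. Samples where `mask` is `FALSE` are excluded
#' (intermittently observed targets).
#'
#' @param actual,predicted numeric matrices (T x d) or vectors
#' @param mask logical vector of length T; `TRUE` where the target was
#'   observed. Default: all observed.
#' @return scalar loss
#' @export
#' @examples
#' loss_gaussian(matrix(c(1, 2)), matrix(c(0, 0)))  # 1^2 + 2^2 = 5
loss_gaussian <- function(actual, predicted, mask = NULL) {
  actual <- as.matrix(actual)
  predicted <- as.matrix(predicted)
  stopifnot(all(dim(actual) == dim(predicted)))
  if (is.null(mask)) mask <- rep(TRUE, nrow(actual))
  if (!any(mask)) stop("empty objective: mask excludes all samples")
  r <- actual[mask, , drop = FALSE] - predicted[mask, , drop = FALSE]
  sum(r * r)
}

#' Categorical negative log-likelihood loss
#'
#' Summed negative log probability of the observed class over observed
#' samples and behavior dimensions. Probabilities are clamped at 1e-7
#' below to avoid infinite loss from numerically zero probabilities.
#'
#' @param labels integer matrix (T x n_z) of class indices in 1..n_c
#' @param probabilities array (T x n_z x n_c) of class probabilities
#' @param mask logical vector of length T
#' @return scalar loss
#' @export
loss_categorical <- function(labels, probabilities, mask = NULL) {
  labels <- as.matrix(labels)
  stopifnot(length(dim(probabilities)) == 3,
            nrow(labels) == dim(probabilities)[1],
            ncol(labels) == dim(probabilities)[2])
  if (is.null(mask)) mask <- rep(TRUE, nrow(labels))
  if (!any(mask)) stop("empty objective: mask excludes all samples")
  total <- 0
  for (m in seq_len(ncol(labels))) {
    p <- probabilities[mask, m, , drop = FALSE]
    idx <- cbind(seq_len(sum(mask)), 1L, labels[mask, m])
    total <- total - sum(log(pmax(p[idx], 1e-7)))
  }
  total
}

#' Softmax over the class axis
#'
#' Converts logits to class probabilities; numerically stabilized by
#' subtracting the per-sample maximum.
#'
#' @param logits matrix (n_c x N) or array (T x n_z x n_c)
#' @return same shape, probabilities summing to one over the class axis
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- sweep(logits, 2, apply(logits, 2, max), "-")
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else if (length(dim(logits)) == 3) {
    out <- logits
    mx <- apply(logits, c(1, 2), max)
    out <- exp(logits - as.vector(mx))
    s <- apply(out, c(1, 2), sum)
    out / as.vector(s)
  } else stop("logits must be a matrix or a 3-d array")
}
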