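# Training objective: mean cross-entropy over pixels plus L2 weight decay.

#' Loss configuration
#'
#' @param beta Non-negative L2 regularization weight; default 0.0002.
#' @export
loss_config <- function(beta = 0.0002) {
  if (beta < 0) stop("beta must be non-negative")
  structure(list(beta = beta), class = "loss_config")
}

coerce_prob <- function(prob) {
  d <- dim(prob)
  if (is.null(d)) stop("prob must be an array")
  if (length(d) == 3L) {
    # (C, H, W) single image -> (1, C, H, W); with N = 1 the linear layout
    # is unchanged, so a dim change suffices
    array(prob, dim = c(1L, d))
  } else if (length(d) == 4L) prob
  else stop("prob must be (C,H,W) or (N,C,H,W)")
}

#' Mean cross-entropy of a probability map against a label mask
#'
#' Categorical form: minus the mean log-probability of the true class over
#' all pixels. For two classes with per-pixel probabilities summing to one
#' this reduces to the familiar binary form
#' `-(1/n) * sum(y*log(y') + (1-y)*log(1-y'))`. Probabilities are clamped at
#' `clamp` before the log so the value stays finite.
#'
#' @param prob (N, num_classes, H, W) or (num_classes, H, W) probability
#'   array, normalized per pixel.
#' @param target Integer labels in 0..num_classes-1, shaped (N, H, W) or
#'   (H, W).
#' @param clamp Probability floor.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(prob, target, clamp = 1e-12) {
  prob <- coerce_prob(prob)
  d <- dim(prob)
  target <- as.integer(round(target))
  if (length(target) != d[1] * d[3] * d[4]) {
    stop("target size does not match probability map")
  }
  if (length(target) == 0L) stop("empty target: n = 0")
  if (any(target < 0L) || any(target >= d[2])) {
    stop("label out of range [0, ", d[2] - 1L, "]")
  }
  tgt <- array(target, dim = c(d[1], d[3], d[4]))
  sel <- cbind(
    rep(seq_len(d[1]), times = d[3] * d[4]),
    c(tgt) + 1L,
    rep(rep(seq_len(d[3]), each = d[1]), times = d[4]),
    rep(seq_len(d[4]), each = d[1] * d[3])
  )
  -mean(log(pmax(prob[sel], clamp)))
}

#' Total training loss: cross-entropy + beta * ||W||^2
#'
#' The squared L2 norm runs over every learned scalar supplied in `weights`
#' (convolution kernels, biases, normalization scales and offsets).
#'
#' @inheritParams cross_entropy
#' @param weights Named (possibly nested) list of numeric arrays, or a
#'   `sanet_model`.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar, `>= cross_entropy(prob, target)`.
#' @export
total_loss <- function(prob, target, weights, cfg = loss_config()) {
  cross_entropy(prob, target) + cfg$beta * weight_sq_norm(weights)
}

weight_sq_norm <- function(weights) {
  if (inherits(weights, "sanet_model")) weights <- weights$params
  sum(rapply(weights, function(x) sum(x^2), how = "unlist"))
}
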