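# Scale-attention building blocks.
#
# The bridge block is a residual bottleneck whose middle 3x3 convolution is
# replaced by a hierarchical channel split: the `width` channels produced by a
# reducing 1x1 convolution are divided into k subsets x_1..x_k of width/k
# channels each. The subsets are processed by the recurrence
#
#   y_1 = x_1
#   y_2 = F_2(x_2)
#   y_i = F_i(concat(x_i, A_{i-1}(y_{i-1})))   for 2 < i <= k   (attention on)
#   y_i = F_i(x_i + y_{i-1})                   for 2 < i <= k   (attention off)
#
# where F_i is a same-padding 3x3 convolution (+ batch norm + ReLU) and A_j
# is a channel-attention gate: sigmoid(conv1x1(globalmax + globalavg))
# multiplied back onto its input. The y_i are concatenated, fused by a 1x1
# convolution and added to the identity skip. The first subset bypasses its
# 3x3 convolution, which keeps the parameter count flat as k grows.

#' Configuration for a scale-attention bridge block
#'
#' @param in_channels,out_channels Channel counts entering/leaving the block.
#' @param width Channels produced by the reducing 1x1 convolution, i.e. the
#'   channel count entering the split. Must be divisible by `k`. Defaults to
#'   `out_channels` (the bridge channel count).
#' @param k Scale dimension: number of channel subsets. Each subset carries
#'   `width / k` channels.
#' @param use_attention If `TRUE` the hierarchical chain passes each stage's
#'   output through a channel-attention gate and concatenates (the
#'   scale-attention block); if `FALSE` stages are combined by addition
#'   (the plain hierarchical-residual block used in the ablation ladder).
#' @param use_norm Apply batch normalization inside the block.
#' @return An object of class `sa_block_config`.
#' @export
sa_block_config <- function(in_channels, out_channels, width = out_channels,
                            k = 4L, use_attention = TRUE, use_norm = TRUE) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (width %% k != 0L) {
    stop("width (", width, ") must be divisible by k (", k, ")")
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 width = as.integer(width), k = k,
                 use_attention = isTRUE(use_attention),
                 use_norm = isTRUE(use_norm)),
            class = "sa_block_config")
}

# ---- parameter containers --------------------------------------------------

conv_params <- function(rng, cout, cin, kh, kw) {
  list(w = init_weight(rng, c(cout, cin, kh, kw), fan_in = cin * kh * kw),
       b = numeric(cout))
}

bn_params <- function(c) list(gamma = rep(1, c), beta = numeric(c))

bn_state <- function(c) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(c)
  e$running_var <- rep(1, c)
  e
}

#' Initialize attention-gate parameters
#'
#' The gate's 1x1 convolution maps C channels to C channels (no reduction
#' ratio) and carries a bias.
#'
#' @param channels Channel count the gate operates on.
#' @param rng A [sanet_rng()] stream (defaults to seed 0).
#' @return List with `mix_weights` (C,C,1,1 array) and `mix_bias`.
#' @export
attention_params <- function(channels, rng = sanet_rng(0L)) {
  p <- conv_params(rng, channels, channels, 1L, 1L)
  list(mix_weights = p$w, mix_bias = p$b)
}

#' Initialize the parameters of a scale-attention (or plain) block
#'
#' @param config An [sa_block_config()].
#' @param rng A [sanet_rng()] stream.
#' @return Named list of parameter arrays.
#' @export
sa_block_params <- function(config, rng = sanet_rng(0L)) {
  ck <- config$width %/% config$k
  p <- list(reduce = conv_params(rng, config$width, config$in_channels, 1L, 1L),
            reduce_bn = bn_params(config$width))
  if (config$k >= 2L) {
    for (i in 2:config$k) {
      cin <- if (i == 2L || !config$use_attention) ck else 2L * ck
      p[[paste0("f", i)]] <- conv_params(rng, ck, cin, 3L, 3L)
      p[[paste0("f", i, "_bn")]] <- bn_params(ck)
    }
    if (config$use_attention && config$k >= 3L) {
      for (j in 2:(config$k - 1L)) {
        p[[paste0("gate", j)]] <- attention_params(ck, rng)
      }
    }
  }
  p$fuse <- conv_params(rng, config$out_channels, config$width, 1L, 1L)
  p$fuse_bn <- bn_params(config$out_channels)
  if (config$in_channels != config$out_channels) {
    p$proj <- conv_params(rng, config$out_channels, config$in_channels, 1L, 1L)
  }
  p
}

#' Parameters of a conventional residual bottleneck block
#'
#' 1x1 reduce, single 3x3, 1x1 expand, identity skip. The canonical
#' comparator for the ablation ladder.
#'
#' @inheritParams sa_block_params
#' @export
resnet_block_params <- function(config, rng = sanet_rng(0L)) {
  p <- list(reduce = conv_params(rng, config$width, config$in_channels, 1L, 1L),
            reduce_bn = bn_params(config$width),
            mid = conv_params(rng, config$width, config$width, 3L, 3L),
            mid_bn = bn_params(config$width),
            fuse = conv_params(rng, config$out_channels, config$width, 1L, 1L),
            fuse_bn = bn_params(config$out_channels))
  if (config$in_channels != config$out_channels) {
    p$proj <- conv_params(rng, config$out_channels, config$in_channels, 1L, 1L)
  }
  p
}

# Zero every learned array of a parameter list (testing aid: with all weights
# zero a block reduces to its identity skip).
zero_params <- function(params) rapply(params, function(x) x * 0, how = "replace")

# ---- tape-level builders ---------------------------------------------------
# `pn` maps parameter arrays to tape leaves so gradients can be harvested.

ag_wrap_params <- function(tape, params) {
  rapply(params, function(x) ag_leaf(tape, x), how = "replace",
         classes = c("numeric", "array", "matrix", "integer"))
}

bld_attention <- function(tape, x, p) {
  pooled <- ag_add(tape, ag_global_max(tape, x), ag_global_avg(tape, x))
  gate <- ag_sigmoid(tape, ag_conv2d(tape, pooled, p$mix_weights, p$mix_bias, 0L))
  ag_gate_mul(tape, x, gate)
}

bld_conv_bn_relu <- function(tape, x, conv, bn, states, name, pad, training,
                             use_norm = TRUE, activation = TRUE) {
  out <- ag_conv2d(tape, x, conv$w, conv$b, pad)
  if (use_norm && !is.null(bn)) {
    if (is.null(states[[name]])) states[[name]] <- bn_state(length(bn$gamma$value))
    out <- ag_batchnorm(tape, out, bn$gamma, bn$beta, states[[name]], training)
  }
  if (activation) out <- ag_relu(tape, out)
  out
}

bld_sa_recurrence <- function(tape, subsets, config, p, states, training) {
  k <- length(subsets)
  ys <- vector("list", k)
  ys[[1]] <- subsets[[1]]
  if (k >= 2L) {
    ys[[2]] <- bld_conv_bn_relu(tape, subsets[[2]], p$f2, p$f2_bn, states,
                                "f2", 1L, training, config$use_norm)
  }
  if (k >= 3L) {
    for (i in 3:k) {
      fin <- if (config$use_attention) {
        gated <- bld_attention(tape, ys[[i - 1L]], p[[paste0("gate", i - 1L)]])
        ag_concat_ch(tape, list(subsets[[i]], gated))
      } else {
        ag_add(tape, subsets[[i]], ys[[i - 1L]])
      }
      ys[[i]] <- bld_conv_bn_relu(tape, fin, p[[paste0("f", i)]],
                                  p[[paste0("f", i, "_bn")]], states,
                                  paste0("f", i), 1L, training, config$use_norm)
    }
  }
  ys
}

bld_sa_block <- function(tape, x, config, p, states, training) {
  h <- bld_conv_bn_relu(tape, x, p$reduce, p$reduce_bn, states, "reduce", 0L,
                        training, config$use_norm)
  subsets <- ag_split_ch(tape, h, config$k)
  ys <- bld_sa_recurrence(tape, subsets, config, p, states, training)
  fused <- if (config$k == 1L) ys[[1]] else ag_concat_ch(tape, ys)
  out <- bld_conv_bn_relu(tape, fused, p$fuse, p$fuse_bn, states, "fuse", 0L,
                          training, config$use_norm, activation = FALSE)
  skip <- if (is.null(p$proj)) x else ag_conv2d(tape, x, p$proj$w, p$proj$b, 0L)
  ag_add(tape, out, skip)
}

bld_resnet_block <- function(tape, x, config, p, states, training) {
  h <- bld_conv_bn_relu(tape, x, p$reduce, p$reduce_bn, states, "reduce", 0L,
                        training, config$use_norm)
  h <- bld_conv_bn_relu(tape, h, p$mid, p$mid_bn, states, "mid", 1L,
                        training, config$use_norm)
  out <- bld_conv_bn_relu(tape, h, p$fuse, p$fuse_bn, states, "fuse", 0L,
                          training, config$use_norm, activation = FALSE)
  skip <- if (is.null(p$proj)) x else ag_conv2d(tape, x, p$proj$w, p$proj$b, 0L)
  ag_add(tape, out, skip)
}

# ---- user-facing array-in/array-out operations -----------------------------

#' Channel-attention gate forward pass
#'
#' Computes `x * sigmoid(conv1x1(globalmax(x) + globalavg(x)))`, where the
#' pooling operators reduce each channel's HxW plane to a scalar and the gate
#' is broadcast back over space. Gate values lie strictly in (0, 1), so the
#' output is elementwise bounded by the input.
#'
#' @param x Rank-4 (N, C, H, W) numeric array.
#' @param params Gate parameters from [attention_params()]; the 1x1
#'   convolution maps C channels to C channels.
#' @return Array of the same shape as `x`.
#' @export
attention_forward <- function(x, params) {
  x <- as_nchw(x)
  if (dim(x)[2] != dim(params$mix_weights)[1]) {
    stop("attention gate channel count (", dim(params$mix_weights)[1],
         ") does not match input channels (", dim(x)[2], ")")
  }
  tape <- ag_tape()
  bld_attention(tape, ag_leaf(tape, x), ag_wrap_params(tape, params))$value
}

#' Split a feature map into k channel subsets
#'
#' Each subset keeps 1/k of the channels; concatenating the subsets in order
#' reconstructs the input exactly.
#'
#' @param x Rank-4 (N, C, H, W) array with C divisible by `k`.
#' @param k Number of subsets.
#' @return List of k arrays of shape (N, C/k, H, W).
#' @export
split_channels <- function(x, k) {
  x <- as_nchw(x)
  k <- as.integer(k)
  d <- dim(x)
  if (k < 1L) stop("k must be >= 1")
  if (d[2] %% k != 0L) {
    stop("channel count ", d[2], " is not divisible by k = ", k)
  }
  ck <- d[2] %/% k
  lapply(seq_len(k), function(i) x[, (i - 1L) * ck + seq_len(ck), , , drop = FALSE])
}

#' Hierarchical scale-attention recurrence over channel subsets
#'
#' @param subsets List of k equally shaped (N, C/k, H, W) arrays.
#' @param config An [sa_block_config()]; `use_attention` selects the gated
#'   concatenation chain or the additive chain.
#' @param params Parameters from [sa_block_params()]; only the `f*` and
#'   `gate*` entries are used.
#' @param training Batch-norm mode.
#' @return List of k arrays, each shaped like the subsets.
#' @export
sa_recurrence <- function(subsets, config, params = NULL, training = FALSE) {
  if (length(subsets) < 1L) stop("need at least one subset")
  ds <- lapply(subsets, dim4)
  if (length(unique(vapply(ds, paste, character(1), collapse = "x"))) != 1L) {
    stop("subsets must share a common shape")
  }
  if (is.null(params)) params <- sa_block_params(config)
  tape <- ag_tape()
  pn <- ag_wrap_params(tape, params)
  nodes <- lapply(subsets, function(s) ag_leaf(tape, s))
  states <- new.env(parent = emptyenv())
  lapply(bld_sa_recurrence(tape, nodes, config, pn, states, training),
         function(nd) nd$value)
}

#' Scale-attention block forward pass
#'
#' Bottleneck composition: 1x1 reduce, channel split, hierarchical
#' (attention-gated) recurrence, concatenation, 1x1 fusion, identity skip
#' (1x1-projected when channel counts differ). No activation follows the
#' skip addition, so a block with all-zero weights is an exact identity.
#'
#' @inheritParams sa_recurrence
#' @param x Input (N, in_channels, H, W) array.
#' @return Array of shape (N, out_channels, H, W).
#' @export
sa_block_forward <- function(x, config, params = NULL, training = FALSE) {
  x <- as_nchw(x)
  if (dim(x)[2] != config$in_channels) stop("input channel mismatch")
  if (is.null(params)) params <- sa_block_params(config)
  tape <- ag_tape()
  pn <- ag_wrap_params(tape, params)
  states <- new.env(parent = emptyenv())
  bld_sa_block(tape, ag_leaf(tape, x), config, pn, states, training)$value
}

#' Conventional residual bottleneck forward pass
#'
#' @inheritParams sa_block_forward
#' @export
resnet_bottleneck_forward <- function(x, config, params = NULL,
                                      training = FALSE) {
  x <- as_nchw(x)
  if (dim(x)[2] != config$in_channels) stop("input channel mismatch")
  if (is.null(params)) params <- resnet_block_params(config)
  tape <- ag_tape()
  pn <- ag_wrap_params(tape, params)
  states <- new.env(parent = emptyenv())
  bld_resnet_block(tape, ag_leaf(tape, x), config, pn, states, training)$value
}

# Count scalars in a (nested) parameter list.
param_count <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
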