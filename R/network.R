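# Configurable U-Net with a pluggable bridge.
#
# Encoder: `depth` stages of (3x3 conv + BN + ReLU) x 2 with channel doubling,
# 2x2 max pooling between stages. Bottom: the conventional double conv at
# base_width * 2^depth channels. Bridge: `bridge_blocks` residual blocks of
# the chosen variant inserted after the bottom double conv (variant "none"
# inserts nothing, giving the plain backbone). Decoder: transposed-conv
# upsampling, skip concatenation, double conv per stage. Head: 1x1 conv to
# num_classes followed by per-pixel softmax.
#
# Default bridge-block widths follow the blocks' canonical configurations:
# the ResNet bottleneck reduces its middle width to C/4; the hierarchical
# split variants use width = C (the bridge channel count).

#' Network configuration
#'
#' @param depth Number of down/up-sampling stages (>= 1).
#' @param base_width Channels at the first encoder stage.
#' @param num_classes Number of output classes (>= 2).
#' @param in_channels 1 (grayscale) or 3 (RGB).
#' @param bridge_variant One of `"none"`, `"resnet"`, `"res2net"`, `"sa"`.
#' @param k Scale dimension for the channel-splitting variants.
#' @param bridge_blocks Number of stacked bridge blocks.
#' @param seed Seed for weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(depth = 4L, base_width = 64L, num_classes = 2L,
                           in_channels = 1L,
                           bridge_variant = c("sa", "res2net", "resnet", "none"),
                           k = 4L, bridge_blocks = 1L, seed = 42L) {
  bridge_variant <- match.arg(bridge_variant)
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  k <- as.integer(k)
  if (depth < 1L) stop("depth must be >= 1")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (!in_channels %in% c(1L, 3L)) stop("in_channels must be 1 or 3")
  cb <- base_width * 2L^depth
  if (bridge_variant %in% c("res2net", "sa") && cb %% k != 0L) {
    stop("bridge width ", cb, " is not divisible by k = ", k)
  }
  structure(list(depth = depth, base_width = base_width,
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 bridge_variant = bridge_variant, k = k,
                 bridge_blocks = as.integer(bridge_blocks),
                 seed = as.integer(seed)),
            class = "network_config")
}

bridge_block_config <- function(config) {
  cb <- config$base_width * 2L^config$depth
  switch(config$bridge_variant,
    none = NULL,
    resnet = sa_block_config(cb, cb, width = max(cb %/% 4L, 1L), k = 1L,
                             use_attention = FALSE),
    res2net = sa_block_config(cb, cb, width = cb, k = config$k,
                              use_attention = FALSE),
    sa = sa_block_config(cb, cb, width = cb, k = config$k,
                         use_attention = TRUE))
}

#' Build a segmentation model
#'
#' Allocates and deterministically initializes all weights from
#' `config$seed`. Two calls with the same configuration produce identical
#' parameter arrays.
#'
#' @param config A [network_config()].
#' @return An object of class `sanet_model` with elements `config`, `params`
#'   (named list of arrays) and `state` (batch-norm running statistics).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  rng <- sanet_rng(config$seed)
  d <- config$depth
  widths <- config$base_width * 2L^(0:(d - 1L))
  cb <- config$base_width * 2L^d
  params <- list()
  dbl <- function(cin, cmid) {
    list(conv1 = conv_params(rng, cmid, cin, 3L, 3L), bn1 = bn_params(cmid),
         conv2 = conv_params(rng, cmid, cmid, 3L, 3L), bn2 = bn_params(cmid))
  }
  cin <- config$in_channels
  for (s in seq_len(d)) {
    params[[paste0("enc", s)]] <- dbl(cin, widths[s])
    cin <- widths[s]
  }
  params$bottom <- dbl(widths[d], cb)
  bcfg <- bridge_block_config(config)
  if (!is.null(bcfg)) {
    for (bidx in seq_len(config$bridge_blocks)) {
      params[[paste0("bridge", bidx)]] <-
        if (config$bridge_variant == "resnet") resnet_block_params(bcfg, rng)
        else sa_block_params(bcfg, rng)
    }
  }
  cup <- cb
  for (s in rev(seq_len(d))) {
    params[[paste0("up", s)]] <- list(
      w = init_weight(rng, c(cup, widths[s], 2L, 2L), fan_in = cup * 4L),
      b = numeric(widths[s]))
    params[[paste0("dec", s)]] <- dbl(2L * widths[s], widths[s])
    cup <- widths[s]
  }
  params$head <- conv_params(rng, config$num_classes, config$base_width, 1L, 1L)
  model <- list(config = config, params = params,
                state = new.env(parent = emptyenv()))
  class(model) <- "sanet_model"
  model
}

# Build the forward graph on a tape. Returns list(prob = node, pn = wrapped
# parameter nodes). `training` switches batch-norm mode.
model_graph <- function(model, tape, x_node, training = FALSE) {
  cfg <- model$config
  p <- ag_wrap_params(tape, model$params)
  states <- model$state
  dblf <- function(x, pp, name) {
    x <- bld_conv_bn_relu(tape, x, pp$conv1, pp$bn1, states,
                          paste0(name, "_1"), 1L, training)
    bld_conv_bn_relu(tape, x, pp$conv2, pp$bn2, states,
                     paste0(name, "_2"), 1L, training)
  }
  skips <- vector("list", cfg$depth)
  h <- x_node
  for (s in seq_len(cfg$depth)) {
    h <- dblf(h, p[[paste0("enc", s)]], paste0("enc", s))
    skips[[s]] <- h
    h <- ag_maxpool2(tape, h)
  }
  h <- dblf(h, p$bottom, "bottom")
  bcfg <- bridge_block_config(cfg)
  if (!is.null(bcfg)) {
    for (bidx in seq_len(cfg$bridge_blocks)) {
      bp <- p[[paste0("bridge", bidx)]]
      bstates <- bridge_states(states, bidx)
      h <- if (cfg$bridge_variant == "resnet") {
        bld_resnet_block(tape, h, bcfg, bp, bstates, training)
      } else {
        bld_sa_block(tape, h, bcfg, bp, bstates, training)
      }
    }
  }
  for (s in rev(seq_len(cfg$depth))) {
    up <- p[[paste0("up", s)]]
    h <- ag_convT2(tape, h, up$w, up$b)
    h <- ag_concat_ch(tape, list(skips[[s]], h))
    h <- dblf(h, p[[paste0("dec", s)]], paste0("dec", s))
  }
  logits <- ag_conv2d(tape, h, p$head$w, p$head$b, 0L)
  list(prob = ag_softmax_ch(tape, logits), logits = logits, pn = p)
}

# Namespaced view of the shared state env for bridge block `bidx`.
bridge_states <- function(states, bidx) {
  key <- paste0(".bridge", bidx)
  if (is.null(states[[key]])) {
    states[[key]] <- new.env(parent = emptyenv())
  }
  states[[key]]
}

check_input_dims <- function(config, d) {
  div <- 2L^config$depth
  if (d[3] %% div != 0L || d[4] %% div != 0L) {
    stop("spatial dimensions (", d[3], "x", d[4],
         ") must be divisible by 2^depth = ", div)
  }
  if (d[2] != config$in_channels) {
    stop("expected ", config$in_channels, " input channels, got ", d[2])
  }
}

#' Forward pass: per-pixel class probabilities
#'
#' @param model A [build_model()] result.
#' @param batch (N, in_channels, H, W) array with H, W divisible by
#'   2^depth. No implicit padding is performed.
#' @param training Batch-norm mode; evaluation mode (default) uses running
#'   statistics and is deterministic.
#' @return (N, num_classes, H, W) array; class probabilities sum to 1 at
#'   every pixel.
#' @export
forward <- function(model, batch, training = FALSE) {
  batch <- as_nchw(batch)
  check_input_dims(model$config, dim(batch))
  tape <- ag_tape()
  g <- model_graph(model, tape, ag_leaf(tape, batch), training)
  g$prob$value
}

#' Total scalar parameter count of a model
#'
#' Counts every learned scalar: convolution kernels, biases, batch-norm
#' scales and offsets. Running statistics are buffers, not parameters, and
#' are excluded.
#'
#' @param model A [build_model()] result.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  param_count(model$params)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, every named weight array and the
#' batch-norm running statistics; a load reproduces the model exactly.
#'
#' @param model A `sanet_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  env_to_list <- function(e) {
    lapply(as.list(e, all.names = TRUE), function(v) {
      if (is.environment(v)) env_to_list(v) else v
    })
  }
  saveRDS(list(config = model$config, params = model$params,
               state = env_to_list(model$state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list_to_env <- function(l) {
    e <- new.env(parent = emptyenv())
    for (key in names(l)) {
      v <- l[[key]]
      # leaf bn-state lists hold numeric running stats; anything else nests
      e[[key]] <- if (is.list(v) && is.null(v$running_mean)) list_to_env(v)
                  else if (is.list(v)) list2env(v, parent = emptyenv())
                  else v
    }
    e
  }
  model <- list(config = ck$config, params = ck$params,
                state = list_to_env(ck$state))
  class(model) <- "sanet_model"
  model
}
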