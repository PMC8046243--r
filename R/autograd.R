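# Reverse-mode automatic differentiation on NCHW arrays.
#
# A tape records nodes in creation order (which is a topological order, since
# the graph is built by the forward pass); backpropagation walks the list in
# reverse. Each node is an environment holding its value, accumulated
# gradient, parent nodes and a backward closure. Broadcasting over (H, W)
# exploits R's column-major recycling: for a dim = c(N, C, H, W) array the
# first N*C elements cycle fastest, so `x * c(g)` with g of dim (N, C, 1, 1)
# multiplies every spatial position by its per-sample, per-channel gate.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(tape, root) {
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- array(1, dim = if (is.null(dim(root$value))) 1L else dim(root$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a rank-4 (N,C,H,W) array")
  d
}

# ---- primitive ops ---------------------------------------------------------

ag_conv2d <- function(tape, x, w, b, pad) {
  val <- cpp_conv2d(x$value, w$value, b$value, as.integer(pad))
  ag_node(tape, val, list(x, w, b), function(nd) {
    gr <- cpp_conv2d_backward(x$value, w$value, nd$grad, as.integer(pad))
    ag_accum(x, gr$dx); ag_accum(w, gr$dw); ag_accum(b, gr$db)
  })
}

ag_convT2 <- function(tape, x, w, b) {
  val <- cpp_convT2(x$value, w$value, b$value)
  ag_node(tape, val, list(x, w, b), function(nd) {
    gr <- cpp_convT2_backward(x$value, w$value, nd$grad)
    ag_accum(x, gr$dx); ag_accum(w, gr$dw); ag_accum(b, gr$db)
  })
}

ag_maxpool2 <- function(tape, x) {
  r <- cpp_maxpool2(x$value)
  ag_node(tape, r$value, list(x), function(nd) {
    ag_accum(x, cpp_maxpool2_backward(nd$grad, r$argmax, dim4(x$value)))
  })
}

ag_relu <- function(tape, x) {
  keep <- x$value > 0
  val <- x$value * keep
  ag_node(tape, val, list(x), function(nd) ag_accum(x, nd$grad * keep))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(nd) ag_accum(x, nd$grad * s * (1 - s)))
}

ag_add <- function(tape, x, y) {
  ag_node(tape, x$value + y$value, list(x, y), function(nd) {
    ag_accum(x, nd$grad); ag_accum(y, nd$grad)
  })
}

# x: (N,C,H,W), g: (N,C,1,1) channel gate broadcast over H, W
ag_gate_mul <- function(tape, x, g) {
  gv <- c(g$value)
  val <- x$value * gv
  ag_node(tape, val, list(x, g), function(nd) {
    ag_accum(x, nd$grad * gv)
    dg <- apply(nd$grad * x$value, c(1, 2), sum)
    ag_accum(g, array(dg, dim = dim(g$value)))
  })
}

ag_global_avg <- function(tape, x) {
  d <- dim4(x$value)
  m <- apply(x$value, c(1, 2), mean)
  ag_node(tape, array(m, dim = c(d[1], d[2], 1L, 1L)), list(x), function(nd) {
    ag_accum(x, array(c(nd$grad) / (d[3] * d[4]), dim = d))
  })
}

ag_global_max <- function(tape, x) {
  d <- dim4(x$value)
  xm <- matrix(x$value, nrow = d[1] * d[2])  # rows (n,c), cols (h,w)
  idx <- max.col(xm, ties.method = "first")
  m <- xm[cbind(seq_len(nrow(xm)), idx)]
  ag_node(tape, array(m, dim = c(d[1], d[2], 1L, 1L)), list(x), function(nd) {
    dxm <- matrix(0, nrow(xm), ncol(xm))
    dxm[cbind(seq_len(nrow(xm)), idx)] <- c(nd$grad)
    ag_accum(x, array(dxm, dim = d))
  })
}

ag_concat_ch <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim4(x$value))
  cs <- vapply(ds, `[`, integer(1), 2L)
  d0 <- ds[[1]]
  out <- array(0, dim = c(d0[1], sum(cs), d0[3], d0[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, off + seq_len(cs[i]), , ] <- xs[[i]]$value
    off <- off + cs[i]
  }
  ag_node(tape, out, xs, function(nd) {
    off <- 0L
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], nd$grad[, off + seq_len(cs[i]), , , drop = FALSE])
      off <- off + cs[i]
    }
  })
}

ag_split_ch <- function(tape, x, k) {
  d <- dim4(x$value)
  if (d[2] %% k != 0) stop("channel count ", d[2], " not divisible by k = ", k)
  ck <- d[2] %/% k
  lapply(seq_len(k), function(i) {
    rng <- (i - 1L) * ck + seq_len(ck)
    ag_node(tape, x$value[, rng, , , drop = FALSE], list(x), function(nd) {
      g <- array(0, dim = d)
      g[, rng, , ] <- nd$grad
      ag_accum(x, g)
    })
  })
}

# Batch normalization over (N, H, W) per channel. `state` is an environment
# with running_mean / running_var (used in evaluation mode and updated with
# exponential momentum during training).
ag_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim4(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    mu <- apply(x$value, 2, mean)
    xc <- sweep(x$value, 2, mu, "-")
    va <- apply(xc * xc, 2, mean)  # biased variance
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    xc <- sweep(x$value, 2, mu, "-")
    va <- state$running_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, ivar, "*")
  gv <- c(gamma$value); bv <- c(beta$value)
  val <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  ag_node(tape, val, list(x, gamma, beta), function(nd) {
    dgamma <- apply(nd$grad * xhat, 2, sum)
    dbeta <- apply(nd$grad, 2, sum)
    ag_accum(gamma, dgamma); ag_accum(beta, dbeta)
    dxhat <- sweep(nd$grad, 2, gv, "*")
    if (training) {
      s1 <- apply(dxhat, 2, sum)
      s2 <- apply(dxhat * xhat, 2, sum)
      dx <- sweep(dxhat, 2, ivar, "*") -
        sweep(array(1, d), 2, ivar * s1 / m, "*") -
        sweep(xhat, 2, ivar * s2 / m, "*")
      ag_accum(x, dx)
    } else {
      ag_accum(x, sweep(dxhat, 2, ivar, "*"))
    }
  })
}

# Channel softmax (per-pixel class probabilities).
ag_softmax_ch <- function(tape, x) {
  d <- dim4(x$value)
  mx <- apply(x$value, c(1, 3, 4), max)
  shifted <- x$value - aperm(array(mx, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  ex <- exp(shifted)
  ssum <- apply(ex, c(1, 3, 4), sum)
  p <- ex / aperm(array(ssum, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  ag_node(tape, p, list(x), function(nd) {
    dot <- apply(nd$grad * p, c(1, 3, 4), sum)
    dotb <- aperm(array(dot, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
    ag_accum(x, p * (nd$grad - dotb))
  })
}

# Mean negative log-likelihood of the true class, on probabilities.
# target: integer array (N, H, W) with labels in 0..C-1.
ag_nll_prob <- function(tape, prob, target, clamp = 1e-12) {
  d <- dim4(prob$value)
  n <- d[1] * d[3] * d[4]
  sel <- cbind(
    rep(seq_len(d[1]), times = d[3] * d[4]),
    c(target) + 1L,
    rep(rep(seq_len(d[3]), each = d[1]), times = d[4]),
    rep(seq_len(d[4]), each = d[1] * d[3])
  )
  pt <- pmax(prob$value[sel], clamp)
  val <- -mean(log(pt))
  ag_node(tape, val, list(prob), function(nd) {
    g <- array(0, dim = d)
    g[sel] <- -c(nd$grad) / (n * pt)
    ag_accum(prob, g)
  })
}
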