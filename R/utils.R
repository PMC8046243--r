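# Seeded random stream objects. All package randomness flows through one of
# these so that no function touches the caller's global RNG state.

#' Create a seeded random stream
#'
#' Returns a self-contained random number stream. Functions that accept an
#' `rng` argument draw from the stream without disturbing `.Random.seed` in
#' the calling session, so results are reproducible regardless of what the
#' caller does with R's global generator.
#'
#' @param seed Integer seed.
#' @return An object of class `sanet_rng`.
#' @export
sanet_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  class(e) <- "sanet_rng"
  e
}

# Evaluate `expr` using the stream's state, then save the advanced state back.
rng_with <- function(rng, expr) {
  stopifnot(inherits(rng, "sanet_rng"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

rng_runif <- function(rng, n, min = 0, max = 1) rng_with(rng, runif(n, min, max))
rng_rnorm <- function(rng, n, mean = 0, sd = 1) rng_with(rng, rnorm(n, mean, sd))
rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  rng_with(rng, sample(x, size, replace))
}

# Fan-in-scaled uniform initialization: U(-a, a), a = sqrt(3 / fan_in),
# giving Var = 1/fan_in (LeCun-uniform).
init_weight <- function(rng, dims, fan_in) {
  a <- sqrt(3 / fan_in)
  array(rng_runif(rng, prod(dims), -a, a), dim = dims)
}

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a rank-4 (N,C,H,W) array")
  if (any(!is.finite(x))) stop("non-finite values in feature map")
  x
}
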