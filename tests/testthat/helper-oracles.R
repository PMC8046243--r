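# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the most literal formulation
# (pixel enumeration, exhaustive pairwise ranking, Pearson correlation of
# indicator vectors) rather than sharing any code with the package.

oracle_confusion <- function(pred, truth, fov = NULL) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      if (!is.null(fov) && fov[i, j] == 0) next
      p <- pred[i, j] != 0; t <- truth[i, j] != 0
      if (p && t) tp <- tp + 1L
      else if (!p && !t) tn <- tn + 1L
      else if (p && !t) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# MCC as the Pearson correlation of the paired 0/1 indicator vectors.
oracle_mcc <- function(pred, truth, fov = NULL) {
  keep <- if (is.null(fov)) rep(TRUE, length(truth)) else c(fov != 0)
  p <- as.numeric(c(pred != 0)[keep])
  t <- as.numeric(c(truth != 0)[keep])
  if (stats::sd(p) == 0 || stats::sd(t) == 0) return(0)
  stats::cor(p, t)
}

# AUC by exhaustive comparison of every (positive, negative) pixel pair.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels != 0]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

oracle_jaccard <- function(pred, truth, cl) {
  p <- c(pred) == cl; t <- c(truth) == cl
  u <- sum(p | t)
  if (u == 0) 1 else sum(p & t) / u
}

# Closed-form scalar tally of a conv layer (weights + biases) and batch norm.
tally_conv <- function(cout, cin, k) cout * cin * k * k + cout
tally_bn <- function(c) 2 * c
tally_double_conv <- function(cin, c) {
  tally_conv(c, cin, 3) + tally_bn(c) + tally_conv(c, c, 3) + tally_bn(c)
}

# Layer-by-layer tally of the bridge blocks at the model's default widths.
tally_resnet_block <- function(C) {
  w <- C %/% 4
  tally_conv(w, C, 1) + tally_bn(w) +      # reduce
    tally_conv(w, w, 3) + tally_bn(w) +    # middle 3x3
    tally_conv(C, w, 1) + tally_bn(C)      # expand
}

tally_split_block <- function(C, k, attention) {
  ck <- C %/% k
  total <- tally_conv(C, C, 1) + tally_bn(C)           # reduce
  for (i in 2:k) {
    cin <- if (i == 2 || !attention) ck else 2 * ck
    total <- total + tally_conv(ck, cin, 3) + tally_bn(ck)
  }
  if (attention && k >= 3) {
    total <- total + (k - 2) * tally_conv(ck, ck, 1)    # gates
  }
  total + tally_conv(C, C, 1) + tally_bn(C)             # fuse
}

# Small random binary mask helper.
random_mask <- function(h = 16, w = 16, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Tiny deterministic phantom datasets used by the engine tests.
tiny_vessel_dataset <- function(n, hw = 32, seed = 50, noise_sd = 0,
                                max_width = 5) {
  gen_dataset(phantom_spec(size = c(hw, hw), task = "vessel",
                           max_width = max_width, noise_sd = noise_sd,
                           seed = seed), n)
}
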