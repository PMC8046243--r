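# Seeded synthetic phantoms with the statistical structure of the four
# segmentation tasks: branching curvilinear vessels on a disc field of view,
# large smooth lung-like blobs, 5-class concentric blastocyst rings, and a
# 3-class artery/vein variant with two interleaved vessel trees.
#
# Vessel trees are grown as a queue of tapering segments: each segment is a
# midpoint-displaced polyline whose stroke width decays by a factor drawn
# from 0.7-0.9 along the tree, sprouting side branches until the width falls
# below one pixel or the segment budget runs out. The budget is sized so the
# vasculature covers roughly 10-20% of the field of view (the density of
# real fundus vasculature) with a long-tailed width histogram.

#' Phantom specification
#'
#' @param size (H, W) image size in pixels.
#' @param task One of `"vessel"`, `"lung"`, `"av"`, `"blastocyst"`.
#' @param max_width Trunk stroke width in pixels (vessel tasks); branch
#'   widths taper from this value down to 1.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise;
#'   background texture amplitude scales with it, so `noise_sd = 0` yields a
#'   clean high-contrast image.
#' @param n_branches Number of primary vessel trunks sprouting from the
#'   periphery (vessel tasks).
#' @param seed Generator seed; equal seeds give identical samples.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         task = c("vessel", "lung", "av", "blastocyst"),
                         max_width = 10, noise_sd = 0.05, n_branches = 3L,
                         seed = 1L) {
  task <- match.arg(task)
  if (max_width < 1) stop("max_width must be >= 1 pixel")
  structure(list(size = as.integer(size), task = task,
                 max_width = max_width, noise_sd = noise_sd,
                 n_branches = as.integer(n_branches),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

disc_fov <- function(h, w, frac = 0.47) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- frac * min(h, w)
  i <- matrix(seq_len(h), h, w); j <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((i - cy)^2 + (j - cx)^2 <= r^2), h, w)
}

# Distance from every pixel in a bounding box to the segment (a, b);
# accumulates stroke coverage (anti-aliased alpha) and the hard mask.
stamp_segment <- function(acc, a, b, w_start, w_end) {
  h <- nrow(acc$alpha); w <- ncol(acc$alpha)
  wmax <- max(w_start, w_end)
  lo_i <- max(1L, floor(min(a[1], b[1]) - wmax / 2 - 2))
  hi_i <- min(h, ceiling(max(a[1], b[1]) + wmax / 2 + 2))
  lo_j <- max(1L, floor(min(a[2], b[2]) - wmax / 2 - 2))
  hi_j <- min(w, ceiling(max(a[2], b[2]) + wmax / 2 + 2))
  if (lo_i > hi_i || lo_j > hi_j) return(acc)
  ii <- matrix(lo_i:hi_i, hi_i - lo_i + 1L, hi_j - lo_j + 1L)
  jj <- matrix(lo_j:hi_j, hi_i - lo_i + 1L, hi_j - lo_j + 1L, byrow = TRUE)
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) matrix(0, nrow(ii), ncol(ii)) else {
    pmin(1, pmax(0, ((ii - a[1]) * vx + (jj - a[2]) * vy) / len2))
  }
  d <- sqrt((ii - (a[1] + t * vx))^2 + (jj - (a[2] + t * vy))^2)
  wloc <- w_start + t * (w_end - w_start)   # width tapers along the segment
  alpha <- pmin(1, pmax(0, wloc / 2 + 0.5 - d))
  sub_a <- acc$alpha[lo_i:hi_i, lo_j:hi_j]
  acc$alpha[lo_i:hi_i, lo_j:hi_j] <- pmax(sub_a, alpha)
  sub_m <- acc$mask[lo_i:hi_i, lo_j:hi_j]
  acc$mask[lo_i:hi_i, lo_j:hi_j] <- pmax(sub_m, as.integer(d <= wloc / 2))
  acc
}

# Midpoint-displaced polyline from a to b; returns the list of vertices.
displaced_polyline <- function(rng, a, b, levels = 2L, amp = 0.12) {
  pts <- list(a, b)
  for (l in seq_len(levels)) {
    new_pts <- list(pts[[1]])
    for (i in seq_len(length(pts) - 1L)) {
      p <- pts[[i]]; q <- pts[[i + 1L]]
      mid <- (p + q) / 2
      seg <- q - p
      nrm <- c(-seg[2], seg[1])
      mid <- mid + nrm * rng_rnorm(rng, 1, 0, amp / l)
      new_pts <- c(new_pts, list(mid, q))
    }
    pts <- new_pts
  }
  pts
}

# Grow one vessel tree into the accumulator.
grow_tree <- function(rng, acc, start, dir, width, fov, min_len, max_segments = 4L) {
  queue <- list(list(p = start, dir = dir, w = width))
  segs <- 0L
  h <- nrow(acc$alpha); w_img <- ncol(acc$alpha)
  while (length(queue) > 0L && segs < max_segments) {
    nd <- queue[[1]]; queue <- queue[-1]
    if (nd$w < 1) next
    len <- min_len * rng_runif(rng, 1, 0.8, 1.4)
    turn <- rng_rnorm(rng, 1, 0, 0.25)
    dir2 <- c(cos(turn) * nd$dir[1] - sin(turn) * nd$dir[2],
              sin(turn) * nd$dir[1] + cos(turn) * nd$dir[2])
    endp <- nd$p + len * dir2
    decay <- rng_runif(rng, 1, 0.7, 0.9)
    w_end <- max(nd$w * decay, 0.8)
    pts <- displaced_polyline(rng, nd$p, endp, levels = 2L, amp = 0.08 * len)
    npts <- length(pts)
    for (i in seq_len(npts - 1L)) {
      t0 <- (i - 1) / (npts - 1); t1 <- i / (npts - 1)
      acc <- stamp_segment(acc, pts[[i]], pts[[i + 1L]],
                           nd$w + t0 * (w_end - nd$w),
                           nd$w + t1 * (w_end - nd$w))
    }
    segs <- segs + 1L
    inside <- endp[1] >= 1 && endp[1] <= h && endp[2] >= 1 && endp[2] <= w_img &&
      fov[max(1L, min(h, round(endp[1]))), max(1L, min(w_img, round(endp[2])))] == 1L
    if (!inside || w_end < 1) next
    # continue the trunk and, sometimes, sprout a side branch
    queue <- c(queue, list(list(p = endp, dir = dir2, w = w_end)))
    if (rng_runif(rng, 1) < 0.35) {
      side <- sample_sign(rng) * rng_runif(rng, 1, 0.4, 0.9)
      dir3 <- c(cos(side) * dir2[1] - sin(side) * dir2[2],
                sin(side) * dir2[1] + cos(side) * dir2[2])
      queue <- c(queue, list(list(p = endp, dir = dir3,
                                  w = w_end * rng_runif(rng, 1, 0.55, 0.8))))
    }
  }
  acc
}

sample_sign <- function(rng) if (rng_runif(rng, 1) < 0.5) -1 else 1

smooth_noise <- function(rng, h, w, sd, sigma = 6) {
  if (sd <= 0) return(matrix(0, h, w))
  n <- matrix(rng_rnorm(rng, h * w, 0, 1), h, w)
  # the Gaussian brush (2*ceiling(3*sigma)+1 wide) must fit in the image
  sigma <- min(sigma, (min(h, w) - 2) / 6)
  f <- EBImage::gblur(EBImage::Image(t(n)), sigma = sigma)
  sm <- t(EBImage::imageData(f))
  sm <- sm / max(stats::sd(sm), 1e-9) * sd
  sm
}

vessel_canvas <- function(rng, spec) {
  h <- spec$size[1]; w <- spec$size[2]
  if (spec$max_width >= min(h, w) / 4) {
    stop("max_width (", spec$max_width, ") must be below min(H, W)/4")
  }
  fov <- disc_fov(h, w)
  bg <- 0.85 + smooth_noise(rng, h, w, spec$noise_sd * 0.6, sigma = 10)
  list(fov = fov, bg = bg, h = h, w = w)
}

one_tree <- function(rng, spec, fov) {
  h <- spec$size[1]; w <- spec$size[2]
  acc <- list(alpha = matrix(0, h, w), mask = matrix(0L, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- 0.42 * min(h, w)
  for (b in seq_len(spec$n_branches)) {
    theta <- rng_runif(rng, 1, 0, 2 * pi)
    start <- c(cy + r * sin(theta), cx + r * cos(theta))
    dir <- c(cy - start[1], cx - start[2])
    dir <- dir / sqrt(sum(dir^2))
    acc <- grow_tree(rng, acc, start, dir, spec$max_width, fov,
                     min_len = 0.08 * min(h, w))
  }
  acc$mask <- acc$mask * fov
  acc$alpha <- acc$alpha * fov
  acc
}

#' Generate a synthetic vessel (or artery/vein) phantom
#'
#' Draws one (vessel) or two interleaved (av) branching trees of dark
#' anti-aliased strokes on a bright textured disc field of view, with widths
#' tapering from `max_width` down to ~1 pixel, plus additive Gaussian noise.
#' The mask is binary for `task = "vessel"` and 3-class
#' (0 background / 1 artery / 2 vein) for `task = "av"`.
#'
#' @param spec A [phantom_spec()] with task `"vessel"` or `"av"`.
#' @return A [new_sample()] with a disc FOV.
#' @export
gen_vessel <- function(spec) {
  if (!spec$task %in% c("vessel", "av")) {
    stop("gen_vessel handles tasks 'vessel' and 'av'")
  }
  rng <- sanet_rng(spec$seed)
  cv <- vessel_canvas(rng, spec)
  if (spec$task == "vessel") {
    acc <- one_tree(rng, spec, cv$fov)
    img <- cv$bg - 0.55 * acc$alpha
    mask <- acc$mask
  } else {
    art <- one_tree(rng, spec, cv$fov)
    vei <- one_tree(rng, spec, cv$fov)
    img <- cv$bg - 0.35 * art$alpha
    img <- img - 0.6 * vei$alpha * (1 - 0.5 * art$alpha)
    mask <- art$mask
    mask[vei$mask == 1L] <- 2L  # veins drawn over arteries at crossings
  }
  img <- img + matrix(rng_rnorm(rng, cv$h * cv$w, 0, spec$noise_sd), cv$h, cv$w)
  img[img < 0] <- 0; img[img > 1] <- 1
  img[cv$fov == 0L] <- 0
  new_sample(img, mask, cv$fov, id = paste0(spec$task, "_", spec$seed))
}

wobbly_disc <- function(rng, h, w, cy, cx, r0, wobble = 0.2, nmodes = 3L) {
  i <- matrix(seq_len(h), h, w); j <- matrix(seq_len(w), h, w, byrow = TRUE)
  di <- i - cy; dj <- j - cx
  theta <- atan2(di, dj)
  rr <- matrix(r0, h, w)
  for (m in 2:(nmodes + 1L)) {
    rr <- rr + r0 * wobble / nmodes *
      rng_rnorm(rng, 1) * cos(m * theta + rng_runif(rng, 1, 0, 2 * pi))
  }
  sqrt(di^2 + dj^2) <= rr
}

#' Generate a synthetic lung phantom
#'
#' Two large smooth bright blobs (wobbly ellipse-like discs) on a dark noisy
#' background; the mask is their binary union.
#'
#' @param spec A [phantom_spec()] with task `"lung"`.
#' @return A [new_sample()] without FOV.
#' @export
gen_lung <- function(spec) {
  if (spec$task != "lung") stop("gen_lung expects task 'lung'")
  rng <- sanet_rng(spec$seed)
  h <- spec$size[1]; w <- spec$size[2]
  m <- min(h, w)
  left <- wobbly_disc(rng, h, w, cy = h * rng_runif(rng, 1, 0.45, 0.55),
                      cx = w * rng_runif(rng, 1, 0.26, 0.32), r0 = 0.19 * m)
  right <- wobbly_disc(rng, h, w, cy = h * rng_runif(rng, 1, 0.45, 0.55),
                       cx = w * rng_runif(rng, 1, 0.68, 0.74), r0 = 0.19 * m)
  mask <- matrix(as.integer(left | right), h, w)
  img <- 0.15 + smooth_noise(rng, h, w, spec$noise_sd * 0.6, sigma = 10) +
    0.6 * mask +
    matrix(rng_rnorm(rng, h * w, 0, spec$noise_sd), h, w)
  img[img < 0] <- 0; img[img > 1] <- 1
  new_sample(img, mask, NULL, id = paste0("lung_", spec$seed))
}

#' Generate a synthetic blastocyst phantom
#'
#' Five concentric noisy regions emulating a blastocyst section: background
#' (0), zona pellucida ring (1), trophectoderm ring (2), blastocoel interior
#' (3) and an inner-cell-mass pocket (4). All five labels are present in
#' every sample.
#'
#' @param spec A [phantom_spec()] with task `"blastocyst"`.
#' @return A [new_sample()] without FOV.
#' @export
gen_blastocyst <- function(spec) {
  if (spec$task != "blastocyst") stop("gen_blastocyst expects task 'blastocyst'")
  rng <- sanet_rng(spec$seed)
  h <- spec$size[1]; w <- spec$size[2]
  m <- min(h, w)
  cy <- h * rng_runif(rng, 1, 0.47, 0.53); cx <- w * rng_runif(rng, 1, 0.47, 0.53)
  zp_out <- wobbly_disc(rng, h, w, cy, cx, 0.42 * m, wobble = 0.06)
  zp_in <- wobbly_disc(rng, h, w, cy, cx, 0.345 * m, wobble = 0.06)
  te_in <- wobbly_disc(rng, h, w, cy, cx, 0.27 * m, wobble = 0.08)
  ang <- rng_runif(rng, 1, 0, 2 * pi)
  icm <- wobbly_disc(rng, h, w, cy + 0.12 * m * sin(ang),
                     cx + 0.12 * m * cos(ang), 0.09 * m, wobble = 0.15)
  icm <- icm & te_in
  mask <- matrix(0L, h, w)
  mask[zp_out & !zp_in] <- 1L
  mask[zp_in & !te_in] <- 2L
  mask[te_in] <- 3L
  mask[icm] <- 4L
  tone <- c(0.12, 0.75, 0.45, 0.3, 0.85)
  img <- matrix(tone[mask + 1L], h, w) +
    smooth_noise(rng, h, w, spec$noise_sd * 0.6, sigma = 8) +
    matrix(rng_rnorm(rng, h * w, 0, spec$noise_sd), h, w)
  img[img < 0] <- 0; img[img > 1] <- 1
  new_sample(img, mask, NULL, id = paste0("blastocyst_", spec$seed))
}

#' Generate a phantom for any task
#' @param spec A [phantom_spec()].
#' @export
gen_sample <- function(spec) {
  switch(spec$task,
         vessel = , av = gen_vessel(spec),
         lung = gen_lung(spec),
         blastocyst = gen_blastocyst(spec))
}

#' Generate a dataset of n phantoms
#'
#' Sample i uses seed `spec$seed + i - 1`; group labels alternate between
#' `"left"` and `"right"` so stratified splitting is exercised.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of samples (>= 1).
#' @return List of [new_sample()] objects.
#' @export
gen_dataset <- function(spec, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- spec$seed + i - 1L
    out <- gen_sample(s)
    out$group_label <- if (i %% 2L == 1L) "left" else "right"
    out$id <- paste0(out$id, "_", i)
    out
  })
}
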