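# Sample containers, raster I/O, fundus preprocessing, rotation-only
# augmentation, stratified fold assignment and the skeleton-based vessel
# diameter profile.

#' Construct a segmentation sample
#'
#' @param image (H, W) grayscale matrix in \[0, 1\] or (H, W, 3) RGB array.
#' @param mask Integer label matrix (H, W).
#' @param fov Optional binary field-of-view matrix (H, W).
#' @param group_label Categorical label used for stratified fold assignment
#'   (e.g. eye side).
#' @param id Sample identifier string.
#' @return Object of class `sanet_sample`.
#' @export
new_sample <- function(image, mask, fov = NULL, group_label = NA_character_,
                       id = "sample") {
  hw <- dim(image)[1:2]
  if (!identical(dim(mask), hw)) stop("image/mask shape mismatch for ", id)
  if (!is.null(fov) && !identical(dim(fov), hw)) {
    stop("image/fov shape mismatch for ", id)
  }
  structure(list(image = image, mask = matrix(as.integer(round(mask)),
                                              hw[1], hw[2]),
                 fov = fov, group_label = group_label, id = id),
            class = "sanet_sample")
}

read_raster <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
}

#' Read a sample from the standard directory layout
#'
#' Expects `images/<id>.(png|tif|tiff)`, `masks/<id>.png` and optionally
#' `fov/<id>.png` under `dir`. Label masks are 8-bit PNGs whose pixel values
#' are the integer labels; reading inverts the PNG \[0, 1\] scaling.
#'
#' @param dir Dataset root directory.
#' @param id Sample stem.
#' @param group_label Optional stratification label.
#' @return A [new_sample()].
#' @export
read_sample <- function(dir, id, group_label = NA_character_) {
  img_path <- NULL
  for (ext in c("png", "tif", "tiff")) {
    cand <- file.path(dir, "images", paste0(id, ".", ext))
    if (file.exists(cand)) { img_path <- cand; break }
  }
  if (is.null(img_path)) stop("no image found for id '", id, "' under ", dir)
  image <- read_raster(img_path)
  if (length(dim(image)) == 3L && dim(image)[3] == 4L) {
    image <- image[, , 1:3]  # drop alpha
  }
  mask_path <- file.path(dir, "masks", paste0(id, ".png"))
  if (!file.exists(mask_path)) stop("missing mask for id '", id, "'")
  mask <- round(png::readPNG(mask_path) * 255)
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  fov_path <- file.path(dir, "fov", paste0(id, ".png"))
  fov <- if (file.exists(fov_path)) {
    f <- png::readPNG(fov_path)
    if (length(dim(f)) == 3L) f <- f[, , 1]
    matrix(as.integer(f > 0.5), nrow(f), ncol(f))
  } else NULL
  new_sample(image, mask, fov, group_label, id)
}

#' Write a label mask as an 8-bit PNG
#'
#' Stores the integer labels in the pixel values; [read_sample()] recovers
#' them exactly (labels must be below 256).
#'
#' @param mask Integer label matrix.
#' @param path Output file.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 255L) stop("labels above 255 cannot be stored in 8-bit PNG")
  png::writePNG(matrix(as.integer(mask), nrow(mask), ncol(mask)) / 255, path)
  invisible(path)
}

#' Write a sample into the standard directory layout
#' @param sample A [new_sample()].
#' @param dir Dataset root; `images/`, `masks/` (and `fov/`) are created.
#' @export
write_sample <- function(sample, dir) {
  for (sub in c("images", "masks")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  png::writePNG(sample$image, file.path(dir, "images", paste0(sample$id, ".png")))
  write_mask(sample$mask, file.path(dir, "masks", paste0(sample$id, ".png")))
  if (!is.null(sample$fov)) {
    dir.create(file.path(dir, "fov"), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(matrix(as.numeric(sample$fov != 0), nrow(sample$fov),
                         ncol(sample$fov)),
                  file.path(dir, "fov", paste0(sample$id, ".png")))
  }
  invisible(dir)
}

#' Fundus preprocessing: grayscale conversion + local contrast enhancement
#'
#' RGB images are converted to luminance with Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B) and passed through contrast-limited
#' adaptive histogram equalization (CLAHE), then rescaled to \[0, 1\].
#' Non-RGB inputs pass through unchanged.
#'
#' @param sample A [new_sample()].
#' @param clip CLAHE clip limit.
#' @param tiles Number of CLAHE tiles per axis.
#' @return The sample with a single-channel image.
#' @export
preprocess_fundus <- function(sample, clip = 2, tiles = 8L) {
  img <- sample$image
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) return(sample)
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  rng <- range(gray)
  if (rng[2] > rng[1]) {
    eq <- EBImage::clahe(EBImage::Image(t(gray)), nx = tiles, ny = tiles,
                         limit = clip)
    gray <- t(EBImage::imageData(eq))
    rng <- range(gray)
    if (rng[2] > rng[1]) gray <- (gray - rng[1]) / (rng[2] - rng[1])
  }
  gray[gray < 0] <- 0; gray[gray > 1] <- 1
  sample$image <- gray
  sample
}

# Rotate a matrix about its centre by `angle` degrees (counter-clockwise in
# standard orientation). Inverse mapping; bilinear or nearest-neighbour
# interpolation; canvas preserved; exposed regions filled with `fill`.
rotate_matrix <- function(m, angle, bilinear = TRUE, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  i <- matrix(seq_len(h), h, w)
  j <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse rotation of output coordinates into the source frame
  di <- i - cy; dj <- j - cx
  si <- cos(th) * di - sin(th) * dj + cy
  sj <- sin(th) * di + cos(th) * dj + cx
  out <- matrix(fill, h, w)
  if (bilinear) {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    val <- matrix(0, h, w); wsum <- matrix(0, h, w)
    for (da in 0:1) for (db in 0:1) {
      ii <- i0 + da; jj <- j0 + db
      wt <- (if (da == 0) 1 - fi else fi) * (if (db == 0) 1 - fj else fj)
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      idx <- cbind(ii[ok], jj[ok])
      val[ok] <- val[ok] + wt[ok] * m[idx]
      wsum[ok] <- wsum[ok] + wt[ok]
    }
    inside <- wsum > 1e-9
    out[inside] <- val[inside] / wsum[inside]
  } else {
    ii <- round(si); jj <- round(sj)
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    out[ok] <- m[cbind(ii[ok], jj[ok])]
  }
  out
}

#' Rotate a sample by a random (or forced) angle
#'
#' Image, mask and FOV rotate jointly by the same angle about the image
#' centre: the image bilinearly, mask and FOV by nearest neighbour (so the
#' label set can only shrink). The canvas is preserved and exposed corners
#' are filled with background (0).
#'
#' @param sample A [new_sample()].
#' @param rng A [sanet_rng()] stream; the angle is drawn uniformly from
#'   \[0, 360) degrees.
#' @param angle Optional forced angle in degrees (overrides `rng`).
#' @return The rotated sample.
#' @export
augment_rotation <- function(sample, rng = sanet_rng(0L), angle = NULL) {
  if (is.null(angle)) angle <- rng_runif(rng, 1, 0, 360)
  if (angle %% 360 == 0) return(sample)
  img <- sample$image
  if (length(dim(img)) == 3L) {
    for (ch in seq_len(dim(img)[3])) {
      img[, , ch] <- rotate_matrix(img[, , ch], angle, bilinear = TRUE)
    }
  } else {
    img <- rotate_matrix(img, angle, bilinear = TRUE)
  }
  sample$image <- img
  sample$mask <- matrix(as.integer(rotate_matrix(sample$mask, angle,
                                                 bilinear = FALSE)),
                        nrow(sample$mask), ncol(sample$mask))
  if (!is.null(sample$fov)) {
    sample$fov <- matrix(as.integer(rotate_matrix(sample$fov, angle,
                                                  bilinear = FALSE)),
                         nrow(sample$fov), ncol(sample$fov))
  }
  sample
}

#' Stratified k-fold assignment
#'
#' Samples are partitioned into k folds of as-equal-as-possible size, with
#' each `group_label` spread across folds as evenly as the arithmetic
#' allows: within each group, shuffled members are dealt round-robin,
#' with the starting fold rotated between groups to balance totals.
#'
#' @param samples List of [new_sample()] objects (or a data.frame with
#'   columns `id` and `group_label`).
#' @param k Number of folds (2 <= k <= n).
#' @param seed Shuffling seed; the assignment is deterministic given it.
#' @return Data frame with columns `identifier` and `fold` (1..k).
#' @export
make_folds <- function(samples, k, seed = 1L) {
  if (is.data.frame(samples)) {
    ids <- as.character(samples$id)
    groups <- as.character(samples$group_label)
  } else {
    ids <- vapply(samples, function(s) s$id, character(1))
    groups <- vapply(samples, function(s) as.character(s$group_label),
                     character(1))
  }
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (anyDuplicated(ids)) stop("duplicate sample identifiers")
  rng <- sanet_rng(seed)
  groups[is.na(groups)] <- "<none>"
  fold <- integer(n)
  offset <- 0L
  for (g in sort(unique(groups))) {
    members <- which(groups == g)
    members <- members[rng_sample(rng, seq_along(members))]
    fold[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
    offset <- (offset + length(members)) %% k
  }
  data.frame(identifier = ids, fold = fold, stringsAsFactors = FALSE)
}

#' Write / read a fold assignment as CSV
#' @param folds A [make_folds()] result.
#' @param path CSV file path.
#' @export
write_folds <- function(folds, path) {
  utils::write.csv(folds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Zhang-Suen morphological thinning, vectorized over the whole image.
# The classic simultaneous-deletion rule erases an isolated 2x2 block (a
# known artifact, e.g. the last remnant of a filled disc); a guard keeps the
# deepest pixel (largest distance to background) whenever a pass would
# delete every remaining foreground pixel.
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  h <- nrow(img); w <- ncol(img)
  if (sum(img) == 0L) return(img)
  edt <- EBImage::distmap(img, metric = "euclidean")
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  shift <- function(m, di, dj) m[2:(h + 1L) + di, 2:(w + 1L) + dj]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad[2:(h + 1L), 2:(w + 1L)]
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- p == 1L & b >= 2L & b <= 6L & a == 1L
      cond <- cond & if (step == 1) {
        (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        inner <- pad[2:(h + 1L), 2:(w + 1L)]
        if (sum(inner) == sum(cond)) {
          # the pass would delete everything: keep the deepest pixel
          keep <- which(cond & edt == max(edt[cond]))[1]
          cond[keep] <- FALSE
        }
        if (any(cond)) {
          changed <- TRUE
          inner[cond] <- 0L
          pad[2:(h + 1L), 2:(w + 1L)] <- inner
        }
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L)]
}

#' Skeleton-based vessel diameter profile
#'
#' Computes the morphological skeleton of a binary mask (Zhang-Suen
#' thinning) and, at every skeleton pixel, the local vessel diameter
#' `2 * EDT - 1` in pixel units, where EDT is the Euclidean distance to the
#' nearest background pixel (a width-w straight strip yields exactly w at
#' its centreline). Returns the diameters with a binned histogram.
#'
#' @param mask Binary vessel mask.
#' @param bins Number of equal-width histogram bins.
#' @return Object of class `diameter_profile`: list with `skeleton`
#'   (binary matrix), `diameters` (one value per skeleton pixel, >= 1) and
#'   `histogram` (list with `mids`, `counts`, `breaks`; counts sum to the
#'   number of skeleton pixels).
#' @export
diameter_profile <- function(mask, bins = 32L) {
  bin <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(bin) == 0L) {
    return(structure(list(skeleton = bin, diameters = numeric(0),
                          histogram = list(mids = numeric(0),
                                           counts = integer(0),
                                           breaks = numeric(0))),
                     class = "diameter_profile"))
  }
  skel <- skeletonize(bin)
  edt <- EBImage::distmap(bin, metric = "euclidean")
  diam <- 2 * edt[skel == 1L] - 1
  if (length(diam)) {
    breaks <- seq(min(diam) - 0.5, max(diam) + 0.5, length.out = bins + 1L)
    hs <- graphics::hist(diam, breaks = breaks, plot = FALSE)
    histogram <- list(mids = hs$mids, counts = hs$counts, breaks = hs$breaks)
  } else {
    histogram <- list(mids = numeric(0), counts = integer(0),
                      breaks = numeric(0))
  }
  structure(list(skeleton = skel, diameters = diam, histogram = histogram),
            class = "diameter_profile")
}
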