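# Training loop (Adam + L2 weight decay, per-batch rotation augmentation),
# plateau-based epoch selection, prediction and task-specific evaluation.

#' Training configuration
#'
#' @param max_epochs Maximum number of passes over the data.
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam step size.
#' @param optimizer_name Only `"adam"` is provided.
#' @param loss A [loss_config()].
#' @param plateau_window Trailing window (epochs) for final-epoch selection.
#' @param plateau_tolerance Maximum loss fluctuation (max - min) within the
#'   window for it to count as a plateau.
#' @param seed Seed controlling shuffling, augmentation angles and any other
#'   training randomness.
#' @param threshold Probability threshold for binary prediction.
#' @param augment Apply per-batch random rotation augmentation.
#' @export
train_config <- function(max_epochs = 50L, batch_size = 2L,
                         learning_rate = 1e-3, optimizer_name = "adam",
                         loss = loss_config(), plateau_window = 20L,
                         plateau_tolerance = 0.01, seed = 1L,
                         threshold = 0.5, augment = TRUE) {
  if (plateau_window < 1L) stop("plateau_window must be >= 1")
  if (plateau_tolerance <= 0) stop("plateau_tolerance must be > 0")
  if (optimizer_name != "adam") stop("unsupported optimizer: ", optimizer_name)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name, loss = loss,
                 plateau_window = as.integer(plateau_window),
                 plateau_tolerance = plateau_tolerance,
                 seed = as.integer(seed), threshold = threshold,
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Select the final epoch from a training-loss history
#'
#' Returns the last epoch e (1-based) whose trailing window of `window`
#' epochs fluctuates less than `tolerance` (max - min strictly below it).
#' If no window qualifies, the last epoch is returned as a fallback.
#'
#' @param losses Per-epoch mean training losses.
#' @param window Window length in epochs.
#' @param tolerance Fluctuation bound.
#' @return 1-based epoch index.
#' @export
select_final_epoch <- function(losses, window = 20L, tolerance = 0.01) {
  n <- length(losses)
  if (n == 0L) stop("empty loss history")
  qual <- vapply(seq_len(n), function(e) {
    e >= window && {
      w <- losses[(e - window + 1L):e]
      (max(w) - min(w)) < tolerance
    }
  }, logical(1))
  if (any(qual)) max(which(qual)) else n
}

# ---- batch assembly --------------------------------------------------------

sample_channels <- function(s) {
  if (length(dim(s$image)) == 3L) dim(s$image)[3] else 1L
}

samples_to_batch <- function(samples) {
  n <- length(samples)
  hw <- dim(samples[[1]]$image)[1:2]
  cin <- sample_channels(samples[[1]])
  x <- array(0, dim = c(n, cin, hw[1], hw[2]))
  y <- array(0L, dim = c(n, hw[1], hw[2]))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    if (cin == 1L) x[i, 1, , ] <- img
    else for (ch in seq_len(cin)) x[i, ch, , ] <- img[, , ch]
    y[i, , ] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

# ---- optimizer -------------------------------------------------------------

adam_state <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0), how = "replace",
         classes = c("numeric", "array", "matrix"))
}

# One Adam step over the nested parameter list. `grads` mirrors `params`.
# L2 weight decay enters through the gradient (d/dw beta*||W||^2 = 2*beta*w).
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(p)) && !is.numeric(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    gg <- g + 2 * l2 * p
    m <- beta1 * s$m + (1 - beta1) * gg
    v <- beta2 * s$v + (1 - beta2) * gg^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

# Harvest gradients from wrapped parameter nodes into a mirror list.
harvest_grads <- function(pn) {
  rapply(pn, function(nd) {
    if (is.null(nd$grad)) nd$value * 0 else nd$grad
  }, how = "replace", classes = "environment")
}

# ---- training --------------------------------------------------------------

#' Train a segmentation model
#'
#' Minimizes cross-entropy + beta * ||W||^2 with Adam, shuffling samples
#' each epoch and (optionally) rotating every batch by one random angle.
#' The per-epoch mean training loss is recorded; the returned weights are
#' those of the epoch chosen by [select_final_epoch()] (a snapshot is kept
#' whenever the trailing window qualifies as a plateau, falling back to the
#' final epoch).
#'
#' @param model A [build_model()] result.
#' @param dataset List of [new_sample()] objects with equal image sizes.
#' @param cfg A [train_config()].
#' @param verbose Emit one structured log line per epoch to stderr.
#' @return List with `model` (weights at the selected epoch) and `history`
#'   (list with `losses` and `selected_epoch`).
#' @export
train <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  rng <- sanet_rng(cfg$seed)
  opt <- adam_state(model$params)
  losses <- numeric(0)
  snap <- NULL; snap_epoch <- NA_integer_
  t_step <- 0L
  n <- length(dataset)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- rng_sample(rng, seq_len(n))
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      batch_samples <- dataset[idx]
      if (cfg$augment) {
        angle <- rng_runif(rng, 1, 0, 360)
        batch_samples <- lapply(batch_samples, augment_rotation, angle = angle)
      }
      b <- samples_to_batch(batch_samples)
      tape <- ag_tape()
      g <- model_graph(model, tape, ag_leaf(tape, b$x), training = TRUE)
      loss_node <- ag_nll_prob(tape, g$prob, b$y)
      total <- loss_node$value + cfg$loss$beta * weight_sq_norm(model$params)
      if (!is.finite(total)) {
        stop("non-finite training loss at epoch ", epoch,
             " (cross-entropy = ", loss_node$value, ")")
      }
      ag_backward(tape, loss_node)
      grads <- harvest_grads(g$pn)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, opt, cfg$learning_rate, t_step,
                       l2 = cfg$loss$beta)
      model$params <- upd$p
      opt <- upd$s
      batch_losses <- c(batch_losses, total)
    }
    losses <- c(losses, mean(batch_losses))
    if (verbose) {
      message(sprintf("epoch=%d loss=%.6f", epoch, losses[epoch]))
    }
    e <- length(losses)
    if (e >= cfg$plateau_window) {
      w <- losses[(e - cfg$plateau_window + 1L):e]
      if ((max(w) - min(w)) < cfg$plateau_tolerance) {
        snap <- snapshot_model(model)
        snap_epoch <- e
      }
    }
  }
  selected <- select_final_epoch(losses, cfg$plateau_window,
                                 cfg$plateau_tolerance)
  final <- if (!is.na(snap_epoch) && snap_epoch == selected) snap
           else snapshot_model(model)
  if (verbose) message(sprintf("selected_epoch=%d", selected))
  list(model = final,
       history = list(losses = losses, selected_epoch = selected))
}

snapshot_model <- function(model) {
  clone_env <- function(e) {
    e2 <- new.env(parent = emptyenv())
    for (key in ls(e, all.names = TRUE)) {
      v <- e[[key]]
      e2[[key]] <- if (is.environment(v)) clone_env(v) else v
    }
    e2
  }
  out <- list(config = model$config, params = model$params,
              state = clone_env(model$state))
  class(out) <- "sanet_model"
  out
}

#' Predict masks and probability maps for a list of samples
#'
#' Runs the model in evaluation mode on each sample. Binary tasks are
#' thresholded with [binarize()]; multi-class tasks take the per-pixel
#' argmax. Pixels outside a sample's FOV are set to background.
#'
#' @param model A trained `sanet_model`.
#' @param samples List of [new_sample()] objects.
#' @param threshold Foreground threshold for binary tasks.
#' @return List with `masks` and `probs` (per-sample lists; each probability
#'   map is (num_classes, H, W)).
#' @export
predict_samples <- function(model, samples, threshold = 0.5) {
  nc <- model$config$num_classes
  masks <- vector("list", length(samples))
  probs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    b <- samples_to_batch(list(s))
    p <- forward(model, b$x, training = FALSE)
    d <- dim(p)
    pm <- array(p[1, , , ], dim = d[2:4])
    mk <- if (nc == 2L) {
      binarize(pm, threshold)
    } else {
      apply(pm, c(2, 3), which.max) - 1L
    }
    if (!is.null(s$fov)) mk[s$fov == 0L] <- 0L
    masks[[i]] <- matrix(as.integer(mk), d[3], d[4])
    probs[[i]] <- pm
  }
  list(masks = masks, probs = probs)
}

#' Evaluate predictions with the task-appropriate metric suite
#'
#' Confusion counts are pooled over all scored pixels of all images
#' (micro-averaging); AUC is computed on the pooled in-FOV scores.
#'
#' Suites: `vessel` = se/sp/acc/mcc/f1/auc; `lung` = e/acc/se;
#' `av` = bacc/se_av/sp_av/f1_a/f1_v (scored on ground-truth vessel pixels,
#' arteries positive); `blastocyst` = per-class Jaccard + mean.
#'
#' @param pred_masks,probs Lists from [predict_samples()].
#' @param truths List of ground-truth label matrices.
#' @param fovs List of FOV matrices (or NULLs).
#' @param task One of `"vessel"`, `"lung"`, `"av"`, `"blastocyst"`.
#' @return Named list of metrics.
#' @export
evaluate <- function(pred_masks, probs, truths, fovs = NULL,
                     task = c("vessel", "lung", "av", "blastocyst")) {
  task <- match.arg(task)
  n <- length(pred_masks)
  if (length(truths) != n) stop("pred/truth count mismatch")
  if (is.null(fovs)) fovs <- vector("list", n)
  if (task == "vessel") {
    cs <- lapply(seq_len(n), function(i) {
      confusion(pred_masks[[i]], truths[[i]], fovs[[i]])
    })
    pooled <- pool_confusion(cs)
    bm <- basic_metrics(pooled)
    scores <- unlist(lapply(seq_len(n), function(i) {
      s <- c(foreground_prob(probs[[i]]))
      if (!is.null(fovs[[i]])) s[c(fovs[[i]] != 0)] else s
    }))
    labs <- unlist(lapply(seq_len(n), function(i) {
      t <- c(truths[[i]] != 0)
      if (!is.null(fovs[[i]])) t[c(fovs[[i]] != 0)] else t
    }))
    r <- rank(scores, ties.method = "average")
    npos <- sum(labs); nneg <- sum(!labs)
    bm$auc <- (sum(r[labs]) - npos * (npos + 1) / 2) / (npos * nneg)
    bm[c("se", "sp", "acc", "mcc", "f1", "auc")]
  } else if (task == "lung") {
    pooled <- pool_confusion(lapply(seq_len(n), function(i) {
      confusion(pred_masks[[i]], truths[[i]], fovs[[i]])
    }))
    bm <- basic_metrics(pooled)
    e <- 1 - safe_div(as.numeric(pooled$tp),
                      as.numeric(pooled$tp + pooled$fp + pooled$fn), 1)
    list(e = if (pooled$tp + pooled$fp + pooled$fn == 0) 0 else e,
         acc = bm$acc, se = bm$se)
  } else if (task == "av") {
    cs <- lapply(seq_len(n), function(i) {
      tr <- truths[[i]]
      vessel <- tr == 1L | tr == 2L
      pd <- pred_masks[[i]]
      # arteries positive; a vessel pixel predicted background counts as vein
      confusion(pd == 1L & vessel, tr == 1L & vessel, fov = vessel)
    })
    pooled <- pool_confusion(cs)
    av <- av_metrics(pooled)
    f1a <- basic_metrics(pooled)$f1
    swapped <- structure(list(tp = pooled$tn, tn = pooled$tp,
                              fp = pooled$fn, fn = pooled$fp),
                         class = "confusion_counts")
    f1v <- basic_metrics(swapped)$f1
    list(bacc = av$bacc, se_av = av$se_av, sp_av = av$sp_av,
         f1_a = f1a, f1_v = f1v)
  } else {
    nc <- max(unlist(lapply(truths, max))) + 1L
    pall <- unlist(lapply(pred_masks, c))
    tall <- unlist(lapply(truths, c))
    jc <- jaccard_per_class(pall, tall, nc)
    list(jaccard_per_class = jc$per_class, mean_jaccard = jc$mean)
  }
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the dataset with [make_folds()], trains a freshly initialized
#' model (same configuration and seed every fold) on each training split and
#' evaluates on the held-out fold. Reports per-fold metrics, their mean
#' across folds, and a pooled recomputation over all test pixels.
#'
#' @param dataset List of samples.
#' @param k Number of folds.
#' @param net_config A [network_config()].
#' @param train_cfg A [train_config()].
#' @param task Metric suite passed to [evaluate()].
#' @return List with `per_fold`, `mean` and `pooled`.
#' @export
run_cv <- function(dataset, k, net_config, train_cfg = train_config(),
                   task = "vessel") {
  folds <- make_folds(dataset, k, seed = train_cfg$seed)
  per_fold <- vector("list", k)
  all_masks <- list(); all_probs <- list(); all_truths <- list(); all_fovs <- list()
  for (f in seq_len(k)) {
    test_idx <- which(folds$fold == f)
    train_idx <- which(folds$fold != f)
    model <- build_model(net_config)
    fit <- train(model, dataset[train_idx], train_cfg)
    pr <- predict_samples(fit$model, dataset[test_idx], train_cfg$threshold)
    truths <- lapply(dataset[test_idx], `[[`, "mask")
    fovs <- lapply(dataset[test_idx], `[[`, "fov")
    per_fold[[f]] <- evaluate(pr$masks, pr$probs, truths, fovs, task)
    all_masks <- c(all_masks, pr$masks); all_probs <- c(all_probs, pr$probs)
    all_truths <- c(all_truths, truths); all_fovs <- c(all_fovs, fovs)
  }
  keys <- names(per_fold[[1]])
  mean_metrics <- lapply(keys, function(kk) {
    vals <- lapply(per_fold, `[[`, kk)
    Reduce(`+`, vals) / length(vals)
  })
  names(mean_metrics) <- keys
  pooled <- evaluate(all_masks, all_probs, all_truths, all_fovs, task)
  list(per_fold = per_fold, mean = mean_metrics, pooled = pooled,
       folds = folds)
}
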