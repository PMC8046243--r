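# Training loop, plateau-based epoch selection, prediction and evaluation
# orchestration.

test_that("plateau selection follows the trailing-window rule", {
  # constant history: every trailing window qualifies; last epoch wins
  expect_identical(select_final_epoch(rep(1, 30), 20, 0.01), 30L)
  # strictly decreasing by 0.1: no window qualifies; fall back to the end
  expect_identical(select_final_epoch(seq(3, by = -0.1, length.out = 30),
                                      20, 0.01), 30L)
  # 10 epochs at 1.0 then 25 at 0.5: the last all-flat window ends at 35
  expect_identical(select_final_epoch(c(rep(1, 10), rep(0.5, 25)), 20, 0.01),
                   35L)
  # plateau then a drift: the last window whose range stays under the
  # tolerance ends at epoch 25 (epochs 6-25 are all 0.5; epoch 26 = 0.48)
  losses <- c(rep(1, 5), rep(0.5, 20), seq(0.48, by = -0.02, length.out = 15))
  expect_identical(select_final_epoch(losses, 20, 0.01), 25L)
  # shorter history than the window: fallback
  expect_identical(select_final_epoch(c(0.5, 0.4), 20, 0.01), 2L)
  expect_error(select_final_epoch(numeric(0)), "empty")
})

test_that("training is deterministic and zero learning rate is static", {
  ds <- tiny_vessel_dataset(4, hw = 32, seed = 70)
  cfg <- network_config(depth = 1, base_width = 4, bridge_variant = "sa",
                        k = 4, seed = 2)
  tc <- train_config(max_epochs = 4, batch_size = 2, seed = 3)
  f1 <- train(build_model(cfg), ds, tc)
  f2 <- train(build_model(cfg), ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)

  tc0 <- train_config(max_epochs = 3, batch_size = 4, learning_rate = 0,
                      seed = 3, augment = FALSE)
  f0 <- train(build_model(cfg), ds, tc0)
  expect_lt(diff(range(f0$history$losses)), 1e-12)
})

test_that("all four bridge variants train without divergence", {
  ds <- tiny_vessel_dataset(2, hw = 32, seed = 75)
  for (v in c("none", "resnet", "res2net", "sa")) {
    cfg <- network_config(depth = 1, base_width = 4, bridge_variant = v,
                          k = 4, seed = 2)
    fit <- train(build_model(cfg), ds,
                 train_config(max_epochs = 3, batch_size = 2, seed = 1))
    expect_true(all(is.finite(fit$history$losses)))
  }
})

test_that("prediction obeys the threshold, argmax and FOV contracts", {
  ds <- tiny_vessel_dataset(2, hw = 32, seed = 80)
  cfg <- network_config(depth = 1, base_width = 4, bridge_variant = "none",
                        seed = 2)
  m <- build_model(cfg)
  pr <- predict_samples(m, ds, threshold = 0.5)
  for (i in 1:2) {
    expect_identical(pr$masks[[i]][ds[[i]]$fov == 0L] * 1L,
                     rep(0L, sum(ds[[i]]$fov == 0L)))
    inside <- ds[[i]]$fov == 1L
    expect_identical(pr$masks[[i]][inside],
                     binarize(pr$probs[[i]], 0.5)[inside])
    expect_lt(max(abs(apply(pr$probs[[i]], c(2, 3), sum) - 1)), 1e-6)
  }
  # multi-class: argmax labels below num_classes
  ds5 <- gen_dataset(phantom_spec(size = c(32, 32), task = "blastocyst",
                                  seed = 81), 1)
  m5 <- build_model(network_config(depth = 1, base_width = 4,
                                   num_classes = 5, bridge_variant = "none",
                                   seed = 2))
  pr5 <- predict_samples(m5, ds5)
  expect_true(all(pr5$masks[[1]] %in% 0:4))
})

test_that("perfect predictions score perfectly in every task suite", {
  set.seed(82)
  truth <- list(random_mask(12, 12), random_mask(12, 12))
  probs <- lapply(truth, function(t) {
    p <- array(0, c(2, 12, 12)); p[2, , ] <- t; p[1, , ] <- 1 - t; p
  })
  rv <- evaluate(truth, probs, truth, NULL, "vessel")
  expect_equal(unlist(rv), c(se = 1, sp = 1, acc = 1, mcc = 1, f1 = 1,
                             auc = 1))
  rl <- evaluate(truth, probs, truth, NULL, "lung")
  expect_equal(unlist(rl), c(e = 0, acc = 1, se = 1))
  truth_av <- list(matrix(sample(0:2, 144, TRUE), 12, 12))
  rav <- evaluate(truth_av, list(NULL), truth_av, NULL, "av")
  expect_equal(unlist(rav), c(bacc = 1, se_av = 1, sp_av = 1, f1_a = 1,
                              f1_v = 1))
  truth5 <- list(matrix(sample(0:4, 144, TRUE), 12, 12))
  rb <- evaluate(truth5, list(NULL), truth5, NULL, "blastocyst")
  expect_equal(rb$mean_jaccard, 1)
})

test_that("multi-image evaluation pools confusion counts over pixels", {
  set.seed(83)
  preds <- lapply(1:3, function(i) random_mask(10, 10))
  truths <- lapply(1:3, function(i) random_mask(10, 10))
  probs <- lapply(preds, function(p) {
    pr <- array(0, c(2, 10, 10))
    pr[2, , ] <- pmin(pmax(p + rnorm(100, 0, 0.3), 0), 1)
    pr[1, , ] <- 1 - pr[2, , ]
    pr
  })
  rep3 <- evaluate(preds, probs, truths, NULL, "vessel")
  pooled <- pool_confusion(lapply(1:3, function(i) {
    confusion(preds[[i]], truths[[i]])
  }))
  oracle <- basic_metrics(pooled)
  expect_equal(rep3[c("se", "sp", "acc", "mcc", "f1")],
               oracle[c("se", "sp", "acc", "mcc", "f1")])
  # pooled AUC equals the rank statistic over the concatenated pixels
  all_scores <- unlist(lapply(probs, function(p) c(p[2, , ])))
  all_labs <- unlist(lapply(truths, c))
  expect_equal(rep3$auc, oracle_auc(all_scores, all_labs), tolerance = 1e-9)
})

test_that("cross-validation visits every sample exactly once", {
  ds <- tiny_vessel_dataset(4, hw = 32, seed = 85)
  cfg <- network_config(depth = 1, base_width = 4, bridge_variant = "none",
                        seed = 2)
  res <- run_cv(ds, 2, cfg, train_config(max_epochs = 2, batch_size = 2,
                                         seed = 4))
  expect_identical(sort(res$folds$identifier),
                   sort(vapply(ds, `[[`, character(1), "id")))
  expect_identical(unname(c(table(res$folds$fold))), c(2L, 2L))
  expect_true(all(is.finite(unlist(res$mean))))
  # the fold average is the arithmetic mean of the per-fold reports
  for (kk in names(res$mean)) {
    expect_equal(res$mean[[kk]],
                 mean(vapply(res$per_fold, `[[`, numeric(1), kk)))
  }
})

test_that("checkpoints preserve a trained model's predictions", {
  ds <- tiny_vessel_dataset(2, hw = 32, seed = 86)
  cfg <- network_config(depth = 1, base_width = 4, bridge_variant = "sa",
                        k = 4, seed = 2)
  fit <- train(build_model(cfg), ds,
               train_config(max_epochs = 2, batch_size = 2, seed = 1))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  p1 <- predict_samples(fit$model, ds)
  p2 <- predict_samples(m2, ds)
  expect_identical(p1$probs, p2$probs)
})
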