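# Evaluation statistics, each cross-checked against brute-force oracles.

test_that("binarize applies a strict threshold", {
  expect_error(binarize(matrix(0.5, 2, 2), 1.5), "threshold")
  expect_identical(binarize(matrix(0.5, 2, 2), 0.5), matrix(0L, 2, 2))
  expect_identical(binarize(matrix(1, 2, 2), 0.5), matrix(1L, 2, 2))
  expect_identical(binarize(matrix(c(0.4, 0.6), 1, 2), 0.5),
                   matrix(c(0L, 1L), 1, 2))
})

test_that("confusion counts enumerate pixels, restricted to the FOV", {
  truth <- matrix(c(1, 0, 1, 0), 2, 2)  # rows: [1,1; 0,0]
  pred <- matrix(c(1, 1, 0, 0), 2, 2)   # rows: [1,0; 1,0]
  cc <- confusion(pred, truth)
  expect_identical(cc[c("tp", "fn", "fp", "tn")],
                   list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  fov <- matrix(c(1, 1, 0, 0), 2, 2)    # column 2 masked out
  cc2 <- confusion(pred, truth, fov)
  expect_identical(cc2[c("tp", "fn", "fp", "tn")],
                   list(tp = 1L, fn = 0L, fp = 1L, tn = 0L))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
  # predictions equal to truth leave no errors
  cc3 <- confusion(truth, truth)
  expect_identical(cc3$fp + cc3$fn, 0L)
})

test_that("a full FOV is the same as no FOV", {
  set.seed(30)
  pred <- random_mask(); truth <- random_mask()
  expect_identical(confusion(pred, truth),
                   confusion(pred, truth, matrix(1L, 16, 16)))
})

test_that("basic metrics reproduce hand-worked confusion cases", {
  perfect <- structure(list(tp = 10L, tn = 20L, fp = 0L, fn = 0L),
                       class = "confusion_counts")
  bm <- basic_metrics(perfect)
  expect_equal(unlist(bm), c(se = 1, sp = 1, acc = 1, f1 = 1, mcc = 1))

  sym <- structure(list(tp = 1L, tn = 1L, fp = 1L, fn = 1L),
                   class = "confusion_counts")
  expect_equal(basic_metrics(sym)$acc, 0.5)
  expect_equal(basic_metrics(sym)$mcc, 0)

  c1 <- structure(list(tp = 9L, tn = 8L, fp = 2L, fn = 1L),
                  class = "confusion_counts")
  bm1 <- basic_metrics(c1)
  expect_equal(bm1$se, 0.9)
  expect_equal(bm1$sp, 0.8)
  expect_equal(bm1$acc, 0.85)
  expect_equal(bm1$f1, 18 / 21)
  # MCC as the Pearson correlation of the 20 paired indicators
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(1, 2), rep(0, 8))
  expect_equal(bm1$mcc, stats::cor(pred, truth), tolerance = 1e-12)

  # degenerate denominators fall back to 0
  empty_pos <- structure(list(tp = 0L, tn = 5L, fp = 0L, fn = 0L),
                         class = "confusion_counts")
  expect_equal(basic_metrics(empty_pos)$se, 0)
  expect_equal(basic_metrics(empty_pos)$mcc, 0)
})

test_that("AUC equals exhaustive pairwise comparison and tie conventions", {
  scores <- matrix(c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2), 1, 6)
  truth <- matrix(c(0, 0, 1, 1, 1, 0), 1, 6)
  expect_equal(auc_roc(scores, truth), oracle_auc(c(scores), c(truth)),
               tolerance = 1e-12)
  # perfectly separating scores
  expect_equal(auc_roc(matrix(c(0.9, 0.8, 0.1), 1, 3),
                       matrix(c(1, 1, 0), 1, 3)), 1)
  # all-identical scores: 0.5 by the tie convention
  expect_equal(auc_roc(matrix(0.3, 1, 4), matrix(c(1, 0, 1, 0), 1, 4)), 0.5)
  expect_error(auc_roc(matrix(0.3, 1, 4), matrix(1, 1, 4)), "classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  s <- matrix(runif(64), 8, 8)
  t <- random_mask(8, 8)
  a0 <- auc_roc(s, t)
  expect_equal(auc_roc(exp(3 * s), t), a0, tolerance = 1e-12)
  expect_equal(auc_roc(log(s + 0.01), t), a0, tolerance = 1e-12)
})

test_that("overlap error counts pixels of union and intersection", {
  m <- random_mask(4, 4)
  m[1, 1] <- 1L
  expect_equal(overlap_error(m, m), 0)
  a <- matrix(c(1, 0, 0, 0), 2, 2); b <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(overlap_error(a, b), 1)
  # |P intersect T| = 1, |P union T| = 4 on a 2x2 toy
  p <- matrix(c(1, 1, 1, 0), 2, 2); t <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(overlap_error(p, t), 0.75)
  expect_equal(overlap_error(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
})

test_that("per-class Jaccard handles permutations and perfection", {
  set.seed(32)
  pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
  truth <- matrix(sample(0:2, 64, TRUE), 8, 8)
  jc <- jaccard_per_class(pred, truth, 3)
  for (cl in 0:2) {
    expect_equal(jc$per_class[cl + 1], oracle_jaccard(pred, truth, cl),
                 tolerance = 1e-12)
  }
  # relabeling permutes the per-class values but preserves the mean
  relab <- c(2L, 0L, 1L)
  jc2 <- jaccard_per_class(matrix(relab[pred + 1], 8, 8),
                           matrix(relab[truth + 1], 8, 8), 3)
  expect_equal(sort(jc2$per_class), sort(jc$per_class), tolerance = 1e-12)
  expect_equal(jc2$mean, jc$mean, tolerance = 1e-12)
  expect_equal(jaccard_per_class(truth, truth, 3)$mean, 1)
})

test_that("artery/vein metrics follow the printed formulas", {
  c1 <- structure(list(tp = 9L, tn = 8L, fp = 2L, fn = 1L),
                  class = "confusion_counts")
  av <- av_metrics(c1)
  expect_equal(unlist(av), c(se_av = 0.9, sp_av = 0.8, bacc = 0.85))
  perfect <- structure(list(tp = 5L, tn = 5L, fp = 0L, fn = 0L),
                       class = "confusion_counts")
  expect_equal(unlist(av_metrics(perfect)), c(se_av = 1, sp_av = 1, bacc = 1))
  swapped <- structure(list(tp = 0L, tn = 0L, fp = 5L, fn = 5L),
                       class = "confusion_counts")
  expect_equal(unlist(av_metrics(swapped)), c(se_av = 0, sp_av = 0, bacc = 0))
  none <- structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L),
                    class = "confusion_counts")
  expect_error(av_metrics(none), "vessel")
})

test_that("every metric agrees with brute force on random masks", {
  set.seed(33)
  for (rep in 1:200) {
    pred <- random_mask()
    truth <- random_mask()
    fov <- if (rep %% 3 == 0) random_mask(p = 0.8) else NULL
    cc <- confusion(pred, truth, fov)
    oc <- oracle_confusion(pred, truth, fov)
    expect_identical(cc[c("tp", "tn", "fp", "fn")], oc)
    bm <- basic_metrics(cc)
    expect_equal(bm$mcc, oracle_mcc(pred, truth, fov), tolerance = 1e-9)
    keep <- if (is.null(fov)) rep(TRUE, 256) else c(fov != 0)
    scores <- runif(256)
    labs <- c(truth)[keep]
    if (any(labs != 0) && any(labs == 0)) {
      expect_equal(auc_roc(matrix(scores, 16, 16), truth, fov),
                   oracle_auc(scores[keep], labs), tolerance = 1e-9)
    }
    expect_equal(overlap_error(pred, truth),
                 1 - oracle_jaccard(pred, truth, 1), tolerance = 1e-9)
  }
})

test_that("metric reports serialize to JSON and CSV with fixed names", {
  rep <- list(se = 0.91234, sp = 0.87, acc = 0.9, mcc = 0.8, f1 = 0.85,
              auc = 0.97)
  path <- tempfile()
  write_metrics(rep, path)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(names(js), names(rep))
  expect_equal(js$se, 0.91234)
  csv <- read.csv(paste0(path, ".csv"))
  expect_identical(csv$metric, names(rep))
  expect_identical(csv$value[1], 0.9123)  # 4-decimal table formatting
})
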