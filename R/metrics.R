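# Evaluation statistics for the four segmentation tasks: thresholding,
# FOV-restricted confusion counts, SE/SP/ACC/F1/MCC, ROC AUC, overlap error,
# per-class Jaccard, and artery/vein balanced accuracy.

#' Threshold a binary-task probability map
#'
#' Foreground wherever the foreground probability strictly exceeds the
#' threshold (a pixel at exactly the threshold is background).
#'
#' @param prob Foreground-probability matrix (H, W), or a (2, H, W) /
#'   (N, 2, H, W) probability array whose second class is foreground.
#' @param threshold Value in \[0, 1\].
#' @return Integer 0/1 mask with the spatial shape of `prob`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  fg <- foreground_prob(prob)
  array(as.integer(fg > threshold), dim = dim(fg))
}

foreground_prob <- function(prob) {
  d <- dim(prob)
  if (length(d) == 2L) return(prob)
  if (length(d) == 3L && d[1] == 2L) return(array(prob[2, , ], dim = d[2:3]))
  if (length(d) == 4L && d[2] == 2L) {
    return(array(aperm(prob[, 2, , , drop = FALSE], c(1, 3, 4, 2)),
                 dim = d[c(1, 3, 4)]))
  }
  stop("cannot identify the foreground channel of this probability array")
}

#' Confusion counts over in-FOV pixels
#'
#' @param pred,truth Binary masks of matching shape.
#' @param fov Optional binary field-of-view mask; when absent every pixel is
#'   scored.
#' @return Object of class `confusion_counts`: list with tp, tn, fp, fn.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  keep <- if (is.null(fov)) rep(TRUE, length(truth)) else {
    if (!identical(dim(fov), dim(truth))) stop("fov shape mismatch")
    c(fov != 0)
  }
  p <- c(pred != 0)[keep]
  t <- c(truth != 0)[keep]
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Pool confusion counts across images
#' @param ... `confusion_counts` objects (or a single list of them).
#' @export
pool_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1]], "confusion_counts")) cs <- cs[[1]]
  structure(list(tp = sum(vapply(cs, `[[`, numeric(1), "tp")),
                 tn = sum(vapply(cs, `[[`, numeric(1), "tn")),
                 fp = sum(vapply(cs, `[[`, numeric(1), "fp")),
                 fn = sum(vapply(cs, `[[`, numeric(1), "fn"))),
            class = "confusion_counts")
}

safe_div <- function(num, den, fallback = 0) {
  if (den == 0) fallback else num / den
}

#' Sensitivity, specificity, accuracy, F1 and MCC from confusion counts
#'
#' SE = tp/(tp+fn), SP = tn/(tn+fp), ACC = (tp+tn)/total,
#' F1 = 2tp/(2tp+fp+fn), MCC by the determinant formula. Degenerate
#' denominators yield 0 by convention.
#'
#' @param c A [confusion()] result.
#' @return Named list with se, sp, acc, f1, mcc.
#' @export
basic_metrics <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(se = safe_div(tp, tp + fn),
       sp = safe_div(tn, tn + fp),
       acc = safe_div(tp + tn, tp + tn + fp + fn),
       f1 = safe_div(2 * tp, 2 * tp + fp + fn),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

#' Area under the ROC curve
#'
#' Trapezoidal ROC area, computed as the tie-corrected Mann-Whitney rank
#' statistic: the probability that a random foreground pixel scores above a
#' random background pixel, counting ties as 1/2.
#'
#' @param prob Foreground scores (matrix or probability array accepted by
#'   [binarize()]).
#' @param truth Binary truth mask.
#' @param fov Optional field-of-view mask.
#' @return Value in \[0, 1\].
#' @export
auc_roc <- function(prob, truth, fov = NULL) {
  s <- c(foreground_prob(prob))
  t <- c(truth != 0)
  if (!is.null(fov)) {
    keep <- c(fov != 0)
    s <- s[keep]; t <- t[keep]
  }
  npos <- sum(t); nneg <- sum(!t)
  if (npos == 0 || nneg == 0) stop("AUC needs both classes present")
  r <- rank(s, ties.method = "average")
  (sum(r[t]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Overlapping error between binary masks
#'
#' `E = 1 - |P intersect T| / |P union T|` (one minus the Jaccard index).
#' When both masks are empty E = 0 by convention.
#'
#' @param pred,truth Binary masks.
#' @return Value in \[0, 1\].
#' @export
overlap_error <- function(pred, truth) {
  p <- c(pred != 0); t <- c(truth != 0)
  u <- sum(p | t)
  if (u == 0) return(0)
  1 - sum(p & t) / u
}

#' Per-class Jaccard index (intersection over union)
#'
#' @param pred,truth Integer label masks with values below `num_classes`.
#' @param num_classes Number of classes.
#' @return List with `per_class` (length `num_classes`, classes 0..K-1) and
#'   `mean` (unweighted arithmetic mean over classes).
#' @export
jaccard_per_class <- function(pred, truth, num_classes) {
  p <- c(pred); t <- c(truth)
  per <- vapply(seq_len(num_classes) - 1L, function(cl) {
    pi <- p == cl; ti <- t == cl
    u <- sum(pi | ti)
    if (u == 0) 1 else sum(pi & ti) / u
  }, numeric(1))
  list(per_class = per, mean = mean(per))
}

#' Mean of per-class Jaccard values
#'
#' The summary used in multi-class segmentation report tables: the
#' unweighted arithmetic mean of the per-class intersection-over-union
#' values.
#'
#' @param per_class Numeric vector of per-class Jaccard indices.
#' @export
mean_jaccard <- function(per_class) mean(per_class)

#' Artery/vein classification metrics
#'
#' With arteries as the positive class and veins negative, scored on vessel
#' pixels only: SE_AV = TP/(TP+FN), SP_AV = TN/(FP+TN),
#' BACC = (SE_AV + SP_AV)/2.
#'
#' @param c A [confusion()] result over vessel pixels.
#' @return Named list with se_av, sp_av, bacc.
#' @export
av_metrics <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("no vessel pixels to score")
  se <- safe_div(as.numeric(c$tp), as.numeric(c$tp + c$fn))
  sp <- safe_div(as.numeric(c$tn), as.numeric(c$fp + c$tn))
  list(se_av = se, sp_av = sp, bacc = (se + sp) / 2)
}

#' Relative drop between two values, in percent
#'
#' `100 * (from - to) / from`; e.g. an error falling from 0.038 to 0.035 is
#' a 7.89 percent drop.
#'
#' @param from Baseline value.
#' @param to New value.
#' @export
percent_drop <- function(from, to) 100 * (from - to) / from

#' Write a metrics report to JSON and CSV
#'
#' @param report Named list of numeric metric values.
#' @param path Output path without extension; `.json` and `.csv` files are
#'   written.
#' @param digits Decimal places used in the CSV table (JSON keeps full
#'   precision).
#' @export
write_metrics <- function(report, path, digits = 4L) {
  flat <- unlist(report)
  jsonlite::write_json(as.list(flat), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  df <- data.frame(metric = names(flat),
                   value = formatC(flat, format = "f", digits = digits))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
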