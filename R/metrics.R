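#' Classification metrics from a score matrix
#'
#' Predictions are the argmax of each score row (ties to the lower label).
#' Precision, recall and F-score are computed per class from the confusion
#' matrix and macro-averaged (unweighted mean over classes); a class with no
#' predicted (resp. true) samples contributes 0 to precision (resp. recall),
#' the usual zero-division convention.
#'
#' @param scores `N x P` matrix of class scores (softmax probabilities).
#' @param labels Integer vector of 0-based true labels.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f_score`
#'   (macro-averaged, all in `[0, 1]`).
#' @export
classification_metrics <- function(scores, labels) {
  stopifnot(nrow(scores) == length(labels))
  p <- ncol(scores)
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  prec <- rec <- f1 <- numeric(p)
  for (c in seq_len(p) - 1L) {
    tp <- sum(pred == c & labels == c)
    fp <- sum(pred == c & labels != c)
    fn <- sum(pred != c & labels == c)
    prec[c + 1L] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1L] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec[c + 1L] + rec[c + 1L] > 0) {
      2 * prec[c + 1L] * rec[c + 1L] / (prec[c + 1L] + rec[c + 1L])
    } else 0
  }
  tibble(accuracy = acc, precision = mean(prec),
         recall = mean(rec), f_score = mean(f1))
}

#' Cumulative match characteristic curve
#'
#' Entry `r` of the CMC is the fraction of samples whose true identity is
#' among the `r` highest-scoring identities. Scores are ranked per sample in
#' decreasing order with ties broken by label index (lower label ranks
#' first), so the curve is deterministic. It is non-decreasing and reaches 1
#' at rank `P`; rank 1 equals classification accuracy.
#'
#' @inheritParams classification_metrics
#' @return Tibble with columns `rank` (1..P) and `cmc`.
#' @export
cmc_curve <- function(scores, labels) {
  stopifnot(nrow(scores) == length(labels))
  p <- ncol(scores)
  n <- nrow(scores)
  ranks <- vapply(seq_len(n), function(i) {
    ord <- order(-scores[i, ], seq_len(p))
    which(ord == labels[i] + 1L)
  }, integer(1))
  tibble(rank = seq_len(p),
         cmc = vapply(seq_len(p), function(r) mean(ranks <= r), numeric(1)))
}

# step-wise ROC points for one binary problem, as (fpr, tpr) corner points
# including (0,0) and (1,1)
binary_roc_points <- function(scores, truth) {
  np <- sum(truth)
  nn <- sum(!truth)
  if (np == 0L || nn == 0L) return(NULL)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  tp <- cumsum(t)
  fp <- cumsum(!t)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last point of each tied block
  tibble(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

#' Macro-averaged ROC curve, nAUC and EER
#'
#' Computes a one-vs-rest ROC curve per class, interpolates each onto a
#' shared false-positive-rate grid, and averages the true positive rates
#' (macro average, every class weighted equally). The normalized area under
#' the curve (nAUC) is the trapezoidal area of the macro curve, already in
#' `[0, 1]`. The equal error rate (EER) is the operating point at which the
#' false positive rate equals the false negative rate `1 - TPR`, located by
#' linear interpolation between the bracketing grid points. Classes absent
#' from `labels` are excluded with a warning.
#'
#' @inheritParams classification_metrics
#' @param grid_size Number of FPR grid points (default 1001).
#' @return A `macro_roc` object: list with `curve` (tibble `fpr`, `tpr`),
#'   `nauc`, `eer`, and `n_classes` actually averaged.
#' @export
roc_macro <- function(scores, labels, grid_size = 1001L) {
  stopifnot(nrow(scores) == length(labels), ncol(scores) >= 2L)
  p <- ncol(scores)
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- list()
  for (c in seq_len(p) - 1L) {
    pts <- binary_roc_points(scores[, c + 1L], labels == c)
    if (is.null(pts)) next
    # interpolate along the exact ROC path: every threshold-block corner is
    # kept, and duplicated FPR values (vertical segments) are staggered by an
    # infinitesimal step so horizontal runs are not cut into diagonals
    occ <- stats::ave(pts$fpr, pts$fpr, FUN = seq_along)
    cnt <- stats::ave(pts$fpr, pts$fpr, FUN = length)
    fx <- pts$fpr - (cnt - occ) * 1e-9  # jump points take their upper value
    tprs[[length(tprs) + 1L]] <- approx(fx, pts$tpr, xout = grid, rule = 2)$y
  }
  if (!length(tprs)) abort("No class present in `labels` has both positives and negatives.")
  if (length(tprs) < p) {
    warn(sprintf("%d of %d classes absent from `labels`; excluded from the macro ROC.",
                 p - length(tprs), p))
  }
  tpr <- Reduce(`+`, tprs) / length(tprs)
  curve <- tibble(fpr = grid, tpr = tpr)
  structure(list(curve = curve, nauc = trapezoid_area(grid, tpr),
                 eer = eer(curve), n_classes = length(tprs)),
            class = "macro_roc")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @rdname roc_macro
#' @param curve A `macro_roc` or a data frame with `fpr` and `tpr` columns
#'   (increasing `fpr`).
#' @export
eer <- function(curve) {
  if (inherits(curve, "macro_roc")) return(curve$eer)
  fpr <- curve$fpr
  fnr <- 1 - curve$tpr
  d <- fpr - fnr
  if (d[1] >= 0) return(fpr[1])
  i <- which(d >= 0)[1L]
  if (is.na(i)) return(fpr[length(fpr)])
  # linear interpolation of both rates along the bracketing segment
  t <- -d[i - 1L] / (d[i] - d[i - 1L])
  fpr[i - 1L] + t * (fpr[i] - fpr[i - 1L])
}

#' @export
print.macro_roc <- function(x, ...) {
  cat(sprintf("<macro_roc: %d classes, nAUC %.4f, EER %.4f>\n",
              x$n_classes, x$nauc, x$eer))
  invisible(x)
}

#' Evaluate a trained model on a test split
#'
#' Runs inference on every cycle of the test split and reports accuracy and
#' macro precision/recall/F-score, keeping the full softmax score matrix for
#' CMC/ROC analysis. At `level = "sequence"` per-cycle predictions within a
#' walking sequence are combined by majority vote (ties to the lower label)
#' and metrics are computed per sequence instead of per cycle; the default
#' is per-cycle classification.
#'
#' @param fit A `gait_cnn_fit` or `gait_cnn`.
#' @param dataset A `gait_dataset` test split (non-empty).
#' @param level `"cycle"` (default) or `"sequence"`.
#' @return A `gait_eval`: list with `metrics` (one-row tibble), `scores`,
#'   `labels`, and `level`.
#' @export
evaluate_model <- function(fit, dataset, level = c("cycle", "sequence")) {
  level <- match.arg(level)
  stopifnot(inherits(dataset, "gait_dataset"))
  if (nrow(dataset) == 0L) abort("Test split is empty.")
  scores <- predict(fit, dataset)
  labels <- dataset$label
  if (level == "sequence") {
    key <- paste(dataset$subject_id, dataset$sequence_id, sep = "\r")
    pred <- max.col(scores, ties.method = "first") - 1L
    agg <- lapply(split(seq_along(key), key), function(ii) {
      votes <- tabulate(pred[ii] + 1L, nbins = ncol(scores))
      list(scores = votes / length(ii), label = labels[ii][1L])
    })
    scores <- do.call(rbind, lapply(agg, `[[`, "scores"))
    labels <- vapply(agg, `[[`, integer(1), "label")
  }
  structure(list(metrics = classification_metrics(scores, labels),
                 scores = scores, labels = labels, level = level),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<gait_eval (%s level): accuracy %.3f, macro P/R/F %.3f/%.3f/%.3f on %d samples>\n",
              x$level, m$accuracy, m$precision, m$recall, m$f_score,
              length(x$labels)))
  invisible(x)
}
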