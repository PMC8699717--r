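# Multiclass evaluation metrics, naive threshold baselines, and Fisher
# exact overlap tests.

# average precision by the precision-recall step integral; tied scores are
# one threshold step (deterministic across library versions)
.average_precision <- function(labels, scores) {
  pos <- sum(labels)
  if (pos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  s <- scores[o]
  cum_tp <- cumsum(l)
  n <- seq_along(l)
  step <- which(diff(c(s, -Inf)) != 0)   # last index of each tie group
  precision <- cum_tp[step] / n[step]
  recall <- cum_tp[step] / pos
  sum(diff(c(0, recall)) * precision)
}

# rank-based ROC AUC (mid-ranks handle ties); NA when degenerate
.roc_auc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# generalized multiclass Matthews correlation (Gorodkin) from a confusion
# matrix with rows = truth, cols = predicted
.mcc_multiclass <- function(confusion) {
  C <- as.matrix(confusion)
  s <- sum(C)
  c_diag <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- c_diag * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Multiclass metric report
#'
#' Computes the 4x4 confusion matrix (rows = truth, columns = predicted,
#' prediction = argmax probability), accuracy, micro-averaged F1 and
#' average precision (pooling all class-example decisions), the
#' generalized multiclass Matthews correlation coefficient, and per-class
#' average precision, ROC AUC and F1. Per-class ROC AUC is `NA` when the
#' truth is degenerate for that class.
#'
#' @param truth Character/factor vector of true classes.
#' @param probs n x 4 matrix of class probabilities, columns in the order
#'   promoter, enhancer, insulator, other.
#' @return List of class `metric_report`.
#' @export
compute_metrics <- function(truth, probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, length(truth) == nrow(probs))
  truth <- as.character(truth)
  stopifnot(all(truth %in% CLASS_LEVELS))
  pred <- CLASS_LEVELS[max.col(probs, ties.method = "first")]
  tf <- factor(truth, CLASS_LEVELS)
  pf <- factor(pred, CLASS_LEVELS)
  confusion <- table(truth = tf, predicted = pf)
  n <- length(truth)
  accuracy <- sum(diag(confusion)) / n
  # micro-averaged F1 from pooled one-vs-rest decisions
  tp <- sum(diag(confusion))
  fp <- n - tp
  fn <- n - tp
  micro_f1 <- 2 * tp / (2 * tp + fp + fn)
  onehot <- outer(truth, CLASS_LEVELS, `==`) * 1
  micro_ap <- .average_precision(as.vector(onehot), as.vector(probs))
  per_class <- data.frame(
    class = CLASS_LEVELS,
    average_precision = vapply(seq_len(4), function(j)
      .average_precision(onehot[, j], probs[, j]), numeric(1)),
    roc_auc = vapply(seq_len(4), function(j)
      .roc_auc(onehot[, j], probs[, j]), numeric(1)),
    f1 = vapply(seq_len(4), function(j) {
      tpj <- confusion[j, j]
      den <- 2 * tpj + sum(confusion[, j]) - tpj + sum(confusion[j, ]) - tpj
      if (den == 0) return(0)
      2 * tpj / den
    }, numeric(1)))
  structure(list(confusion = confusion, accuracy = accuracy,
                 micro_f1 = micro_f1, micro_average_precision = micro_ap,
                 mcc = .mcc_multiclass(confusion), per_class = per_class),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | micro-F1 %.4f | micro-AP %.4f | MCC %.4f\n",
    x$accuracy, x$micro_f1, x$micro_average_precision, x$mcc))
  print(x$confusion)
  invisible(x)
}

#' Naive threshold baseline settings
#'
#' The menus explored for the baseline are 1/2/5 kb TSS distance, MACS2
#' FDR q-values 0.01/0.001/0.0001 and CTCF motif counts > 0/2/4; the
#' defaults are the best-performing combination (2 kb, 0.001, > 0).
#'
#' @param tss_distance_bp Promoter rule: `|distance| <= tss_distance_bp`.
#' @param qval_threshold Enhancer rule: `qval <= qval_threshold` (raw q).
#' @param ctcf_min_count Insulator rule: `count > ctcf_min_count`.
#' @export
naive_thresholds <- function(tss_distance_bp = 2000,
                             qval_threshold = 0.001,
                             ctcf_min_count = 0) {
  structure(list(tss_distance_bp = tss_distance_bp,
                 qval_threshold = qval_threshold,
                 ctcf_min_count = ctcf_min_count),
            class = "naive_thresholds")
}

#' Naive threshold classifier with the promoter > insulator priority rule
#'
#' Promoter if the TSS distance rule holds; otherwise insulator if the
#' CTCF rule holds; the remaining peaks are enhancer or other by the
#' q-value rule. Emitted probabilities are hard 1/0.
#'
#' @param tss_distance Signed distance to the nearest TSS (bp).
#' @param qval MACS2 FDR q-value, raw by default.
#' @param ctcf_count CTCF motif count.
#' @param thresholds A [naive_thresholds()].
#' @param qval_is_neglog10 Set TRUE when `qval` is on the -log10 scale.
#' @return `list(label, probs)` with `probs` an n x 4 0/1 matrix.
#' @export
naive_classify <- function(tss_distance, qval, ctcf_count,
                           thresholds = naive_thresholds(),
                           qval_is_neglog10 = FALSE) {
  n <- length(tss_distance)
  stopifnot(length(ctcf_count) == n, length(qval) == n)
  if (qval_is_neglog10) qval <- 10^(-qval)
  label <- rep(NA_character_, n)
  is_prom <- abs(tss_distance) <= thresholds$tss_distance_bp
  label[is_prom] <- "promoter"
  is_ins <- !is_prom & ctcf_count > thresholds$ctcf_min_count
  label[is_ins] <- "insulator"
  rest <- !is_prom & !is_ins
  if (any(rest & is.na(qval)))
    stop("q-value required to separate enhancer from other", call. = FALSE)
  label[rest] <- ifelse(qval[rest] <= thresholds$qval_threshold,
                        "enhancer", "other")
  probs <- outer(label, CLASS_LEVELS, `==`) * 1
  colnames(probs) <- paste0("prob_", CLASS_LEVELS)
  list(label = label, probs = probs)
}

#' Fisher exact test of overlap between two peak sets
#'
#' Builds the 2x2 membership table of `predicted` and `reference` within
#' `background` (which must contain both) and reports the two-sided exact
#' p-value and the sample cross-product odds ratio, Haldane-corrected
#' (+0.5 per cell) when any cell is zero.
#'
#' @param predicted,reference Character vectors of peak identifiers.
#' @param background Character vector: the universe of peaks.
#' @return `list(odds_ratio, p_value, table)`.
#' @export
fisher_overlap <- function(predicted, reference, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  predicted <- unique(predicted)
  reference <- unique(reference)
  if (!all(predicted %in% background) || !all(reference %in% background))
    stop("background must contain predicted and reference sets",
         call. = FALSE)
  inp <- background %in% predicted
  inr <- background %in% reference
  tab <- matrix(c(sum(inp & inr), sum(inp & !inr),
                  sum(!inp & inr), sum(!inp & !inr)),
                2, 2, byrow = TRUE,
                dimnames = list(predicted = c("yes", "no"),
                                reference = c("yes", "no")))
  p <- stats::fisher.test(tab)$p.value
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p_value = p, table = tab)
}
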