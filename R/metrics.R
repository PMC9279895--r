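#' Confusion matrix for a binary classifier
#'
#' @param reference true labels (+1/-1, or class labels matching `classes`).
#' @param predicted predicted labels, same coding.
#' @param classes named vector `c(positive = ..., negative = ...)`; the
#'   positive class is the case group.
#' @return object of class `confusion_matrix` with counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion_matrix <- function(reference, predicted,
                             classes = c(positive = "IGD", negative = "HC")) {
  to_pm1 <- function(v) {
    if (is.numeric(v)) as_pm1(v)
    else {
      bad <- setdiff(unique(as.character(v)), unname(classes))
      if (length(bad))
        stop(sprintf("label(s) outside declared classes: %s",
                     paste(bad, collapse = ", ")))
      ifelse(as.character(v) == classes[["positive"]], 1, -1)
    }
  }
  r <- to_pm1(reference)
  p <- to_pm1(predicted)
  if (length(r) != length(p)) stop("label vectors differ in length")
  new_confusion_matrix(tp = sum(r > 0 & p > 0), fn = sum(r > 0 & p < 0),
                       fp = sum(r < 0 & p > 0), tn = sum(r < 0 & p < 0),
                       classes = classes)
}

new_confusion_matrix <- function(tp, fn, fp, tn,
                                 classes = c(positive = "IGD",
                                             negative = "HC")) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  structure(as.list(counts), classes = classes, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cl <- attr(x, "classes")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(predicted = unname(cl),
                              reference = unname(cl)))
  print(m)
  met <- confusion_metrics(x)
  cat(sprintf("Accuracy: %.1f%%  Sensitivity: %.1f%%  Specificity: %.1f%%\n",
              met["accuracy"], met["sensitivity"], met["specificity"]))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`, reported as percentages rounded to one decimal. An empty
#' denominator (no cases, or no controls) is an error rather than `NaN`.
#'
#' @param cm a [confusion_matrix()], or a list/vector with elements
#'   `tp`, `fn`, `fp`, `tn`.
#' @return named numeric vector (percent): `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix")
  if (cm$tp + cm$fn == 0)
    stop("sensitivity undefined: no positive-class subjects")
  if (cm$tn + cm$fp == 0)
    stop("specificity undefined: no negative-class subjects")
  round(c(accuracy = 100 * (cm$tp + cm$tn) / n,
          sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
          specificity = 100 * cm$tn / (cm$tn + cm$fp)), 1)
}

# fast tie-aware Mann-Whitney AUC used inside the grid search
auc_score <- function(y, scores) {
  pos <- y > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability: the fraction of
#' (case, control) pairs with the case scored higher, counting ties as 1/2.
#' ROC points are computed at every distinct score threshold; the curve
#' object for plotting is delegated to \pkg{pROC}.
#'
#' @param labels +1/-1 labels (or factor; see [mksvm()]).
#' @param scores real decision values, higher = more case-like.
#' @return list with `auc`, `roc` (data.frame of `threshold`, `tpr`, `fpr`)
#'   and `proc` (the underlying [pROC::roc] object).
#' @export
roc_auc <- function(labels, scores) {
  y <- as_pm1(labels)
  if (length(unique(y)) < 2L) stop("AUC requires both classes")
  auc <- auc_score(y, scores)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y > 0] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[y < 0] >= t), 0)
  proc <- pROC::roc(response = factor(y, levels = c(-1, 1)),
                    predictor = scores, direction = "<", quiet = TRUE)
  list(auc = auc, roc = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
       proc = proc)
}

#' Per-feature Welch t screen across all modalities
#'
#' Welch two-sample t test (case vs control) for every feature of every
#' modality, with \eqn{-\log_{10} p} for Manhattan-style plotting and a
#' Bonferroni flag at `alpha / p_m` where `p_m` is the number of features in
#' the feature's own modality (the plotted family). Features with zero
#' variance in both groups are flagged (`degenerate = TRUE`) with `p = NA`.
#'
#' @param data a [multimodal_dataset].
#' @param alpha family-wise error target for the Bonferroni threshold.
#' @return data.frame of class `mkfusion_screen`: `modality`, `feature`,
#'   `t`, `df`, `p`, `neg_log10_p`, `bonferroni`, `significant`,
#'   `degenerate`.
#' @export
feature_screen <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "multimodal_dataset"))
  if (sum(data$y > 0) < 2L || sum(data$y < 0) < 2L)
    stop("both groups need at least 2 subjects")
  out <- do.call(rbind, lapply(names(data$blocks), function(m) {
    X <- data$blocks[[m]]
    bonf <- alpha / ncol(X)
    rows <- lapply(colnames(X), function(f) {
      a <- X[data$y > 0, f]
      b <- X[data$y < 0, f]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(data.frame(modality = m, feature = f, t = NA_real_,
                          df = NA_real_, p = NA_real_,
                          neg_log10_p = NA_real_, bonferroni = bonf,
                          significant = NA, degenerate = TRUE))
      tt <- stats::t.test(a, b)
      data.frame(modality = m, feature = f, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 neg_log10_p = -log10(tt$p.value), bonferroni = bonf,
                 significant = tt$p.value < bonf, degenerate = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  class(out) <- c("mkfusion_screen", "data.frame")
  out
}

#' Manhattan plot of the feature screen
#'
#' One panel per modality: \eqn{-\log_{10} p} per feature, a dashed red line
#' at the modality's Bonferroni threshold and a solid red line at the nominal
#' 0.05 level.
#'
#' @param x a [feature_screen()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mkfusion_screen <- function(x, ...) {
  mods <- unique(x$modality)
  old <- graphics::par(mfrow = c(length(mods), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in mods) {
    s <- x[x$modality == m, ]
    graphics::plot(seq_len(nrow(s)), s$neg_log10_p, pch = 20,
                   xlab = "", ylab = expression(-log[10](p)), main = m,
                   ylim = c(0, max(s$neg_log10_p,
                                   -log10(s$bonferroni[1]), na.rm = TRUE)),
                   ...)
    graphics::abline(h = -log10(s$bonferroni[1]), col = "red", lty = 2)
    graphics::abline(h = -log10(0.05), col = "red", lty = 1)
  }
  invisible(x)
}
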