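# Interpretation of the fused kernel: modality contributions, kernel PCA,
# two-component separation plane, group-ordered kernel heatmaps.

#' Kernel principal component analysis
#'
#' Eigendecomposition of the (double-centered) kernel matrix. The score of
#' subject `i` on component `c` is `eigvec[i, c] * sqrt(eigval[c])`, so
#' pairwise Euclidean distances in full score space equal the kernel-induced
#' feature-space distances. Components are ordered by decreasing eigenvalue;
#' the sign of each component is fixed so its largest-magnitude score is
#' positive, making results reproducible across eigensolvers.
#'
#' @param K symmetric PSD kernel matrix.
#' @param n_components number of components to keep (at most `n - 1`);
#'   requests beyond the matrix rank are truncated with a warning.
#' @param center apply double centering first (the standard choice; disable
#'   only if `K` is already centered).
#' @return object of class `kernel_pca` with `scores` (subjects x
#'   components), `eigenvalues` and `explained` (fraction of total centered
#'   similarity per component).
#' @export
kernel_pca <- function(K, n_components = NULL, center = TRUE) {
  if (nrow(K) != ncol(K) || !kernel_is_symmetric(K, tol = 1e-8))
    stop("'K' must be a square symmetric matrix")
  n <- nrow(K)
  Kc <- if (center) unclass(center_kernel(K)) else unclass(K)
  Kc <- (Kc + t(Kc)) / 2
  e <- eigen(Kc, symmetric = TRUE)
  tr <- sum(diag(Kc))
  if (min(e$values) < -1e-8 * max(tr, 1))
    stop(sprintf("kernel is not positive semidefinite (min eigenvalue %.3g)",
                 min(e$values)))
  vals <- pmax(e$values, 0)
  rank <- sum(vals > 1e-10 * max(vals, 1))
  if (is.null(n_components)) n_components <- min(n - 1L, rank)
  if (n_components > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    n_components, rank))
    n_components <- rank
  }
  if (n_components > n - 1L) stop("'n_components' must be at most n - 1")
  idx <- seq_len(n_components)
  scores <- e$vectors[, idx, drop = FALSE] %*% diag(sqrt(vals[idx]), n_components)
  for (c in idx) {
    i <- which.max(abs(scores[, c]))
    if (scores[i, c] < 0) scores[, c] <- -scores[, c]
  }
  dimnames(scores) <- list(rownames(K), paste0("PC", idx))
  structure(list(scores = scores, eigenvalues = vals[idx],
                 explained = vals[idx] / sum(vals), total_variance = sum(vals)),
            class = "kernel_pca")
}

#' @export
print.kernel_pca <- function(x, ...) {
  cat(sprintf("Kernel PCA: %d components\n", ncol(x$scores)))
  ex <- utils::head(x$explained, 5L)
  cat("  explained similarity:",
      paste(sprintf("%.1f%%", 100 * ex), collapse = ", "),
      if (length(x$explained) > 5L) "..." else "", "\n")
  invisible(x)
}

#' @param x a `kernel_pca` object.
#' @param labels optional group labels used to color the subjects.
#' @param boundary optional [pc_separation()] result whose line is overlaid.
#' @param ... passed to [graphics::plot()].
#' @rdname kernel_pca
#' @export
plot.kernel_pca <- function(x, labels = NULL, boundary = NULL, ...) {
  s <- x$scores
  col <- if (is.null(labels)) 1 else ifelse(as_pm1(labels) > 0, 2, 4)
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]), ...)
  if (!is.null(boundary)) {
    if (boundary$boundary$vertical)
      graphics::abline(v = boundary$boundary$x, col = "blue")
    else
      graphics::abline(boundary$boundary$intercept, boundary$boundary$slope,
                       col = "blue")
  }
  invisible(x)
}

#' Two-component logistic separation plane
#'
#' Logistic regression of the group label on the first two kernel principal
#' components, as a readout of how much of the class structure the fused
#' kernel captures. Under perfect separation the logistic MLE diverges; the
#' boundary is then taken from the maximum-margin direction (a hard-margin
#' linear SVM on the two scores) and flagged via `separated = TRUE`.
#'
#' @param scores matrix with at least two columns of component scores.
#' @param labels +1/-1 or factor labels.
#' @return object of class `pc_separation`: `coefficients` (PC1, PC2),
#'   `intercept`, `accuracy` (in-sample), `separated`, and `boundary`
#'   (slope/intercept of the decision line in the PC1-PC2 plane).
#' @export
pc_separation <- function(scores, labels) {
  y <- as_pm1(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(scores)[, 1:2, drop = FALSE]
  df <- data.frame(y01 = (y + 1) / 2, PC1 = X[, 1L], PC2 = X[, 2L])
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y01 ~ PC1 + PC2, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated) {
    # maximum-margin direction: hard-margin linear SVM on the two scores
    svm <- mksvm.default(tcrossprod(X), y, C = 1e6, check_psd = FALSE)
    w <- drop(crossprod(X, svm$alpha * y))
    b <- svm$b
  } else {
    cf <- stats::coef(fit)
    b <- unname(cf[1L])
    w <- unname(cf[2:3])
  }
  pred <- ifelse(drop(X %*% w) + b >= 0, 1, -1)
  vertical <- abs(w[2L]) < 1e-12 * max(abs(w), 1)
  structure(list(coefficients = stats::setNames(w, c("PC1", "PC2")),
                 intercept = b, accuracy = mean(pred == y),
                 separated = separated,
                 boundary = list(
                   slope = if (!vertical) -w[1L] / w[2L],
                   intercept = if (!vertical) -b / w[2L],
                   vertical = vertical,
                   x = if (vertical) -b / w[1L])),
            class = "pc_separation")
}

#' @export
print.pc_separation <- function(x, ...) {
  cat(sprintf("2-PC logistic separation: in-sample accuracy %.1f%%%s\n",
              100 * x$accuracy,
              if (x$separated) " (perfectly separated; max-margin boundary)"
              else ""))
  cat(sprintf("  boundary: %.4g * PC1 + %.4g * PC2 + %.4g = 0\n",
              x$coefficients[1L], x$coefficients[2L], x$intercept))
  invisible(x)
}

#' Group-ordered kernel heatmap
#'
#' Reorders subjects so the positive class occupies the leading block (within
#' class, by subject id) and renders the kernel with a diverging palette in
#' which low similarity appears red. If the kernel separates the groups, the
#' image shows four visually distinct blocks: similar within-class corners
#' and dissimilar (reddish) off-diagonal blocks.
#'
#' @param K kernel matrix with subject ids as dimnames.
#' @param labels group labels aligned with `K` (+1/-1 or factor).
#' @param path optional PNG output path; when `NULL` the current device is
#'   used.
#' @param main plot title.
#' @return the reordered matrix, invisibly, with the permutation in the
#'   `"order"` attribute.
#' @export
kernel_heatmap <- function(K, labels, path = NULL, main = NULL) {
  y <- as_pm1(labels)
  if (length(y) != nrow(K)) stop("labels do not align with the kernel")
  ids <- rownames(K)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(K)))
  ord <- order(-y, ids)
  K2 <- unclass(K)[ord, ord]
  render <- function() {
    pal <- grDevices::hcl.colors(101, "RdBu")  # index 1 = red = low
    graphics::image(seq_len(nrow(K2)), seq_len(ncol(K2)),
                    t(K2[rev(seq_len(nrow(K2))), ]), col = pal,
                    xlab = "", ylab = "", axes = FALSE,
                    main = if (is.null(main)) attr(K, "modality") else main)
    k1 <- sum(y > 0)
    graphics::abline(h = nrow(K2) - k1 + 0.5, v = k1 + 0.5)
    graphics::box()
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    render()
  } else render()
  invisible(structure(K2, order = ord))
}

#' Modality contribution report
#'
#' Mean and sample (n-1) standard deviation of the selected kernel weights
#' over the outer cross-validation folds — the study's headline summary of
#' how much each modality contributes to the fused kernel. Because every
#' fold's weights lie on the unit simplex, the means again sum to one.
#'
#' @param cv an `mksvm_cv` from [nested_weight_search()] (or any result
#'   carrying `fold_beta`).
#' @return data.frame: `modality`, `mean`, `sd`.
#' @export
contribution_report <- function(cv) {
  if (is.null(cv$fold_beta)) stop("'cv' carries no per-fold kernel weights")
  mu <- colMeans(cv$fold_beta)
  stopifnot(abs(sum(mu) - 1) < 1e-6)
  mods <- colnames(cv$fold_beta)
  if (is.null(mods)) mods <- paste0("modality", seq_along(mu))
  data.frame(modality = mods, mean = unname(mu),
             sd = unname(apply(cv$fold_beta, 2L, stats::sd)))
}
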