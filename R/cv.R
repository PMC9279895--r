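# Cross-validated evaluation: LOOCV outer loop, stratified k-fold inner
# loop for the kernel-weight (and C) grid search.

# seeded stratified fold assignment; returns a fold id per element of y
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# symmetric deterministic selection among inner-AUC ties: first C attaining
# the maximum; centroid of the tying weight vectors at that C, snapped back
# to the nearest grid point (first point on exact distance ties)
select_grid_point <- function(grid, aucs, Cs, tol = 1e-12) {
  amax <- max(aucs)
  ci <- which(apply(aucs, 2L, max) >= amax - tol)[1L]
  ties <- which(aucs[, ci] >= amax - tol)
  centroid <- colMeans(grid[ties, , drop = FALSE])
  d2 <- rowSums(sweep(grid, 2L, centroid)^2)
  g <- which.min(d2)
  list(auc = amax, beta = grid[g, ], C = Cs[ci], n_ties = length(ties))
}

# assemble a CVResult-style object from pooled held-out scores
make_cv_result <- function(scores, y, classes, method, ...) {
  predicted <- ifelse(scores >= 0, 1, -1)
  cm <- new_confusion_matrix(tp = sum(y > 0 & predicted > 0),
                             fn = sum(y > 0 & predicted < 0),
                             fp = sum(y < 0 & predicted > 0),
                             tn = sum(y < 0 & predicted < 0),
                             classes = classes)
  ra <- roc_auc(y, scores)
  structure(c(list(scores = scores, predicted = predicted, y = y,
                   classes = classes, confusion = cm,
                   metrics = confusion_metrics(cm), auc = ra$auc,
                   roc = ra$roc, method = method),
              list(...)),
            class = "mksvm_cv")
}

#' @export
print.mksvm_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV [%s]: n = %d\n", x$method, length(x$y)))
  if (!is.null(x$beta_mean)) {
    cat("  kernel weights (mean +/- SD over outer folds):\n")
    for (m in names(x$beta_mean))
      cat(sprintf("    %-10s %.2f +/- %.2f\n", m, x$beta_mean[m],
                  x$beta_sd[m]))
  }
  cat(sprintf("  AUC %.3f | Accuracy %.1f%% | Sensitivity %.1f%% | Specificity %.1f%%\n",
              x$auc, x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"]))
  invisible(x)
}

#' @export
summary.mksvm_cv <- function(object, ...) {
  print(object)
  print(object$confusion)
  invisible(object)
}

# per-modality normalized kernels over `rows`, statistics from the
# `train_pos` positions within those rows
fold_kernels <- function(data, specs, rows, train_pos) {
  lapply(names(data$blocks), function(m)
    unclass(normalize_kernel(compute_kernel(
      data$blocks[[m]][rows, , drop = FALSE], specs[[m]],
      train_rows = train_pos, modality = m))))
}

#' Nested cross-validated kernel-weight search
#'
#' The study protocol for choosing the modality weights: leave-one-out CV as
#' the outer loop; within each outer training set, a seeded stratified
#' `inner_folds`-fold CV scores every candidate weight vector on the simplex
#' grid (and every `C`) by the pooled inner-validation AUC. The maximizer is
#' refit on the full outer training set and scores the held-out subject.
#'
#' With small samples many weight vectors can tie at the maximal inner AUC
#' (often exactly 1). Ties are resolved symmetrically and deterministically:
#' the winning `C` is the first candidate attaining the maximum; the winning
#' weights are the centroid of all tying grid points at that `C`, snapped to
#' the nearest grid point (lexicographically first on exact distance ties).
#' An asymmetric rule such as "first tying point" would systematically bias
#' the selected weights toward particular modalities whenever the inner
#' criterion saturates. All feature standardization and kernel
#' statistics are recomputed inside every training portion, so no held-out
#' information leaks into any kernel.
#'
#' @param data a [multimodal_dataset] with at least 10 subjects and at least
#'   2 per class.
#' @param kernel a [kernel_spec()] (recycled over modalities) or named list
#'   of specs.
#' @param grid candidate weight matrix (rows on the simplex); defaults to
#'   [simplex_grid()] over the dataset's modalities at `grid_step`.
#' @param grid_step resolution of the default grid.
#' @param C candidate soft-margin costs (scalar or vector).
#' @param inner_folds number of inner folds.
#' @param seed master seed; inner splits for outer fold `o` use `seed + o`.
#' @return object of class `mksvm_cv`: held-out `scores` and `predicted`
#'   labels (one per subject), `fold_beta` (chosen weights per outer fold),
#'   `fold_C`, `beta_mean`/`beta_sd` (per-modality mean and sample SD over
#'   outer folds), pooled `roc`, `auc`, `confusion` and `metrics`.
#' @seealso [loocv_fixed_weights()], [contribution_report()]
#' @export
nested_weight_search <- function(data, kernel = kernel_spec(), grid = NULL,
                                 grid_step = 0.05, C = 1, inner_folds = 5L,
                                 seed = 1L) {
  stopifnot(inherits(data, "multimodal_dataset"))
  n <- n_subjects(data)
  if (n < 10L) stop("nested search needs at least 10 subjects")
  if (sum(data$y > 0) < 2L || sum(data$y < 0) < 2L)
    stop("both classes need at least 2 subjects")
  mods <- names(data$blocks)
  specs <- as_spec_list(kernel, mods)
  if (is.null(grid)) grid <- simplex_grid(length(mods), grid_step)
  if (ncol(grid) != length(mods))
    stop("grid columns must match the number of modalities")
  Cs <- as.numeric(C)

  scores <- stats::setNames(numeric(n), data$subject_ids)
  fold_beta <- matrix(NA_real_, n, length(mods),
                      dimnames = list(data$subject_ids, mods))
  fold_C <- numeric(n)

  for (o in seq_len(n)) {
    tr <- setdiff(seq_len(n), o)
    y_tr <- data$y[tr]
    folds <- stratified_folds(y_tr, inner_folds, seed = seed + o)

    # per inner fold: combined-kernel ingredients restricted to the outer
    # training rows, standardized on the inner-training portion only
    pre <- lapply(seq_len(inner_folds), function(f) {
      it <- which(folds != f)
      iv <- which(folds == f)
      if (length(unique(y_tr[it])) < 2L)
        stop(sprintf("inner fold %d has a single-class training set; re-stratify", f))
      Ks <- fold_kernels(data, specs, rows = tr, train_pos = it)
      list(it = it, iv = iv,
           Ktt = lapply(Ks, function(K) K[it, it, drop = FALSE]),
           Kvt = lapply(Ks, function(K) K[iv, it, drop = FALSE]))
    })

    aucs <- matrix(-Inf, nrow(grid), length(Cs))
    val_scores <- numeric(length(tr))
    for (g in seq_len(nrow(grid))) {
      beta <- grid[g, ]
      for (ci in seq_along(Cs)) {
        for (f in seq_len(inner_folds)) {
          p <- pre[[f]]
          if (length(p$iv) == 0L) next
          Ktt <- 0; Kvt <- 0
          for (m in seq_along(mods)) {
            Ktt <- Ktt + beta[m] * p$Ktt[[m]]
            Kvt <- Kvt + beta[m] * p$Kvt[[m]]
          }
          yit <- y_tr[p$it]
          sol <- .smo_solve(Ktt, yit, rep(Cs[ci], length(p$it)), 1e-8,
                            1000000L)
          val_scores[p$iv] <- drop(Kvt %*% (sol$alpha * yit)) + sol$b
        }
        aucs[g, ci] <- auc_score(y_tr, val_scores)
      }
    }
    best <- select_grid_point(grid, aucs, Cs)
    Ks <- fold_kernels(data, specs, rows = seq_len(n), train_pos = tr)
    Kc <- 0
    for (m in seq_along(mods)) Kc <- Kc + best$beta[m] * Ks[[m]]
    sol <- .smo_solve(Kc[tr, tr, drop = FALSE], y_tr,
                      rep(best$C, length(tr)), 1e-8, 1000000L)
    scores[o] <- sum(Kc[o, tr] * (sol$alpha * y_tr)) + sol$b
    fold_beta[o, ] <- best$beta
    fold_C[o] <- best$C
  }

  make_cv_result(scores, data$y, data$classes, method = "mksvm_nested",
                 fold_beta = fold_beta, fold_C = fold_C,
                 beta_mean = colMeans(fold_beta),
                 beta_sd = apply(fold_beta, 2L, stats::sd),
                 kernel_specs = specs, grid_step = grid_step,
                 C_options = Cs, seed = seed)
}

#' Leave-one-out CV of the multiple-kernel SVM with frozen weights
#'
#' Plain LOOCV with the kernel weights fixed in advance (e.g. the fold-
#' averaged weights from a nested search) — the protocol behind the study's
#' reported confusion matrices. A weight vector at a simplex vertex
#' reproduces single-modality LOOCV.
#'
#' @inheritParams nested_weight_search
#' @param beta fixed simplex weights over the modalities.
#' @param C soft-margin cost (scalar).
#' @return an `mksvm_cv` object; `fold_beta` repeats `beta` for every fold.
#' @export
loocv_fixed_weights <- function(data, beta, kernel = kernel_spec(), C = 1) {
  stopifnot(inherits(data, "multimodal_dataset"))
  n <- n_subjects(data)
  mods <- names(data$blocks)
  specs <- as_spec_list(kernel, mods)
  beta <- if (inherits(beta, "kernel_weights")) beta else
    kernel_weights(beta, mods)

  scores <- stats::setNames(numeric(n), data$subject_ids)
  for (o in seq_len(n)) {
    tr <- setdiff(seq_len(n), o)
    y_tr <- data$y[tr]
    if (length(unique(y_tr)) < 2L)
      stop("removing one subject leaves a single class; need >= 2 per class")
    Ks <- fold_kernels(data, specs, rows = seq_len(n), train_pos = tr)
    Kc <- 0
    for (m in seq_along(mods)) Kc <- Kc + beta[m] * Ks[[m]]
    sol <- .smo_solve(Kc[tr, tr, drop = FALSE], y_tr, rep(C, n - 1L),
                      1e-8, 1000000L)
    scores[o] <- sum(Kc[o, tr] * (sol$alpha * y_tr)) + sol$b
  }
  fb <- matrix(rep(unclass(beta), each = n), n, length(mods),
               dimnames = list(data$subject_ids, mods))
  make_cv_result(scores, data$y, data$classes, method = "mksvm_fixed",
                 fold_beta = fb, fold_C = rep(C, n),
                 beta_mean = colMeans(fb), beta_sd = apply(fb, 2L, stats::sd),
                 kernel_specs = specs, C_options = C)
}
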