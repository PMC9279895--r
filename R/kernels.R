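#' Specify a kernel
#'
#' @param family `"linear"` (inner products, the default for small-n
#'   high-dimensional modalities) or `"rbf"` (Gaussian,
#'   `K_ij = exp(-gamma ||z_i - z_j||^2)`).
#' @param gamma positive bandwidth for the rbf kernel, or
#'   `"median-heuristic"` to set `gamma = 1 / (2 m^2)` where `m` is the
#'   median pairwise distance among the training rows.
#' @param standardize z-score each feature using statistics of the training
#'   rows only (recommended; makes the linear kernel scale-free).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "rbf"),
                        gamma = "median-heuristic", standardize = TRUE) {
  family <- match.arg(family)
  if (is.numeric(gamma) && gamma <= 0) stop("'gamma' must be positive")
  structure(list(family = family, gamma = gamma, standardize = standardize),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s%s%s\n", x$family,
              if (x$family == "rbf")
                sprintf(" (gamma = %s)", format(x$gamma)) else "",
              if (x$standardize) ", standardized features" else ""))
  invisible(x)
}

new_kernel_matrix <- function(values, modality = NULL, spec = NULL,
                              subject_ids = rownames(values)) {
  dimnames(values) <- list(subject_ids, subject_ids)
  structure(values, modality = modality, spec = spec,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("%d x %d kernel matrix%s\n", nrow(x), ncol(x),
              if (!is.null(attr(x, "modality")))
                paste0(" [", attr(x, "modality"), "]") else ""))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Compute a kernel matrix for one feature block
#'
#' Standardization statistics (per-feature mean/SD) and the median-heuristic
#' bandwidth are estimated from `train_rows` only, so the same function is
#' safe inside cross-validation folds: the returned matrix covers all rows of
#' `X`, but no statistic depends on rows outside `train_rows`.
#'
#' Features with zero variance on the training rows are dropped with a
#' warning (they carry no information and break z-scoring); the dropped
#' names are recorded in the returned spec.
#'
#' @param X numeric matrix, subjects x features.
#' @param spec a [kernel_spec()].
#' @param train_rows indices of the training subjects.
#' @param modality optional tag stored on the result.
#' @return a `kernel_matrix` (n x n) whose `spec` attribute carries the
#'   fitted standardization statistics and bandwidth.
#' @export
compute_kernel <- function(X, spec = kernel_spec(),
                           train_rows = seq_len(nrow(X)), modality = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("'X' must be non-empty")
  if (length(train_rows) == 0L) stop("'train_rows' must be non-empty")

  fitted <- spec
  if (spec$standardize) {
    ctr <- colMeans(X[train_rows, , drop = FALSE])
    scl <- apply(X[train_rows, , drop = FALSE], 2L, stats::sd)
    dead <- which(scl == 0 | !is.finite(scl))
    if (length(dead)) {
      warning(sprintf("dropping %d zero-variance feature(s): %s",
                      length(dead),
                      paste(utils::head(colnames(X)[dead], 5L),
                            collapse = ", ")))
      fitted$dropped_features <- colnames(X)[dead]
      X <- X[, -dead, drop = FALSE]
      ctr <- ctr[-dead]
      scl <- scl[-dead]
      if (ncol(X) == 0L) stop("all features have zero variance")
    }
    Z <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
    fitted$center <- ctr
    fitted$scale <- scl
  } else {
    Z <- X
  }

  if (spec$family == "linear") {
    K <- tcrossprod(Z)
  } else {
    sq <- rowSums(Z^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Z)
    D2[D2 < 0] <- 0
    gamma <- spec$gamma
    if (identical(gamma, "median-heuristic")) {
      Dtr <- D2[train_rows, train_rows]
      med <- stats::median(sqrt(Dtr[upper.tri(Dtr)]))
      if (!is.finite(med) || med == 0) med <- 1
      gamma <- 1 / (2 * med^2)
    }
    fitted$gamma <- gamma
    K <- exp(-gamma * D2)
  }
  new_kernel_matrix(K, modality = modality, spec = fitted,
                    subject_ids = rownames(X))
}

#' Normalize a kernel to unit diagonal
#'
#' Cosine normalization `K_ij / sqrt(K_ii K_jj)`, making per-modality kernels
#' commensurate before they are combined: without it, the simplex weights
#' would conflate modality scale with modality information.
#'
#' @param K a kernel matrix with strictly positive diagonal.
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    who <- rownames(K)[which(d <= 0)[1L]]
    stop(sprintf("degenerate kernel: non-positive self-similarity for subject %s",
                 if (is.null(who)) as.character(which(d <= 0)[1L]) else who))
  }
  s <- 1 / sqrt(d)
  Kn <- unclass(K) * tcrossprod(s)
  diag(Kn) <- 1
  new_kernel_matrix(Kn, modality = attr(K, "modality"),
                    spec = attr(K, "spec"), subject_ids = rownames(K))
}

#' Simplex-constrained kernel weights
#'
#' Validates a weight vector over modalities: all components non-negative and
#' summing to one (to within 1e-12), then renormalized to sum exactly 1.
#'
#' @param beta numeric weights, one per modality.
#' @param modalities optional names.
#' @export
kernel_weights <- function(beta, modalities = names(beta)) {
  if (any(beta < 0)) stop("kernel weights must be non-negative")
  if (abs(sum(beta) - 1) > 1e-12)
    stop(sprintf("kernel weights must sum to 1 (got %.15g)", sum(beta)))
  beta <- beta / sum(beta)
  names(beta) <- modalities
  structure(beta, class = "kernel_weights")
}

#' Convex combination of kernel matrices
#'
#' Forms the combined (mixed) kernel `K = sum_m beta_m K^(m)` over modalities
#' sharing the same subjects in the same order. A convex combination of
#' symmetric PSD matrices is symmetric PSD, so the result is a valid kernel.
#'
#' @param kernels list of kernel matrices with identical subject order.
#' @param beta weights on the unit simplex ([kernel_weights()] or a plain
#'   vector of the same length as `kernels`).
#' @export
combine_kernels <- function(kernels, beta) {
  if (!inherits(beta, "kernel_weights"))
    beta <- kernel_weights(beta, modalities = names(kernels))
  if (length(kernels) != length(beta))
    stop(sprintf("%d kernels but %d weights", length(kernels), length(beta)))
  ids <- rownames(kernels[[1L]])
  for (m in seq_along(kernels))
    if (!identical(rownames(kernels[[m]]), ids))
      stop("kernels do not share the same subject order")
  K <- 0
  for (m in seq_along(kernels)) K <- K + beta[m] * unclass(kernels[[m]])
  new_kernel_matrix(K, modality = "combined",
                    spec = list(beta = beta,
                                components = lapply(kernels, attr, "spec")),
                    subject_ids = ids)
}

#' Double-center a kernel matrix
#'
#' `K_c = (I - 11'/n) K (I - 11'/n)`; every row and column of the result sums
#' to zero. This is the centering step required by kernel PCA.
#'
#' @param K square symmetric kernel matrix.
#' @export
center_kernel <- function(K) {
  if (nrow(K) != ncol(K)) stop("'K' must be square")
  Kv <- unclass(K)
  rm <- rowMeans(Kv)
  Kc <- Kv - outer(rm, rep(1, ncol(Kv))) -
    outer(rep(1, nrow(Kv)), colMeans(Kv)) + mean(Kv)
  new_kernel_matrix(Kc, modality = attr(K, "modality"),
                    spec = attr(K, "spec"), subject_ids = rownames(K))
}

#' Write a kernel matrix as delimited text
#'
#' @param K kernel matrix with subject ids as dimnames.
#' @param path output CSV path.
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(subject_id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# validity helpers used by tests and fit()
kernel_is_symmetric <- function(K, tol = 1e-10)
  max(abs(unclass(K) - t(unclass(K)))) <= tol

kernel_min_eigenvalue <- function(K)
  min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
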