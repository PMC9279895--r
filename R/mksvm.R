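#' Fit a (multiple-kernel) support vector machine on a precomputed kernel
#'
#' Solves the soft-margin SVM dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
#'       y_i y_j K_{ij} \quad \mathrm{s.t.}\; \sum_i \alpha_i y_i = 0,\;
#'       0 \le \alpha_i \le C,}
#' by SMO-type decomposition (maximal violating pair), and recovers the bias
#' `b` as the mean of \eqn{y_i - \sum_j \alpha_j y_j K_{ij}} over margin
#' support vectors (midpoint of the feasible interval if none are free).
#' The multiple-kernel model is obtained by fitting on a convex combination
#' of per-modality kernels ([combine_kernels()]); applied to a
#' [multimodal_dataset] this is done internally from `beta`.
#'
#' @param x a kernel matrix (n x n, symmetric PSD) or a
#'   [multimodal_dataset].
#' @param ... passed to methods.
#' @return an object of class `mksvm` with components `alpha`, `b`, `C`,
#'   `y`, `support` (indices with `alpha > 1e-8 C`), `margin_sv` (free
#'   support vectors), `objective` (dual objective), `beta` and
#'   `kernel_specs` when fitted from a dataset.
#' @seealso [predict.mksvm()], [nested_weight_search()]
#' @examples
#' K <- diag(2)
#' fit <- mksvm(K, c(1, -1), C = 10)
#' coef(fit)
#' @export
mksvm <- function(x, ...) UseMethod("mksvm")

#' @rdname mksvm
#' @param y labels: +1/-1 numeric vector (positive class = case) or a
#'   two-level factor whose first level is taken as negative.
#' @param C soft-margin cost; a scalar, or one value per training subject.
#' @param tol stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap for the SMO loop.
#' @param check_psd verify symmetry and positive semidefiniteness of the
#'   kernel before solving (disable in tight loops over kernels already known
#'   to be valid).
#' @export
mksvm.default <- function(x, y, C = 1, tol = 1e-8, max_iter = 1000000L,
                          check_psd = TRUE, ...) {
  K <- unclass(as.matrix(x))
  y <- as_pm1(y)
  n <- nrow(K)
  if (length(y) != n) stop("length(y) must match nrow(K)")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'y'")
  if (any(C <= 0)) stop("'C' must be positive")
  Cvec <- rep_len(as.numeric(C), n)
  if (check_psd) {
    if (!kernel_is_symmetric(K))
      stop("kernel is not symmetric")
    lmin <- kernel_min_eigenvalue(K)
    if (lmin < -1e-8 * sum(diag(K)) / n)
      stop(sprintf(paste0("kernel is not positive semidefinite ",
                          "(min eigenvalue %.3g); check the kernel ",
                          "computation"), lmin))
  }
  sol <- .smo_solve(K, y, Cvec, tol, as.integer(max_iter))
  if (!sol$converged)
    warning(sprintf("SMO did not converge in %d iterations (gap %.3g)",
                    max_iter, sol$kkt_gap))
  alpha <- as.vector(sol$alpha)
  eps <- 1e-8 * Cvec
  structure(list(alpha = alpha, b = sol$b, C = C,
                 y = y, subject_ids = rownames(K),
                 support = which(alpha > eps),
                 margin_sv = which(alpha > eps & alpha < Cvec - eps),
                 objective = sol$objective, iterations = sol$iterations,
                 kkt_gap = sol$kkt_gap,
                 K = K, beta = attr(x, "spec")$beta,
                 call = match.call()),
            class = "mksvm")
}

#' @rdname mksvm
#' @param beta simplex weights over the dataset's modalities
#'   ([kernel_weights()] or a plain non-negative vector summing to 1).
#' @param kernel a [kernel_spec()] used for every modality, or a named list
#'   of specs (one per modality).
#' @export
mksvm.multimodal_dataset <- function(x, beta = NULL,
                                     kernel = kernel_spec(), C = 1, ...) {
  specs <- as_spec_list(kernel, names(x$blocks))
  if (is.null(beta))
    beta <- rep(1 / length(x$blocks), length(x$blocks))
  beta <- if (inherits(beta, "kernel_weights")) beta else
    kernel_weights(beta, names(x$blocks))
  kerns <- lapply(names(x$blocks), function(m)
    normalize_kernel(compute_kernel(x$blocks[[m]], specs[[m]], modality = m)))
  names(kerns) <- names(x$blocks)
  K <- combine_kernels(kerns, beta)
  fit <- mksvm.default(K, x$y, C = C, ...)
  fit$beta <- beta
  fit$kernel_specs <- lapply(kerns, attr, "spec")
  fit$data <- x
  fit$classes <- x$classes
  fit$call <- match.call()
  fit
}

as_pm1 <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("'y' must have exactly two levels")
    ifelse(as.integer(y) == 2L, 1, -1)
  } else {
    if (!all(y %in% c(-1, 1))) stop("'y' must be +1/-1")
    as.numeric(y)
  }
}

as_spec_list <- function(kernel, modalities) {
  if (inherits(kernel, "kernel_spec")) {
    specs <- rep(list(kernel), length(modalities))
    names(specs) <- modalities
    specs
  } else {
    if (!all(modalities %in% names(kernel)))
      stop("'kernel' must be a kernel_spec or a named list covering every modality")
    kernel[modalities]
  }
}

#' Decision values and class predictions
#'
#' Returns raw decision scores
#' \eqn{f(z) = \sum_i y_i \alpha_i K(z, x_i) + b} (needed for ROC analysis)
#' or hard labels `sign(f)`; a score of exactly zero is mapped to the
#' positive class.
#'
#' @param object fitted [mksvm()] model.
#' @param newdata a test x train kernel block whose columns align with the
#'   training subjects, or a [multimodal_dataset] of new subjects (only for
#'   models fitted from a dataset). Omit to score the training set.
#' @param type `"decision"` for raw scores, `"class"` for labels.
#' @param ... unused.
#' @export
predict.mksvm <- function(object, newdata = NULL,
                          type = c("decision", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Kt <- object$K
  } else if (inherits(newdata, "multimodal_dataset")) {
    if (is.null(object$data))
      stop("model was not fitted from a dataset; supply a kernel block instead")
    Kt <- cross_kernel(object$data, newdata, object$kernel_specs,
                       object$beta)
  } else {
    Kt <- as.matrix(newdata)
    if (ncol(Kt) != length(object$alpha))
      stop(sprintf("kernel block has %d columns; expected %d training subjects",
                   ncol(Kt), length(object$alpha)))
    if (!is.null(colnames(Kt)) && !is.null(object$subject_ids) &&
        !identical(colnames(Kt), object$subject_ids))
      stop("kernel block columns are not aligned with the training subjects")
  }
  scores <- drop(Kt %*% (object$alpha * object$y)) + object$b
  if (type == "decision") return(scores)
  lab <- ifelse(scores >= 0, 1, -1)
  if (!is.null(object$classes))
    lab <- ifelse(lab > 0, object$classes[["positive"]],
                  object$classes[["negative"]])
  lab
}

# test x train combined kernel for dataset-fitted models: recompute each
# modality kernel over (train, new) rows with the training rows as the
# statistics source, then combine with the fitted beta
cross_kernel <- function(train_data, new_data, specs, beta) {
  n_tr <- n_subjects(train_data)
  kerns <- lapply(names(train_data$blocks), function(m) {
    Xall <- rbind(train_data$blocks[[m]], new_data$blocks[[m]])
    rownames(Xall) <- make.unique(c(train_data$subject_ids,
                                    new_data$subject_ids))
    sp <- specs[[m]]
    sp$center <- sp$scale <- sp$dropped_features <- NULL
    if (sp$family == "rbf" && !is.null(sp$gamma)) sp$gamma <- sp$gamma
    class(sp) <- "kernel_spec"
    normalize_kernel(compute_kernel(Xall, sp, train_rows = seq_len(n_tr),
                                    modality = m))
  })
  names(kerns) <- names(train_data$blocks)
  K <- combine_kernels(kerns, beta)
  unclass(K)[-seq_len(n_tr), seq_len(n_tr), drop = FALSE]
}

#' @export
fitted.mksvm <- function(object, ...) predict(object, type = "decision")

#' @export
coef.mksvm <- function(object, ...) {
  list(alpha = stats::setNames(object$alpha, object$subject_ids),
       b = object$b, beta = object$beta)
}

#' @export
print.mksvm <- function(x, ...) {
  cat("Kernel SVM (precomputed kernel)\n")
  cat(sprintf("  n = %d, C = %s, support vectors = %d (%d on margin)\n",
              length(x$alpha), paste(format(unique(x$C)), collapse = "/"),
              length(x$support), length(x$margin_sv)))
  if (!is.null(x$beta))
    cat("  kernel weights:",
        paste(sprintf("%s = %.3f", names(x$beta), x$beta), collapse = ", "),
        "\n")
  cat(sprintf("  dual objective %.6g (KKT gap %.2g)\n",
              x$objective, x$kkt_gap))
  invisible(x)
}

#' @export
summary.mksvm <- function(object, ...) {
  scores <- fitted(object)
  acc <- mean(sign(scores) * object$y > 0 | scores == 0 & object$y > 0)
  out <- list(model = object, train_accuracy = acc,
              n_support = length(object$support),
              n_margin = length(object$margin_sv))
  class(out) <- "summary.mksvm"
  out
}

#' @export
print.summary.mksvm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy %.1f%%\n", 100 * x$train_accuracy))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores the dual solution (`alpha`, `b`, `C`), the kernel weights, the
#' per-modality kernel specifications with their fitted standardization
#' statistics, the training labels and subject ids. Feature data are not
#' embedded; [read_mksvm()] re-attaches a dataset for prediction.
#'
#' @param model fitted [mksvm()] model.
#' @param path output path.
#' @export
write_mksvm <- function(model, path) {
  obj <- list(alpha = model$alpha, b = model$b, C = model$C,
              y = model$y, subject_ids = model$subject_ids,
              beta = if (!is.null(model$beta)) as.list(unclass(model$beta)),
              kernel_specs = lapply(model$kernel_specs, unclass),
              classes = as.list(model$classes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON file written by [write_mksvm()].
#' @param data optional [multimodal_dataset] with the original training
#'   subjects (same ids and order), re-attached so that `predict()` can score
#'   new datasets.
#' @export
read_mksvm <- function(path, data = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(alpha = obj$alpha, b = obj$b, C = obj$C, y = obj$y,
                subject_ids = obj$subject_ids,
                support = which(obj$alpha > 1e-8 * rep_len(obj$C, length(obj$alpha))),
                beta = if (!is.null(obj$beta))
                  kernel_weights(unlist(obj$beta)),
                kernel_specs = lapply(obj$kernel_specs, function(s) {
                  class(s) <- "kernel_spec"
                  s
                }),
                classes = unlist(obj$classes))
  if (!is.null(data)) {
    if (!identical(data$subject_ids, model$subject_ids))
      stop("'data' subjects do not match the serialized training subjects")
    model$data <- data
  }
  class(model) <- "mksvm"
  model
}
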