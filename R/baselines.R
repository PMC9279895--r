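#' Baseline classifiers under the identical LOOCV protocol
#'
#' Conventional single-vector classifiers for comparison with the
#' multiple-kernel fusion: a linear SVM, random forest, gradient boosting or
#' a single-hidden-layer MLP, trained on one modality's features or on all
#' modalities stacked into one long vector. The evaluation protocol is the
#' same leave-one-out loop as for the fusion model, with feature
#' standardization refit on each training fold; stochastic learners are
#' reseeded deterministically per fold from `seed`.
#'
#' @param data a [multimodal_dataset].
#' @param method `"svm_stacked"` (linear SVM via \pkg{e1071}),
#'   `"random_forest"` (\pkg{randomForest}), `"gradient_boosting"`
#'   (\pkg{xgboost}) or `"mlp"` (\pkg{nnet}, one hidden layer of
#'   `mlp_size` units).
#' @param modality `"all_stacked"` (concatenate every block) or one of the
#'   dataset's modalities.
#' @param C linear-SVM cost.
#' @param seed base seed; fold `o` uses `seed + o`.
#' @param mlp_size hidden-layer width for `"mlp"`.
#' @return an `mksvm_cv` object with held-out decision scores (signed margin
#'   for the SVM, centred class probability for the others).
#' @export
baseline_cv <- function(data,
                        method = c("svm_stacked", "random_forest",
                                   "gradient_boosting", "mlp"),
                        modality = c("all_stacked", names(data$blocks)),
                        C = 1, seed = 1L, mlp_size = 32L) {
  stopifnot(inherits(data, "multimodal_dataset"))
  method <- tryCatch(match.arg(method), error = function(e)
    stop(sprintf("unknown method '%s'; options: svm_stacked, random_forest, gradient_boosting, mlp",
                 method[1L])))
  modality <- match.arg(modality)
  X <- if (modality == "all_stacked") stack_features(data)
       else data$blocks[[modality]]
  y <- data$y
  n <- nrow(X)

  scores <- stats::setNames(numeric(n), data$subject_ids)
  for (o in seq_len(n)) {
    tr <- setdiff(seq_len(n), o)
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    keep <- which(scl > 0)
    Ztr <- sweep(sweep(X[tr, keep, drop = FALSE], 2L, ctr[keep]), 2L,
                 scl[keep], `/`)
    Zte <- sweep(sweep(X[o, keep, drop = FALSE], 2L, ctr[keep]), 2L,
                 scl[keep], `/`)
    set.seed(as.integer(seed) + o)
    scores[o] <- switch(
      method,
      svm_stacked = {
        fit <- e1071::svm(Ztr, factor(y[tr], levels = c(-1, 1)),
                          kernel = "linear", cost = C, scale = FALSE)
        dv <- attr(stats::predict(fit, Zte, decision.values = TRUE),
                   "decision.values")
        # e1071 orients the decision value toward the first named class
        if (startsWith(colnames(dv)[1L], "-1")) -dv[1L] else dv[1L]
      },
      random_forest = {
        fit <- randomForest::randomForest(Ztr,
                                          factor(y[tr], levels = c(-1, 1)))
        stats::predict(fit, Zte, type = "prob")[, "1"] - 0.5
      },
      gradient_boosting = {
        dtr <- xgboost::xgb.DMatrix(Ztr, label = (y[tr] + 1) / 2)
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3L,
                        eta = 0.3, nthread = 1L),
          data = dtr, nrounds = 50L, verbose = 0)
        stats::predict(fit, xgboost::xgb.DMatrix(Zte)) - 0.5
      },
      mlp = {
        fit <- nnet::nnet(Ztr, (y[tr] + 1) / 2, size = mlp_size,
                          decay = 0.01, maxit = 100L, MaxNWts = 100000L,
                          trace = FALSE)
        stats::predict(fit, Zte)[1L] - 0.5
      })
  }
  make_cv_result(scores, y, data$classes,
                 method = paste(method, modality, sep = "/"),
                 seed = seed)
}

#' Run the full baseline comparison matrix
#'
#' Stacked-feature versions of every baseline method plus single-modality
#' linear SVMs, each under the common LOOCV protocol.
#'
#' @param data a [multimodal_dataset].
#' @param methods baseline methods for the stacked features.
#' @param single_modality_svm also run a linear SVM per single modality.
#' @inheritParams baseline_cv
#' @return data.frame with one row per run: `method`, `modality`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`; the full `mksvm_cv` objects
#'   are attached as the `"runs"` attribute.
#' @export
compare_baselines <- function(data,
                              methods = c("svm_stacked", "random_forest",
                                          "gradient_boosting"),
                              single_modality_svm = TRUE, C = 1, seed = 1L) {
  runs <- list()
  for (m in methods)
    runs[[paste(m, "all_stacked", sep = "/")]] <-
      baseline_cv(data, m, "all_stacked", C = C, seed = seed)
  if (single_modality_svm)
    for (mod in names(data$blocks))
      runs[[paste("svm_stacked", mod, sep = "/")]] <-
        baseline_cv(data, "svm_stacked", mod, C = C, seed = seed)
  out <- do.call(rbind, lapply(names(runs), function(k) {
    r <- runs[[k]]
    parts <- strsplit(k, "/", fixed = TRUE)[[1L]]
    data.frame(method = parts[1L], modality = parts[2L], auc = r$auc,
               accuracy = unname(r$metrics["accuracy"]),
               sensitivity = unname(r$metrics["sensitivity"]),
               specificity = unname(r$metrics["specificity"]))
  }))
  attr(out, "runs") <- runs
  out
}
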