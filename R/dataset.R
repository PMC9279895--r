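#' Construct a multimodal dataset
#'
#' Bundles per-modality feature blocks (subjects in rows) with binary group
#' labels into a validated container used throughout the package. All blocks
#' must share the same subjects in the same order, contain no missing values,
#' and both classes must be represented.
#'
#' @param blocks named list of numeric matrices (subjects x features), one per
#'   modality, all with identical rownames in identical order.
#' @param labels numeric vector of +1/-1 (positive class = case), or a factor
#'   / character vector matching `classes`.
#' @param classes named character vector `c(positive = ..., negative = ...)`
#'   giving the class labels; defaults to IGD (case) vs HC (control).
#' @param subject_ids character vector of subject identifiers; defaults to the
#'   rownames of the first block.
#' @param covariates optional data.frame of per-subject variables (e.g. age)
#'   that are carried along but not used as classifier features.
#' @param provenance free-form list recording how the data were produced
#'   (simulation spec and seed, or file paths).
#' @return an object of class `multimodal_dataset` with elements `blocks`,
#'   `y` (+1/-1), `classes`, `subject_ids`, `covariates`, `provenance`.
#' @export
multimodal_dataset <- function(blocks, labels,
                               classes = c(positive = "IGD", negative = "HC"),
                               subject_ids = NULL, covariates = NULL,
                               provenance = list()) {
  if (!is.list(blocks) || length(blocks) == 0L || is.null(names(blocks)))
    stop("'blocks' must be a non-empty named list of matrices")
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  n <- nrow(blocks[[1L]])
  if (is.null(subject_ids)) subject_ids <- rownames(blocks[[1L]])
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  for (m in names(blocks)) {
    b <- blocks[[m]]
    if (nrow(b) != n)
      stop(sprintf("block '%s' has %d rows; expected %d", m, nrow(b), n))
    if (!is.null(rownames(b)) && !identical(rownames(b), subject_ids))
      stop(sprintf("block '%s' row order does not match subject ids", m))
    if (anyNA(b))
      stop(sprintf("block '%s' contains missing values", m))
    rownames(blocks[[m]]) <- subject_ids
  }

  if (is.factor(labels) || is.character(labels)) {
    lab <- as.character(labels)
    bad <- setdiff(unique(lab), unname(classes))
    if (length(bad))
      stop(sprintf("label value(s) outside declared classes: %s",
                   paste(bad, collapse = ", ")))
    y <- ifelse(lab == classes[["positive"]], 1, -1)
  } else {
    if (!all(labels %in% c(-1, 1)))
      stop("numeric labels must be +1/-1")
    y <- as.numeric(labels)
  }
  if (length(y) != n)
    stop(sprintf("labels have length %d; expected %d", length(y), n))
  if (length(unique(y)) < 2L)
    stop("both classes must be present (at least one subject each)")
  names(y) <- subject_ids

  structure(list(blocks = blocks, y = y, classes = classes,
                 subject_ids = subject_ids, covariates = covariates,
                 provenance = provenance),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("Multimodal dataset:", length(x$subject_ids), "subjects (",
      sum(x$y > 0), x$classes[["positive"]], "/",
      sum(x$y < 0), x$classes[["negative"]], ")\n")
  for (m in names(x$blocks))
    cat(sprintf("  %-10s %4d features\n", m, ncol(x$blocks[[m]])))
  invisible(x)
}

#' @export
summary.multimodal_dataset <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$blocks), function(m) {
    b <- object$blocks[[m]]
    data.frame(modality = m, features = ncol(b),
               mean_abs = mean(abs(b)), sd = stats::sd(as.vector(b)))
  }))
  out
}

# number of subjects
n_subjects <- function(data) length(data$subject_ids)

# subset a dataset by row index, keeping alignment
subset_dataset <- function(data, idx) {
  multimodal_dataset(
    blocks = lapply(data$blocks, function(b) b[idx, , drop = FALSE]),
    labels = data$y[idx], classes = data$classes,
    subject_ids = data$subject_ids[idx],
    covariates = if (!is.null(data$covariates))
      data$covariates[idx, , drop = FALSE],
    provenance = data$provenance)
}

# stack selected modalities into one feature matrix
stack_features <- function(data, modalities = names(data$blocks)) {
  blocks <- data$blocks[modalities]
  out <- do.call(cbind, blocks)
  rownames(out) <- data$subject_ids
  out
}
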