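#' Read a multimodal dataset from delimited text files
#'
#' Each modality lives in its own CSV/TSV file: header row, subject id in the
#' first column, one numeric feature per remaining column. A JSON manifest
#' maps modality names to files and declares the label file and the two class
#' labels. Subjects are aligned across files and ordered as in the label
#' file; a subject missing from any modality is an error.
#'
#' The manifest has the form
#' \preformatted{
#' {"modalities": {"clinical": "clinical.csv", "eeg": "eeg.csv",
#'                 "pet": "pet.csv"},
#'  "labels": "labels.csv", "label_column": "group",
#'  "positive_class": "IGD", "negative_class": "HC"}
#' }
#'
#' @param manifest path to a JSON manifest, or an equivalent named list.
#' @param dir directory against which relative file paths are resolved;
#'   defaults to the manifest's directory.
#' @return a [multimodal_dataset].
#' @export
read_multimodal <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (is.null(dir)) dir <- "."
  for (f in c("modalities", "labels", "label_column", "positive_class"))
    if (is.null(manifest[[f]]))
      stop(sprintf("manifest is missing required field '%s'", f))
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)

  lab_df <- utils::read.csv(resolve(manifest$labels), check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!manifest$label_column %in% names(lab_df))
    stop(sprintf("label column '%s' not found in %s",
                 manifest$label_column, manifest$labels))
  ids <- as.character(lab_df[[1L]])
  labels <- as.character(lab_df[[manifest$label_column]])
  neg <- manifest$negative_class
  if (is.null(neg)) {
    neg <- setdiff(unique(labels), manifest$positive_class)
    if (length(neg) != 1L)
      stop("cannot infer negative class; declare 'negative_class'")
  }
  bad <- setdiff(unique(labels), c(manifest$positive_class, neg))
  if (length(bad))
    stop(sprintf("label value(s) outside the declared classes: %s",
                 paste(bad, collapse = ", ")))

  blocks <- lapply(names(manifest$modalities), function(m) {
    path <- resolve(manifest$modalities[[m]])
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    for (j in seq_along(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (anyNA(v)) {
        row <- which(is.na(v))[1L]
        stop(sprintf(
          "non-numeric or missing value in %s at row %d ('%s'), column '%s'",
          basename(path), row, rn[row], names(df)[j]))
      }
      df[[j]] <- v
    }
    x <- as.matrix(df)
    rownames(x) <- rn
    missing <- setdiff(ids, rn)
    if (length(missing))
      stop(sprintf("modality '%s' (%s) is missing subject(s): %s", m,
                   basename(path), paste(missing, collapse = ", ")))
    x[ids, , drop = FALSE]
  })
  names(blocks) <- names(manifest$modalities)

  multimodal_dataset(
    blocks = blocks, labels = labels,
    classes = c(positive = manifest$positive_class, negative = neg),
    subject_ids = ids,
    provenance = list(source = "read_multimodal",
                      files = manifest$modalities,
                      labels = manifest$labels))
}

#' Write a multimodal dataset as delimited text plus a JSON manifest
#'
#' Inverse of [read_multimodal()]: one CSV per modality (subject id first
#' column), a label CSV, and `manifest.json` tying them together.
#'
#' @param data a [multimodal_dataset].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_multimodal <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (m in names(data$blocks)) {
    df <- data.frame(subject_id = data$subject_ids,
                     data$blocks[[m]], check.names = FALSE)
    f <- paste0(m, ".csv")
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    files[[m]] <- f
  }
  lab <- data.frame(
    subject_id = data$subject_ids,
    group = ifelse(data$y > 0, data$classes[["positive"]],
                   data$classes[["negative"]]))
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(modalities = files, labels = "labels.csv",
                   label_column = "group",
                   positive_class = unname(data$classes[["positive"]]),
                   negative_class = unname(data$classes[["negative"]]))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
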