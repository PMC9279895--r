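# End-to-end study replica: simulate/load -> screen -> nested weight search
# -> fixed-weight LOOCV -> baselines -> kernel interpretation, written to an
# output directory with a machine-readable manifest.

#' Build a study configuration
#'
#' @param data either a [cohort_spec()] (synthetic cohort), a path to a
#'   dataset manifest (see [read_multimodal()]), or a ready
#'   [multimodal_dataset].
#' @param kernel [kernel_spec()] or named list of specs per modality.
#' @param grid_step simplex-grid resolution for the weight search.
#' @param C candidate soft-margin costs.
#' @param inner_folds inner CV folds.
#' @param seed master seed; all stage seeds derive from it.
#' @param baselines character vector of baseline methods for the stacked
#'   features (empty to skip baselines).
#' @param single_modality_svm include single-modality linear SVM baselines.
#' @param interpretation produce kernel heatmaps / kernel PCA artifacts.
#' @return list of class `study_config`.
#' @export
study_config <- function(data = cohort_spec(), kernel = kernel_spec(),
                         grid_step = 0.05, C = 1, inner_folds = 5L,
                         seed = 1L,
                         baselines = c("svm_stacked", "random_forest",
                                       "gradient_boosting"),
                         single_modality_svm = TRUE,
                         interpretation = TRUE) {
  if (!(inherits(data, "cohort_spec") || inherits(data, "multimodal_dataset") ||
        is.character(data)))
    stop("'data' must be a cohort_spec, a multimodal_dataset or a manifest path")
  structure(list(data = data, kernel = kernel, grid_step = grid_step,
                 C = C, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), baselines = baselines,
                 single_modality_svm = single_modality_svm,
                 interpretation = interpretation),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys: `grid_step`, `C`, `inner_folds`, `seed`, `baselines`,
#' `single_modality_svm`, `interpretation`, `kernel` (list with `family`,
#' `gamma`, `standardize`), and either `manifest` (path to a dataset
#' manifest) or `cohort` (a list of [cohort_spec()] arguments).
#'
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$manifest)) y$manifest
          else do.call(cohort_spec, as.list(y$cohort))
  kernel <- if (is.null(y$kernel)) kernel_spec()
            else do.call(kernel_spec, y$kernel)
  args <- y[intersect(names(y), c("grid_step", "C", "inner_folds", "seed",
                                  "baselines", "single_modality_svm",
                                  "interpretation"))]
  do.call(study_config, c(list(data = data, kernel = kernel), args))
}

write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the complete fusion study
#'
#' Executes, in order: data simulation (or loading), a Table-1-style group
#' summary of the clinical features, the per-feature Welch screen with its
#' Manhattan plot, the nested cross-validated kernel-weight search, a
#' fixed-weight LOOCV at the fold-averaged weights, the baseline comparison,
#' and the kernel interpretation artifacts (group-ordered heatmaps per
#' modality and for the combined kernel, kernel PCA with the two-component
#' logistic boundary). Everything is deterministic given the configuration
#' and its master seed; every output file is listed in `manifest.json`
#' together with its MD5 digest and the MD5 digest of the serialized
#' configuration.
#'
#' @param config a [study_config()] (or anything accepted by its `data`
#'   argument, which is wrapped with defaults).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with the dataset, the nested and fixed CV
#'   results, the baseline table, the interpretation objects and the
#'   manifest.
#' @export
run_study <- function(config = study_config(), out_dir, quiet = FALSE) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  emit <- function(name) files <<- c(files, name)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("study stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))

  # --- configuration -------------------------------------------------------
  cfg_serial <- list(
    data = if (inherits(config$data, "cohort_spec")) unclass(config$data)
           else if (is.character(config$data)) config$data
           else "preloaded multimodal_dataset",
    kernel = if (inherits(config$kernel, "kernel_spec"))
      unclass(config$kernel) else lapply(config$kernel, unclass),
    grid_step = config$grid_step, C = config$C,
    inner_folds = config$inner_folds, seed = config$seed,
    baselines = config$baselines,
    single_modality_svm = config$single_modality_svm,
    interpretation = config$interpretation)
  write_json_file(cfg_serial, file.path(out_dir, "config.json"))
  emit("config.json")
  config_hash <- unname(tools::md5sum(file.path(out_dir, "config.json")))

  # --- stage: data ---------------------------------------------------------
  data <- stage("data", {
    if (inherits(config$data, "cohort_spec")) {
      say("simulating cohort (seed %d)", config$seed)
      simulate_cohort(config$data, seed = config$seed)
    } else if (is.character(config$data)) {
      say("loading dataset from %s", config$data)
      read_multimodal(config$data)
    } else config$data
  })
  stage("data", {
    write_multimodal(data, file.path(out_dir, "dataset"))
    for (f in list.files(file.path(out_dir, "dataset")))
      emit(file.path("dataset", f))
  })

  # --- stage: group summary + feature screen -------------------------------
  screen <- stage("feature_screen", {
    say("feature screen (Welch t per feature)")
    sc <- feature_screen(data)
    utils::write.csv(sc, file.path(out_dir, "screen.csv"), row.names = FALSE)
    emit("screen.csv")
    grDevices::png(file.path(out_dir, "manhattan.png"), 900, 700)
    plot(sc)
    grDevices::dev.off()
    emit("manhattan.png")
    clin <- data$blocks$clinical
    gs <- do.call(rbind, lapply(colnames(clin), function(f) {
      a <- clin[data$y > 0, f]; b <- clin[data$y < 0, f]
      tt <- stats::t.test(a, b)
      data.frame(feature = f, case_mean = mean(a), case_sd = stats::sd(a),
                 control_mean = mean(b), control_sd = stats::sd(b),
                 t = unname(tt$statistic), p = tt$p.value)
    }))
    utils::write.csv(gs, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    emit("group_summary.csv")
    sc
  })

  # --- stage: nested weight search -----------------------------------------
  nested <- stage("nested_weight_search", {
    say("nested cross-validated weight search (grid step %g)",
        config$grid_step)
    nested_weight_search(data, kernel = config$kernel,
                         grid_step = config$grid_step, C = config$C,
                         inner_folds = config$inner_folds,
                         seed = config$seed)
  })
  stage("nested_weight_search", {
    write_json_file(list(
      method = nested$method, auc = nested$auc,
      metrics = as.list(nested$metrics),
      confusion = unclass(nested$confusion)[c("tp", "fn", "fp", "tn")],
      beta_mean = as.list(nested$beta_mean),
      beta_sd = as.list(nested$beta_sd),
      fold_C = nested$fold_C,
      fold_beta = as.data.frame(nested$fold_beta),
      scores = as.list(nested$scores)),
      file.path(out_dir, "nested_cv.json"))
    emit("nested_cv.json")
    utils::write.csv(nested$roc, file.path(out_dir, "roc_nested.csv"),
                     row.names = FALSE)
    emit("roc_nested.csv")
    utils::write.csv(contribution_report(nested),
                     file.path(out_dir, "contribution.csv"),
                     row.names = FALSE)
    emit("contribution.csv")
  })

  # --- stage: fixed-weight LOOCV at the fold-averaged weights --------------
  beta_bar <- kernel_weights(nested$beta_mean / sum(nested$beta_mean),
                             names(nested$beta_mean))
  fixed <- stage("loocv_fixed_weights", {
    say("fixed-weight LOOCV at beta = (%s)",
        paste(sprintf("%.2f", beta_bar), collapse = ", "))
    loocv_fixed_weights(data, beta_bar, kernel = config$kernel,
                        C = config$C[1L])
  })
  stage("loocv_fixed_weights", {
    write_json_file(list(
      method = fixed$method, beta = as.list(unclass(beta_bar)),
      auc = fixed$auc, metrics = as.list(fixed$metrics),
      confusion = unclass(fixed$confusion)[c("tp", "fn", "fp", "tn")]),
      file.path(out_dir, "fixed_loocv.json"))
    emit("fixed_loocv.json")
  })

  # --- stage: baselines ----------------------------------------------------
  baselines <- NULL
  if (length(config$baselines)) {
    baselines <- stage("baselines", {
      say("baseline comparison (%s)", paste(config$baselines, collapse = ", "))
      cb <- compare_baselines(data, methods = config$baselines,
                              single_modality_svm = config$single_modality_svm,
                              C = config$C[1L], seed = config$seed)
      fusion_row <- data.frame(method = "mksvm_nested", modality = "fusion",
                               auc = nested$auc,
                               accuracy = unname(nested$metrics["accuracy"]),
                               sensitivity = unname(nested$metrics["sensitivity"]),
                               specificity = unname(nested$metrics["specificity"]))
      out <- rbind(fusion_row, cb)
      utils::write.csv(out, file.path(out_dir, "baselines.csv"),
                       row.names = FALSE)
      emit("baselines.csv")
      out
    })
  }

  # --- stage: interpretation -----------------------------------------------
  interp <- NULL
  if (config$interpretation) {
    interp <- stage("interpretation", {
      say("kernel interpretation (heatmaps, kernel PCA)")
      specs <- as_spec_list(config$kernel, names(data$blocks))
      kerns <- lapply(names(data$blocks), function(m)
        normalize_kernel(compute_kernel(data$blocks[[m]], specs[[m]],
                                        modality = m)))
      names(kerns) <- names(data$blocks)
      Kc <- combine_kernels(kerns, beta_bar)
      for (m in names(kerns)) {
        f <- sprintf("kernel_%s.png", m)
        kernel_heatmap(kerns[[m]], data$y, file.path(out_dir, f), main = m)
        emit(f)
      }
      kernel_heatmap(Kc, data$y, file.path(out_dir, "kernel_combined.png"),
                     main = "combined")
      emit("kernel_combined.png")
      kp <- kernel_pca(Kc)
      utils::write.csv(
        data.frame(subject_id = rownames(kp$scores), kp$scores,
                   check.names = FALSE),
        file.path(out_dir, "kpca_scores.csv"), row.names = FALSE)
      emit("kpca_scores.csv")
      sep <- pc_separation(kp$scores, data$y)
      write_json_file(list(coefficients = as.list(sep$coefficients),
                           intercept = sep$intercept,
                           accuracy = sep$accuracy,
                           separated = sep$separated),
                      file.path(out_dir, "pc_separation.json"))
      emit("pc_separation.json")
      grDevices::png(file.path(out_dir, "kpca.png"), 700, 700)
      plot(kp, labels = data$y, boundary = sep)
      grDevices::dev.off()
      emit("kpca.png")
      list(kernels = kerns, combined = Kc, kpca = kp, separation = sep)
    })
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    config_hash = config_hash,
    files = lapply(files, function(f)
      list(path = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  say("done: %d files in %s", length(files) + 1L, out_dir)

  invisible(list(data = data, screen = screen, nested = nested,
                 fixed = fixed, baselines = baselines,
                 interpretation = interp, manifest = manifest,
                 out_dir = out_dir))
}
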