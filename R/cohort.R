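#' Reference clinical questionnaire summaries for the IGD/HC cohort
#'
#' Published group means and standard deviations for the demographic and
#' clinical scales of the internet gaming disorder (IGD, case) and healthy
#' control (HC) groups. These drive the default synthetic cohort: each
#' clinical feature is drawn per group from a Gaussian with the tabulated
#' mean and SD.
#'
#' Two variables are generated but excluded from the default classifier
#' feature set: age (no group difference) and Y-IAT (the diagnostic severity
#' score, which nearly defines the label; include it explicitly via
#' `include_yiat` in [cohort_spec()] if desired).
#'
#' @return data.frame with columns `name`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `in_features`.
#' @export
igd_clinical_reference <- function() {
  ref <- data.frame(
    name = c("Age", "Y-IAT", "BDI", "BAI", "BIS", "BAS", "AQ", "BIS-11",
             "PWI", "ECQ", "CD-RISC", "WHOQOL-BREF"),
    case_mean    = c(24.21, 63.21, 16.69, 13.40, 21.47, 35.16, 73.43, 66.50,
                     64.42, 10.64, 49.58, 48.85),
    case_sd      = c(5.01, 17.00, 11.16, 12.24, 3.75, 7.43, 18.22, 11.12,
                     26.90, 3.87, 17.32, 9.35),
    control_mean = c(24.25, 31.70, 3.88, 5.01, 16.97, 31.90, 56.17, 54.88,
                     29.95, 10.33, 72.26, 59.87),
    control_sd   = c(2.72, 9.38, 4.03, 6.02, 4.42, 6.74, 13.82, 7.69,
                     15.73, 2.77, 9.29, 7.09),
    stringsAsFactors = FALSE)
  ref$in_features <- !(ref$name %in% c("Age", "Y-IAT"))
  ref
}

#' Generic flat clinical block for simulation studies
#'
#' A convenience alternative to [igd_clinical_reference()]: `p` questionnaire-
#' like features with control mean 50 / SD 10 and a uniform standardized group
#' difference `d` (case mean `50 + 10 d`). Useful for cohorts where the
#' clinical signal must be switched off (`d = 0`) or set to a known effect
#' size, e.g. in weight-recovery experiments.
#'
#' @param d Cohen's d applied to every feature.
#' @param p number of features.
#' @export
flat_clinical_reference <- function(d = 0, p = 10) {
  data.frame(name = sprintf("CLIN%02d", seq_len(p)),
             case_mean = 50 + 10 * d, case_sd = 10,
             control_mean = 50, control_sd = 10,
             in_features = TRUE, stringsAsFactors = FALSE)
}

eeg_channels_10_20 <- c("FP1", "F3", "F7", "Fz", "FP2", "F4", "F8", "T3",
                        "C3", "Cz", "T4", "C4", "T5", "P3", "O1", "Pz",
                        "T6", "P4", "O2")
eeg_band_names <- c("delta", "theta", "alpha", "beta", "high_beta",
                    "gamma", "high_gamma")

#' Specify a synthetic multimodal cohort
#'
#' Describes a two-group (case/control) cohort with three feature modalities:
#' clinical questionnaire totals, EEG spectral band power (channels x
#' frequency bands x absolute/relative power) and PET regional glucose uptake
#' (one value per anatomical ROI). Defaults reproduce the structure of the
#' published IGD study cohort: 28 cases vs 24 controls, strong group
#' separation in most clinical scales, and only weak per-feature signal in
#' the EEG and PET blocks.
#'
#' EEG and PET features are standard-normal with an exchangeable within-block
#' correlation `rho` and a group mean shift of `d` standard deviations, where
#' `d` is `weak_effect_size` for most features and `strong_effect_size` for a
#' randomly designated `signal_fraction` of them.
#'
#' @param n_case,n_control group sizes.
#' @param clinical_features data.frame with columns `name`, `case_mean`,
#'   `case_sd`, `control_mean`, `control_sd` and optionally `in_features`;
#'   defaults to [igd_clinical_reference()].
#' @param eeg_channels,eeg_bands,eeg_power_types EEG block shape (19 x 7 x 2
#'   = 266 features by default).
#' @param pet_rois number of PET regions (90 by default).
#' @param weak_effect_size baseline Cohen's d for EEG/PET features.
#' @param strong_effect_size Cohen's d for the designated signal features.
#' @param signal_fraction fraction of EEG/PET features carrying the strong
#'   effect.
#' @param eeg_effect_size,pet_effect_size optional per-modality overrides of
#'   `weak_effect_size` (strong features still use `strong_effect_size`
#'   unless `signal_fraction = 0`).
#' @param within_modality_correlation exchangeable correlation rho in [0, 1)
#'   within the EEG and PET blocks.
#' @param include_yiat include the Y-IAT severity score among classifier
#'   features (excluded by default; it nearly defines the label).
#' @param clip_nonnegative truncate negative clinical draws at 0
#'   (questionnaire scores are bounded below); the number of clipped draws is
#'   recorded in the dataset provenance.
#' @param seed default random seed used by [simulate_cohort()].
#' @return object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_case = 28, n_control = 24,
                        clinical_features = igd_clinical_reference(),
                        eeg_channels = 19, eeg_bands = 7, eeg_power_types = 2,
                        pet_rois = 90,
                        weak_effect_size = 0.1, strong_effect_size = 0.4,
                        signal_fraction = 0.05,
                        eeg_effect_size = weak_effect_size,
                        pet_effect_size = weak_effect_size,
                        within_modality_correlation = 0.3,
                        include_yiat = FALSE, clip_nonnegative = TRUE,
                        seed = 1L) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop(sprintf("invalid cohort spec: '%s' %s", field, msg))
  chk(is.numeric(n_case) && n_case >= 2, "n_case", "must be >= 2")
  chk(is.numeric(n_control) && n_control >= 2, "n_control", "must be >= 2")
  need <- c("name", "case_mean", "case_sd", "control_mean", "control_sd")
  chk(is.data.frame(clinical_features) &&
        all(need %in% names(clinical_features)),
      "clinical_features", "must have columns name/case_mean/case_sd/control_mean/control_sd")
  chk(all(clinical_features$case_sd > 0) &&
        all(clinical_features$control_sd > 0),
      "clinical_features", "must have all SDs > 0")
  chk(weak_effect_size >= 0, "weak_effect_size", "must be >= 0")
  chk(strong_effect_size >= 0, "strong_effect_size", "must be >= 0")
  chk(eeg_effect_size >= 0, "eeg_effect_size", "must be >= 0")
  chk(pet_effect_size >= 0, "pet_effect_size", "must be >= 0")
  chk(signal_fraction >= 0 && signal_fraction <= 1, "signal_fraction",
      "must be in [0, 1]")
  chk(within_modality_correlation >= 0 && within_modality_correlation < 1,
      "within_modality_correlation", "must be in [0, 1)")
  chk(eeg_channels >= 1 && eeg_bands >= 1 && eeg_power_types >= 1,
      "eeg_shape", "must be positive")
  chk(pet_rois >= 1, "pet_rois", "must be positive")
  if (!"in_features" %in% names(clinical_features))
    clinical_features$in_features <- TRUE

  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 clinical_features = clinical_features,
                 eeg_channels = as.integer(eeg_channels),
                 eeg_bands = as.integer(eeg_bands),
                 eeg_power_types = as.integer(eeg_power_types),
                 pet_rois = as.integer(pet_rois),
                 weak_effect_size = weak_effect_size,
                 strong_effect_size = strong_effect_size,
                 signal_fraction = signal_fraction,
                 eeg_effect_size = eeg_effect_size,
                 pet_effect_size = pet_effect_size,
                 within_modality_correlation = within_modality_correlation,
                 include_yiat = include_yiat,
                 clip_nonnegative = clip_nonnegative,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic multimodal cohort spec:\n")
  cat(sprintf("  %d cases / %d controls\n", x$n_case, x$n_control))
  cat(sprintf("  clinical: %d features (%d used)\n",
              nrow(x$clinical_features), sum(x$clinical_features$in_features)))
  cat(sprintf("  eeg: %d x %d x %d = %d features (d = %.2g)\n",
              x$eeg_channels, x$eeg_bands, x$eeg_power_types,
              x$eeg_channels * x$eeg_bands * x$eeg_power_types,
              x$eeg_effect_size))
  cat(sprintf("  pet: %d ROIs (d = %.2g)\n", x$pet_rois, x$pet_effect_size))
  cat(sprintf("  signal fraction %.2g at d = %.2g; rho = %.2g; seed %d\n",
              x$signal_fraction, x$strong_effect_size,
              x$within_modality_correlation, x$seed))
  invisible(x)
}

# correlated standard-normal block with group shift d per feature
# (exchangeable correlation via a shared per-subject latent factor)
rnorm_block <- function(n, p, rho, d_per_feature, case_rows) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    u <- stats::rnorm(n)
    z <- sqrt(rho) * u + sqrt(1 - rho) * z
  }
  z[case_rows, ] <- sweep(z[case_rows, , drop = FALSE], 2L, d_per_feature, `+`)
  z
}

#' Simulate a multimodal cohort
#'
#' Draws a [multimodal_dataset] from a [cohort_spec()]: clinical features per
#' group from Gaussians with the specified means/SDs, EEG and PET features
#' from correlated standard Gaussians with group mean shifts of `d` standard
#' deviations. Deterministic given `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return a [multimodal_dataset] with blocks `clinical`, `eeg`, `pet`.
#' @examples
#' d <- simulate_cohort(cohort_spec(seed = 7))
#' d
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  set.seed(as.integer(seed))
  n <- spec$n_case + spec$n_control
  case_rows <- seq_len(spec$n_case)
  ids <- sprintf("S%03d", seq_len(n))
  labels <- rep(c("IGD", "HC"), c(spec$n_case, spec$n_control))

  # clinical: independent Gaussians per feature, group-specific mean/SD
  cf <- spec$clinical_features
  clin <- matrix(0, n, nrow(cf), dimnames = list(ids, cf$name))
  for (j in seq_len(nrow(cf))) {
    clin[case_rows, j] <- stats::rnorm(spec$n_case, cf$case_mean[j],
                                       cf$case_sd[j])
    clin[-case_rows, j] <- stats::rnorm(spec$n_control, cf$control_mean[j],
                                        cf$control_sd[j])
  }
  n_clipped <- 0L
  if (spec$clip_nonnegative) {
    n_clipped <- sum(clin < 0)
    clin[clin < 0] <- 0
  }

  rho <- spec$within_modality_correlation
  p_eeg <- spec$eeg_channels * spec$eeg_bands * spec$eeg_power_types
  eeg_names <- as.vector(outer(
    as.vector(outer(eeg_channels_10_20[seq_len(spec$eeg_channels)],
                    eeg_band_names[seq_len(spec$eeg_bands)], paste, sep = ".")),
    c("abs", "rel")[seq_len(spec$eeg_power_types)], paste, sep = "."))
  d_eeg <- rep(spec$eeg_effect_size, p_eeg)
  n_sig <- round(spec$signal_fraction * p_eeg)
  sig_eeg <- if (n_sig > 0) sample.int(p_eeg, n_sig) else integer(0)
  d_eeg[sig_eeg] <- spec$strong_effect_size
  eeg <- rnorm_block(n, p_eeg, rho, d_eeg, case_rows)
  dimnames(eeg) <- list(ids, eeg_names)

  p_pet <- spec$pet_rois
  d_pet <- rep(spec$pet_effect_size, p_pet)
  n_sig <- round(spec$signal_fraction * p_pet)
  sig_pet <- if (n_sig > 0) sample.int(p_pet, n_sig) else integer(0)
  d_pet[sig_pet] <- spec$strong_effect_size
  pet <- rnorm_block(n, p_pet, rho, d_pet, case_rows)
  dimnames(pet) <- list(ids, sprintf("ROI%03d", seq_len(p_pet)))

  keep <- cf$in_features | (spec$include_yiat & cf$name == "Y-IAT")
  covars <- as.data.frame(clin[, !keep, drop = FALSE])
  rownames(covars) <- ids

  multimodal_dataset(
    blocks = list(clinical = clin[, keep, drop = FALSE], eeg = eeg, pet = pet),
    labels = labels, subject_ids = ids, covariates = covars,
    provenance = list(source = "simulate_cohort", seed = as.integer(seed),
                      spec = unclass(spec), n_clipped = n_clipped,
                      eeg_signal_features = eeg_names[sig_eeg],
                      pet_signal_features = sprintf("ROI%03d", sig_pet)))
}
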