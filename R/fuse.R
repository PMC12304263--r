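# Low-level data fusion: per-patient concatenation of vector-normalised
# ATR-FTIR and Raman spectra into one feature vector.

#' Concatenate ATR-FTIR and Raman spectra into a fused dataset
#'
#' Builds the combined representation used by the fused classification
#' model: replicates are averaged per patient within each modality, each
#' patient's mean ATR-FTIR row is re-normalised to unit Euclidean norm and
#' concatenated (ATR-FTIR block first) with the re-normalised mean Raman
#' row. Every patient must be present in both modalities; missing patients
#' are reported, never silently dropped.
#'
#' @param ftir A pre-processed ATR-FTIR `spectral_dataset`
#'   (`purpose = "fused"`, i.e. vector-normalised rows).
#' @param raman A pre-processed Raman `spectral_dataset`
#'   (`purpose = "fused"`).
#' @return An object of class `fused_dataset`: intensity matrix with one
#'   row per patient, a `feature_axis` data frame (`modality`,
#'   `wavenumber`), and patient-level `samples`.
#' @export
concatenate_modalities <- function(ftir, raman) {
  stopifnot(inherits(ftir, "spectral_dataset"),
            inherits(raman, "spectral_dataset"))
  if (!all(ftir$samples$modality == "ftir"))
    stop("first argument must contain only ATR-FTIR rows")
  if (!all(raman$samples$modality == "raman"))
    stop("second argument must contain only Raman rows")

  fa <- average_replicates(ftir, "patient_id")
  ra <- average_replicates(raman, "patient_id")

  pf <- fa$samples$patient_id
  pr <- ra$samples$patient_id
  missing_r <- setdiff(pf, pr)
  missing_f <- setdiff(pr, pf)
  if (length(missing_r) || length(missing_f))
    stop("fusion incomplete; patient(s) missing a modality: ",
         paste(c(sprintf("%s (no raman)", missing_r),
                 sprintf("%s (no ftir)", missing_f)), collapse = ", "))

  ord <- match(sort(pf), pf)
  fa <- fa[ord]
  ra <- ra[match(fa$samples$patient_id, pr)]

  mism <- fa$samples$class_label != ra$samples$class_label |
    fa$samples$group != ra$samples$group
  if (any(mism))
    stop("class-label disagreement between modalities for patient(s): ",
         paste(fa$samples$patient_id[mism], collapse = ", "))

  # Averaging unit-norm replicates shortens the mean vector slightly;
  # re-normalise so each block meets the unit-norm fusion contract.
  fmat <- t(apply(fa$intensities, 1, vector_normalize))
  rmat <- t(apply(ra$intensities, 1, vector_normalize))

  samples <- fa$samples
  samples$modality <- "fused"
  samples$hydration <- "wet"
  feature_axis <- rbind(
    data.frame(modality = "ftir", wavenumber = fa$grid),
    data.frame(modality = "raman", wavenumber = ra$grid))

  structure(list(intensities = cbind(fmat, rmat),
                 feature_axis = feature_axis,
                 grids = list(ftir = fa$grid, raman = ra$grid),
                 samples = samples),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  nf <- sum(x$feature_axis$modality == "ftir")
  cat(sprintf(
    "fused_dataset: %d patients x %d features (ATR-FTIR %d + Raman %d)\n",
    nrow(x$intensities), nrow(x$feature_axis), nf,
    nrow(x$feature_axis) - nf))
  invisible(x)
}

#' @export
dim.fused_dataset <- function(x) dim(x$intensities)

#' Extract one modality block from a fused dataset
#'
#' @param fused A `fused_dataset`.
#' @param modality `"ftir"` or `"raman"`.
#' @return A `spectral_dataset` holding that block.
#' @export
fused_block <- function(fused, modality = c("ftir", "raman")) {
  modality <- match.arg(modality)
  cols <- fused$feature_axis$modality == modality
  samples <- fused$samples
  samples$modality <- modality
  spectral_dataset(fused$feature_axis$wavenumber[cols],
                   fused$intensities[, cols, drop = FALSE], samples)
}

# Shared accessors so the evaluation engine treats both containers alike.
dataset_matrix <- function(ds) ds$intensities
dataset_samples <- function(ds) ds$samples
dataset_feature_axis <- function(ds) {
  if (inherits(ds, "fused_dataset")) ds$feature_axis
  else data.frame(modality = ds$samples$modality[1], wavenumber = ds$grid)
}
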