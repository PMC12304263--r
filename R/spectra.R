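#' @keywords internal
"_PACKAGE"

# Required metadata columns of every sample table, in storage order.
META_COLS <- c("patient_id", "group", "modality", "hydration", "replicate")

GROUPS <- c("cancer", "healthy", "pcos")
MODALITIES <- c("ftir", "raman")
HYDRATIONS <- c("wet", "dry")

#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds an intensity matrix on a single shared
#' wavenumber grid together with per-row sample metadata. It is the container
#' consumed by every pipeline stage (pre-processing, fusion, classification,
#' biomarker ranking).
#'
#' The wavenumber axis is always stored in strictly ascending cm^-1 order;
#' descending input (the common instrument export convention) is reversed,
#' with intensity columns re-ordered consistently.
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly monotone.
#' @param intensities Numeric matrix, one row per acquisition, `length(grid)`
#'   columns.
#' @param samples Data frame with columns `patient_id`, `group` (one of
#'   `"cancer"`, `"healthy"`, `"pcos"`), `modality` (`"ftir"` or `"raman"`),
#'   `hydration` (`"wet"` or `"dry"`), `replicate` (integer >= 1), plus any
#'   optional demographic columns. A `class_label` column
#'   (cancer vs control, where control = healthy + PCOS) is derived
#'   automatically.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, intensities, samples) {
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (length(grid) < 2L)
    stop("grid must contain at least 2 wavenumbers")
  if (ncol(intensities) != length(grid))
    stop("intensities must have one column per grid point")
  if (nrow(intensities) != nrow(samples))
    stop("intensities row count must equal number of sample records")

  d <- diff(grid)
  if (all(d < 0)) {            # descending export: normalise at the boundary
    grid <- rev(grid)
    intensities <- intensities[, rev(seq_along(grid)), drop = FALSE]
  } else if (!all(d > 0)) {
    stop("grid must be strictly monotone (ascending or descending)")
  }

  missing_cols <- setdiff(META_COLS, names(samples))
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  samples$patient_id <- as.character(samples$patient_id)
  if (any(!nzchar(samples$patient_id)) || anyNA(samples$patient_id))
    stop("patient_id values must be non-empty")
  bad_group <- setdiff(unique(samples$group), GROUPS)
  if (length(bad_group))
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "))
  bad_mod <- setdiff(unique(samples$modality), MODALITIES)
  if (length(bad_mod))
    stop("unknown modality value(s): ", paste(bad_mod, collapse = ", "))
  bad_hyd <- setdiff(unique(samples$hydration), HYDRATIONS)
  if (length(bad_hyd))
    stop("unknown hydration value(s): ", paste(bad_hyd, collapse = ", "))
  samples$replicate <- as.integer(samples$replicate)
  if (anyNA(samples$replicate) || any(samples$replicate < 1L))
    stop("replicate indices must be integers >= 1")

  if (!all(is.finite(intensities))) {
    idx <- which(!is.finite(intensities), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite intensity at row %d, wavenumber %g",
                 idx[1L], grid[idx[2L]]))
  }

  key <- paste(samples$patient_id, samples$modality, samples$hydration,
               samples$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), META_COLS][1L, ]
    stop(sprintf(
      "duplicate acquisition key: patient %s, %s, %s, replicate %d",
      dup$patient_id, dup$modality, dup$hydration, dup$replicate))
  }

  samples$class_label <- ifelse(samples$group == "cancer", "cancer", "control")
  rownames(samples) <- NULL
  dimnames(intensities) <- NULL

  structure(list(grid = grid, intensities = intensities, samples = samples),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "spectral_dataset: %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)\n",
    nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  patients: %d | groups: %s\n",
              length(unique(x$samples$patient_id)),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  cat(sprintf("  modality: %s | hydration: %s\n",
              paste(unique(x$samples$modality), collapse = "/"),
              paste(unique(x$samples$hydration), collapse = "/")))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Number of spectra in a dataset
#' @param ds A `spectral_dataset` or `fused_dataset`.
#' @return Integer row count.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Subset a spectral dataset by row
#' @param x A `spectral_dataset`.
#' @param i Row index vector.
#' @param ... Unused.
#' @return A `spectral_dataset` with the selected acquisitions.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  structure(list(grid = x$grid,
                 intensities = x$intensities[i, , drop = FALSE],
                 samples = x$samples[i, , drop = FALSE]),
            class = "spectral_dataset")
}

#' Read a spectral dataset from delimited text
#'
#' Expects a "wide" chemometrics export: one row per acquisition, leading
#' metadata columns (`patient_id`, `group`, `modality`, `hydration`,
#' `replicate`, plus optional extras), and one column per wavenumber whose
#' header is the numeric wavenumber in cm^-1. Comma- or tab-separated is
#' auto-detected. Descending wavenumber storage is normalised to ascending.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A validated `spectral_dataset`.
#' @export
read_dataset <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  cols <- names(df)
  wn <- suppressWarnings(as.numeric(cols))
  is_wave <- !is.na(wn)
  if (sum(is_wave) < 2L)
    stop("fewer than 2 wavenumber columns found in header")
  missing_cols <- setdiff(META_COLS, cols[!is_wave])
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))

  wave_cols <- which(is_wave)
  for (j in wave_cols) {
    if (!is.numeric(df[[j]])) {
      conv <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(conv) & !is.na(df[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric intensity at row %d, column '%s'",
                     bad[1L], cols[j]))
      df[[j]] <- conv
    }
  }
  mat <- as.matrix(df[, is_wave, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat) || !all(is.finite(mat))) {
    idx <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite intensity at row %d, column '%s'",
                 idx[1L], cols[is_wave][idx[2L]]))
  }
  spectral_dataset(wn[is_wave], mat, df[, !is_wave, drop = FALSE])
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of [read_dataset()]: metadata columns first, then one column per
#' wavenumber. Round-trips through text at better than 1e-9 relative
#' precision on intensities and exactly on metadata.
#'
#' @param ds A `spectral_dataset`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (nrow(ds$intensities) == 0L) stop("cannot serialize an empty dataset")
  meta <- ds$samples[, setdiff(names(ds$samples), "class_label"), drop = FALSE]
  mat <- as.data.frame(ds$intensities)
  names(mat) <- format(ds$grid, digits = 15, trim = TRUE, scientific = FALSE)
  out <- cbind(meta, mat)
  utils::write.table(format(out, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a spectral dataset
#'
#' Reports (rather than raises) every invariant violation it finds:
#' non-finite intensities, grid disorder, replicate counts inconsistent with
#' an expected count, and patients missing a modality when fusion is
#' intended.
#'
#' @param ds A `spectral_dataset`, or a list of them (checked jointly for
#'   fusion completeness).
#' @param expected_replicates Optional named integer, e.g.
#'   `c(wet = 2, dry = 20)`: expected acquisitions per patient per
#'   modality/hydration.
#' @param for_fusion If `TRUE` and `ds` is a list over modalities, flag
#'   patients absent from any modality.
#' @return A data frame with columns `check` and `message`; zero rows iff
#'   the dataset is valid.
#' @export
validate_dataset <- function(ds, expected_replicates = NULL,
                             for_fusion = FALSE) {
  issues <- list()
  add <- function(check, message)
    issues[[length(issues) + 1L]] <<- data.frame(check = check,
                                                 message = message)
  check_one <- function(d) {
    if (any(diff(d$grid) <= 0))
      add("grid", "wavenumber grid is not strictly ascending")
    if (!all(is.finite(d$intensities)))
      add("finite", sprintf("%d non-finite intensity value(s)",
                            sum(!is.finite(d$intensities))))
    if (any(!nzchar(d$samples$patient_id)))
      add("patient_id", "empty patient_id value(s)")
    if (!is.null(expected_replicates)) {
      tab <- table(d$samples$patient_id, d$samples$hydration)
      for (hyd in colnames(tab)) {
        if (!hyd %in% names(expected_replicates)) next
        bad <- rownames(tab)[tab[, hyd] != 0 &
                               tab[, hyd] != expected_replicates[[hyd]]]
        for (p in bad)
          add("replicates", sprintf(
            "patient %s has %d %s acquisition(s), expected %d",
            p, tab[p, hyd], hyd, expected_replicates[[hyd]]))
      }
    }
  }
  dss <- if (inherits(ds, "spectral_dataset")) list(ds) else ds
  lapply(dss, check_one)
  if (for_fusion && length(dss) > 1L) {
    pats <- lapply(dss, function(d) unique(d$samples$patient_id))
    all_pats <- unique(unlist(pats))
    for (i in seq_along(dss)) {
      absent <- setdiff(all_pats, pats[[i]])
      mod <- unique(dss[[i]]$samples$modality)
      for (p in absent)
        add("fusion", sprintf("patient %s has no %s spectra", p,
                              paste(mod, collapse = "/")))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(), message = character())
}
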