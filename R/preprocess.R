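# Pre-processing operator stack.
#
# ATR-FTIR: truncate to 1800-900 cm^-1 -> optional atmospheric reference
# subtraction -> asymmetric-least-squares baseline -> vector normalisation.
# Raman: truncate to 1800-750 cm^-1 -> rubber-band baseline -> CH2-band
# area normalisation (single-modality models) or vector normalisation
# (pre-concatenation, fused model).

#' Pre-processing parameters
#'
#' @param ftir_range,raman_range Truncation windows, cm^-1 (closed
#'   intervals).
#' @param asls_lambda Asymmetric-least-squares smoothing constant.
#' @param asls_p Asymmetry weight in (0, 1).
#' @param asls_max_iter Maximum reweighting iterations.
#' @param raman_band CH2 deformation band integration window, cm^-1.
#' @param raman_band_target Value the band integral is scaled to.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(ftir_range = c(900, 1800),
                              raman_range = c(750, 1800),
                              asls_lambda = 1000, asls_p = 0.05,
                              asls_max_iter = 10L,
                              raman_band = c(1378.1, 1490.1),
                              raman_band_target = 1.0) {
  stopifnot(ftir_range[1] < ftir_range[2], raman_range[1] < raman_range[2],
            asls_lambda > 0, asls_p > 0, asls_p < 1, asls_max_iter >= 1,
            raman_band[1] < raman_band[2], raman_band_target > 0)
  structure(as.list(environment()), class = "preprocess_params")
}

#' Truncate a dataset to a wavenumber window
#'
#' Keeps grid points inside the closed interval `[range[1], range[2]]`.
#'
#' @param ds A `spectral_dataset`.
#' @param range Length-2 numeric, ascending, cm^-1.
#' @return Truncated `spectral_dataset`.
#' @export
truncate_range <- function(ds, range) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  keep <- ds$grid >= range[1] & ds$grid <= range[2]
  if (sum(keep) < 2L)
    stop(sprintf("fewer than 2 grid points survive truncation to [%g, %g]",
                 range[1], range[2]))
  structure(list(grid = ds$grid[keep],
                 intensities = ds$intensities[, keep, drop = FALSE],
                 samples = ds$samples),
            class = "spectral_dataset")
}

#' Atmospheric reference subtraction
#'
#' Removes residual water-vapour and CO2 contributions by subtracting
#' non-negative multiples of reference spectra, with coefficients chosen to
#' minimise the first-difference roughness of the corrected spectrum
#' (vapour lines are sharp, so the smoothest corrected spectrum is the one
#' with the artefact removed). Coefficients are clipped at zero: the
#' correction can only remove reference signal, never add it.
#'
#' @param y Numeric intensity vector.
#' @param vapor_ref,co2_ref Reference spectra on the same grid (either may
#'   be `NULL`).
#' @return List with `corrected`, and coefficients `a` (vapour), `b` (CO2).
#' @export
atmospheric_correction <- function(y, vapor_ref = NULL, co2_ref = NULL) {
  refs <- Filter(Negate(is.null), list(vapor = vapor_ref, co2 = co2_ref))
  if (!length(refs)) return(list(corrected = y, a = 0, b = 0))
  for (r in refs) {
    stopifnot(length(r) == length(y))
    if (all(r == 0)) stop("degenerate all-zero atmospheric reference")
  }
  dy <- diff(y)
  D <- vapply(refs, diff, numeric(length(dy)))
  # Non-negative least squares on the differenced signals; with at most two
  # references the active sets can be enumerated exactly.
  k <- ncol(D)
  best <- NULL
  for (active in 0:(2^k - 1)) {
    free <- which(bitwAnd(active, 2^(seq_len(k) - 1L)) == 0)
    coefs <- numeric(k)
    if (length(free)) {
      fit <- tryCatch(qr.solve(D[, free, drop = FALSE], dy),
                      error = function(e) NULL)
      if (is.null(fit)) next
      coefs[free] <- fit
    }
    if (any(coefs < -1e-12)) next
    coefs <- pmax(coefs, 0)
    resid <- dy - D %*% coefs
    obj <- sum(resid^2)
    if (is.null(best) || obj < best$obj - 1e-15)
      best <- list(coefs = coefs, obj = obj)
  }
  coefs <- best$coefs
  corrected <- y
  for (j in seq_len(k)) corrected <- corrected - coefs[j] * refs[[j]]
  a <- if (!is.null(vapor_ref)) coefs[[which(names(refs) == "vapor")]] else 0
  b <- if (!is.null(co2_ref)) coefs[[which(names(refs) == "co2")]] else 0
  list(corrected = corrected, a = a, b = b)
}

#' Asymmetric-least-squares baseline estimation
#'
#' Eilers-Boelens iterative scheme: the baseline z minimises
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` where
#' points above the current baseline get weight `p` and points below get
#' `1 - p`. Weights start at 1 and the iteration stops at a weight fixed
#' point or after `max_iter` passes. The linear system is pentadiagonal and
#' solved sparsely.
#'
#' @param y Numeric intensity vector, length >= 3, finite.
#' @param lambda Smoothing constant (default 1000).
#' @param p Asymmetry weight (default 0.05).
#' @param max_iter Maximum iterations (default 10).
#' @return List with `baseline` and `corrected` (`y - baseline`).
#' @export
asls_baseline <- function(y, lambda = 1000, p = 0.05, max_iter = 10L) {
  n <- length(y)
  stopifnot(n >= 3L)
  if (!all(is.finite(y))) stop("non-finite input to asls_baseline")
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  list(baseline = z, corrected = y - z)
}

#' Rubber-band baseline correction
#'
#' The baseline is the lower convex hull of the points `(grid, y)`,
#' evaluated by linear interpolation between hull vertices; subtracting it
#' leaves a non-negative spectrum that touches zero at every hull vertex,
#' including both endpoints.
#'
#' @param y Numeric intensity vector, length >= 3, finite.
#' @param grid Wavenumber axis, strictly ascending, same length as `y`.
#' @return List with `baseline` and `corrected`.
#' @export
rubberband_baseline <- function(y, grid) {
  n <- length(y)
  stopifnot(n >= 3L, length(grid) == n, all(diff(grid) > 0))
  if (!all(is.finite(y))) stop("non-finite input to rubberband_baseline")
  hull <- lower_hull_indices(grid, y)
  baseline <- stats::approx(grid[hull], y[hull], xout = grid)$y
  corrected <- y - baseline
  corrected[hull] <- 0       # exact zero at hull vertices by definition
  list(baseline = baseline, corrected = corrected)
}

# Andrew monotone-chain lower hull on points already sorted by x.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      # pop while the last two hull points and i make a non-left turn
      cr <- (x[hull[m]] - x[hull[m - 1L]]) * (y[i] - y[hull[m - 1L]]) -
            (y[hull[m]] - y[hull[m - 1L]]) * (x[i] - x[hull[m - 1L]])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

#' Vector (unit Euclidean norm) normalisation
#'
#' @param y Numeric vector with positive Euclidean norm.
#' @return `y / sqrt(sum(y^2))`.
#' @export
vector_normalize <- function(y) {
  nrm <- sqrt(sum(y^2))
  if (!is.finite(nrm) || nrm == 0) stop("cannot vector-normalise a zero vector")
  y / nrm
}

# Trapezoidal integral of y over [lo, hi], with the band edges obtained by
# linear interpolation when they fall between grid points.
band_integral <- function(y, grid, band) {
  lo <- max(band[1], grid[1]); hi <- min(band[2], grid[length(grid)])
  if (lo >= hi) stop("integration band does not overlap the grid")
  inside <- grid > lo & grid < hi
  xs <- c(lo, grid[inside], hi)
  ys <- c(stats::approx(grid, y, lo)$y, y[inside], stats::approx(grid, y, hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Band-area normalisation
#'
#' Scales a spectrum so that its trapezoidal integral over a reference band
#' (by default the ~1450 cm^-1 CH2 deformation band) equals a fixed target,
#' making intensities comparable across acquisitions.
#'
#' @param y Numeric intensity vector.
#' @param grid Wavenumber axis.
#' @param band Length-2 integration window, cm^-1.
#' @param target Target integral value.
#' @return Scaled intensity vector.
#' @export
band_area_normalize <- function(y, grid, band = c(1378.1, 1490.1),
                                target = 1.0) {
  I <- band_integral(y, grid, band)
  if (!is.finite(I) || I <= 0)
    stop("non-positive band integral; baseline correction may have failed")
  y * (target / I)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; exact where target points coincide with source
#' points. Extrapolation outside the source span is refused.
#'
#' @param y Numeric intensity vector.
#' @param grid Source wavenumber axis.
#' @param target_grid New axis, inside `range(grid)`.
#' @return Intensities on `target_grid`.
#' @export
resample_to_grid <- function(y, grid, target_grid) {
  if (min(target_grid) < grid[1] || max(target_grid) > grid[length(grid)])
    stop("target grid requires extrapolation outside the source span")
  stats::approx(grid, y, xout = target_grid)$y
}

#' Average replicate spectra
#'
#' Collapses acquisitions to one arithmetic-mean row per grouping key
#' (default: per patient). Group and class labels must be constant within a
#' key group; the replicate index is collapsed to 1.
#'
#' @param ds A `spectral_dataset`.
#' @param key Character vector of metadata columns defining the groups.
#' @return A `spectral_dataset` with one row per key group, in order of
#'   first appearance.
#' @export
average_replicates <- function(ds, key = "patient_id") {
  kv <- do.call(paste, c(ds$samples[key], sep = "\r"))
  kv <- factor(kv, levels = unique(kv))
  for (col in c("group", "class_label")) {
    nlev <- tapply(ds$samples[[col]], kv, function(v) length(unique(v)))
    if (any(nlev > 1))
      stop("conflicting ", col, " values within an averaging group")
  }
  idx <- split(seq_len(nrow(ds$intensities)), kv)
  mat <- t(vapply(idx, function(i) colMeans(ds$intensities[i, , drop = FALSE]),
                  numeric(length(ds$grid))))
  samples <- ds$samples[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  samples$replicate <- 1L
  spectral_dataset(ds$grid, mat, samples)
}

#' Run the full pre-processing stack for one modality
#'
#' ATR-FTIR rows: truncation, optional atmospheric reference subtraction,
#' asymmetric-least-squares baseline, vector normalisation. Raman rows:
#' truncation, rubber-band baseline, then CH2 band-area normalisation for a
#' single-modality model (`purpose = "single"`) or vector normalisation
#' when the rows are destined for concatenation (`purpose = "fused"`).
#'
#' @param ds A `spectral_dataset` whose rows are all of one modality.
#' @param params A [preprocess_params()].
#' @param purpose `"single"` or `"fused"`.
#' @param vapor_ref,co2_ref Optional atmospheric reference spectra on the
#'   raw ATR-FTIR grid (skipped when `NULL`, as for synthetic data).
#' @return The pre-processed `spectral_dataset`.
#' @export
preprocess_modality <- function(ds, params = preprocess_params(),
                                purpose = c("single", "fused"),
                                vapor_ref = NULL, co2_ref = NULL) {
  purpose <- match.arg(purpose)
  modality <- unique(ds$samples$modality)
  if (length(modality) != 1L)
    stop("dataset mixes modalities; pre-process each separately")

  if (modality == "ftir") {
    keep <- ds$grid >= params$ftir_range[1] & ds$grid <= params$ftir_range[2]
    out <- truncate_range(ds, params$ftir_range)
    if (!is.null(vapor_ref) || !is.null(co2_ref)) {
      vr <- if (!is.null(vapor_ref)) vapor_ref[keep]
      cr <- if (!is.null(co2_ref)) co2_ref[keep]
      out$intensities <- t(apply(out$intensities, 1, function(y)
        atmospheric_correction(y, vr, cr)$corrected))
    }
    out$intensities <- t(apply(out$intensities, 1, function(y)
      vector_normalize(asls_baseline(y, params$asls_lambda, params$asls_p,
                                     params$asls_max_iter)$corrected)))
  } else {
    out <- truncate_range(ds, params$raman_range)
    norm_fun <- if (purpose == "single") {
      function(y) band_area_normalize(y, out$grid, params$raman_band,
                                      params$raman_band_target)
    } else {
      vector_normalize
    }
    out$intensities <- t(apply(out$intensities, 1, function(y)
      norm_fun(rubberband_baseline(y, out$grid)$corrected)))
  }
  out
}
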