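# Synthetic blood-plasma spectrum generator.
#
# Emulates the statistical structure of a dual-modality plasma study:
# a cohort of cancer / healthy / PCOS patients, Gaussian vibrational bands
# with class-dependent amplitudes driven by a latent disease score,
# polynomial baseline drift, a broad water absorption band in wet ATR-FTIR,
# coffee-ring site heterogeneity in dried films, slow dehydration drift over
# wet acquisitions, and additive instrument noise.

#' Synthetic study configuration
#'
#' Defaults emulate the study design this pipeline is built around: 54
#' patients (22 endometrial cancer, 18 PCOS, 14 healthy), two wet
#' acquisitions per sample per modality, 20 dried-film site spectra per
#' ATR-FTIR sample, with the acquisition artefacts listed below.
#'
#' @param n_cancer,n_pcos,n_healthy Cohort sizes.
#' @param replicates_wet Wet acquisitions per patient per modality.
#' @param replicates_dry Dried-film site spectra per patient (ATR-FTIR).
#' @param effect_scale Multiplier on every class-dependent band amplitude;
#'   0 gives a null study with no class signal.
#' @param pcos_mixing Function `n -> n latent scores in [0, 1]` for PCOS
#'   patients (default uniform), realising the intermediate biochemical
#'   position of PCOS between healthy and cancer.
#' @param biological_sd SD of the per-patient, per-band log-normal
#'   amplitude variability (between-patient biochemistry).
#' @param noise_sd Additive instrument noise SD (intensity units).
#' @param water_band_amplitude Amplitude of the broad ~1637 cm^-1 water
#'   absorption superimposed on wet ATR-FTIR spectra.
#' @param coffee_ring_sd Relative site-to-site amplitude SD for dried-film
#'   replicates (coffee-ring heterogeneity).
#' @param dehydration_drift Fractional per-acquisition loss of the water
#'   band over successive wet acquisitions.
#' @param baseline_sd SD of the random low-order polynomial baseline
#'   coefficients per acquisition.
#' @param raw_grid_ftir,raw_grid_raman Raw acquisition grids, cm^-1
#'   (ascending numeric vectors).
#' @param seed Integer seed; the whole study is a pure function of the
#'   configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_cancer = 22L, n_pcos = 18L, n_healthy = 14L,
                         replicates_wet = 2L, replicates_dry = 20L,
                         effect_scale = 1, pcos_mixing = stats::runif,
                         biological_sd = 0.10, noise_sd = 0.025,
                         water_band_amplitude = 1.0, coffee_ring_sd = 0.08,
                         dehydration_drift = 0.05, baseline_sd = 0.03,
                         raw_grid_ftir = seq(800, 2000, by = 2),
                         raw_grid_raman = seq(600, 2000, by = 2),
                         seed = 1L) {
  stopifnot(n_cancer >= 0, n_pcos >= 0, n_healthy >= 0,
            replicates_wet >= 1, replicates_dry >= 1,
            noise_sd >= 0, biological_sd >= 0, coffee_ring_sd >= 0,
            is.function(pcos_mixing),
            length(raw_grid_ftir) >= 2, all(diff(raw_grid_ftir) > 0),
            length(raw_grid_raman) >= 2, all(diff(raw_grid_raman) > 0))
  if (n_cancer + n_pcos + n_healthy == 0L)
    stop("cohort is empty: all three group counts are zero")
  structure(as.list(environment()), class = "synth_config")
}

# Band templates. Centers sit at biochemically meaningful plasma bands
# (Amide I/II, lipid ester carbonyl, CH2/CH3 deformations, carotenoid C-C,
# nucleic-acid PO2-, phenylalanine ring). class_effect is the signed
# amplitude shift per unit latent disease score; signs are fixed by
# convention (e.g. carotenoids depleted in cancer).
ftir_band_table <- function() {
  data.frame(
    center = c(1733, 1695, 1670, 1655, 1545, 1506, 1456, 1400, 1380,
               1343, 1240, 1170, 1080, 1030),
    width  = c(  10,   12,   12,   25,   22,   10,   12,   15,   10,
                 10,   18,   12,   16,   12),
    base   = c(0.12, 0.30, 0.35, 1.00, 0.75, 0.18, 0.30, 0.35, 0.20,
               0.15, 0.25, 0.15, 0.30, 0.20),
    effect = c(0.050, 0.030, -0.036, 0, 0, 0.019, -0.030, 0, 0.020,
               -0.015, 0, 0.015, 0.030, 0))
}

raman_band_table <- function() {
  data.frame(
    center = c(1655, 1525, 1450, 1317, 1279, 1260, 1241, 1128, 1090,
               1071, 1003, 940, 807),
    width  = c(  20,   10,   18,   10,   10,   12,   12,    8,   10,
                  8,    6,   10,    8),
    base   = c(0.80, 0.25, 1.00, 0.25, 0.20, 0.25, 0.25, 0.20, 0.25,
               0.20, 0.90, 0.15, 0.15),
    effect = c(0, -0.068, 0, 0.031, 0.024, -0.024, 0.027, 0.018, 0.027,
               -0.018, 0, 0, 0.018))
}

band_table <- function(modality) {
  switch(modality, ftir = ftir_band_table(), raman = raman_band_table(),
         stop("unknown modality: ", modality))
}

#' Build a synthetic patient cohort
#'
#' Assigns each patient a latent disease score d: 1 for cancer, 0 for
#' healthy, and a draw from `pcos_mixing` for PCOS (so PCOS biochemistry
#' sits between the two). Demographics loosely mirror a gynaecological
#' cancer-vs-control cohort (cancer mean age 63, SD 10; controls mean 39,
#' SD 13).
#'
#' @param config A [synth_config()].
#' @return Data frame of patient records with `patient_id`, `group`,
#'   `class_label`, `latent_score`, `age_years`.
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cancer + config$n_pcos + config$n_healthy
  group <- rep(c("cancer", "pcos", "healthy"),
               c(config$n_cancer, config$n_pcos, config$n_healthy))
  d <- numeric(n)
  d[group == "cancer"] <- 1
  d[group == "pcos"] <- config$pcos_mixing(sum(group == "pcos"))
  if (any(d < 0 | d > 1))
    stop("pcos_mixing must return scores in [0, 1]")
  age <- ifelse(group == "cancer",
                stats::rnorm(n, 63, 10), stats::rnorm(n, 39, 13))
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             group = group,
             class_label = ifelse(group == "cancer", "cancer", "control"),
             latent_score = d,
             age_years = round(pmax(age, 18)))
}

# Gaussian band mixture on a grid: amplitudes is a vector per band.
band_mixture <- function(grid, centers, widths, amplitudes) {
  G <- exp(-outer(grid, centers, "-")^2 / rep(2 * widths^2, each = length(grid)))
  drop(G %*% amplitudes)
}

#' Generate one synthetic acquisition
#'
#' Intensity model: sum of Gaussian bands with amplitude
#' `(base + d * effect * effect_scale) * patient band factor`, plus a random
#' low-order polynomial baseline, plus (wet ATR-FTIR only) a broad water
#' band near 1637 cm^-1 attenuated by dehydration drift over successive
#' replicates, times a coffee-ring site factor for dried films, plus
#' additive Gaussian noise; clipped at zero.
#'
#' Draws from the current RNG state: call [set.seed()] (or use
#' [synth_study()], which seeds once) for reproducibility.
#'
#' @param latent_score Patient latent disease score in [0, 1].
#' @param modality `"ftir"` or `"raman"`.
#' @param hydration `"wet"` or `"dry"`; `("raman", "dry")` is not an
#'   acquisition mode of this design and errors.
#' @param replicate 1-based acquisition index.
#' @param config A [synth_config()].
#' @param band_factors Optional per-band multiplicative patient factors
#'   (default all 1); [synth_study()] draws them log-normally once per
#'   patient.
#' @return List with `grid` and `intensities` for the single spectrum.
#' @export
synth_spectrum <- function(latent_score, modality, hydration, replicate,
                           config, band_factors = NULL) {
  if (modality == "raman" && hydration == "dry")
    stop("unsupported modality/hydration pair: raman + dry")
  grid <- if (modality == "ftir") config$raw_grid_ftir else config$raw_grid_raman
  bands <- band_table(modality)
  if (is.null(band_factors)) band_factors <- rep(1, nrow(bands))
  amp <- (bands$base +
            latent_score * bands$effect * config$effect_scale) * band_factors
  y <- band_mixture(grid, bands$center, bands$width, amp)

  t <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  coef <- stats::rnorm(3, 0, config$baseline_sd)
  y <- y + abs(coef[1]) + coef[2] * t + coef[3] * t^2

  if (modality == "ftir" && hydration == "wet") {
    wamp <- config$water_band_amplitude *
      (1 - config$dehydration_drift * replicate)
    y <- y + wamp * exp(-(grid - 1637)^2 / (2 * 60^2))
  }
  if (hydration == "dry")
    y <- y * stats::rnorm(1, 1, config$coffee_ring_sd)
  y <- y + stats::rnorm(length(grid), 0, config$noise_sd)
  list(grid = grid, intensities = pmax(y, 0))
}

#' Generate a complete synthetic study
#'
#' Produces the three acquisition datasets of the design — wet ATR-FTIR,
#' dry ATR-FTIR, wet Raman — for one seeded cohort. Per-patient band
#' factors are drawn once per patient per modality (shared between the wet
#' and dry ATR-FTIR acquisitions of a patient, since they reflect the same
#' plasma biochemistry).
#'
#' @param config A [synth_config()].
#' @param datasets Character subset of
#'   `c("ftir_wet", "ftir_dry", "raman_wet")` to generate (all by default;
#'   the cohort and patient factors are drawn identically regardless, so a
#'   subset run reproduces the corresponding full-run datasets).
#' @return List with `cohort` (data frame) and one `spectral_dataset` per
#'   requested element.
#' @export
synth_study <- function(config = synth_config(),
                        datasets = c("ftir_wet", "ftir_dry", "raman_wet")) {
  stopifnot(inherits(config, "synth_config"))
  datasets <- match.arg(datasets, several.ok = TRUE)
  cohort <- build_cohort(config)   # seeds the RNG with config$seed
  n_pat <- nrow(cohort)
  factors <- list(
    ftir = matrix(exp(stats::rnorm(n_pat * nrow(ftir_band_table()),
                                   0, config$biological_sd)), n_pat),
    raman = matrix(exp(stats::rnorm(n_pat * nrow(raman_band_table()),
                                    0, config$biological_sd)), n_pat))

  gen <- function(modality, hydration, n_rep) {
    rows <- vector("list", n_pat * n_rep)
    meta <- vector("list", n_pat * n_rep)
    k <- 0L
    for (i in seq_len(n_pat)) {
      for (r in seq_len(n_rep)) {
        k <- k + 1L
        s <- synth_spectrum(cohort$latent_score[i], modality, hydration, r,
                            config, factors[[modality]][i, ])
        rows[[k]] <- s$intensities
        meta[[k]] <- data.frame(patient_id = cohort$patient_id[i],
                                group = cohort$group[i],
                                modality = modality, hydration = hydration,
                                replicate = r)
      }
    }
    spectral_dataset(if (modality == "ftir") config$raw_grid_ftir
                     else config$raw_grid_raman,
                     do.call(rbind, rows), do.call(rbind, meta))
  }

  out <- list(cohort = cohort)
  # Fixed generation order so that a subset run is reproducible: each
  # dataset consumes an independent RNG substream derived from the seed.
  specs <- list(ftir_wet = list("ftir", "wet", config$replicates_wet),
                ftir_dry = list("ftir", "dry", config$replicates_dry),
                raman_wet = list("raman", "wet", config$replicates_wet))
  for (nm in names(specs)) {
    if (!nm %in% datasets) next
    set.seed((config$seed + match(nm, names(specs)) * 7919L) %% .Machine$integer.max)
    sp <- specs[[nm]]
    out[[nm]] <- gen(sp[[1]], sp[[2]], sp[[3]])
  }
  out
}
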