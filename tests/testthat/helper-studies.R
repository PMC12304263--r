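# Shared multi-seed study runs for the heavier end-to-end properties.
# Computed lazily once per session and cached, so several test blocks can
# interrogate the same simulations.

.study_cache <- new.env(parent = emptyenv())

# Default-effect studies over ten seeds: wet ATR-FTIR, wet Raman and the
# fused dataset through the full supervised pipeline, plus the biomarker
# analysis of the wet ATR-FTIR data under the same split plans.
signal_runs <- function(seeds = 1:10) {
  key <- paste0("signal_", paste(seeds, collapse = "_"))
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  pp <- preprocess_params()
  runs <- lapply(seeds, function(seed) {
    st <- synth_study(synth_config(seed = seed),
                      datasets = c("ftir_wet", "raman_wet"))
    fw <- preprocess_modality(st$ftir_wet, pp, "single")
    rw <- preprocess_modality(st$raman_wet, pp, "single")
    fu <- concatenate_modalities(
      preprocess_modality(st$ftir_wet, pp, "fused"),
      preprocess_modality(st$raman_wet, pp, "fused"))
    cfg <- eval_config(compute_cv = FALSE, master_seed = seed)
    study <- run_supervised_study(
      list(ftir_wet = fw, raman_wet = rw, fused = fu), cfg)
    bio <- run_biomarker_study(fw, study$plan, ranking_config(seed = seed))
    list(seed = seed, study = study, bio = bio,
         ftir = fw, raman = rw, fused = fu)
  })
  .study_cache[[key]] <- runs
  runs
}

# Null studies (effect_scale = 0) over ten seeds on the wet Raman data.
null_runs <- function(seeds = 1:10) {
  key <- paste0("null_", paste(seeds, collapse = "_"))
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  pp <- preprocess_params()
  runs <- lapply(seeds, function(seed) {
    st <- synth_study(synth_config(seed = seed, effect_scale = 0),
                      datasets = "raman_wet")
    rw <- preprocess_modality(st$raman_wet, pp, "single")
    cfg <- eval_config(compute_cv = FALSE, master_seed = seed)
    run_supervised_study(list(raman_wet = rw), cfg)
  })
  .study_cache[[key]] <- runs
  runs
}

# Best-classifier mean test accuracy per dataset for one study.
best_accuracy <- function(study) {
  acc <- study$summary[study$summary$metric == "accuracy", ]
  vapply(split(acc, acc$dataset), function(g) max(g$mean), numeric(1))
}
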