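#!/usr/bin/env Rscript
# Simulate the synthetic perioperative cohort with planted preoperative
# drivers and intraoperative motifs, and persist it (with its ground
# truth) as plain-text tables for the downstream drivers.

source("analysis/_config.R")

spec <- cohort_spec(
  n_encounters = config$n_encounters,
  seed = stage_seed("synth"),
  preop_effect_scale = config$preop_effect_scale,
  motif_effect_scale = config$motif_effect_scale
)
truth <- plant_truth(spec)
cohort <- generate_cohort(spec, truth)

write_cohort(cohort, paths$cohort, truth = truth)
saveRDS(spec, file.path(paths$cache, "spec.rds"))

prev <- colMeans(cohort$outcomes)
message("cohort: ", n_encounters(cohort), " encounters")
message("observed prevalences: ",
        paste(sprintf("%s=%.3f", outcome_names(), prev), collapse = ", "))
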