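#!/usr/bin/env Rscript
# Model introspection on the validation set: Monte Carlo dropout
# uncertainty per prediction point and ranked integrated-gradients
# feature attributions from the postoperative model.

source("analysis/_config.R")

val <- readRDS(file.path(paths$cache, "tensors_val.rds"))

unc_inputs <- list()
for (phase in config$phases) {
  model <- readRDS(file.path(paths$cache, paste0("model_", phase, ".rds")))
  mc <- mc_dropout(model, val, n_trials = config$mc_trials,
                   seed = stage_seed(paste0("mc_", phase)))
  unc_inputs[[phase]] <- list(phase = phase, scheme = "multitask",
                              mc = mc, labels = val$labels)
  message("uncertainty for ", phase, " done")
}
write_table(summarize_uncertainty(unc_inputs), "uncertainty.csv")

postop <- readRDS(file.path(paths$cache, "model_postop.rds"))
idx <- seq_len(min(config$ig_encounters, length(val$encounter_id)))
attributions <- do.call(rbind, lapply(seq_len(9), function(k) {
  reports <- lapply(idx, function(i) {
    integrated_gradients(postop, val, i, task = k)
  })
  cbind(outcome = outcome_names()[k],
        aggregate_attributions(reports, top_k = 10))
}))
write_table(attributions, "attributions.csv")
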