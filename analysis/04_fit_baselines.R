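#!/usr/bin/env Rscript
# Train the comparison classifiers (random forest, gradient boosted
# trees) per outcome on fixed-length summary features and persist their
# validation predictions.

source("analysis/_config.R")

dev <- readRDS(file.path(paths$cache, "tensors_dev.rds"))
val <- readRDS(file.path(paths$cache, "tensors_val.rds"))

rows <- list()
for (kind in c("random_forest", "gradient_boosted_trees")) {
  for (phase in config$phases) {
    fx_dev <- baseline_feature_matrix(dev, phase)
    fx_val <- baseline_feature_matrix(val, phase)
    for (k in seq_len(9)) {
      fit <- fit_baseline(fx_dev, dev$labels[, k], kind,
                          seed = stage_seed(paste(kind, phase, k)))
      rows[[length(rows) + 1]] <- data.frame(
        encounter_id = val$encounter_id, phase = phase, scheme = kind,
        outcome = outcome_names()[k],
        probability = predict(fit, fx_val))
    }
    message(kind, " / ", phase, " done")
  }
}

write_table(do.call(rbind, rows), "predictions_baselines.csv")
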