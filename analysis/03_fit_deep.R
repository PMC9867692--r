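#!/usr/bin/env Rscript
# Train the multitask deep models (preoperative, intraoperative and
# postoperative prediction points) and persist validation risk
# predictions.

source("analysis/_config.R")

dev <- readRDS(file.path(paths$cache, "tensors_dev.rds"))
val <- readRDS(file.path(paths$cache, "tensors_val.rds"))
layout <- model_layout(dev)

predictions <- list()
for (phase in config$phases) {
  cfg <- do.call(model_config, c(
    list(phase = phase, scheme = "multitask",
         seed = stage_seed(paste0("deep_", phase))),
    config$model_args))
  t0 <- Sys.time()
  model <- train_model(build_model(cfg, layout), dev)
  message(sprintf("%s: best epoch %d of %d, %.1f min", phase,
                  model$best_epoch, nrow(model$log),
                  as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  saveRDS(model, file.path(paths$cache, paste0("model_", phase, ".rds")))
  predictions[[phase]] <- predict_risk(model, val)
}

write_table(do.call(rbind, predictions), "predictions_deep.csv")
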