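#!/usr/bin/env Rscript
# Validation-set evaluation: discrimination metrics with bootstrap
# confidence intervals for every (model, phase, outcome), and net
# reclassification of postoperative versus preoperative deep
# predictions.

source("analysis/_config.R")

val <- readRDS(file.path(paths$cache, "tensors_val.rds"))
deep <- data.table::fread(file.path(paths$tables, "predictions_deep.csv"))
base <- data.table::fread(file.path(paths$tables,
                                    "predictions_baselines.csv"))
preds <- rbind(deep[, c("encounter_id", "phase", "scheme", "outcome",
                        "probability")],
               base)

metrics <- do.call(rbind, lapply(
  split(preds, preds[, c("phase", "scheme", "outcome")], drop = TRUE),
  function(g) {
    y <- val$labels[match(g$encounter_id, val$encounter_id),
                    g$outcome[1]]
    row <- compute_metrics(g$probability, y)
    ci <- bootstrap_ci(g$probability, y, "auroc",
                       n_resamples = config$n_bootstrap,
                       seed = stage_seed(paste("ci", g$phase[1],
                                               g$scheme[1], g$outcome[1])))
    cbind(data.frame(phase = g$phase[1], scheme = g$scheme[1],
                     outcome = g$outcome[1]), row,
          data.frame(auroc_lo = ci[["lower"]], auroc_hi = ci[["upper"]],
                     hm_ci_width = auroc_ci_width(length(y), mean(y),
                                                  max(row$auroc, 0.51))))
  }))
rownames(metrics) <- NULL
write_table(metrics, "metrics.csv")

wide <- function(want_scheme, want_phase) {
  # plain names on purpose: data.table evaluates `i` with columns in
  # scope, so an argument named `scheme` would be shadowed by the column
  g <- preds[preds$scheme == want_scheme & preds$phase == want_phase, ]
  m <- matrix(NA_real_, length(val$encounter_id), 9,
              dimnames = list(NULL, outcome_names()))
  for (k in outcome_names()) {
    gk <- g[g$outcome == k, ]
    m[match(gk$encounter_id, val$encounter_id), k] <- gk$probability
  }
  m
}
pre <- wide("multitask", "preop")
post <- wide("multitask", "postop")
nri_table <- do.call(rbind, lapply(outcome_names(), function(k) {
  r <- nri(pre[, k], post[, k], val$labels[, k])
  data.frame(outcome = k, nri = r$nri, nri_events = r$nri_events,
             nri_nonevents = r$nri_nonevents,
             overall_correct_pct = r$overall_correct_pct,
             p_value = r$p_value)
}))
write_table(nri_table, "nri_postop_vs_preop.csv")

message("\nValidation AUROC by model and outcome:")
print(stats::reshape(
  metrics[, c("phase", "scheme", "outcome", "auroc")],
  idvar = c("phase", "scheme"), timevar = "outcome",
  direction = "wide"), digits = 3)
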