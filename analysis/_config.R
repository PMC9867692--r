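# Shared configuration for the numbered analysis drivers. Every script
# sources this file; run the drivers from the repository root, e.g.
#   Rscript analysis/01_simulate.R
# A single edit here rescales the whole study.

suppressPackageStartupMessages(library(periopnet))

config <- list(
  seed = 20240101L,
  # Desk-scale study: large enough for stable validation metrics on the
  # common outcomes, small enough to run end to end on one CPU.
  n_encounters = 4000L,
  # Strong planted drivers (the regime the recovery analyses study).
  preop_effect_scale = 1.5,
  motif_effect_scale = 5,
  # Reduced network widths and epoch cap for desk runs; the
  # model_config() defaults hold the full-scale study conditions.
  model_args = list(fc_dim = 32, rnn_hidden = 32, attention_dim = 16,
                    embed_dim = 8, max_epochs = 10),
  phases = c("preop", "intraop", "postop"),
  n_bootstrap = 200,
  mc_trials = 50,
  ig_encounters = 20
)

paths <- list(
  cohort = file.path("results", "cohort"),
  cache = file.path("results", "cache"),
  tables = file.path("results", "tables")
)
for (p in paths) dir.create(p, showWarnings = FALSE, recursive = TRUE)

stage_seed <- function(stage) derive_seed(config$seed, stage)

write_table <- function(df, name) {
  path <- file.path(paths$tables, name)
  data.table::fwrite(df, path)
  message("wrote ", path)
}
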