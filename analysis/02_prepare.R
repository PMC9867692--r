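#!/usr/bin/env Rscript
# Chronological development/validation split, development-only feature
# dictionary, and tensor assembly for both partitions.

source("analysis/_config.R")

spec <- readRDS(file.path(paths$cache, "spec.rds"))
cohort <- read_cohort(paths$cohort, spec)
split <- split_chronological(cohort)
dictionary <- fit_feature_dictionary(split$development)

dev <- prepare_tensors(split$development, dictionary)
val <- prepare_tensors(split$validation, dictionary)

saveRDS(dictionary, file.path(paths$cache, "dictionary.rds"))
saveRDS(dev, file.path(paths$cache, "tensors_dev.rds"))
saveRDS(val, file.path(paths$cache, "tensors_val.rds"))

message("development: ", length(dev$encounter_id), " encounters; ",
        "validation: ", length(val$encounter_id))
message("numeric block: ", ncol(dev$preop$numeric), " columns; ",
        "series width: ", ncol(dev$intraop[[1]]$series))
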