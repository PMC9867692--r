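# End-to-end experiment orchestration: synthetic cohort -> preprocessing
# -> deep and baseline model training -> prediction -> introspection ->
# evaluation, over the {preop, intraop, postop} x {individual,
# multitask} x {deep, random forest, gradient boosted trees} grid, with
# a provenance manifest.

#' Run the full experiment grid on a synthetic cohort
#'
#' Generates a cohort, splits it chronologically, fits the development
#' feature dictionary, trains the requested deep models and baselines,
#' and evaluates everything on the validation set: an AUROC comparison
#' table (phase x scheme x family x outcome), an uncertainty summary
#' (optional), ranked attribution tables (optional), and net
#' reclassification of postoperative versus preoperative deep
#' predictions. All stage seeds derive from the single `seed`.
#'
#' @param spec a [cohort_spec()] (its own seed is overridden by `seed`).
#' @param model_args named overrides for [model_config()] (e.g. smaller
#'   widths or epoch caps for desk-scale runs).
#' @param phases,schemes,families subsets of the grid to run.
#' @param n_bootstrap bootstrap resamples for AUROC confidence intervals
#'   (0 disables).
#' @param mc_trials Monte Carlo dropout trials for the uncertainty table
#'   (0 disables).
#' @param ig_encounters validation encounters to attribute per task for
#'   the ranked feature table (0 disables).
#' @param out_dir optional output directory for CSV tables and
#'   `manifest.json`.
#' @param seed global experiment seed.
#' @return A list with `metrics`, `uncertainty`, `attributions`, `nri`,
#'   `models`, `dictionary` and `manifest`.
#' @export
run_experiment <- function(spec,
                           model_args = list(),
                           phases = c("preop", "intraop", "postop"),
                           schemes = "multitask",
                           families = "deep",
                           n_bootstrap = 200,
                           mc_trials = 0,
                           ig_encounters = 0,
                           out_dir = NULL,
                           seed = 1L) {
  t_start <- Sys.time()
  spec$seed <- as.integer(derive_seed(seed, "synth"))
  truth <- plant_truth(spec)
  cohort <- generate_cohort(spec, truth)
  split <- split_chronological(cohort)
  dict <- fit_feature_dictionary(split$development)
  dev <- prepare_tensors(split$development, dict)
  val <- prepare_tensors(split$validation, dict)
  layout <- model_layout(dev)

  metrics <- list()
  unc_inputs <- list()
  models <- list()
  preds <- list()

  eval_preds <- function(pmat, labels, phase, scheme, family) {
    do.call(rbind, lapply(seq_len(ncol(pmat)), function(k) {
      onm <- colnames(pmat)[k]
      y <- labels[, onm]
      row <- compute_metrics(pmat[, k], y)
      ci <- if (n_bootstrap > 0) {
        bootstrap_ci(pmat[, k], y, auroc, n_resamples = n_bootstrap,
                     seed = derive_seed(seed, paste0("ci", phase, scheme,
                                                     family, onm)))
      } else c(lower = NA_real_, upper = NA_real_)
      cbind(data.frame(outcome = onm, phase = phase, scheme = scheme,
                       family = family), row,
            data.frame(auroc_lo = ci[["lower"]], auroc_hi = ci[["upper"]]))
    }))
  }

  if ("deep" %in% families) {
    for (phase in phases) {
      for (scheme in schemes) {
        tasks <- if (scheme == "individual") seq_len(9) else NA
        if (scheme == "multitask") {
          cfg <- do.call(model_config, c(
            list(phase = phase, scheme = scheme,
                 seed = derive_seed(seed, paste0("m", phase, scheme))),
            model_args))
          model <- train_model(build_model(cfg, layout), dev)
          pmat <- predict_risk_matrix(model, val)
          key <- paste(phase, scheme, sep = ".")
          models[[key]] <- model
          preds[[key]] <- pmat
          metrics[[key]] <- eval_preds(pmat, val$labels, phase, scheme,
                                       "deep")
          if (mc_trials > 0) {
            mc <- mc_dropout(model, val, n_trials = mc_trials,
                             seed = derive_seed(seed, paste0("mc", key)))
            unc_inputs[[key]] <- list(phase = phase, scheme = scheme,
                                      mc = mc, labels = val$labels)
          }
        } else {
          pmat <- matrix(NA_real_, length(val$encounter_id), 9,
                         dimnames = list(NULL, outcome_names()))
          for (k in tasks) {
            cfg <- do.call(model_config, c(
              list(phase = phase, scheme = "individual", outcome = k,
                   seed = derive_seed(seed, paste0("m", phase, k))),
              model_args))
            mk <- train_model(build_model(cfg, layout), dev)
            pmat[, k] <- predict_risk_matrix(mk, val)[, 1]
            models[[paste(phase, "individual", k, sep = ".")]] <- mk
          }
          key <- paste(phase, "individual", sep = ".")
          preds[[key]] <- pmat
          metrics[[key]] <- eval_preds(pmat, val$labels, phase,
                                       "individual", "deep")
        }
      }
    }
  }

  base_kinds <- intersect(families,
                          c("random_forest", "gradient_boosted_trees"))
  for (kind in base_kinds) {
    for (phase in phases) {
      fx_dev <- baseline_feature_matrix(dev, phase)
      fx_val <- baseline_feature_matrix(val, phase)
      pmat <- matrix(NA_real_, nrow(fx_val), 9,
                     dimnames = list(NULL, outcome_names()))
      for (k in seq_len(9)) {
        fit <- fit_baseline(fx_dev, dev$labels[, k], kind,
                            seed = derive_seed(seed, paste0(kind, phase, k)))
        pmat[, k] <- predict(fit, fx_val)
      }
      key <- paste(phase, kind, sep = ".")
      preds[[key]] <- pmat
      metrics[[key]] <- eval_preds(pmat, val$labels, phase, "per-outcome",
                                   kind)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  uncertainty <- if (length(unc_inputs) > 0) {
    summarize_uncertainty(unc_inputs)
  } else NULL

  attributions <- NULL
  att_model_key <- intersect(c("postop.multitask", "preop.multitask"),
                             names(models))
  if (ig_encounters > 0 && length(att_model_key) > 0) {
    am <- models[[att_model_key[1]]]
    idx <- seq_len(min(ig_encounters, length(val$encounter_id)))
    attributions <- lapply(seq_len(9), function(k) {
      reports <- lapply(idx, function(i) {
        integrated_gradients(am, val, i, task = k)
      })
      cbind(outcome = outcome_names()[k], aggregate_attributions(reports))
    })
    attributions <- do.call(rbind, attributions)
  }

  nri_table <- NULL
  if (all(c("preop.multitask", "postop.multitask") %in% names(preds))) {
    nri_table <- do.call(rbind, lapply(seq_len(9), function(k) {
      r <- nri(preds[["preop.multitask"]][, k],
               preds[["postop.multitask"]][, k], val$labels[, k])
      data.frame(outcome = outcome_names()[k], nri = r$nri,
                 nri_events = r$nri_events, nri_nonevents = r$nri_nonevents,
                 overall_correct_pct = r$overall_correct_pct,
                 p_value = r$p_value)
    }))
  }

  manifest <- list(
    seed = seed, spec_seed = spec$seed,
    n_encounters = spec$n_encounters,
    phases = phases, schemes = schemes, families = families,
    model_args = model_args,
    started = format(t_start), finished = format(Sys.time()),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("periopnet")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(uncertainty)) {
      data.table::fwrite(uncertainty, file.path(out_dir, "uncertainty.csv"))
    }
    if (!is.null(attributions)) {
      data.table::fwrite(attributions, file.path(out_dir, "attributions.csv"))
    }
    if (!is.null(nri_table)) {
      data.table::fwrite(nri_table, file.path(out_dir, "nri.csv"))
    }
    files <- list.files(out_dir, full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(metrics = metrics, uncertainty = uncertainty,
       attributions = attributions, nri = nri_table, models = models,
       predictions = preds, dictionary = dict, truth = truth,
       manifest = manifest)
}
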