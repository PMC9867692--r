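# Model introspection: Monte Carlo dropout predictive uncertainty and
# integrated-gradients feature attribution on the pre-sigmoid task
# logit.

#' Monte Carlo dropout uncertainty estimates
#'
#' Performs `n_trials` stochastic forward passes with dropout active at
#' inference (the same dropout layers and rate used in training) and
#' returns the per-encounter, per-task mean risk and sample variance of
#' the per-trial probabilities. The spread across trials approximates
#' Bayesian predictive uncertainty.
#'
#' @param model a `periop_model` with dropout layers (a model built with
#'   `dropout_rate = NULL` is rejected).
#' @param tensors [prepare_tensors()] output for the encounters to score.
#' @param n_trials stochastic passes (default 100).
#' @param seed integer seed for the dropout mask stream.
#' @param keep_trials retain the full trials array (default `TRUE`).
#' @return An object of class `mc_dropout`: `mean` and `variance`
#'   (encounters x tasks), `n_trials`, and optionally `trials`
#'   (encounters x tasks x trials).
#' @export
mc_dropout <- function(model, tensors, n_trials = 100, seed = 1L,
                       keep_trials = TRUE) {
  stopifnot(n_trials >= 2)
  if (is.null(model$config$dropout_rate)) {
    stop("model has no dropout layers; Monte Carlo dropout is unavailable")
  }
  n <- length(tensors$encounter_id)
  K <- n_heads(model$config)
  trials <- array(NA_real_, dim = c(n, K, n_trials))
  lens <- if (needs_intraop(model)) series_lengths(tensors) else NULL
  batches <- lapply(
    length_sorted_chunks(seq_len(n), model$config$batch_size, lens),
    function(bidx) make_batch(tensors, bidx, needs_intraop(model),
                              needs_preop(model)))
  set.seed(derive_seed(seed, "mc"))
  for (r in seq_len(n_trials)) {
    for (batch in batches) {
      fw <- nn_forward(model, batch, dropout_active = TRUE)
      trials[batch$idx, , r] <- sigmoid(fw$logits)
    }
  }
  mean_risk <- apply(trials, c(1, 2), mean)
  variance <- apply(trials, c(1, 2), var)
  out <- list(encounter_id = tensors$encounter_id,
              mean = mean_risk, variance = variance, n_trials = n_trials)
  if (keep_trials) out$trials <- trials
  class(out) <- "mc_dropout"
  out
}

#' Aggregate uncertainty into a per-outcome summary table
#'
#' One row per (outcome, prediction point, model type): the mean
#' prediction variance (reported as variance x 10^3) over all encounters
#' and the AUROC of the Monte Carlo mean risks against the labels.
#'
#' @param results list of entries, each a list with `phase`, `scheme`,
#'   `mc` (an [mc_dropout()] object) and `labels` (0/1 matrix aligned to
#'   the scored encounters).
#' @return A data frame with columns `Outcome`, `Prediction point`,
#'   `Model type`, `Mean uncertainty` (variance x 10^3) and
#'   `Mean AUROC`.
#' @export
summarize_uncertainty <- function(results) {
  rows <- list()
  for (res in results) {
    K <- ncol(res$mc$mean)
    onames <- if (K == 1) res$outcome else outcome_names()[seq_len(K)]
    for (k in seq_len(K)) {
      y <- if (is.matrix(res$labels)) {
        res$labels[, if (K == 1) res$outcome_index else k]
      } else res$labels
      if (length(unique(y)) < 2) {
        warning(sprintf("group %s/%s/%s has a single outcome class; row omitted",
                        onames[k], res$phase, res$scheme))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        Outcome = onames[k],
        `Prediction point` = res$phase,
        `Model type` = res$scheme,
        `Mean uncertainty` = mean(res$mc$variance[, k]) * 1000,
        `Mean AUROC` = auroc(res$mc$mean[, k], y),
        check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Forward pass of a single encounter at interpolation scale alpha in
# [0, 1], replicated across a batch of scales: inputs are alpha * x with
# the zero vector as baseline (embedded nominals are scaled in embedding
# space from the zero embedding).
ig_batch <- function(model, tensors, i, alphas) {
  m <- length(alphas)
  cfg <- model$config
  batch <- list(B = m, idx = rep(i, m))
  if (needs_preop(model)) {
    p <- tensors$preop
    xnum <- c(p$numeric[i, ], p$onehot[i, ], p$cyclic[i, ])
    batch$numeric <- outer(alphas, xnum)
    colnames(batch$numeric) <- c(colnames(p$numeric), colnames(p$onehot),
                                 colnames(p$cyclic))
    e <- cfg$embed_dim
    emb <- unlist(lapply(1:6, function(j) {
      model$params[[paste0("emb_", j)]][p$index[i, j] + 1L, ]
    }))
    batch$embed_override <- outer(alphas, emb)
    batch$index <- matrix(rep(p$index[i, ], each = m), m)
    batch$x_numeric <- xnum
    batch$x_embed <- emb
  }
  if (needs_intraop(model)) {
    tb <- tensors$intraop[[i]]
    Tn <- tb$length
    X <- array(0, dim = c(m, 24L, Tn))
    for (b in seq_len(m)) X[b, , ] <- alphas[b] * t(tb$series)
    batch$X <- X
    batch$lens <- rep(as.integer(Tn), m)
    batch$statics <- outer(alphas, as.numeric(tb$statics))
    batch$x_series <- tb$series
    batch$x_statics <- as.numeric(tb$statics)
  }
  batch
}

ig_logit <- function(model, batch, task) {
  fw <- nn_forward(model, batch, dropout_active = FALSE)
  fw$logits[, task]
}

#' Integrated-gradients attribution for one encounter and task
#'
#' Midpoint Riemann approximation of the path integral of the task-logit
#' gradient along the straight line from the zero-vector baseline (the
#' per-variable cohort mean in normalized space) to the input. The
#' pre-sigmoid logit is attributed, for which the completeness axiom
#' (attributions sum to F(x) - F(baseline)) holds exactly in the limit;
#' if the residual exceeds max(1e-3, 1% of |F(x) - F(0)|) the step count
#' doubles, up to `max_steps`. Embedded nominals are attributed by path
#' integration in embedding space from the zero embedding.
#'
#' @param model a `periop_model`.
#' @param tensors [prepare_tensors()] output.
#' @param i encounter index within `tensors`.
#' @param task task index (1 for individual-scheme models).
#' @param n_steps initial Riemann step count (default 50).
#' @param max_steps adaptive ceiling (default 400).
#' @return An object of class `attribution_report`: `static` (named, the
#'   full numeric block including masks/one-hots/cyclic), `nominal`
#'   (named, 6 embedded features, summed over embedding components),
#'   `temporal` (T x 24), `statics` (3), `f_x`, `f_baseline`,
#'   `completeness_residual`, `n_steps`.
#' @export
integrated_gradients <- function(model, tensors, i, task = 1,
                                 n_steps = 50, max_steps = 400) {
  cfg <- model$config
  stopifnot(task >= 1, task <= n_heads(cfg))
  repeat {
    alphas <- (seq_len(n_steps) - 0.5) / n_steps
    batch <- ig_batch(model, tensors, i, alphas)
    fw <- nn_forward(model, batch, dropout_active = FALSE)
    if (any(!is.finite(fw$logits))) stop("non-finite logits during attribution")
    dlog <- matrix(0, n_steps, n_heads(cfg))
    dlog[, task] <- 1
    bw <- nn_backward(model, batch, fw$cache, dlog,
                      param_grads = FALSE, input_grads = TRUE)
    rep_out <- list(encounter_id = tensors$encounter_id[i], task = task,
                    n_steps = n_steps)
    total <- 0
    if (needs_preop(model)) {
      g_num <- colMeans(bw$dnumeric)
      rep_out$static <- batch$x_numeric * g_num
      g_emb <- colMeans(bw$dembed)
      contrib <- batch$x_embed * g_emb
      e <- cfg$embed_dim
      rep_out$nominal <- vapply(1:6, function(j) {
        sum(contrib[(j - 1) * e + seq_len(e)])
      }, numeric(1))
      names(rep_out$nominal) <- colnames(tensors$preop$index)
      total <- total + sum(rep_out$static) + sum(rep_out$nominal)
    }
    if (needs_intraop(model)) {
      if (any(!is.finite(bw$dX))) stop("non-finite gradients during attribution")
      g_X <- apply(bw$dX, c(2, 3), mean)        # 24 x T
      rep_out$temporal <- batch$x_series * t(g_X)
      rep_out$statics <- batch$x_statics * colMeans(bw$dstatics)
      names(rep_out$statics) <- c("blood_loss", "urine_output", "duration")
      total <- total + sum(rep_out$temporal) + sum(rep_out$statics)
    }
    f1 <- ig_logit(model, ig_batch(model, tensors, i, 1), task)
    f0 <- ig_logit(model, ig_batch(model, tensors, i, 0), task)
    resid <- abs(total - (f1 - f0))
    rep_out$f_x <- f1
    rep_out$f_baseline <- f0
    rep_out$completeness_residual <- resid
    if (resid <= max(1e-3, 0.01 * abs(f1 - f0)) || n_steps >= max_steps) {
      class(rep_out) <- "attribution_report"
      return(rep_out)
    }
    n_steps <- min(2 * n_steps, max_steps)
  }
}

# Roll an attribution report up to interpretable feature names: a
# feature's presence-mask column folds into the feature, one-hot columns
# fold into their source nominal, cyclic pairs fold into admission day /
# month, temporal columns fold into their channel. Scores are sums of
# absolute attributions (signed sums cancel planted effects).
rollup_attributions <- function(report) {
  out <- numeric(0)
  add <- function(acc, names, vals) {
    s <- tapply(abs(vals), names, sum)
    for (nm in names(s)) acc[nm] <- (if (nm %in% names(acc)) acc[nm] else 0) + s[nm]
    acc
  }
  if (!is.null(report$static)) {
    nm <- names(report$static)
    nm <- sub("_mask$", "", nm)
    nm <- sub("^(nominal_[0-9]+)_.*$", "\\1", nm)
    nm[nm %in% c("day_sin", "day_cos")] <- "admission_day"
    nm[nm %in% c("month_sin", "month_cos")] <- "admission_month"
    out <- add(out, nm, report$static)
    out <- add(out, names(report$nominal), report$nominal)
  }
  if (!is.null(report$temporal)) {
    nm <- sub("_mask$", "", colnames(report$temporal))
    out <- add(out, rep(nm, each = nrow(report$temporal)),
               as.vector(report$temporal))
    out <- add(out, names(report$statics), report$statics)
  }
  out
}

#' Aggregate attributions across a cohort into a ranked feature table
#'
#' Per-feature mean absolute attribution over encounters (temporal
#' attributions rolled up per channel; masks, one-hot and cyclic columns
#' rolled into their source features), normalized to sum to one across
#' features, ranked descending.
#'
#' @param reports list of [integrated_gradients()] reports for one task
#'   on a common feature namespace.
#' @param top_k rows to return (default 10); `Inf` for all.
#' @return A data frame with `feature`, `score`, and a `label` column in
#'   "feature (score)" format.
#' @export
aggregate_attributions <- function(reports, top_k = 10) {
  rolled <- lapply(reports, rollup_attributions)
  nms <- names(rolled[[1]])
  if (!all(vapply(rolled, function(r) identical(names(r), nms), logical(1)))) {
    stop("attribution reports do not share a feature namespace")
  }
  m <- do.call(rbind, rolled)
  score <- colMeans(m)
  score <- score / sum(score)
  ord <- order(score, decreasing = TRUE)
  k <- min(top_k, length(score))
  data.frame(feature = nms[ord][seq_len(k)],
             score = unname(score[ord][seq_len(k)]),
             label = sprintf("%s (%.3f)", nms[ord][seq_len(k)],
                             score[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Per-channel temporal attribution profile
#'
#' Splits a report's temporal attribution matrix into channel-labeled
#' value and mask series aligned to the surgery timeline (suitable for
#' heatmap rendering).
#'
#' @param report an [integrated_gradients()] report with a temporal
#'   matrix.
#' @return A list with `value` and `mask`, each T x 12 with channel
#'   column names, and `minutes` (0-based).
#' @export
temporal_attribution_profile <- function(report) {
  if (is.null(report$temporal)) stop("report has no temporal attributions")
  tm <- report$temporal
  list(value = tm[, 1:12, drop = FALSE],
       mask = tm[, 13:24, drop = FALSE],
       minutes = seq_len(nrow(tm)) - 1L)
}
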