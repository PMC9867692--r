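# Class-weighted multi-task training with Adam, weight decay, and
# patience-based early stopping on an internal development holdout.

#' Inverse-frequency positive-class weights
#'
#' For each outcome, the weight applied to positive examples in the
#' binary cross-entropy is n_negative / n_positive, so minority-class
#' samples receive proportionally more focus.
#'
#' @param labels 0/1 matrix (encounters x outcomes) or vector.
#' @return Numeric vector of per-outcome positive-class weights.
#' @export
class_weights <- function(labels) {
  labels <- as.matrix(labels)
  vapply(seq_len(ncol(labels)), function(k) {
    y <- labels[, k]
    n_pos <- sum(y == 1)
    n_neg <- sum(y == 0)
    if (n_pos == 0 || n_neg == 0) {
      stop(sprintf("outcome %d has a single class; cannot derive a class weight",
                   k))
    }
    n_neg / n_pos
  }, numeric(1))
}

#' Early-stopping epoch under a patience rule
#'
#' Scans a per-epoch holdout-loss sequence and stops after `patience`
#' consecutive epochs without improvement over the best loss so far; the
#' best epoch's weights are the ones restored.
#'
#' @param losses numeric vector of per-epoch holdout losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return A list with `stop_epoch` and `best_epoch`.
#' @export
early_stopping_epoch <- function(losses, patience) {
  stopifnot(patience >= 1, length(losses) >= 1)
  best <- 1L
  for (e in seq_along(losses)) {
    if (losses[e] < losses[best]) best <- e
    if (e - best >= patience) {
      return(list(stop_epoch = e, best_epoch = best))
    }
  }
  list(stop_epoch = length(losses), best_epoch = best)
}

# Class-weighted binary cross-entropy and its logit gradient.
# labels: B x K; logits: B x K; weights: K positive-class weights.
weighted_bce <- function(logits, labels, weights) {
  p <- sigmoid(logits)
  eps <- 1e-12
  w <- 1 + sweep(labels, 2, weights - 1, `*`)
  loss <- -w * (labels * log(p + eps) + (1 - labels) * log(1 - p + eps))
  list(loss = sum(loss) / nrow(labels),
       dlogits = w * (p - labels) / nrow(labels))
}

decay_param <- function(name) {
  grepl("_W", name) || grepl("att_v", name)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (l2 > 0 && decay_param(nm) && !grepl("^emb_", nm)) {
      g <- g + l2 * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

task_labels <- function(model, labels) {
  if (model$config$scheme == "individual") {
    labels[, model$config$outcome, drop = FALSE]
  } else {
    labels
  }
}

needs_intraop <- function(model) model$config$phase != "preop"
needs_preop <- function(model) model$config$phase != "intraop"

# Chunk indices into minibatches after ordering by decreasing series
# length, so padded timesteps per batch stay low. Deterministic.
length_sorted_chunks <- function(idx, bs, lens = NULL) {
  if (!is.null(lens)) idx <- idx[order(lens[idx], decreasing = TRUE)]
  unname(split(idx, ceiling(seq_along(idx) / bs)))
}

# Stochastic epoch batching: shuffle, sort by series length within pools
# of several batches (keeping padding low), cut into minibatches, and
# shuffle the batch order. Without lengths this is a plain shuffle-split.
epoch_batches <- function(idx, bs, lens = NULL) {
  idx <- sample(idx)
  if (!is.null(lens)) {
    pools <- split(idx, ceiling(seq_along(idx) / (bs * 8L)))
    idx <- unlist(lapply(pools, function(p) {
      p[order(lens[p], decreasing = TRUE)]
    }), use.names = FALSE)
  }
  sets <- unname(split(idx, ceiling(seq_along(idx) / bs)))
  if (length(sets) > 1) sets <- sample(sets)
  sets
}

series_lengths <- function(tensors) {
  vapply(tensors$intraop, function(t) t$length, numeric(1))
}

# Mean holdout loss over an index set, dropout disabled.
eval_loss <- function(model, tensors, idx, weights) {
  lens <- if (needs_intraop(model)) series_lengths(tensors) else NULL
  total <- 0
  for (bidx in length_sorted_chunks(idx, model$config$batch_size, lens)) {
    batch <- make_batch(tensors, bidx, needs_intraop(model),
                        needs_preop(model))
    fw <- nn_forward(model, batch, dropout_active = FALSE)
    lb <- task_labels(model, batch$labels)
    total <- total + weighted_bce(fw$logits, lb, weights)$loss * length(bidx)
  }
  total / length(idx)
}

#' Train a risk model on development tensors
#'
#' Minimizes the sum of per-task class-weighted binary cross-entropies
#' with Adam (weight decay on non-embedding weight matrices). A seeded
#' 10% internal holdout of the development encounters drives early
#' stopping: training halts after `patience` consecutive epochs without
#' holdout improvement and the best epoch's weights are restored.
#'
#' @param model a [build_model()] handle.
#' @param tensors development-set [prepare_tensors()] output (with
#'   labels).
#' @param holdout_fraction internal early-stopping share (default 0.1).
#' @param verbose print per-epoch losses.
#' @return The trained model, with a `log` data frame (epoch, train and
#'   holdout loss) and the class weights used.
#' @export
train_model <- function(model, tensors, holdout_fraction = 0.1,
                        verbose = FALSE) {
  cfg <- model$config
  n <- nrow(tensors$labels)
  set.seed(derive_seed(cfg$seed, "train"))
  weights <- class_weights(task_labels(model, tensors$labels))
  hold <- sample.int(n, max(1, round(holdout_fraction * n)))
  devi <- setdiff(seq_len(n), hold)
  opt <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    holdout_loss = numeric(0))
  hold_losses <- numeric(0)
  best_params <- model$params
  bs <- cfg$batch_size
  lens <- if (needs_intraop(model)) series_lengths(tensors) else NULL

  for (epoch in seq_len(cfg$max_epochs)) {
    ep_loss <- 0
    for (bidx in epoch_batches(devi, bs, lens)) {
      batch <- make_batch(tensors, bidx, needs_intraop(model),
                          needs_preop(model))
      fw <- nn_forward(model, batch, dropout_active = TRUE)
      lb <- task_labels(model, batch$labels)
      bce <- weighted_bce(fw$logits, lb, weights)
      if (!is.finite(bce$loss)) {
        stop(sprintf("training diverged at epoch %d (non-finite loss)",
                     epoch))
      }
      bw <- nn_backward(model, batch, fw$cache, bce$dlogits)
      upd <- adam_step(model$params, bw$grads, opt, cfg$learning_rate,
                       cfg$l2)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + bce$loss * length(bidx)
    }
    hl <- eval_loss(model, tensors, hold, weights)
    hold_losses <- c(hold_losses, hl)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = ep_loss / length(devi),
                                 holdout_loss = hl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f holdout %.4f", epoch,
                      ep_loss / length(devi), hl))
    }
    es <- early_stopping_epoch(hold_losses, cfg$patience)
    if (es$best_epoch == epoch) best_params <- model$params
    if (es$stop_epoch == epoch && epoch < cfg$max_epochs &&
        epoch - es$best_epoch >= cfg$patience) {
      break
    }
  }
  es <- early_stopping_epoch(hold_losses, cfg$patience)
  model$params <- best_params
  model$trained <- TRUE
  model$log <- log
  model$class_weights <- weights
  model$best_epoch <- es$best_epoch
  model
}

#' Predict complication risks
#'
#' Deterministic forward pass with dropout disabled. Probabilities are
#' strictly inside (0, 1) (sigmoid outputs) and invariant to batch
#' composition.
#'
#' @param model a trained (or explicitly initialized) `periop_model`.
#' @param tensors [prepare_tensors()] output for the encounters to score.
#' @return A data frame (`RiskPrediction` rows): `encounter_id`,
#'   `phase`, `scheme`, `outcome`, `probability`.
#' @export
predict_risk <- function(model, tensors) {
  cfg <- model$config
  n <- length(tensors$encounter_id)
  K <- n_heads(cfg)
  probs <- matrix(NA_real_, n, K)
  lens <- if (needs_intraop(model)) series_lengths(tensors) else NULL
  for (bidx in length_sorted_chunks(seq_len(n), cfg$batch_size, lens)) {
    batch <- make_batch(tensors, bidx, needs_intraop(model),
                        needs_preop(model))
    fw <- nn_forward(model, batch, dropout_active = FALSE)
    probs[batch$idx, ] <- sigmoid(fw$logits)
  }
  out_names <- if (cfg$scheme == "individual") {
    outcome_names()[cfg$outcome]
  } else {
    outcome_names()[seq_len(K)]
  }
  data.frame(
    encounter_id = rep(tensors$encounter_id, times = K),
    phase = cfg$phase, scheme = cfg$scheme,
    outcome = rep(out_names, each = n),
    probability = as.vector(probs),
    stringsAsFactors = FALSE
  )
}

#' Risk-prediction matrix (encounters x outcomes)
#'
#' @inheritParams predict_risk
#' @return Numeric matrix of probabilities with outcome column names.
#' @export
predict_risk_matrix <- function(model, tensors) {
  pr <- predict_risk(model, tensors)
  K <- n_heads(model$config)
  m <- matrix(pr$probability, ncol = K)
  colnames(m) <- unique(pr$outcome)
  rownames(m) <- NULL
  m
}
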