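# Comparison arm: fixed-length intraoperative summary features and a
# thin harness over random forests (ranger) and gradient boosted trees
# (xgboost) on the same feature sets as the deep models, with
# high-cardinality nominals one-hot encoded.

#' Summary-statistic features from an intraoperative tensor
#'
#' Per channel (12): mean, standard deviation, minimum, maximum of the
#' one-minute resampled values (the value half of the T x 24 series;
#' mask columns are ignored), plus surgery duration in minutes: exactly
#' 49 features. Channels without raw measurements contribute statistics
#' of the median-filled series; attribute `median_filled` flags them.
#'
#' @param tensor an [assemble_intraop()] tensor.
#' @return Named numeric vector of length 49.
#' @export
extract_summary_features <- function(tensor) {
  stopifnot(inherits(tensor, "intraop_tensor"))
  values <- tensor$series[, 1:12, drop = FALSE]
  masks <- tensor$series[, 13:24, drop = FALSE]
  chn <- colnames(values)
  stats <- lapply(seq_len(12), function(c) {
    v <- values[, c]
    s <- if (length(v) > 1) sd(v) else 0
    setNames(c(mean(v), s, min(v), max(v)),
             paste0(chn[c], c("_mean", "_sd", "_min", "_max")))
  })
  out <- c(unlist(stats), duration = as.numeric(tensor$length))
  attr(out, "median_filled") <- setNames(colSums(masks) == 0, chn)
  out
}

# One-hot expansion of the 6 high-cardinality index-encoded nominals.
highcard_onehot <- function(preop) {
  blocks <- lapply(seq_len(ncol(preop$index)), function(k) {
    card <- preop$index_cardinalities[k]
    m <- matrix(0, nrow(preop$index), card)
    m[cbind(seq_len(nrow(m)), preop$index[, k] + 1L)] <- 1
    colnames(m) <- paste0(colnames(preop$index)[k], "_", seq_len(card) - 1L)
    m
  })
  do.call(cbind, blocks)
}

#' Baseline feature matrix for a phase
#'
#' Mirrors the deep models' inputs: the preoperative phase uses the
#' numeric block, one-hot nominals (including one-hot expanded
#' high-cardinality features) and cyclic features; the intraoperative
#' phase uses the 49 summary statistics plus the blood-loss and
#' urine-output statics; the postoperative phase concatenates both.
#'
#' @param tensors [prepare_tensors()] output.
#' @param phase `"preop"`, `"intraop"` or `"postop"`.
#' @return Numeric feature matrix.
#' @export
baseline_feature_matrix <- function(tensors,
                                    phase = c("postop", "preop", "intraop")) {
  phase <- match.arg(phase)
  pre <- NULL
  if (phase != "intraop") {
    p <- tensors$preop
    pre <- cbind(p$numeric, p$onehot, p$cyclic, highcard_onehot(p))
  }
  intra <- NULL
  if (phase != "preop") {
    sf <- t(vapply(tensors$intraop, extract_summary_features, numeric(49)))
    st <- t(vapply(tensors$intraop, function(t) t$statics, numeric(3)))
    colnames(st) <- c("blood_loss", "urine_output", "duration_z")
    intra <- cbind(sf, st[, c("blood_loss", "urine_output"), drop = FALSE])
  }
  cbind(pre, intra)
}

#' Fit a baseline classifier for one outcome
#'
#' Random forest (ranger) or gradient boosted trees (xgboost) with
#' inverse-frequency class weighting, library-default hyperparameters
#' and a fixed seed. Single-threaded so that repeated fits with the same
#' seed reproduce identical probabilities.
#'
#' @param features numeric feature matrix.
#' @param labels 0/1 outcome vector.
#' @param kind `"random_forest"` or `"gradient_boosted_trees"`.
#' @param seed integer seed.
#' @return An object of class `baseline_fit` holding the fitted model
#'   and `probabilities` aligned to the training encounter order.
#' @export
fit_baseline <- function(features, labels,
                         kind = c("random_forest",
                                  "gradient_boosted_trees"),
                         seed = 1L) {
  kind <- match.arg(kind)
  check_binary_labels(labels)
  w_pos <- class_weights(matrix(labels, ncol = 1))
  features <- as.matrix(features)
  if (kind == "random_forest") {
    df <- data.frame(.y = factor(labels, levels = c(0, 1)), features,
                     check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      case.weights = ifelse(labels == 1, w_pos, 1),
      seed = seed, num.threads = 1)
    probs <- fit$predictions[, "1"]
  } else {
    dtrain <- xgboost::xgb.DMatrix(features, label = labels)
    set.seed(seed)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    scale_pos_weight = w_pos, nthread = 1, seed = seed),
      data = dtrain, nrounds = 50, verbose = 0)
    probs <- predict(fit, dtrain)
  }
  structure(list(kind = kind, model = fit, seed = seed,
                 feature_names = colnames(features),
                 probabilities = probs),
            class = "baseline_fit")
}

#' Predict probabilities from a fitted baseline
#'
#' @param object a [fit_baseline()] result.
#' @param features feature matrix with the training columns.
#' @param ... unused.
#' @return Numeric probability vector.
#' @export
predict.baseline_fit <- function(object, features, ...) {
  features <- as.matrix(features)
  if (object$kind == "random_forest") {
    predict(object$model, data.frame(features, check.names = FALSE),
            num.threads = 1)$predictions[, "1"]
  } else {
    predict(object$model, xgboost::xgb.DMatrix(features))
  }
}
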