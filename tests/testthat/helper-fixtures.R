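# Shared small fixtures, built once per test run.

tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # prevalences high enough that every outcome shows both classes
      # in 80 encounters (needed by the training-based tests)
      spec <- cohort_spec(n_encounters = 80, seed = 7L,
                          prevalence_targets = rep(0.3, 9))
      truth <- plant_truth(spec)
      cohort <- generate_cohort(spec, truth)
      dict <- fit_feature_dictionary(cohort)
      tensors <- prepare_tensors(cohort, dict)
      cache <<- list(spec = spec, truth = truth, cohort = cohort,
                     dict = dict, tensors = tensors)
    }
    cache
  }
})

# A small model of the requested phase on the tiny fixture, untrained.
tiny_model <- function(phase, scheme = "multitask", dropout_rate = NULL,
                       seed = 7L, ...) {
  fx <- tiny_fixture()
  cfg <- model_config(phase = phase, scheme = scheme,
                      fc_dim = 6, rnn_hidden = 4, attention_dim = 3,
                      embed_dim = 3, dropout_rate = dropout_rate,
                      seed = seed, ...)
  build_model(cfg, model_layout(fx$tensors))
}

# Force every rectifier into its linear regime by adding large positive
# biases, making the preop logit affine in its inputs on the whole
# attribution path. IG is exact for affine maps at any step count.
affine_preop_model <- function(seed = 13L) {
  m <- tiny_model("preop", seed = seed)
  for (nm in c("num_b", "nom_b", "fuse_b")) {
    m$params[[nm]] <- m$params[[nm]] + 100
  }
  m
}

# Exhaustive-pair AUROC oracle (O(n^2)), independent of the package
# implementation.
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden search oracle under score >= threshold => positive,
# ties broken toward the lowest threshold.
exhaustive_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  thr[which(j == max(j))[1]]
}
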