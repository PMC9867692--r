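test_that("mc_dropout needs dropout layers and matches recomputed variance", {
  fx <- tiny_fixture()
  m0 <- tiny_model("preop", dropout_rate = NULL)
  expect_error(mc_dropout(m0, fx$tensors), "dropout")
  m <- tiny_model("preop", dropout_rate = 0.3)
  mc <- mc_dropout(m, fx$tensors, n_trials = 20, seed = 4L)
  expect_s3_class(mc, "mc_dropout")
  expect_equal(dim(mc$mean), c(80, 9))
  expect_equal(dim(mc$trials), c(80, 9, 20))
  # reported moments are exactly the sample moments of the kept trials
  expect_equal(mc$variance, apply(mc$trials, c(1, 2), var))
  expect_equal(mc$mean, apply(mc$trials, c(1, 2), mean))
  # seeded determinism and seed sensitivity
  mc2 <- mc_dropout(m, fx$tensors, n_trials = 20, seed = 4L)
  expect_identical(mc$trials, mc2$trials)
  mc3 <- mc_dropout(m, fx$tensors, n_trials = 20, seed = 5L)
  expect_false(identical(mc$trials, mc3$trials))
})

test_that("dropout rate zero yields exactly zero predictive variance", {
  fx <- tiny_fixture()
  m <- tiny_model("preop", dropout_rate = 0)
  mc <- mc_dropout(m, fx$tensors, n_trials = 5, seed = 1L,
                   keep_trials = FALSE)
  expect_true(all(mc$variance == 0))
  expect_null(mc$trials)
})

test_that("summarize_uncertainty emits the documented table", {
  fx <- tiny_fixture()
  m <- tiny_model("preop", dropout_rate = 0.2)
  mc <- mc_dropout(m, fx$tensors, n_trials = 5, seed = 2L)
  tab <- summarize_uncertainty(list(list(
    phase = "preop", scheme = "multitask", mc = mc,
    labels = fx$tensors$labels)))
  expect_identical(colnames(tab),
                   c("Outcome", "Prediction point", "Model type",
                     "Mean uncertainty", "Mean AUROC"))
  expect_equal(nrow(tab), 9)
  expect_equal(tab[["Mean uncertainty"]][1], mean(mc$variance[, 1]) * 1000)
  expect_equal(tab[["Mean AUROC"]][3],
               auroc(mc$mean[, 3], fx$tensors$labels[, 3]))
  # single-class groups warn and drop out instead of poisoning the table
  labs <- fx$tensors$labels
  labs[, 2] <- 0
  expect_warning(tab2 <- summarize_uncertainty(list(list(
    phase = "preop", scheme = "multitask", mc = mc, labels = labs))),
    "single outcome class")
  expect_equal(nrow(tab2), 8)
})

test_that("integrated gradients are exact on an affine network", {
  fx <- tiny_fixture()
  m <- affine_preop_model()
  ig <- integrated_gradients(m, fx$tensors, i = 3, task = 2, n_steps = 8)
  # completeness at machine precision, no adaptive refinement needed
  expect_lt(ig$completeness_residual, 1e-8)
  expect_equal(ig$n_steps, 8)
  total <- sum(ig$static) + sum(ig$nominal)
  expect_equal(total, ig$f_x - ig$f_baseline, tolerance = 1e-8)
  # per-feature exactness: attribution_i = x_i * dF/dx_i, with the
  # gradient estimated by central differences through the whole network
  eps <- 1e-4
  for (j in c(1, 50, 400)) {
    b1 <- periopnet:::ig_batch(m, fx$tensors, 3, 1)
    x <- unname(b1$numeric[1, j])
    b1$numeric[1, j] <- x + eps
    f_hi <- periopnet:::ig_logit(m, b1, 2)
    b1$numeric[1, j] <- x - eps
    f_lo <- periopnet:::ig_logit(m, b1, 2)
    expect_equal(unname(ig$static[j]), x * (f_hi - f_lo) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("the baseline gets zero attribution and zero inputs get zero", {
  fx <- tiny_fixture()
  m <- affine_preop_model()
  # an input equal to the baseline has nothing to attribute
  tz <- fx$tensors
  tz$preop$numeric[5, ] <- 0
  tz$preop$onehot[5, ] <- 0
  tz$preop$cyclic[5, ] <- 0
  ig <- integrated_gradients(m, tz, i = 5, task = 1, n_steps = 4)
  expect_true(all(ig$static == 0))
  # only the embedded nominals differ from the baseline here, so they
  # carry the whole logit difference
  expect_equal(sum(ig$nominal), ig$f_x - ig$f_baseline, tolerance = 1e-8)
  # zero-valued coordinates of a nonzero input also get exactly zero
  ig2 <- integrated_gradients(m, fx$tensors, i = 6, task = 1, n_steps = 4)
  zero_cols <- which(periopnet:::ig_batch(m, fx$tensors, 6, 1)$numeric[1, ] == 0)
  expect_true(all(ig2$static[zero_cols] == 0))
})

test_that("completeness holds on a trained nonlinear multitask model", {
  fx <- tiny_fixture()
  m <- train_model(tiny_model("postop", max_epochs = 2, seed = 17L),
                   fx$tensors)
  ig <- integrated_gradients(m, fx$tensors, i = 2, task = 4)
  expect_lte(ig$completeness_residual,
             max(1e-3, 0.01 * abs(ig$f_x - ig$f_baseline)))
  expect_equal(dim(ig$temporal),
               c(fx$tensors$intraop[[2]]$length, 24))
  expect_length(ig$statics, 3)
  expect_length(ig$nominal, 6)
})

test_that("rollup folds masks, one-hots, cyclic pairs and channels", {
  fx <- tiny_fixture()
  m <- tiny_model("postop")
  ig <- integrated_gradients(m, fx$tensors, i = 1, task = 1, n_steps = 8,
                             max_steps = 8)
  r <- rollup_attributions(ig)
  nms <- names(r)
  expect_false(any(grepl("_mask$", nms)))
  expect_true(all(c("admission_day", "admission_month") %in% nms))
  expect_true("hr" %in% nms)                       # channel rollup
  expect_true(all(paste0("nominal_", 1:19) %in% nms) ||
                any(grepl("^nominal_", nms)))
  # absolute-value aggregation: every score is nonnegative
  expect_true(all(r >= 0))
  # a folded feature's score is the |.|-sum of its member columns
  hr_cols <- grep("^hr(_mask)?$", colnames(ig$temporal))
  expect_equal(unname(r["hr"]), sum(abs(ig$temporal[, hr_cols])))
})

test_that("aggregate_attributions ranks, normalizes, and checks namespaces", {
  fx <- tiny_fixture()
  m <- tiny_model("preop")
  igs <- lapply(1:3, function(i) {
    integrated_gradients(m, fx$tensors, i, task = 1, n_steps = 4,
                         max_steps = 4)
  })
  tab <- aggregate_attributions(igs, top_k = 5)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$score) <= 0))
  expect_identical(tab$label,
                   sprintf("%s (%.3f)", tab$feature, tab$score))
  full <- aggregate_attributions(igs, top_k = Inf)
  expect_equal(sum(full$score), 1, tolerance = 1e-12)
  # mismatched namespaces (preop-only vs postop reports) must error
  m2 <- tiny_model("postop")
  ig_post <- integrated_gradients(m2, fx$tensors, 1, task = 1, n_steps = 4,
                                  max_steps = 4)
  expect_error(aggregate_attributions(list(igs[[1]], ig_post)),
               "namespace")
})

test_that("temporal_attribution_profile exposes aligned channel series", {
  fx <- tiny_fixture()
  m <- tiny_model("intraop")
  ig <- integrated_gradients(m, fx$tensors, i = 4, task = 1, n_steps = 4,
                             max_steps = 4)
  pr <- temporal_attribution_profile(ig)
  Tn <- fx$tensors$intraop[[4]]$length
  expect_equal(dim(pr$value), c(Tn, 12))
  expect_equal(dim(pr$mask), c(Tn, 12))
  expect_equal(pr$minutes, 0:(Tn - 1))
  expect_identical(colnames(pr$value),
                   intraop_channels()$channel)
  # a preop-only report has no timeline to profile
  ig_pre <- integrated_gradients(tiny_model("preop"), fx$tensors, 1,
                                 n_steps = 4, max_steps = 4)
  expect_error(temporal_attribution_profile(ig_pre), "temporal")
})
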