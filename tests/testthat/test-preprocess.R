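test_that("the dictionary caps, medians and SDs come from observed values", {
  fx <- tiny_fixture()
  d <- fx$dict
  xc <- fx$cohort$preop_continuous
  j <- 5
  v <- xc[, j][!is.na(xc[, j])]
  caps <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  expect_equal(d$continuous$cap_lo[j], caps[1])
  expect_equal(d$continuous$cap_hi[j], caps[2])
  vc <- pmin(pmax(v, caps[1]), caps[2])
  expect_equal(d$continuous$median[j], median(vc))
  expect_equal(d$continuous$sd[j], sd(vc))
  # binary medians are majority values on observed entries
  xb <- fx$cohort$preop_binary[, 3]
  expect_equal(d$binary$median[3], median(xb[!is.na(xb)]))
})

test_that("cap -> impute -> z-normalize is applied in that order", {
  fx <- tiny_fixture()
  p <- fx$tensors$preop
  d <- fx$dict
  xc <- fx$cohort$preop_continuous
  for (j in c(1, 100, 341)) {
    v <- pmin(pmax(xc[, j], d$continuous$cap_lo[j]), d$continuous$cap_hi[j])
    v[is.na(v)] <- d$continuous$median[j]
    z <- (v - d$continuous$mean[j]) / d$continuous$sd[j]
    expect_equal(unname(p$numeric[, j]), unname(z), tolerance = 1e-12)
  }
  # an imputed entry sits exactly at the normalized development median
  na_pos <- which(is.na(xc[, 1]))[1]
  expect_equal(unname(p$numeric[na_pos, 1]),
               (d$continuous$median[1] - d$continuous$mean[1]) /
                 d$continuous$sd[1])
})

test_that("masks record the pre-imputation missingness pattern", {
  fx <- tiny_fixture()
  p <- fx$tensors$preop
  mask_cols <- 384:766
  expect_equal(unname(p$numeric[, 341 + 42 + seq_len(341)]),
               unname(1 - is.na(fx$cohort$preop_continuous)) + 0)
  expect_true(all(p$numeric[, mask_cols] %in% c(0, 1)))
})

test_that("binary features are imputed and masked but not normalized", {
  fx <- tiny_fixture()
  p <- fx$tensors$preop
  bin_block <- p$numeric[, 341 + seq_len(42)]
  # median imputation of a balanced binary feature can land on 0.5
  expect_true(all(bin_block %in% c(0, 0.5, 1)))
  expect_false(anyNA(bin_block))
})

test_that("the numeric block is 766 columns wide: values then masks", {
  fx <- tiny_fixture()
  expect_equal(ncol(fx$tensors$preop$numeric), 766)
  expect_equal(sum(grepl("_mask$", colnames(fx$tensors$preop$numeric))), 383)
})

test_that("one-hot rows sum to one including the explicit missing level", {
  fx <- tiny_fixture()
  p <- fx$tensors$preop
  # 13 low-cardinality nominals, each with dev levels + "missing"
  starts <- 0
  for (j in which(fx$dict$nominal_low_card)) {
    w <- length(fx$dict$nominal_levels[[j]]) + 1
    block <- p$onehot[, starts + seq_len(w), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
    starts <- starts + w
  }
  expect_equal(starts, ncol(p$onehot))
  # a missing raw value activates exactly the missing column
  na_i <- which(is.na(fx$cohort$preop_nominal[[1]]))[1]
  if (!is.na(na_i)) {
    miss_col <- grep("^nominal_1_missing$", colnames(p$onehot))
    expect_equal(unname(p$onehot[na_i, miss_col]), 1)
  }
})

test_that("high-cardinality nominals are 0-based indices with missing = L", {
  fx <- tiny_fixture()
  p <- fx$tensors$preop
  expect_equal(ncol(p$index), 6)
  for (k in 1:6) {
    card <- p$index_cardinalities[k]
    expect_true(all(p$index[, k] >= 0 & p$index[, k] <= card - 1))
  }
  j <- which(!fx$dict$nominal_low_card)[1]
  na_i <- which(is.na(fx$cohort$preop_nominal[[j]]))[1]
  if (!is.na(na_i)) {
    expect_equal(unname(p$index[na_i, 1]),
                 length(fx$dict$nominal_levels[[j]]))
  }
})

test_that("unseen nominal levels map to missing with a message", {
  fx <- tiny_fixture()
  co <- subset_cohort(fx$cohort, 1:5)
  j <- which(!fx$dict$nominal_low_card)[1]
  co$preop_nominal[[j]][1] <- "L9999"
  expect_message(p <- transform_preop(co, fx$dict), "missing")
  expect_equal(unname(p$index[1, 1]), length(fx$dict$nominal_levels[[j]]))
})

test_that("cyclic encoding wraps and rejects out-of-range indices", {
  cc <- encode_cyclic(0:6, 0:6)
  expect_true(all(abs(cc[, "day_sin"]^2 + cc[, "day_cos"]^2 - 1) < 1e-12))
  expect_equal(unname(encode_cyclic(0, 0)[1, ]), c(0, 1, 0, 1))
  # adjacency wraps: distance(Dec, Jan) == distance(Jan, Feb)
  m <- encode_cyclic(0, 0:11)[, c("month_sin", "month_cos")]
  d_dec_jan <- sqrt(sum((m[12, ] - m[1, ])^2))
  d_jan_feb <- sqrt(sum((m[1, ] - m[2, ])^2))
  expect_equal(d_dec_jan, d_jan_feb, tolerance = 1e-12)
  expect_error(encode_cyclic(7, 0), "0..6")
  expect_error(encode_cyclic(0, 12), "0..11")
})

test_that("resample_channel follows the one-minute grid rules", {
  # linear interior interpolation
  rc <- resample_channel(cbind(minute = c(0, 4), value = c(10, 18)), 5, 0)
  expect_equal(rc$values, c(10, 12, 14, 16, 18))
  expect_equal(rc$mask, c(1, 0, 0, 0, 1))
  # edge extension, not extrapolation
  rc <- resample_channel(cbind(minute = c(2, 3), value = c(5, 7)), 6, 0)
  expect_equal(rc$values, c(5, 5, 5, 7, 7, 7))
  # duplicates at one grid minute are averaged
  rc <- resample_channel(cbind(minute = c(1, 1), value = c(4, 6)), 3, 0)
  expect_equal(rc$values, rep(5, 3))
  expect_equal(rc$mask, c(0, 1, 0))
  # a single measurement extends everywhere
  rc <- resample_channel(cbind(minute = 2, value = 9), 4, 0)
  expect_equal(rc$values, rep(9, 4))
  # empty channel: development median, all-zero mask
  rc <- resample_channel(NULL, 3, 42)
  expect_equal(rc$values, rep(42, 3))
  expect_equal(rc$mask, rep(0, 3))
  expect_error(resample_channel(cbind(minute = -1, value = 0), 3, 0),
               "within")
})

test_that("assembled intraoperative tensors are T x 24 and normalized", {
  fx <- tiny_fixture()
  for (i in c(1, 40)) {
    tb <- fx$tensors$intraop[[i]]
    expect_s3_class(tb, "intraop_tensor")
    expect_equal(dim(tb$series),
                 c(fx$cohort$static$duration[i], 24))
    expect_equal(tb$length, fx$cohort$static$duration[i])
    expect_true(all(tb$series[, 13:24] %in% c(0, 1)))
    expect_equal(length(tb$statics), 3)
  }
  # values are z-scores of the raw series under pooled channel statistics
  i <- 1
  tb <- fx$tensors$intraop[[i]]
  ch <- fx$dict$channels
  rc <- resample_channel(fx$cohort$intraop[[i]][["hr"]],
                         fx$cohort$static$duration[i],
                         ch$median[ch$channel == "hr"])
  expect_equal(unname(tb$series[, "hr"]),
               (rc$values - ch$mean[ch$channel == "hr"]) /
                 ch$sd[ch$channel == "hr"], tolerance = 1e-12)
})

test_that("the dictionary blocks validation leakage by construction", {
  fx <- tiny_fixture()
  sp <- split_chronological(fx$cohort)
  d_dev <- fit_feature_dictionary(sp$development)
  # transforming validation data must not touch validation statistics:
  # transform with the dev dictionary, then check a validation column is
  # NOT zero-mean under its own statistics unless by accident
  p_val <- transform_preop(sp$validation, d_dev)
  expect_equal(ncol(p_val$numeric), 766)
  # deterministic: same inputs, same dictionary, same output
  p2 <- transform_preop(sp$validation, d_dev)
  expect_identical(p_val, p2)
})
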