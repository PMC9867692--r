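# Preoperative preprocessing: development-set feature dictionary
# (percentile caps, medians, normalization statistics, nominal level
# maps), the cap -> impute -> z-normalize pipeline with presence masks,
# nominal encodings, and cyclic calendar features.

#' Fit the development-set feature dictionary
#'
#' Computes, on observed (non-missing) development values only: 1st/99th
#' percentile caps for continuous features (linear-interpolation
#' percentile convention), medians/means/SDs on the capped scale,
#' majority-value medians for binary features, nominal level-to-index
#' maps (with a distinct "missing" level), pooled per-channel statistics
#' for the intraoperative series, and normalization statistics for the
#' end-of-surgery statics. The dictionary is fitted once on the
#' development set and reused verbatim everywhere else, so no validation
#' information leaks into the transforms.
#'
#' A feature with zero observed development values falls back to a median
#' of 0 with a warning; constant features keep their value as both caps
#' and get an SD of 1 so column indices stay stable.
#'
#' @param cohort the development `periop_cohort`.
#' @return An object of class `feature_dictionary`.
#' @export
fit_feature_dictionary <- function(cohort) {
  stopifnot(inherits(cohort, "periop_cohort"), n_encounters(cohort) > 0)
  xc <- cohort$preop_continuous
  cont <- lapply(seq_len(ncol(xc)), function(j) {
    v <- xc[, j][!is.na(xc[, j])]
    if (length(v) == 0) {
      warning(sprintf("continuous feature '%s' has no observed development values; median falls back to 0",
                      colnames(xc)[j]))
      return(data.frame(cap_lo = 0, cap_hi = 0, median = 0, mean = 0, sd = 1))
    }
    caps <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    vc <- pmin(pmax(v, caps[1]), caps[2])
    s <- sd(vc)
    if (is.na(s) || s == 0) s <- 1
    data.frame(cap_lo = caps[1], cap_hi = caps[2], median = median(vc),
               mean = mean(vc), sd = s)
  })
  cont <- do.call(rbind, cont)
  cont$feature <- colnames(xc)

  xb <- cohort$preop_binary
  bin <- data.frame(
    feature = colnames(xb),
    median = vapply(seq_len(ncol(xb)), function(j) {
      v <- xb[, j][!is.na(xb[, j])]
      if (length(v) == 0) {
        warning(sprintf("binary feature '%s' has no observed development values; median falls back to 0",
                        colnames(xb)[j]))
        return(0)
      }
      median(v)
    }, numeric(1))
  )

  nominal <- lapply(cohort$preop_nominal, function(v) {
    sort(unique(v[!is.na(v)]))
  })
  names(nominal) <- names(cohort$preop_nominal)
  # the declared 13/6 split, not the realized level counts, decides routing
  low_card <- cohort$spec$nominal_cardinalities < 5

  channels <- intraop_channels()$channel
  pooled <- lapply(setNames(channels, channels), function(cc) {
    vals <- unlist(lapply(cohort$intraop, function(series) {
      if (is.null(series)) return(numeric(0))
      series[[cc]][, "value"]
    }), use.names = FALSE)
    if (length(vals) == 0) {
      warning(sprintf("channel '%s' has no development measurements", cc))
      return(c(median = 0, mean = 0, sd = 1))
    }
    s <- sd(vals); if (is.na(s) || s == 0) s <- 1
    c(median = median(vals), mean = mean(vals), sd = s)
  })
  chan <- do.call(rbind, pooled)
  chan <- data.frame(channel = rownames(chan), chan, row.names = NULL)

  statics <- vapply(c("blood_loss", "urine_output", "duration"), function(f) {
    v <- cohort$static[[f]]
    s <- sd(v); if (is.na(s) || s == 0) s <- 1
    c(mean = mean(v), sd = s)
  }, numeric(2))

  structure(list(continuous = cont, binary = bin, nominal_levels = nominal,
                 nominal_low_card = low_card,
                 nominal_cardinalities = cohort$spec$nominal_cardinalities,
                 channels = chan, statics = t(statics)),
            class = "feature_dictionary")
}

#' Cyclic encoding of admission day and month
#'
#' Maps a 0-based day-of-week index (period 7) and month index (period
#' 12) to sine/cosine pairs, so that adjacency wraps: December sits as
#' close to January as January does to February.
#'
#' @param day_index integer(s) in 0..6.
#' @param month_index integer(s) in 0..11.
#' @return A matrix with columns `day_sin`, `day_cos`, `month_sin`,
#'   `month_cos`.
#' @export
encode_cyclic <- function(day_index, month_index) {
  if (any(day_index < 0 | day_index > 6)) stop("day_index must be in 0..6")
  if (any(month_index < 0 | month_index > 11)) {
    stop("month_index must be in 0..11")
  }
  cbind(day_sin = sin(2 * pi * day_index / 7),
        day_cos = cos(2 * pi * day_index / 7),
        month_sin = sin(2 * pi * month_index / 12),
        month_cos = cos(2 * pi * month_index / 12))
}

cap_values <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Transform preoperative features into the model-ready matrix
#'
#' Applies, in order, percentile capping, median imputation and
#' z-normalization (development statistics throughout), and records a
#' presence mask (1 = observed, 0 = imputed) over all continuous and
#' binary features *before* imputation. Binary features are imputed and
#' masked but not z-normalized. Low-cardinality nominals are one-hot
#' encoded over their development levels plus an explicit "missing"
#' level; high-cardinality nominals become 0-based integer identifiers
#' with the "missing" index equal to the development level count. Unseen
#' levels at transform time map to "missing" with a message.
#'
#' @param cohort a `periop_cohort`.
#' @param dictionary a fitted [fit_feature_dictionary()].
#' @return An object of class `preop_matrix` with elements `numeric`
#'   (N x 766: 383 values then 383 mask columns), `onehot`, `index`
#'   (N x 6, 0-based), `cyclic` (N x 4) and `index_cardinalities` (level
#'   count + 1 per embedded feature).
#' @export
transform_preop <- function(cohort, dictionary) {
  stopifnot(inherits(cohort, "periop_cohort"),
            inherits(dictionary, "feature_dictionary"))
  n <- n_encounters(cohort)
  xc <- cohort$preop_continuous
  xb <- cohort$preop_binary
  dc <- dictionary$continuous

  mask_c <- 1 - is.na(xc)
  vc <- xc
  for (j in seq_len(ncol(vc))) {
    v <- cap_values(vc[, j], dc$cap_lo[j], dc$cap_hi[j])
    v[is.na(v)] <- dc$median[j]
    vc[, j] <- (v - dc$mean[j]) / dc$sd[j]
  }
  mask_b <- 1 - is.na(xb)
  vb <- xb
  for (j in seq_len(ncol(vb))) {
    vb[is.na(vb[, j]), j] <- dictionary$binary$median[j]
  }
  values <- cbind(vc, vb)
  mask <- cbind(mask_c, mask_b)
  colnames(mask) <- paste0(colnames(values), "_mask")
  numeric_block <- cbind(values, mask)

  low <- which(dictionary$nominal_low_card)
  high <- which(!dictionary$nominal_low_card)
  onehot <- matrix(0, n, 0)
  oh_names <- character(0)
  n_unseen <- 0L
  for (j in low) {
    lv <- dictionary$nominal_levels[[j]]
    v <- cohort$preop_nominal[[j]]
    idx <- match(v, lv)
    n_unseen <- n_unseen + sum(!is.na(v) & is.na(idx))
    idx[is.na(idx)] <- length(lv) + 1L   # the "missing" level
    block <- matrix(0, n, length(lv) + 1L)
    block[cbind(seq_len(n), idx)] <- 1
    colnames(block) <- paste0(names(dictionary$nominal_levels)[j], "_",
                              c(lv, "missing"))
    onehot <- cbind(onehot, block)
  }
  index <- matrix(0L, n, length(high))
  cards <- integer(length(high))
  for (k in seq_along(high)) {
    j <- high[k]
    lv <- dictionary$nominal_levels[[j]]
    v <- cohort$preop_nominal[[j]]
    idx <- match(v, lv)
    n_unseen <- n_unseen + sum(!is.na(v) & is.na(idx))
    idx[is.na(idx)] <- length(lv) + 1L
    index[, k] <- idx - 1L               # 0-based; "missing" = n_levels
    cards[k] <- length(lv) + 1L
  }
  colnames(index) <- names(dictionary$nominal_levels)[high]
  if (n_unseen > 0) {
    message(sprintf("%d nominal values mapped to the 'missing' level (unseen in development)",
                    n_unseen))
  }
  cyclic <- encode_cyclic(cohort$static$admission_day,
                          cohort$static$admission_month)
  structure(list(numeric = numeric_block, onehot = onehot,
                 index = index, cyclic = cyclic,
                 index_cardinalities = cards,
                 encounter_id = cohort$static$encounter_id),
            class = "preop_matrix")
}
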