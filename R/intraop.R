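# Intraoperative tensor assembly: one-minute regridding of irregular
# channel measurements with linear interior interpolation, nearest-value
# edge extension, per-channel presence masks, development-median filling
# of empty channels, and z-normalization.

#' Resample one channel onto the one-minute surgery grid
#'
#' A duration-`T` surgery maps to grid minutes 0..T-1. Measurement
#' offsets are rounded to the nearest grid minute (duplicates averaged);
#' interior gaps are filled by linear interpolation and positions before
#' the first / after the last measurement take the nearest observed value
#' (edge extension rather than extrapolation, which can leave the
#' physiological range). A channel with no measurements is filled with
#' the development median at every step and gets an all-zero mask.
#'
#' @param measurements a two-column matrix `(minute, value)` with minutes
#'   in \[0, T\], or `NULL` / zero rows for an unmeasured channel.
#' @param T surgery duration in minutes (grid length).
#' @param dev_median development-set median for the channel.
#' @return A list with `values` (length `T`) and `mask` (length `T`;
#'   1 only at grid minutes carrying an actual measurement).
#' @export
resample_channel <- function(measurements, T, dev_median) {
  stopifnot(T >= 1)
  if (is.null(measurements) || nrow(measurements) == 0) {
    return(list(values = rep(dev_median, T), mask = rep(0, T)))
  }
  minute <- measurements[, 1]
  if (any(minute < 0 | minute > T)) {
    stop("measurement minutes must lie within [0, T]")
  }
  m <- pmin(as.integer(round(minute)), T - 1L)
  v <- as.numeric(measurements[, 2])
  if (anyDuplicated(m)) {
    agg <- tapply(v, m, mean)
    m <- as.integer(names(agg))
    v <- as.numeric(agg)
  }
  ord <- order(m)
  m <- m[ord]; v <- v[ord]
  grid <- 0:(T - 1)
  if (length(m) == 1) {
    values <- rep(v, T)
  } else {
    values <- approx(m, v, xout = grid, method = "linear", rule = 2)$y
  }
  mask <- as.numeric(grid %in% m)
  list(values = values, mask = mask)
}

#' Assemble one encounter's intraoperative tensor
#'
#' Resamples all 12 channels onto the one-minute grid, z-normalizes the
#' values with development channel statistics, concatenates the 12
#' presence-mask columns (yielding 24 predictors per timestep), and
#' appends the z-normalized end-of-surgery statics (blood loss sum, urine
#' output sum, duration).
#'
#' @param series per-channel list of `(minute, value)` matrices (may hold
#'   `NULL` entries for unmeasured channels).
#' @param duration surgery length in minutes; must be at least 1.
#' @param statics named numeric vector with `blood_loss`, `urine_output`,
#'   `duration` (raw scale).
#' @param dictionary a fitted [fit_feature_dictionary()].
#' @return An object of class `intraop_tensor`: `series` (T x 24 matrix,
#'   12 value columns then 12 mask columns), `length` and `statics`
#'   (z-normalized, length 3).
#' @export
assemble_intraop <- function(series, duration, statics, dictionary) {
  if (duration < 1) stop("surgery duration must be at least 1 minute")
  ch <- dictionary$channels
  values <- matrix(0, duration, nrow(ch))
  mask <- matrix(0, duration, nrow(ch))
  for (c in seq_len(nrow(ch))) {
    rc <- resample_channel(series[[ch$channel[c]]], duration, ch$median[c])
    values[, c] <- (rc$values - ch$mean[c]) / ch$sd[c]
    mask[, c] <- rc$mask
  }
  colnames(values) <- ch$channel
  colnames(mask) <- paste0(ch$channel, "_mask")
  st <- dictionary$statics
  z <- (as.numeric(statics[rownames(st)]) - st[, "mean"]) / st[, "sd"]
  structure(list(series = cbind(values, mask), length = duration,
                 statics = setNames(z, rownames(st))),
            class = "intraop_tensor")
}

#' Prepare all model-ready tensors for a cohort
#'
#' Convenience wrapper: transforms the preoperative matrix and assembles
#' every encounter's intraoperative tensor with one dictionary.
#'
#' @param cohort a `periop_cohort`.
#' @param dictionary a fitted [fit_feature_dictionary()].
#' @return A list with `preop` ([transform_preop()] output), `intraop`
#'   (list of [assemble_intraop()] tensors) and `labels` (N x 9 outcome
#'   matrix).
#' @export
prepare_tensors <- function(cohort, dictionary) {
  preop <- transform_preop(cohort, dictionary)
  intraop <- lapply(seq_len(n_encounters(cohort)), function(i) {
    assemble_intraop(
      cohort$intraop[[i]], cohort$static$duration[i],
      c(blood_loss = cohort$static$blood_loss[i],
        urine_output = cohort$static$urine_output[i],
        duration = cohort$static$duration[i]),
      dictionary)
  })
  list(preop = preop, intraop = intraop, labels = cohort$outcomes,
       encounter_id = cohort$static$encounter_id)
}
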