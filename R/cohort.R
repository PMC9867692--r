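# Seeded synthetic perioperative cohort generator. Emulates the data
# structure the pipeline assumes -- static preoperative features with
# informative-missingness bookkeeping, irregular multivariate
# intraoperative series, end-of-surgery statics, and nine correlated
# binary complications -- with planted ground-truth risk drivers so that
# discrimination and attribution can be verified against a known answer.

#' Names of the nine postoperative complication outcomes
#' @return Character vector of length 9.
#' @export
outcome_names <- function() {
  c("prolonged_icu", "prolonged_mv", "wound", "neuro", "cardiovascular",
    "sepsis", "aki", "vte", "mortality")
}

#' Default outcome prevalence targets
#'
#' Validation-cohort incidences of the nine complications: prolonged ICU
#' stay 33.3%, prolonged mechanical ventilation 7.8%, wound 21.4%,
#' neurological 20.2%, cardiovascular 16.3%, sepsis 8.7%, acute kidney
#' injury 16.9%, venous thromboembolism 5.4%, in-hospital mortality 1.6%.
#' @return Named numeric vector of length 9.
#' @export
default_prevalences <- function() {
  setNames(c(0.333, 0.078, 0.214, 0.202, 0.163, 0.087, 0.169, 0.054, 0.016),
           outcome_names())
}

#' The twelve intraoperative physiological channels
#'
#' Set-points, stationary standard deviations, AR(1) persistence and mean
#' inter-measurement gaps (minutes) used by the generator.
#' @return A data frame with one row per channel.
#' @export
intraop_channels <- function() {
  data.frame(
    channel = c("sbp", "dbp", "map", "hr", "spo2", "fio2", "etco2",
                "tidal_volume", "resp_rate", "pip", "mac", "temp"),
    mean = c(120, 70, 87, 75, 98, 50, 35, 450, 12, 20, 1.0, 36.5),
    sd = c(15, 10, 12, 12, 1.5, 10, 4, 60, 2, 4, 0.2, 0.4),
    phi = 0.97,
    gap = c(3, 3, 3, 1, 1, 1, 1, 1, 1, 1, 5, 15),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic perioperative cohort
#'
#' Defaults mirror the structure of the study cohort: 341 continuous, 42
#' binary and 19 nominal preoperative features (13 with fewer than 5
#' levels, 6 high-cardinality), surgery duration log-normal with median
#' 186 minutes and interquartile range about 132-276 minutes, validation
#' prevalences for the nine outcomes, and a 70% chronological development
#' share.
#'
#' @param n_encounters number of surgical encounters.
#' @param prevalence_targets nine outcome prevalences in (0, 1).
#' @param n_continuous,n_binary counts of continuous/binary preop features.
#' @param nominal_cardinalities 19 level counts; 13 must be below 5 and 6
#'   at least 5 (high-cardinality provider/procedure/ZIP analogues).
#' @param missing_rate_preop per-feature missingness rate in \[0, 1\].
#' @param channel_sampling_rates mean inter-measurement gap in minutes for
#'   each of the 12 channels.
#' @param duration_meanlog,duration_sdlog log-normal surgery duration
#'   parameters (minutes).
#' @param split_fraction development share of the chronological split.
#' @param preop_effect_scale scale of planted preoperative coefficients
#'   (logit units per SD).
#' @param motif_effect_scale scale of planted temporal-motif effects
#'   (logit units per exposure).
#' @param motif_exposure_rate fraction of encounters exposed to each motif.
#' @param seed integer seed; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_encounters,
                        prevalence_targets = default_prevalences(),
                        n_continuous = 341,
                        n_binary = 42,
                        nominal_cardinalities = c(2, 3, 4, 3, 2, 4, 3, 2, 3,
                                                  4, 2, 3, 4,
                                                  60, 80, 120, 200, 300, 500),
                        missing_rate_preop = 0.2,
                        channel_sampling_rates = intraop_channels()$gap,
                        duration_meanlog = log(186),
                        duration_sdlog = 0.55,
                        split_fraction = 0.70,
                        preop_effect_scale = 0.6,
                        motif_effect_scale = 1.5,
                        motif_exposure_rate = 0.3,
                        seed = 1L) {
  stopifnot(n_encounters >= 0, n_continuous >= 1, n_binary >= 1)
  if (length(prevalence_targets) != 9) {
    stop("exactly 9 prevalence targets are required")
  }
  if (any(prevalence_targets <= 0) || any(prevalence_targets >= 1)) {
    stop("prevalence targets must lie strictly in (0, 1)")
  }
  if (length(nominal_cardinalities) != 19) {
    stop("exactly 19 nominal cardinalities are required")
  }
  if (sum(nominal_cardinalities < 5) != 13 ||
      sum(nominal_cardinalities >= 5) != 6) {
    stop("nominal cardinalities must split 13 below 5 and 6 at/above 5")
  }
  stop_if_not_scalar_prob(missing_rate_preop, "missing_rate_preop")
  stop_if_not_scalar_prob(split_fraction, "split_fraction")
  stop_if_not_scalar_prob(motif_exposure_rate, "motif_exposure_rate")
  stopifnot(length(channel_sampling_rates) == 12,
            all(channel_sampling_rates >= 1))
  if (is.null(names(prevalence_targets))) {
    names(prevalence_targets) <- outcome_names()
  }
  structure(list(
    n_encounters = as.integer(n_encounters),
    prevalence_targets = prevalence_targets,
    n_continuous = as.integer(n_continuous),
    n_binary = as.integer(n_binary),
    nominal_cardinalities = as.integer(nominal_cardinalities),
    missing_rate_preop = missing_rate_preop,
    channel_sampling_rates = channel_sampling_rates,
    duration_meanlog = duration_meanlog,
    duration_sdlog = duration_sdlog,
    split_fraction = split_fraction,
    preop_effect_scale = preop_effect_scale,
    motif_effect_scale = motif_effect_scale,
    motif_exposure_rate = motif_exposure_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

zipf_probs <- function(k, s = 1.1) {
  w <- 1 / seq_len(k)^s
  w / sum(w)
}

# Linear risk score for a probe/cohort given planted truth components.
# zc: standardized continuous latents; xb: centered binary values;
# expo: motif exposure indicators.
truth_scores <- function(truth, zc, xb, expo) {
  n <- nrow(zc)
  s <- matrix(0, n, 9)
  for (k in 1:9) {
    dk <- truth$preop_drivers[truth$preop_drivers$outcome == k, ]
    for (r in seq_len(nrow(dk))) {
      v <- if (dk$type[r] == "continuous") zc[, dk$index[r]]
           else xb[, dk$index[r]]
      s[, k] <- s[, k] + dk$coef[r] * v
    }
    mk <- which(truth$motifs$outcome == k)
    for (m in mk) s[, k] <- s[, k] + truth$motifs$effect[m] * expo[, m]
  }
  s
}

#' Plant ground-truth risk structure for a synthetic cohort
#'
#' Chooses sparse preoperative coefficient vectors (with a shared-support
#' block exercising multi-task transfer), one temporal motif per outcome
#' (level shift, trend, or variability burst on one physiological
#' channel), and per-outcome intercepts calibrated by bisection on a
#' 50,000-draw probe sample so that simulated prevalence matches the
#' targets to within 1e-3.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `ground_truth` with elements
#'   `feature_params`, `preop_drivers`, `motifs`, `shared_support` and
#'   `intercepts`.
#' @export
plant_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "truth"))
  nc <- spec$n_continuous; nb <- spec$n_binary
  feature_params <- list(
    cont_mean = round(rnorm(nc, 50, 30), 3),
    cont_sd = round(runif(nc, 0.5, 15), 3),
    bin_p = round(runif(nb, 0.05, 0.6), 3),
    nominal_probs = lapply(spec$nominal_cardinalities, function(k) {
      if (k < 5) {
        p <- runif(k, 0.5, 1.5); p / sum(p)
      } else zipf_probs(k)
    })
  )
  # shared-support continuous drivers reused across outcomes
  shared <- sample.int(nc, 6)
  drivers <- do.call(rbind, lapply(1:9, function(k) {
    own_c <- sample(setdiff(seq_len(nc), shared), 2)
    own_b <- sample.int(nb, 1)
    idx <- c(sample(shared, 2), own_c, own_b)
    type <- c(rep("continuous", 4), "binary")
    coef <- spec$preop_effect_scale * runif(5, 0.5, 1.5) *
      sample(c(-1, 1), 5, replace = TRUE)
    data.frame(outcome = k, type = type, index = idx, coef = coef)
  }))
  motifs <- data.frame(
    outcome = 1:9,
    channel = sample.int(12, 9, replace = TRUE),
    kind = sample(c("level_shift", "trend", "variability_burst"), 9,
                  replace = TRUE),
    magnitude = round(runif(9, 1.2, 2.0), 3),     # channel-SD units
    effect = round(spec$motif_effect_scale * runif(9, 0.8, 1.2), 4)
  )
  truth <- list(feature_params = feature_params, preop_drivers = drivers,
                motifs = motifs, shared_support = shared)

  # intercept calibration on a fixed probe sample
  set.seed(derive_seed(spec$seed, "probe"))
  n_probe <- 50000L
  zc <- matrix(rnorm(n_probe * nc), n_probe, nc)
  xb <- matrix(rbinom(n_probe * nb, 1, rep(feature_params$bin_p,
                                           each = n_probe)), n_probe, nb)
  xb <- sweep(xb, 2, feature_params$bin_p)
  expo <- matrix(rbinom(n_probe * 9, 1, spec$motif_exposure_rate),
                 n_probe, 9)
  s <- truth_scores(truth, zc, xb, expo)
  truth$intercepts <- vapply(1:9, function(k) {
    calibrate_intercept(s[, k], spec$prevalence_targets[k])
  }, numeric(1))
  names(truth$intercepts) <- outcome_names()
  class(truth) <- "ground_truth"
  truth
}

# Bisection on the intercept so that mean(sigmoid(c + s)) hits the target
# prevalence within tol.
calibrate_intercept <- function(scores, target, tol = 1e-3) {
  stop_if_not_scalar_prob(target, "prevalence target")
  if (target <= 0 || target >= 1) stop("infeasible prevalence target")
  f <- function(c0) mean(sigmoid(c0 + scores)) - target
  lo <- -40; hi <- 40
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-10) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Generate a synthetic perioperative cohort
#'
#' Draws preoperative features, motif exposures, outcomes (Bernoulli on
#' the planted linear-logistic risk), missingness (applied after outcome
#' generation), end-of-surgery statics, and irregularly sampled
#' intraoperative series from channel-specific Gaussian AR(1) processes
#' around physiological set-points, with planted motifs superimposed for
#' exposed encounters. Surgery dates increase strictly with encounter
#' index so the chronological split is well defined.
#'
#' @param spec a [cohort_spec()].
#' @param truth the matching [plant_truth()] output.
#' @param include_intraop generate the intraoperative series (default
#'   `TRUE`). Setting `FALSE` skips series synthesis for
#'   prevalence-calibration studies; outcomes are unchanged because they
#'   are drawn first.
#' @return An object of class `periop_cohort`: column-oriented tables
#'   (`static`, `preop_continuous`, `preop_binary`, `preop_nominal`,
#'   `outcomes`, `intraop`, `motif_exposure`) plus the spec.
#' @export
generate_cohort <- function(spec, truth, include_intraop = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  n <- spec$n_encounters
  nc <- spec$n_continuous; nb <- spec$n_binary
  fp <- truth$feature_params
  ch <- intraop_channels()
  ch$gap <- spec$channel_sampling_rates
  set.seed(derive_seed(spec$seed, "cohort"))

  if (n == 0) {
    return(structure(list(spec = spec, static = data.frame(),
                          preop_continuous = matrix(0, 0, nc),
                          preop_binary = matrix(0, 0, nb),
                          preop_nominal = data.frame(),
                          outcomes = matrix(0, 0, 9),
                          intraop = list(),
                          motif_exposure = matrix(0, 0, 9)),
                     class = "periop_cohort"))
  }

  zc <- matrix(rnorm(n * nc), n, nc)
  xc <- sweep(sweep(zc, 2, fp$cont_sd, `*`), 2, fp$cont_mean, `+`)
  xb <- matrix(rbinom(n * nb, 1, rep(fp$bin_p, each = n)), n, nb)
  xnom <- as.data.frame(lapply(seq_along(fp$nominal_probs), function(j) {
    k <- spec$nominal_cardinalities[j]
    paste0("L", sample.int(k, n, replace = TRUE, prob = fp$nominal_probs[[j]]))
  }))
  names(xnom) <- paste0("nominal_", seq_len(19))
  expo <- matrix(rbinom(n * 9, 1, spec$motif_exposure_rate), n, 9)

  s <- truth_scores(truth, zc, sweep(xb, 2, fp$bin_p), expo)
  s <- sweep(s, 2, truth$intercepts, `+`)
  y <- matrix(rbinom(n * 9, 1, sigmoid(s)), n, 9)
  colnames(y) <- outcome_names()

  # missingness after outcome generation (MCAR at the configured rate)
  if (spec$missing_rate_preop > 0) {
    xc[matrix(runif(n * nc) < spec$missing_rate_preop, n, nc)] <- NA
    xb[matrix(runif(n * nb) < spec$missing_rate_preop, n, nb)] <- NA
    for (j in seq_len(19)) {
      xnom[[j]][runif(n) < spec$missing_rate_preop] <- NA
    }
  }

  duration <- pmax(1L, as.integer(round(
    rlnorm(n, spec$duration_meanlog, spec$duration_sdlog))))
  dates <- as.Date("2014-06-01") + seq_len(n) - 1L
  static <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    encounter_id = sprintf("E%06d", seq_len(n)),
    surgery_date = dates,
    admission_day = as.integer(format(dates, "%w")),        # 0 = Sunday
    admission_month = as.integer(format(dates, "%m")) - 1L, # 0-based
    duration = duration,
    blood_loss = round(rlnorm(n, log(150), 1), 1),
    urine_output = round(rlnorm(n, log(300), 0.8), 1),
    stringsAsFactors = FALSE
  )

  intraop <- vector("list", n)
  if (include_intraop) {
    for (i in seq_len(n)) {
      intraop[[i]] <- simulate_intraop_series(
        T = duration[i], channels = ch,
        motifs = truth$motifs[expo[i, truth$motifs$outcome] == 1, ,
                              drop = FALSE])
    }
  }

  colnames(xc) <- paste0("cont_", seq_len(nc))
  colnames(xb) <- paste0("bin_", seq_len(nb))
  structure(list(spec = spec, static = static,
                 preop_continuous = xc, preop_binary = xb,
                 preop_nominal = xnom, outcomes = y,
                 intraop = intraop, motif_exposure = expo),
            class = "periop_cohort")
}

# One encounter's 12-channel irregular series. Latent 1-minute AR(1)
# processes with any exposed motifs superimposed, then thinned to
# channel-specific irregular measurement times (geometric gaps whose mean
# matches the channel sampling rate).
simulate_intraop_series <- function(T, channels, motifs) {
  out <- vector("list", nrow(channels))
  names(out) <- channels$channel
  for (c in seq_len(nrow(channels))) {
    phi <- channels$phi[c]
    sd_c <- channels$sd[c]
    innov <- rnorm(T, 0, sd_c * sqrt(1 - phi^2))
    innov[1] <- rnorm(1, 0, sd_c)
    dev <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    x <- channels$mean[c] + dev
    mc <- motifs[motifs$channel == c, , drop = FALSE]
    for (m in seq_len(nrow(mc))) {
      mag <- mc$magnitude[m] * sd_c
      x <- switch(mc$kind[m],
        level_shift = {
          t0 <- max(1L, as.integer(round(0.4 * T)))
          x + mag * (seq_len(T) >= t0)
        },
        trend = x + seq(0, mag, length.out = T),
        variability_burst = {
          w <- seq_len(T) >= round(0.3 * T) & seq_len(T) <= round(0.7 * T)
          x + rnorm(T, 0, mag) * w
        })
    }
    gap <- channels$gap[c]
    if (gap <= 1) {
      minutes <- 0:(T - 1)
    } else {
      gaps <- 1L + rgeom(T, 1 / gap)
      minutes <- cumsum(c(0L, gaps))
      minutes <- minutes[minutes < T]
    }
    out[[c]] <- cbind(minute = minutes, value = x[minutes + 1L])
  }
  out
}

#' Number of encounters in a cohort
#' @param cohort a `periop_cohort`.
#' @return Integer count.
#' @export
n_encounters <- function(cohort) nrow(cohort$static)

#' Subset a cohort by encounter index
#' @param cohort a `periop_cohort`.
#' @param idx integer indices to keep.
#' @return A `periop_cohort` restricted to `idx`.
#' @export
subset_cohort <- function(cohort, idx) {
  structure(list(spec = cohort$spec,
                 static = cohort$static[idx, , drop = FALSE],
                 preop_continuous = cohort$preop_continuous[idx, , drop = FALSE],
                 preop_binary = cohort$preop_binary[idx, , drop = FALSE],
                 preop_nominal = cohort$preop_nominal[idx, , drop = FALSE],
                 outcomes = cohort$outcomes[idx, , drop = FALSE],
                 intraop = cohort$intraop[idx],
                 motif_exposure = cohort$motif_exposure[idx, , drop = FALSE]),
            class = "periop_cohort")
}

#' Chronological development/validation split
#'
#' Orders encounters by surgery date and assigns the earliest
#' `split_fraction` share to the development set, emulating prospective
#' deployment: every development date precedes (or equals) every
#' validation date.
#'
#' @param cohort a `periop_cohort`.
#' @param split_fraction development share in \[0, 1\]; defaults to the
#'   value in the cohort spec.
#' @return A list with `development` and `validation` cohorts.
#' @export
split_chronological <- function(cohort, split_fraction = NULL) {
  stopifnot(inherits(cohort, "periop_cohort"))
  split_fraction <- split_fraction %||% cohort$spec$split_fraction
  stop_if_not_scalar_prob(split_fraction, "split_fraction")
  dates <- cohort$static$surgery_date
  if (nrow(cohort$static) > 0 && any(is.na(dates))) {
    stop("encounters with missing surgery dates cannot be split")
  }
  ord <- order(dates)
  n <- length(ord)
  n_dev <- floor(split_fraction * n)
  list(development = subset_cohort(cohort, ord[seq_len(n_dev)]),
       validation = subset_cohort(cohort, ord[setdiff(seq_len(n), seq_len(n_dev))]))
}

#' Write a cohort to plain-text files
#'
#' Writes `encounters.csv` (static fields plus all preoperative features,
#' one row per encounter), `timeseries.csv` (long format: encounter_id,
#' channel, minute, value), `outcomes.csv`, and `truth.json` if a ground
#' truth is supplied.
#'
#' @param cohort a `periop_cohort`.
#' @param dir output directory (created if absent).
#' @param truth optional `ground_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- cbind(cohort$static,
               as.data.frame(cohort$preop_continuous),
               as.data.frame(cohort$preop_binary),
               cohort$preop_nominal)
  data.table::fwrite(enc, file.path(dir, "encounters.csv"))
  data.table::fwrite(cbind(cohort$static["encounter_id"],
                           as.data.frame(cohort$outcomes)),
                     file.path(dir, "outcomes.csv"))
  ts <- data.table::rbindlist(lapply(seq_along(cohort$intraop), function(i) {
    series <- cohort$intraop[[i]]
    if (is.null(series)) return(NULL)
    data.table::rbindlist(lapply(names(series), function(chn) {
      data.table::data.table(encounter_id = cohort$static$encounter_id[i],
                             channel = chn,
                             minute = series[[chn]][, "minute"],
                             value = series[[chn]][, "value"])
    }))
  }))
  data.table::fwrite(ts, file.path(dir, "timeseries.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort CSV files.
#' @param spec the `cohort_spec` used at generation time (feature counts
#'   are needed to partition the encounter table).
#' @return A `periop_cohort` (without `motif_exposure`, which is ground
#'   truth rather than data).
#' @export
read_cohort <- function(dir, spec) {
  enc <- as.data.frame(data.table::fread(file.path(dir, "encounters.csv")))
  outc <- as.data.frame(data.table::fread(file.path(dir, "outcomes.csv")))
  ts <- as.data.frame(data.table::fread(file.path(dir, "timeseries.csv")))
  static_cols <- c("patient_id", "encounter_id", "surgery_date",
                   "admission_day", "admission_month", "duration",
                   "blood_loss", "urine_output")
  static <- enc[static_cols]
  static$surgery_date <- as.Date(static$surgery_date)
  nc <- spec$n_continuous; nb <- spec$n_binary
  xc <- as.matrix(enc[paste0("cont_", seq_len(nc))])
  xb <- as.matrix(enc[paste0("bin_", seq_len(nb))])
  xnom <- enc[paste0("nominal_", seq_len(19))]
  for (j in seq_len(19)) {
    xnom[[j]][xnom[[j]] == ""] <- NA
    xnom[[j]] <- as.character(xnom[[j]])
  }
  intraop <- rep(list(NULL), nrow(static))
  if (nrow(ts) > 0) {
    split_ts <- split(ts, factor(ts$encounter_id,
                                 levels = static$encounter_id))
    chn <- intraop_channels()$channel
    for (i in seq_along(split_ts)) {
      d <- split_ts[[i]]
      intraop[[i]] <- lapply(setNames(chn, chn), function(cc) {
        dd <- d[d$channel == cc, , drop = FALSE]
        cbind(minute = dd$minute, value = dd$value)
      })
    }
  }
  structure(list(spec = spec, static = static, preop_continuous = xc,
                 preop_binary = xb, preop_nominal = xnom,
                 outcomes = as.matrix(outc[outcome_names()]),
                 intraop = intraop,
                 motif_exposure = NULL),
            class = "periop_cohort")
}
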