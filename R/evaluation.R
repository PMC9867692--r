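# Discrimination metrics, Youden operating points, bootstrap intervals,
# net reclassification improvement, and the Hanley-McNeil sample-size
# calculator. All scores are risk probabilities (higher = more risk) and
# labels are 0/1.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with half credit for tied
#' scores: the probability that a random positive outscores a random
#' negative, counting ties as 1/2.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Area under the precision-recall curve
#'
#' Step integration over distinct score thresholds (tied scores enter as a
#' single group): the sum of precision times the recall increment, i.e.
#' average precision.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep only the last index of each tied-score group
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Youden-index classification threshold
#'
#' Scans all observed score values as candidate thresholds under the rule
#' `score >= threshold` implies predicted positive, and returns the
#' threshold maximizing J = sensitivity + specificity - 1. Ties in J are
#' broken toward the lowest threshold, favoring sensitivity.
#'
#' @inheritParams auroc
#' @return The threshold, with the achieved index in attribute `"j"`.
#' @export
youden_threshold <- function(scores, labels) {
  check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  thr <- sort(unique(scores))
  # at threshold thr[i], positives predicted are scores >= thr[i]
  ord <- order(scores)
  y <- labels[ord]
  s <- scores[ord]
  # cumulative counts strictly below each unique threshold
  below <- findInterval(thr, s, left.open = TRUE)  # number strictly < thr
  cpos <- cumsum(y)
  cneg <- cumsum(1 - y)
  pos_below <- c(0, cpos)[below + 1]
  neg_below <- c(0, cneg)[below + 1]
  sens <- (n1 - pos_below) / n1
  spec <- neg_below / n0
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # lowest threshold among ties
  out <- thr[best]
  attr(out, "j") <- j[best]
  out
}

#' Confusion-matrix and discrimination metrics at a threshold
#'
#' @inheritParams auroc
#' @param threshold classification cutoff; `score >= threshold` is a
#'   predicted positive. Defaults to the Youden-index threshold.
#' @return A one-row data frame with auroc, auprc, sensitivity,
#'   specificity, ppv, npv, accuracy, youden_threshold and youden_j.
#'   PPV/NPV are `NA` (not 0) when no subject falls in the predicted
#'   class.
#' @export
compute_metrics <- function(scores, labels, threshold = NULL) {
  check_binary_labels(labels)
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  data.frame(
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    sensitivity = sens,
    specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    youden_threshold = as.numeric(threshold),
    youden_j = sens + spec - 1
  )
}

#' Bootstrap percentile confidence interval for a metric
#'
#' Encounter-level resampling with replacement; resamples lacking both
#' outcome classes are redrawn. Errors if the metric is undefined on more
#' than 10 percent of resamples.
#'
#' @inheritParams auroc
#' @param metric a function `f(scores, labels)` returning a scalar, or one
#'   of `"auroc"`, `"auprc"`.
#' @param n_resamples number of bootstrap resamples (the analysis default
#'   is 1000).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auroc",
                         n_resamples = 1000, seed = NULL, level = 0.95) {
  stopifnot(n_resamples >= 2)
  check_binary_labels(labels)
  if (is.character(metric)) {
    metric <- switch(match.arg(metric, c("auroc", "auprc")),
                     auroc = auroc, auprc = auprc)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  vals <- numeric(n_resamples)
  n_bad <- 0L
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
      n_bad <- n_bad + 1L
      if (n_bad > 100L * n_resamples) {
        stop("could not draw bootstrap resamples containing both classes")
      }
    }
    vals[b] <- metric(scores[idx], labels[idx])
  }
  if (n_bad > 0) {
    message(sprintf("redrew %d single-class bootstrap resamples", n_bad))
  }
  if (mean(is.na(vals)) > 0.1) {
    stop("metric undefined on more than 10% of bootstrap resamples")
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  c(lower = ci[1], upper = ci[2])
}

#' Full metric report with bootstrap confidence intervals
#'
#' Point estimates at the Youden operating point plus percentile bootstrap
#' intervals for every metric. Confusion metrics are bootstrapped at the
#' fixed full-sample operating point.
#'
#' @inheritParams bootstrap_ci
#' @param outcome,phase,scheme optional labels carried into the report.
#' @param n_bootstrap bootstrap resamples (default 1000).
#' @return A one-row data frame (`MetricReport`): point estimates plus
#'   `<metric>_lo` / `<metric>_hi` columns.
#' @export
metric_report <- function(scores, labels, outcome = NA, phase = NA,
                          scheme = NA, n_bootstrap = 1000, seed = NULL) {
  pt <- compute_metrics(scores, labels)
  thr <- pt$youden_threshold
  metric_fns <- list(
    auroc = auroc,
    auprc = auprc,
    sensitivity = function(s, y) compute_metrics(s, y, thr)$sensitivity,
    specificity = function(s, y) compute_metrics(s, y, thr)$specificity,
    ppv = function(s, y) compute_metrics(s, y, thr)$ppv,
    npv = function(s, y) compute_metrics(s, y, thr)$npv,
    accuracy = function(s, y) compute_metrics(s, y, thr)$accuracy
  )
  cis <- lapply(seq_along(metric_fns), function(i) {
    bootstrap_ci(scores, labels, metric_fns[[i]], n_resamples = n_bootstrap,
                 seed = if (is.null(seed)) NULL else seed + i)
  })
  names(cis) <- names(metric_fns)
  out <- cbind(data.frame(outcome = outcome, phase = phase, scheme = scheme,
                          n = length(labels), n_bootstrap = n_bootstrap),
               pt)
  for (m in names(cis)) {
    out[[paste0(m, "_lo")]] <- cis[[m]][["lower"]]
    out[[paste0(m, "_hi")]] <- cis[[m]][["upper"]]
  }
  out
}

#' Net reclassification improvement
#'
#' Quantifies how risk predictions move when replacing a reference model
#' with an updated one: NRI = \[P(up|event) - P(down|event)\] +
#' \[P(down|non-event) - P(up|non-event)\]. The continuous (category-free)
#' variant counts any score increase as "up"; the categorical variant uses
#' supplied cutoffs to define risk groups. Also reports the net percentage
#' of all subjects correctly reclassified and an asymptotic normal
#' p-value.
#'
#' @param reference,updated aligned risk-score vectors.
#' @param labels 0/1 outcome labels.
#' @param categories optional increasing numeric cutoffs defining risk
#'   groups; `NULL` (default) selects the continuous variant.
#' @return An object of class `nri_result`: a list with per-stratum
#'   counts/proportions, `nri`, `z`, `p_value` and
#'   `overall_correct_pct`.
#' @export
nri <- function(reference, updated, labels, categories = NULL) {
  stopifnot(length(reference) == length(updated),
            length(reference) == length(labels))
  check_binary_labels(labels)
  if (!is.null(categories)) {
    br <- c(-Inf, sort(categories), Inf)
    ref_c <- as.integer(cut(reference, br))
    upd_c <- as.integer(cut(updated, br))
    up <- upd_c > ref_c
    down <- upd_c < ref_c
  } else {
    up <- updated > reference
    down <- updated < reference
  }
  ev <- labels == 1
  n_e <- sum(ev); n_ne <- sum(!ev)
  p_up_e <- mean(up[ev]); p_down_e <- mean(down[ev])
  p_up_ne <- mean(up[!ev]); p_down_ne <- mean(down[!ev])
  nri_e <- p_up_e - p_down_e
  nri_ne <- p_down_ne - p_up_ne
  total <- nri_e + nri_ne
  se2 <- (p_up_e + p_down_e - nri_e^2) / n_e +
    (p_up_ne + p_down_ne - nri_ne^2) / n_ne
  z <- if (se2 > 0) total / sqrt(se2) else NA_real_
  res <- list(
    n_events = n_e, n_nonevents = n_ne,
    events_up = sum(up[ev]), events_down = sum(down[ev]),
    nonevents_up = sum(up[!ev]), nonevents_down = sum(down[!ev]),
    p_up_event = p_up_e, p_down_event = p_down_e,
    p_up_nonevent = p_up_ne, p_down_nonevent = p_down_ne,
    nri_events = nri_e, nri_nonevents = nri_ne, nri = total,
    z = z, p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
    overall_correct_pct = 100 *
      ((sum(up[ev]) + sum(down[!ev])) - (sum(down[ev]) + sum(up[!ev]))) /
      length(labels),
    categories = if (is.null(categories)) "continuous" else categories
  )
  class(res) <- "nri_result"
  res
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI = %.4f (events %.4f, non-events %.4f), p = %.3g\n",
    x$nri, x$nri_events, x$nri_nonevents, x$p_value))
  cat(sprintf("net correctly reclassified: %.2f%% of %d subjects\n",
              x$overall_correct_pct, x$n_events + x$n_nonevents))
  invisible(x)
}

#' Width of the 95 percent AUROC confidence interval
#'
#' Closed-form sample-size calculation from the Hanley-McNeil (1982)
#' variance of an empirical AUROC, given the cohort size, the outcome
#' prevalence and the anticipated AUROC. Returns the full interval width
#' 2 * 1.96 * SE.
#'
#' @param n_total total validation cohort size.
#' @param prevalence outcome prevalence in (0, 1).
#' @param auroc anticipated AUROC in (0.5, 1).
#' @return Full width of the 95 percent confidence interval.
#' @export
auroc_ci_width <- function(n_total, prevalence, auroc) {
  stop_if_not_scalar_prob(prevalence, "prevalence")
  stopifnot(auroc > 0.5, auroc < 1)
  n1 <- round(n_total * prevalence)
  n2 <- n_total - n1
  if (n1 < 1 || n2 < 1) stop("degenerate stratum: need >= 1 case per class")
  a <- auroc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
    (n1 * n2)
  2 * 1.96 * sqrt(v)
}
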