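sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

#' Derive a stage-specific seed from a global seed
#'
#' A single experiment seed fans out to per-stage seeds so that stages can
#' be re-run independently while remaining jointly reproducible. The
#' derivation keeps results inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"synth"`, `"train"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
}

check_binary_labels <- function(labels, require_both = TRUE) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (require_both && (sum(labels == 1) == 0 || sum(labels == 0) == 0)) {
    stop("labels must contain both classes", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
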