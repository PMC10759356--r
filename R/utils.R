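#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist hclust loess median p.adjust pnorm prcomp predict
#'   quantile rbinom rlnorm rnbinom rnorm runif sd var
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-wide log channel: structured one-line messages to stderr, silenced
# with options(pitscape.quiet = TRUE).
ps_log <- function(...) {
  if (!isTRUE(getOption("pitscape.quiet", FALSE))) {
    message("[pitscape] ", ...)
  }
}

ps_stop <- function(...) stop(..., call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' A single run-level seed is combined with a stage name so each pipeline
#' stage gets its own reproducible stream and can be re-run in isolation.
#' The derived seed always fits in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Largest-remainder apportionment of n items into proportions p (sums to 1).
# Deterministic: remainder ties broken by index order.
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# rank-based AUC of scores for a binary truth vector (TRUE = positive)
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
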