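## Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Deterministic per-stage seed derived from a master seed; kept below 2^31.
#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1000L + as.integer(stage)) %% 2147483399L + 1L
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Column-standardize a dosage vector/matrix (rows = variants).
#' @keywords internal
#' @noRd
row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowSums((m - mu)^2) / (ncol(m) - 1), .Machine$double.eps))
  (m - mu) / s
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
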