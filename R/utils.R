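# Internal numerical helpers shared across modules.

#' Row-wise log-sum-exp
#'
#' Stable computation of `log(rowSums(exp(m)))` for a numeric matrix.
#' Rows that are entirely `-Inf` return `-Inf` rather than `NaN`.
#'
#' @param m numeric matrix of log values.
#' @return numeric vector, one entry per row.
#' @keywords internal
#' @noRd
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed_ <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Derive a distinct child seed from a base seed; stays within 32-bit range.
child_seed <- function(seed, i) {
  (as.integer(seed) + 104729L * as.integer(i)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_that_ <- function(cond, msg) {
  if (!isTRUE(cond)) stop_(msg)
  invisible(TRUE)
}
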