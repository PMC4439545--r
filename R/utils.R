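#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values (may contain -Inf).
#' @return log(sum(exp(x))) computed without underflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or contains Inf/NaN upstream)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a base seed and an index
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#' @keywords internal
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 9973) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sentinel used for features that are undefined on near-silent segments
#' @keywords internal
feature_sentinel <- function() NA_real_
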