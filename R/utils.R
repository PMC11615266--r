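#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Stages
#' derive their own seeds deterministically so that any stage can be replayed
#' in isolation: `child = (master * 48271 + index) mod (2^31 - 1)`, a
#' Lehmer-style mixing step that keeps seeds in the 32-bit integer range.
#'
#' @param seed master seed (non-negative integer).
#' @param index stage index (non-negative integer); distinct stages use
#'   distinct indices.
#' @return an integer usable with [set.seed()].
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + index) %% m)
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale terms.
#' @return log(sum(exp(x))), guarding against overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain trends register as apparent non-convergence.
#'
#' @param draws iterations x chains matrix of draws for one scalar parameter.
#' @return the split-Rhat statistic (NA for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  if (stats::sd(sub) == 0) return(NA_real_)
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Equal-tailed credible interval
#' @param x draws.
#' @param level interval mass in (0,1); default 0.89.
#' @return named vector with median, lower, upper.
#' @export
cri <- function(x, level = 0.89) {
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(0.5, a, 1 - a), names = FALSE, na.rm = TRUE)
  c(median = q[1], lower = q[2], upper = q[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
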