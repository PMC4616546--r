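#' @keywords internal
"_PACKAGE"

msg <- function(...) message("[markerscreen] ", sprintf(...))

#' Round half-up
#'
#' Rounds to `digits` decimal places with halves always rounded away from
#' zero (for the non-negative quantities used here: upward), matching how
#' diagnostic percentages are conventionally printed. Base [round()] uses
#' round-half-even, which would print 92.85 as 92.8.
#'
#' @param x Numeric vector, assumed non-negative.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(100 * 13 / 14)  # 92.9
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # tiny epsilon guards against values like 92.85 stored as 92.8499999...
  floor(x * f + 0.5 + 1e-9) / f
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector with elements `lower` and `upper`, both in
#'   \[0, 1\]. Well-behaved at proportions of 0 and 1, unlike the Wald
#'   interval.
#' @examples
#' wilson_ci(23, 23)  # interval for an observed 100% rate
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

# Deterministic sub-seed so each simulator draws from its own stream and
# adding one generator never perturbs another's output.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 997L
  (as.integer(seed) %% 1000003L) * 1009L + h
}
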