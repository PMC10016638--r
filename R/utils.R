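#' @useDynLib hrvaf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rlnorm rpois rgamma rbinom
#'   sd var cor shapiro.test t.test wilcox.test fisher.test chisq.test
#'   qnorm runmed
#' @importFrom utils read.csv write.csv head tail
NULL

# Round half away from zero at `digits` decimals (base round() is
# round-half-even, which never matches hand-rendered clinical tables).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Population variance / sd (denominator n, not n-1): HRV oracles are
# stated in population form so identities hold bit-for-bit.
pvar <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
psd <- function(x) sqrt(pvar(x))

# Lag-1 autocorrelation, autocovariance form (same estimator as the
# compiled window scanner). Degenerate (zero-variance) input -> 1,
# i.e. "perfectly regular", never AF-like.
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  if (v <= 0) return(1)
  (sum((x[-n] - m) * (x[-1L] - m)) / n) / v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flagged_undefined <- function(x) isTRUE(attr(x, "undefined"))
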