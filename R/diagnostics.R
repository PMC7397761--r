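#' Highest density interval of a sample
#'
#' Returns the narrowest contiguous interval containing at least
#' `ceiling(mass * n)` of the sorted sample values — the smallest interval
#' containing the stated share of MCMC samples. Ties between equally narrow
#' windows are broken leftmost.
#'
#' @param samples Numeric vector of at least 10 finite values.
#' @param mass Probability mass to cover, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' compute_hdi(rnorm(1e4))
#' @export
compute_hdi <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    abort("`mass` must be a single value strictly between 0 and 1.")
  }
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 10) abort("At least 10 finite samples are required for an HDI.")
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths) # which.min is leftmost on ties
  c(lower = x[i], upper = x[i + k - 1])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes R-hat from the between- and within-chain variances of a set of
#' chains of equal length: with within-chain variance W and between-chain
#' variance B (of the chain means, scaled by chain length n),
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate
#' convergence; the fitting functions in this package warn above 1.1.
#'
#' @param chains Numeric matrix with one column per chain (or a list of
#'   equal-length numeric vectors); at least 2 chains of length >= 10.
#' @return Scalar R-hat.
#' @examples
#' compute_rhat(cbind(rnorm(500), rnorm(500)))
#' @export
compute_rhat <- function(chains) {
  if (is.list(chains) && !is.data.frame(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1) abort("All chains must have equal length.")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) abort("R-hat requires at least 2 chains.")
  if (n < 10) abort("R-hat requires chains of length >= 10.")
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  if (W == 0) return(1) # all chains constant and identical
  sqrt(((n - 1) / n * W + B / n) / W)
}
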