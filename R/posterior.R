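# Posterior summarisation of scalar MCMC chains: median, shortest HPD
# interval, sign probability P0, Geweke convergence Z and batch-means Monte
# Carlo standard error.

#' Shortest highest-posterior-density interval
#'
#' Chen-Shao construction: over the sorted sample, slide a window containing
#' `prob` of the draws and return the shortest one.
#'
#' @param chain numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, prob = 0.95) {
  x <- sort(chain)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  w <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

# Spectral density of a chain at frequency zero, via an AR fit
# (the standard time-series variance estimate used in MCMC diagnostics).
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(30L, length(x) - 1L)), silent = TRUE)
  if (inherits(fit, "try-error")) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` of the chain with the mean
#' of the last `frac2`, using spectral-density variance estimates for each
#' window.
#'
#' @param chain numeric vector of draws (in iteration order).
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return Z statistic (NA for a constant chain).
#' @export
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  a <- chain[1:max(1L, floor(frac1 * n))]
  b <- chain[(n - floor(frac2 * n) + 1L):n]
  if (stats::var(chain) == 0) return(NA_real_)
  v <- spectrum0_ar(a) / length(a) + spectrum0_ar(b) / length(b)
  if (v <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(v)
}

#' Batch-means Monte Carlo standard error
#'
#' Splits the chain into ~sqrt(n) consecutive batches and uses the standard
#' error of the batch means.
#'
#' @param chain numeric vector of draws.
#' @return the MCSE estimate.
#' @export
mcse_batch <- function(chain) {
  n <- length(chain)
  nb <- max(2L, floor(sqrt(n)))
  bs <- floor(n / nb)
  means <- vapply(seq_len(nb), function(i) mean(chain[((i - 1L) * bs + 1L):(i * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(nb)
}

#' Summarise a scalar posterior chain
#'
#' Returns the posterior median, the shortest 95% HPD interval, the posterior
#' standard deviation, `p0` (the probability that the parameter is above or
#' below zero, matching the sign of the median), the Geweke convergence Z and
#' the batch-means MCSE, plus `mcse_ok` flagging whether the MCSE is at least
#' 10 times smaller than the posterior standard deviation.
#'
#' @param chain numeric vector of at least 10 posterior draws, in iteration
#'   order.
#' @param prob HPD interval mass (default 0.95).
#' @return a one-row data frame of class `posterior_summary`.
#' @export
summarize_posterior <- function(chain, prob = 0.95) {
  chain <- as.numeric(chain)
  if (length(chain) < 10L) stopf("chain too short to summarise (%d draws)", length(chain))
  if (any(!is.finite(chain))) stopf("non-finite values in chain")
  med <- stats::median(chain)
  hpd <- hpd_interval(chain, prob)
  p0 <- if (med >= 0) mean(chain >= 0) else mean(chain < 0)
  sdv <- stats::sd(chain)
  mcse <- mcse_batch(chain)
  out <- data.frame(median = med, hpd95_low = hpd[1L], hpd95_high = hpd[2L],
                    sd = sdv, p0 = p0, geweke_z = geweke_z(chain),
                    mcse = mcse,
                    mcse_ok = if (sdv > 0) mcse <= sdv / 10 else TRUE)
  class(out) <- c("posterior_summary", class(out))
  out
}
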