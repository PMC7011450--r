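# Point and interval summaries of MCMC chains.

#' Posterior mode of an MCMC chain
#'
#' Mode of a Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth, evaluated on a 512-point grid spanning the sample range. A
#' constant chain returns that constant.
#'
#' @param chain numeric vector of samples.
#' @return the estimated mode.
#' @export
posterior_mode <- function(chain) {
  chain <- chain[is.finite(chain)]
  if (!length(chain)) stop("empty chain")
  rng <- range(chain)
  if (diff(rng) == 0) return(rng[1])
  bw <- stats::bw.nrd0(chain)
  if (!is.finite(bw) || bw <= 0) return(stats::median(chain))
  d <- stats::density(chain, bw = bw, n = 512, from = rng[1], to = rng[2])
  d$x[which.max(d$y)]
}

#' Highest-posterior-density interval
#'
#' The shortest contiguous interval of sorted samples containing
#' `ceiling(prob * n)` of them.
#'
#' @param chain numeric vector of samples.
#' @param prob target posterior mass in (0, 1) (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1) {
    stop("prob must be in (0, 1)")
  }
  x <- sort(chain[is.finite(chain)])
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)                # first minimal window
  c(x[i], x[i + m - 1])
}
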