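## Highest-density intervals and split-R-hat convergence diagnostics.

#' Highest density interval of a posterior sample
#'
#' Shortest contiguous interval containing \code{ceiling(mass * n)} of the
#' sorted draws. For unimodal, roughly symmetric posteriors this is close to
#' the equal-tailed interval; for skewed posteriors it is shorter.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param mass probability mass of the interval (default 0.95).
#' @return named numeric vector \code{c(lower, upper)}.
#' @examples
#' hdi(rnorm(10000))  # ~ c(-1.96, 1.96)
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100L)
    stop("need at least 100 samples for an HDI", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Split-R-hat of a set of chains
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain drift also inflates the statistic. Values
#' below about 1.05 indicate adequate convergence.
#'
#' @param draws numeric matrix, iterations x chains (a single chain may be
#'   passed as a vector).
#' @return scalar R-hat.
#' @export
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
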