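`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudo-logarithmic lag grid
#'
#' Lag times for relaxation analysis are spaced approximately
#' logarithmically (1, 2, 3, 4, 6, 8, 11, ...) so that curves spanning
#' decades in lag are sampled evenly in log time.
#'
#' @param n_frames number of frames in the stack.
#' @param max_lag largest lag in frames; defaults to `floor(n_frames / 2)`.
#' @param n_per_decade target number of lags per decade.
#' @return increasing integer vector of lags (frames), all `< n_frames`.
#' @export
lag_frames <- function(n_frames, max_lag = NULL, n_per_decade = 12) {
  stopifnot(n_frames >= 2)
  max_lag <- max_lag %||% max(1L, floor(n_frames / 2))
  max_lag <- min(max_lag, n_frames - 1L)
  n <- max(2, ceiling(log10(max_lag) * n_per_decade) + 1)
  lags <- unique(round(10^seq(0, log10(max_lag), length.out = n)))
  as.integer(lags[lags >= 1 & lags <= max_lag])
}

# 1D Gaussian kernel, truncated and renormalized to sum 1.
gaussian_kernel_1d <- function(sigma, radius = NULL) {
  stopifnot(sigma > 0)
  radius <- radius %||% max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D Gaussian first-derivative kernel, normalized so that the response to a
# unit ramp is 1 (sum(t * k[t]) = 1 for correlation).
gaussian_deriv_kernel_1d <- function(sigma, radius = NULL) {
  stopifnot(sigma > 0)
  radius <- radius %||% max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- x * exp(-x^2 / (2 * sigma^2))
  k / sum(x * k)
}

# Gaussian smoothing of a matrix with symmetric boundary padding.
gaussian_smooth <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  conv_sep_reflect(m, k, k)
}
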