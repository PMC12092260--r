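#' @useDynLib fpscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft kmeans mvfft optimize quantile rnorm runif sd uniroot
#' @importFrom utils head tail
NULL

# DFT sample frequencies (cycles per unit), ordered as R's fft output:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1 (all divided by n*d)
fft_freq <- function(n, d = 1) {
  if (n == 1L) return(0)
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' @keywords internal
stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# linear interpolation of a 1D vector at fractional indices (1-based),
# values outside [1, n] give 0
lin_interp_at <- function(y, idx) {
  n <- length(y)
  lo <- floor(idx)
  w <- idx - lo
  ok <- idx >= 1 & idx <= n
  lo[!ok] <- 1L
  hi <- pmin(lo + 1L, n)
  out <- (1 - w) * y[lo] + w * y[hi]
  out[!ok] <- 0
  out
}

# small LRU cache for planar operators: geometry builds and power-method
# Lipschitz estimates are reused across reconstructions in one session
.op_cache <- new.env(parent = emptyenv())
.op_cache$keys <- character()

.op_cache_get <- function(key) {
  if (!is.null(.op_cache[[key]])) .op_cache[[key]] else NULL
}

.op_cache_put <- function(key, op, max_entries = 3L) {
  if (!key %in% .op_cache$keys) {
    .op_cache$keys <- c(.op_cache$keys, key)
    while (length(.op_cache$keys) > max_entries) {
      rm(list = .op_cache$keys[1], envir = .op_cache)
      .op_cache$keys <- .op_cache$keys[-1]
    }
  }
  assign(key, op, envir = .op_cache)
  op
}

# units: package-internal convention is micrometres for space, nanoseconds
# for time, kPa for pressure, m/s for sound speed; conversions live here
um_to_m <- function(x) x * 1e-6
ns_to_s <- function(x) x * 1e-9

# normalized cross-correlation of two arrays (zero-lag, mean not removed:
# both are non-negative images on the same grid)
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# FWHM of a sampled 1D profile via linear interpolation of half-max crossings;
# x are sample coordinates (monotone increasing)
profile_fwhm <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  # left crossing
  il <- imax
  while (il > 1 && y[il] > half) il <- il - 1
  if (y[il] > half) return(NA_real_)
  xl <- x[il] + (x[il + 1] - x[il]) * (half - y[il]) / (y[il + 1] - y[il])
  ir <- imax
  n <- length(y)
  while (ir < n && y[ir] > half) ir <- ir + 1
  if (y[ir] > half) return(NA_real_)
  xr <- x[ir - 1] + (x[ir] - x[ir - 1]) * (half - y[ir - 1]) / (y[ir] - y[ir - 1])
  xr - xl
}
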