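#' Band-pass filter A-lines
#'
#' Zero-phase band-pass conditioning of every A-line before reconstruction.
#' The response is the squared magnitude of a 4th-order Butterworth band-pass
#' (the transfer function a forward-backward filter would realize), applied
#' in the frequency domain so the phase is exactly zero and DC is removed
#' completely.
#'
#' @param data a [sensor_time_series()].
#' @param band_lo_mhz low cut-on (default 0.05 MHz = 50 kHz).
#' @param band_hi_mhz high cut-off (default 20 MHz; 30 MHz for the
#'   high-resolution mode).
#' @return Filtered [sensor_time_series()].
#' @export
bandpass <- function(data, band_lo_mhz = 0.05, band_hi_mhz = 20) {
  stopifnot(inherits(data, "sensor_time_series"))
  d <- dim(data$p)
  f_nyq <- 1e3 / (2 * data$dt_ns)
  if (band_hi_mhz >= f_nyq)
    stop(sprintf("band_hi (%g MHz) must be below Nyquist (%g MHz)",
                 band_hi_mhz, f_nyq), call. = FALSE)
  if (band_lo_mhz <= 0 || band_lo_mhz >= band_hi_mhz)
    stop("band must satisfy 0 < band_lo < band_hi", call. = FALSE)
  f <- abs(fft_freq(d[3], ns_to_s(data$dt_ns))) * 1e-6
  # |H|^2 of 4th-order Butterworth low/high sections (order 8 rolloff)
  h <- 1 / (1 + (f / band_hi_mhz)^8)
  h <- h * ifelse(f > 0, 1 / (1 + (band_lo_mhz / pmax(f, 1e-12))^8), 0)
  pm <- matrix(aperm(data$p, c(3, 1, 2)), d[3], d[1] * d[2])
  pf <- Re(mvfft(mvfft(pm) * h, inverse = TRUE)) / d[3]
  data$p <- aperm(array(pf, c(d[3], d[1], d[2])), c(2, 3, 1))
  data
}

# Fourier zero-padding interpolation along one dimension of a matrix
# (columns = signals); preserves the original samples exactly.
.fourier_upsample_1d <- function(m, factor) {
  n <- nrow(m)
  if (factor == 1) return(m)
  n2 <- n * factor
  sp <- mvfft(m)
  out <- matrix(0 + 0i, n2, ncol(m))
  h <- floor(n / 2)
  out[1:(h + 1), ] <- sp[1:(h + 1), ]
  if (n > 1) out[(n2 - (n - h - 2)):n2, ] <- sp[(h + 2):n, ]
  if (n %% 2 == 0) {
    # split the Nyquist bin so the interpolant is real and passes through
    # the original samples
    out[h + 1, ] <- sp[h + 1, ] / 2
    out[n2 - h + 1, ] <- sp[h + 1, ] / 2
  }
  Re(mvfft(out, inverse = TRUE)) * factor / n2
}

#' Spatially upsample the detection grid
#'
#' Interpolates fully sampled sensor data onto a x2 or x3 finer lateral grid
#' by Fourier zero-padding (periodic sinc interpolation); original samples
#' are preserved exactly and spatially band-limited fields are reproduced at
#' the new nodes.
#'
#' @param data a [sensor_time_series()] with an all-true mask.
#' @param factor integer upsampling factor, 1, 2 or 3.
#' @return A [sensor_time_series()] with `factor^2` times as many channels.
#' @export
spatial_upsample <- function(data, factor = 2) {
  stopifnot(inherits(data, "sensor_time_series"))
  if (!factor %in% c(1, 2, 3))
    stop("factor must be 1, 2 or 3", call. = FALSE)
  if (!all(data$mask))
    stop("spatial_upsample requires fully sampled data; reconstruct subsampled scans with reconstruct_tv()",
         call. = FALSE)
  if (factor == 1) return(data)
  d <- dim(data$p)
  # upsample x: treat (x) as rows against all (y,t) columns
  px <- matrix(data$p, d[1], d[2] * d[3])
  px <- Re(.fourier_upsample_1d(px, factor))
  p1 <- array(px, c(d[1] * factor, d[2], d[3]))
  # upsample y
  p2 <- aperm(p1, c(2, 1, 3))
  py <- matrix(p2, d[2], d[1] * factor * d[3])
  py <- Re(.fourier_upsample_1d(py, factor))
  p3 <- aperm(array(py, c(d[2] * factor, d[1] * factor, d[3])), c(2, 1, 3))
  sensor_time_series(p3, data$dx_um / factor, data$dy_um / factor,
                     data$dt_ns, data$c_mps)
}

# Brenner gradient sharpness of a volume: sum of squared axial first
# differences of the envelope (absolute value)
.brenner_sharpness <- function(vol_arr) {
  a <- abs(vol_arr)
  d <- a[, , -1, drop = FALSE] - a[, , -dim(a)[3], drop = FALSE]
  sum(d^2)
}

#' Autofocus sound-speed estimation
#'
#' Estimates the tissue sound speed by maximizing the sharpness (Brenner
#' gradient of the envelope) of trial reconstructions over a coarse grid of
#' candidate speeds, refined by golden-section search around the best
#' candidate. On featureless (pure-noise) data the metric is flat; a warning
#' is issued and the range midpoint returned.
#'
#' @param data a [sensor_time_series()] (fully sampled).
#' @param c_range length-2 search range (m/s), default c(1350, 1700).
#' @param coarse_step coarse grid spacing (m/s), default 25.
#' @param nz depth samples of the trial reconstruction grid (default: data
#'   time samples).
#' @return Estimated sound speed c* (m/s) with attribute `"sharpness"` (the
#'   coarse-grid profile).
#' @export
autofocus_sound_speed <- function(data, c_range = c(1350, 1700),
                                  coarse_step = 25, nz = NULL) {
  stopifnot(inherits(data, "sensor_time_series"))
  d <- dim(data$p)
  if (is.null(nz)) nz <- d[3]
  cands <- seq(c_range[1], c_range[2], by = coarse_step)
  sharp <- function(cc) {
    op <- planar_operator(d[1], d[2], nz, d[3], data$dx_um, data$dy_um,
                          cc * ns_to_s(data$dt_ns) * 1e6, data$dt_ns, cc)
    .brenner_sharpness(op$recon(data$p))
  }
  prof <- vapply(cands, sharp, 0)
  if (max(prof) - min(prof) < 1e-12 * max(abs(prof), 1)) {
    warning("flat autofocus metric (featureless data); returning range midpoint")
    return(structure(mean(c_range), sharpness = prof))
  }
  i <- which.max(prof)
  lo <- cands[max(i - 1, 1)]; hi <- cands[min(i + 1, length(cands))]
  opt <- stats::optimize(sharp, interval = c(lo, hi), maximum = TRUE,
                         tol = coarse_step / 10)
  structure(opt$maximum, sharpness = prof, coarse_mps = cands)
}

#' Depth-dependent attenuation correction
#'
#' First-order correction for optical fluence decay and acoustic attenuation:
#' the reconstructed image intensity is scaled by `exp(mu * z)` with `z` the
#' depth in metres. Exactly invertible with the negated exponent.
#'
#' @param vol a [pressure_volume()].
#' @param mu_per_m exponent (1/m), typically 100-150; default 120.
#' @return The corrected [pressure_volume()].
#' @export
attenuation_correction <- function(vol, mu_per_m = 120) {
  stopifnot(inherits(vol, "pressure_volume"))
  stopifnot_scalar(mu_per_m, "mu_per_m")
  z_m <- um_to_m(.vol_axis(vol, 3))
  gain <- exp(mu_per_m * z_m)
  vol$p0 <- sweep(vol$p0, 3, gain, `*`)
  vol
}
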