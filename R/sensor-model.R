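#' Fabry-Perot sensor specification
#'
#' Bundles the optical and acoustic parameters of a Fabry-Perot interferometer
#' (FPI) ultrasound sensor: the polymer spacer thickness `l`, the fringe
#' finesse `F` (= FSR / fringe FWHM), the fringe visibility `V` (fractional
#' fringe depth on a unit reflected-power background), the free spectral range
#' `FSR`, the interrogation bias wavelength, the -3 dB acoustic bandwidth, and
#' the statistics (mode, FWHM) of the spatial noise-equivalent-pressure (NEP)
#' distribution over the scan area.
#'
#' @param spacer_thickness_um FPI polymer spacer thickness (micrometres).
#' @param finesse reflectivity finesse F (> 1); fringe FWHM = FSR / F.
#' @param visibility fringe visibility V in (0, 1]: fractional modulation depth
#'   of the reflected optical power.
#' @param fsr_nm free spectral range (nm). If `NULL`, derived from the spacer
#'   thickness and refractive index as lambda^2 / (2 n l); a supplied value
#'   always wins over the derived one.
#' @param refractive_index spacer refractive index (default 1.66, Parylene C
#'   in the near infrared); used only when deriving the FSR.
#' @param resonance_nm wavelength of a reflectance minimum (nm); fixes the
#'   fringe comb position.
#' @param bias_wavelength_nm interrogation bias wavelength (nm); if `NULL` it
#'   is set by [optimum_bias()].
#' @param f3db_mhz -3 dB acoustic bandwidth (MHz).
#' @param nep_mode_kpa,nep_fwhm_kpa mode and FWHM of the NEP distribution (kPa).
#' @param band_lo_mhz,band_hi_mhz detection passband used downstream (MHz).
#' @return An object of class `fp_sensor_spec`.
#' @examples
#' spec <- fp_sensor_spec(spacer_thickness_um = 26.6, finesse = 76.6,
#'                        visibility = 0.78, fsr_nm = 26.6, f3db_mhz = 31.5)
#' spec$fringe_fwhm_nm   # FSR / F
#' @export
fp_sensor_spec <- function(spacer_thickness_um = 26.6,
                           finesse = 76.6,
                           visibility = 0.78,
                           fsr_nm = 26.6,
                           refractive_index = 1.66,
                           resonance_nm = 1550,
                           bias_wavelength_nm = NULL,
                           f3db_mhz = 31.5,
                           nep_mode_kpa = 0.2,
                           nep_fwhm_kpa = 0.25,
                           band_lo_mhz = 0.05,
                           band_hi_mhz = 20) {
  stopifnot_scalar(spacer_thickness_um, "spacer_thickness_um", positive = TRUE)
  stopifnot_scalar(finesse, "finesse")
  if (finesse <= 1) stop("non-physical spec: finesse must be > 1", call. = FALSE)
  stopifnot_scalar(visibility, "visibility")
  if (visibility <= 0 || visibility > 1)
    stop("non-physical spec: visibility must be in (0, 1]", call. = FALSE)
  if (is.null(fsr_nm))
    fsr_nm <- resonance_nm^2 / (2 * refractive_index * spacer_thickness_um * 1e3)
  stopifnot_scalar(fsr_nm, "fsr_nm", positive = TRUE)
  stopifnot_scalar(f3db_mhz, "f3db_mhz", positive = TRUE)
  stopifnot_scalar(nep_mode_kpa, "nep_mode_kpa", positive = TRUE)
  stopifnot_scalar(nep_fwhm_kpa, "nep_fwhm_kpa", positive = TRUE)
  spec <- structure(list(
    spacer_thickness_um = spacer_thickness_um,
    refractive_index = refractive_index,
    finesse = finesse,
    visibility = visibility,
    fsr_nm = fsr_nm,
    fringe_fwhm_nm = fsr_nm / finesse,
    resonance_nm = resonance_nm,
    bias_wavelength_nm = bias_wavelength_nm,
    f3db_mhz = f3db_mhz,
    nep_mode_kpa = nep_mode_kpa,
    nep_fwhm_kpa = nep_fwhm_kpa,
    band_lo_mhz = band_lo_mhz,
    band_hi_mhz = band_hi_mhz
  ), class = "fp_sensor_spec")
  if (is.null(spec$bias_wavelength_nm))
    spec$bias_wavelength_nm <- optimum_bias(spec)
  spec
}

#' @export
print.fp_sensor_spec <- function(x, ...) {
  cat("<fp_sensor_spec>\n")
  cat(sprintf("  spacer %.1f um | F = %.1f | V = %.2f | FSR = %.1f nm (fringe FWHM %.3f nm)\n",
              x$spacer_thickness_um, x$finesse, x$visibility, x$fsr_nm, x$fringe_fwhm_nm))
  cat(sprintf("  bias %.4f nm | f-3dB = %.1f MHz | NEP mode %.2f kPa, FWHM %.2f kPa\n",
              x$bias_wavelength_nm, x$f3db_mhz, x$nep_mode_kpa, x$nep_fwhm_kpa))
  invisible(x)
}

#' Interferometer transfer function (ITF): reflected power vs wavelength
#'
#' Airy reflectance of a lossless two-mirror cavity, scaled by the fringe
#' visibility on a unit background:
#' R(lambda) = 1 - V / (1 + Fc sin^2(pi (lambda - lambda0) / FSR)),
#' with the coefficient of finesse Fc = 1 / sin^2(pi / (2 F)) so that the
#' fringe FWHM equals FSR / F. Exactly periodic in the FSR and bounded in
#' `[1 - V, 1]`.
#'
#' @param spec an [fp_sensor_spec()].
#' @param wavelength_nm interrogation wavelength(s), nm.
#' @return Reflected-power fraction(s) in `[0, 1]`.
#' @export
itf_reflectance <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "fp_sensor_spec"))
  fc <- 1 / sin(pi / (2 * spec$finesse))^2
  phase <- pi * (wavelength_nm - spec$resonance_nm) / spec$fsr_nm
  1 - spec$visibility / (1 + fc * sin(phase)^2)
}

# d(ITF)/d(lambda), closed form, nm^-1
itf_slope <- function(spec, wavelength_nm) {
  fc <- 1 / sin(pi / (2 * spec$finesse))^2
  u <- pi * (wavelength_nm - spec$resonance_nm) / spec$fsr_nm
  s <- sin(u); cs <- cos(u)
  spec$visibility * fc * 2 * s * cs * (pi / spec$fsr_nm) / (1 + fc * s^2)^2
}

#' Optimum bias wavelength
#'
#' The interrogation wavelength at the peak derivative of the ITF, which
#' maximizes the acoustic sensitivity of the read-out. Of the two slope
#' extrema flanking each reflectance minimum, the positive-slope solution
#' (long-wavelength side of the resonance) is returned by convention.
#' Located by a dense grid search over one free spectral range refined with
#' [stats::optimize()].
#'
#' @param spec an [fp_sensor_spec()].
#' @param tol_nm refinement tolerance (nm, default 1e-6).
#' @return Bias wavelength lambda_b (nm).
#' @export
optimum_bias <- function(spec, tol_nm = 1e-6) {
  stopifnot(inherits(spec, "fp_sensor_spec"))
  if (spec$visibility <= 0) stop("no fringe: visibility is zero", call. = FALSE)
  # positive-slope branch lies in (resonance, resonance + FSR/2)
  lo <- spec$resonance_nm
  hi <- spec$resonance_nm + spec$fsr_nm / 2
  grid <- seq(lo, hi, length.out = 512L)
  l0 <- grid[which.max(itf_slope(spec, grid))]
  dg <- grid[2] - grid[1]
  opt <- stats::optimize(function(l) itf_slope(spec, l),
                         interval = c(l0 - dg, l0 + dg),
                         maximum = TRUE, tol = tol_nm)
  opt$maximum
}

#' Bias-parity sensitivity ratio under a spread of bias wavelengths
#'
#' With many interrogation beams sharing one laser wavelength, spacer
#' thickness non-uniformity spreads the per-beam optimum bias wavelengths
#' over a range `dlambda_nm`. With the laser tuned to the centre of that
#' spread, the worst-detuned beam sits `dlambda_nm / 2` from its own optimum;
#' this returns the worst-case ITF slope there as a fraction of the peak
#' slope.
#'
#' @param spec an [fp_sensor_spec()].
#' @param dlambda_nm full spread of bias wavelength across the beam array (nm).
#' @return Worst-case sensitivity as a fraction of maximum (0-1).
#' @export
bias_sensitivity_ratio <- function(spec, dlambda_nm) {
  stopifnot_scalar(dlambda_nm, "dlambda_nm", nonneg = TRUE)
  lb <- optimum_bias(spec)
  smax <- abs(itf_slope(spec, lb))
  d <- dlambda_nm / 2
  min(abs(itf_slope(spec, lb - d)), abs(itf_slope(spec, lb + d))) / smax
}

#' Spacer thickness uniformity tolerance
#'
#' The thickness variation `dl` that produces a bias-wavelength variation
#' `dlambda_b`: `dl = l * dlambda_b / lambda_b` (returned in nm).
#'
#' @param l_um spacer thickness (micrometres).
#' @param lambda_b_nm bias wavelength (nm).
#' @param dlambda_b_nm bias-wavelength variation (nm, >= 0).
#' @return Thickness tolerance dl (nm).
#' @examples
#' thickness_tolerance(25, 1550, 0.08)  # ~1.29 nm
#' @export
thickness_tolerance <- function(l_um, lambda_b_nm, dlambda_b_nm) {
  stopifnot_scalar(l_um, "l_um", positive = TRUE)
  stopifnot_scalar(lambda_b_nm, "lambda_b_nm")
  if (lambda_b_nm <= 0) stop("lambda_b_nm must be > 0", call. = FALSE)
  stopifnot_scalar(dlambda_b_nm, "dlambda_b_nm", nonneg = TRUE)
  (l_um * 1e3) * dlambda_b_nm / lambda_b_nm
}

# sinc argument at which |sinc| = 1/sqrt(2); root of sin(pi x)/(pi x) = 2^-1/2
.sinc_half_power <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      f <- function(x) sin(pi * x) / (pi * x) - 1 / sqrt(2)
      val <<- uniroot(f, c(0.3, 0.6), tol = 1e-12)$root
    }
    val
  }
})

#' Acoustic frequency response of the FP sensor
#'
#' Magnitude of a sinc-type thickness-averaging response
#' `|sinc(a f / f3db)|`, with `a` calibrated so the response is exactly
#' 1/sqrt(2) at the sensor's stated -3 dB frequency. Unity at DC and
#' monotonically non-increasing up to the first null.
#'
#' @param spec an [fp_sensor_spec()].
#' @param f_mhz acoustic frequency (MHz, >= 0; vectorized).
#' @return Normalized amplitude(s) in `[0, 1]`.
#' @export
frequency_response <- function(spec, f_mhz) {
  stopifnot(inherits(spec, "fp_sensor_spec"))
  if (any(f_mhz < 0)) stop("f_mhz must be >= 0", call. = FALSE)
  x <- .sinc_half_power() * f_mhz / spec$f3db_mhz
  out <- rep(1, length(x))
  nz <- x > 0
  out[nz] <- abs(sin(pi * x[nz]) / (pi * x[nz]))
  out
}

# log-normal shape parameter matching a given FWHM / mode ratio
.lognorm_shape_from_ratio <- function(ratio) {
  fwhm_over_mode <- function(sigma) {
    mode0 <- exp(-sigma^2)            # mu = 0
    fmax <- stats::dlnorm(mode0, 0, sigma)
    lo <- uniroot(function(x) stats::dlnorm(x, 0, sigma) - fmax / 2,
                  c(1e-12, mode0), tol = 1e-12)$root
    hi <- uniroot(function(x) stats::dlnorm(x, 0, sigma) - fmax / 2,
                  c(mode0, mode0 * exp(10 * sigma)), tol = 1e-12)$root
    (hi - lo) / mode0
  }
  uniroot(function(s) fwhm_over_mode(s) - ratio, c(0.01, 2), tol = 1e-9)$root
}

#' Sample a spatial NEP map
#'
#' Draws a per-channel noise-equivalent-pressure map from a log-normal
#' distribution parameterized by its mode and FWHM (numerically matched),
#' emulating the skewed unimodal NEP histogram of an FP scanner over its
#' scan area.
#'
#' @param nx,ny map dimensions (detection grid points).
#' @param mode_kpa modal NEP (kPa, > 0).
#' @param fwhm_kpa FWHM of the NEP distribution (kPa, > 0).
#' @param seed integer seed for reproducibility.
#' @return An `nx` x `ny` matrix of strictly positive NEP values (kPa).
#' @export
sample_nep_map <- function(nx, ny, mode_kpa = 0.2, fwhm_kpa = 0.25, seed = 1L) {
  stopifnot_scalar(mode_kpa, "mode_kpa", positive = TRUE)
  stopifnot_scalar(fwhm_kpa, "fwhm_kpa", positive = TRUE)
  sigma <- .lognorm_shape_from_ratio(fwhm_kpa / mode_kpa)
  scale <- mode_kpa / exp(-sigma^2)   # exp(mu)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(stats::rlnorm(nx * ny, meanlog = log(scale), sdlog = sigma), nx, ny)
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
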