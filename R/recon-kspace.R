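#' Reconstruction configuration
#'
#' @param c_mps sound speed input to the reconstruction (m/s).
#' @param dz_um output depth pitch (default `c * dt`, the finest alias-free
#'   depth sampling).
#' @param nz output depth samples (default: as many as the temporal record
#'   supports, `floor(nt * dt * c / dz)`).
#' @param band_hi_mhz optional requested detection band; when the lateral
#'   pitch cannot support it a warning reports the aliasing risk.
#' @param post_interp integer factor for interpolating the reconstructed
#'   volume onto a finer lateral grid (default 2, as in routine use; 1
#'   disables).
#' @param taper_lo,taper_hi valid-cone policy passed to [planar_operator()].
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(c_mps = 1500, dz_um = NULL, nz = NULL,
                         post_interp = 1, band_hi_mhz = NULL,
                         taper_lo = 0.15, taper_hi = 0.3) {
  stopifnot_scalar(c_mps, "c_mps", positive = TRUE)
  structure(list(c_mps = c_mps, dz_um = dz_um, nz = nz,
                 post_interp = post_interp, band_hi_mhz = band_hi_mhz,
                 taper_lo = taper_lo, taper_hi = taper_hi),
            class = "recon_config")
}

# lateral Fourier interpolation of a reconstructed volume
.lateral_upsample_volume <- function(vol, factor) {
  if (factor == 1) return(vol)
  d <- dim(vol$p0)
  px <- matrix(vol$p0, d[1], d[2] * d[3])
  px <- Re(.fourier_upsample_1d(px, factor))
  p1 <- array(px, c(d[1] * factor, d[2], d[3]))
  p2 <- aperm(p1, c(2, 1, 3))
  py <- matrix(p2, d[2], d[1] * factor * d[3])
  py <- Re(.fourier_upsample_1d(py, factor))
  p3 <- aperm(array(py, c(d[2] * factor, d[1] * factor, d[3])), c(2, 1, 3))
  pressure_volume(p3, vol$dx_um / factor, vol$dy_um / factor, vol$dz_um,
                  vol$origin_um)
}

#' One-step k-space reconstruction
#'
#' Maps fully sampled planar time-series data to the initial pressure by the
#' Fourier-domain dispersion-shell remap (k-space backprojection): FFT of the
#' data, interpolation from the regular temporal-frequency grid onto the kz
#' grid along `omega = c sqrt(kx^2 + ky^2 + kz^2)` with Jacobian weight
#' `c^2 kz / omega` and the half-space factor 2, inverse FFT. Evanescent
#' content is discarded; the output is real and linear in the data.
#'
#' @param data a [sensor_time_series()] with all channels valid.
#' @param cfg a [recon_config()].
#' @param op optional precomputed [planar_operator()] matching `data`.
#' @return A [pressure_volume()].
#' @export
reconstruct_kspace <- function(data, cfg = recon_config(), op = NULL) {
  stopifnot(inherits(data, "sensor_time_series"))
  if (!all(data$mask))
    stop("masked (subsampled) data: use reconstruct_tv()", call. = FALSE)
  d <- dim(data$p)
  cc <- cfg$c_mps
  dz <- if (is.null(cfg$dz_um)) cc * ns_to_s(data$dt_ns) * 1e6 else cfg$dz_um
  nz <- if (is.null(cfg$nz)) floor(d[3] * data$dt_ns * 1e-3 * cc / dz) else cfg$nz
  lat_nyq_mhz <- cc / (2 * um_to_m(max(data$dx_um, data$dy_um))) * 1e-6
  if (!is.null(cfg$band_hi_mhz) && lat_nyq_mhz < cfg$band_hi_mhz)
    warning(sprintf("lateral pitch supports only %.1f MHz (< requested band %.1f MHz); oblique content above that aliases",
                    lat_nyq_mhz, cfg$band_hi_mhz))
  if (is.null(op))
    op <- planar_operator(d[1], d[2], nz, d[3], data$dx_um, data$dy_um,
                          dz, data$dt_ns, cc,
                          taper_lo = cfg$taper_lo, taper_hi = cfg$taper_hi)
  vol <- pressure_volume(op$recon(data$p), data$dx_um, data$dy_um, dz)
  .lateral_upsample_volume(vol, cfg$post_interp)
}

#' Dual-sound-speed composite reconstruction
#'
#' Reconstructs the full volume twice, at an inner and an outer sound speed,
#' and composites them through a lateral region mask with a 3-voxel cosine
#' blend at the seam — used when a region (for example the nail plate) has a
#' distinctly higher sound speed than the surrounding soft tissue.
#'
#' @param data a [sensor_time_series()].
#' @param c_inner,c_outer sound speeds (m/s) for the masked region and the
#'   remainder.
#' @param region_mask_xy logical matrix on the lateral grid (TRUE = inner).
#' @param cfg a [recon_config()] (its `c_mps` is ignored).
#' @return A [pressure_volume()].
#' @export
reconstruct_dual_speed <- function(data, c_inner, c_outer, region_mask_xy,
                                   cfg = recon_config()) {
  stopifnot(inherits(data, "sensor_time_series"))
  d <- dim(data$p)
  if (!all(dim(region_mask_xy) == d[1:2]))
    stop("region_mask_xy must match the lateral grid", call. = FALSE)
  cfg_out <- cfg; cfg_out$c_mps <- c_outer
  # common depth grid so the two volumes composite voxel-by-voxel
  if (is.null(cfg_out$dz_um))
    cfg_out$dz_um <- min(c_inner, c_outer) * ns_to_s(data$dt_ns) * 1e6
  if (is.null(cfg_out$nz))
    cfg_out$nz <- floor(d[3] * data$dt_ns * 1e-3 * min(c_inner, c_outer) /
                          cfg_out$dz_um)
  outer_vol <- reconstruct_kspace(data, cfg_out)
  if (c_inner == c_outer || !any(region_mask_xy)) return(outer_vol)
  cfg_in <- cfg_out; cfg_in$c_mps <- c_inner
  inner_vol <- reconstruct_kspace(data, cfg_in)
  # cosine blend of the lateral mask over a 3-voxel margin
  wmask <- .blend_mask(region_mask_xy, width = 3) # 1 inside, 0 outside
  if (cfg$post_interp > 1) {
    f <- cfg$post_interp
    wmask <- wmask[rep(seq_len(nrow(wmask)), each = f),
                   rep(seq_len(ncol(wmask)), each = f)][
                     seq_len(dim(inner_vol$p0)[1]),
                     seq_len(dim(inner_vol$p0)[2])]
  }
  blended <- inner_vol
  nzv <- dim(inner_vol$p0)[3]
  blended$p0 <- inner_vol$p0 * array(rep(wmask, nzv), dim(inner_vol$p0)) +
    outer_vol$p0 * array(rep(1 - wmask, nzv), dim(outer_vol$p0))
  blended
}

# distance-based cosine ramp of a logical mask (width in pixels)
.blend_mask <- function(mask, width = 3) {
  m <- mask * 1
  out <- m
  for (i in seq_len(width)) {
    # grow by one 4-neighbour dilation per step, tracking ramp level
    grown <- m
    grown[-1, ] <- pmax(grown[-1, ], m[-nrow(m), ])
    grown[-nrow(m), ] <- pmax(grown[-nrow(m), ], m[-1, ])
    grown[, -1] <- pmax(grown[, -1], m[, -ncol(m)])
    grown[, -ncol(m)] <- pmax(grown[, -ncol(m)], m[, -1])
    ring <- grown - m
    out <- out + ring * (0.5 + 0.5 * cos(pi * i / (width + 1)))
    m <- grown
  }
  pmin(out, 1)
}

#' Point-spread-function probe
#'
#' Simulates point targets at the requested depths (laterally separated so
#' they do not interfere), reconstructs them, and measures the lateral and
#' vertical FWHM of each peak from interpolated line profiles.
#'
#' @param depths_mm numeric vector of target depths (mm).
#' @param cfg a [recon_config()].
#' @param sensor_spec optional [fp_sensor_spec()] whose frequency response is
#'   applied to the simulated data before reconstruction.
#' @param nx,dx_um lateral simulation grid.
#' @param aperture_mm optional finite scan-aperture width: data outside the
#'   central square aperture are zeroed (with a 2-pixel cosine edge) before
#'   reconstruction, emulating the finite scan footprint that makes lateral
#'   resolution degrade with depth. Default `NULL` keeps the full (laterally
#'   periodic) aperture, whose lateral PSF is depth-invariant.
#' @param dt_ns temporal sampling.
#' @return Data frame with `depth_mm`, `fwhm_lateral_um`, `fwhm_vertical_um`.
#' @export
psf_probe <- function(depths_mm, cfg = recon_config(), sensor_spec = NULL,
                      nx = 64, dx_um = 108, aperture_mm = NULL,
                      dt_ns = 16.67) {
  cc <- cfg$c_mps
  dz <- cc * ns_to_s(dt_ns) * 1e6
  zmax_um <- max(depths_mm) * 1e3
  nz <- ceiling(zmax_um / dz * 1.15)
  nt <- next_pow2(ceiling(nz * 1.3))
  if (nt * dt_ns * 1e-3 * cc < zmax_um)
    stop("depth beyond the temporal window", call. = FALSE)
  out <- data.frame(depth_mm = depths_mm, fwhm_lateral_um = NA_real_,
                    fwhm_vertical_um = NA_real_)
  op <- planar_operator(nx, nx, nz, nt, dx_um, dx_um, dz, dt_ns, cc,
                        taper_lo = cfg$taper_lo, taper_hi = cfg$taper_hi)
  centre <- floor(nx / 2)
  apod <- NULL
  if (!is.null(aperture_mm)) {
    half_px <- aperture_mm * 1e3 / (2 * dx_um)
    r <- abs(seq_len(nx) - centre)
    w1 <- pmin(pmax((half_px - r) / 2 + 1, 0), 1)    # 2-pixel cosine edge
    w1 <- 0.5 - 0.5 * cos(pi * w1)
    apod <- outer(w1, w1)
  }
  for (i in seq_along(depths_mm)) {
    p0 <- array(0, c(nx, nx, nz))
    iz <- round(depths_mm[i] * 1e3 / dz) + 1
    p0[centre, centre, iz] <- 1
    y <- op$forward(p0)
    ts <- sensor_time_series(y, dx_um, dx_um, dt_ns, cc)
    if (!is.null(sensor_spec)) ts <- apply_sensor_bandwidth(ts, sensor_spec)
    if (!is.null(apod))
      ts$p <- ts$p * array(rep(apod, dim(ts$p)[3]), dim(ts$p))
    rec <- op$recon(ts$p)
    pk <- which(rec == max(rec), arr.ind = TRUE)[1, ]
    # lateral profile through the peak, Fourier-interpolated x8
    prof_l <- rec[, pk[2], pk[3]]
    up <- Re(.fourier_upsample_1d(matrix(prof_l, ncol = 1), 8))[, 1]
    out$fwhm_lateral_um[i] <- profile_fwhm(seq_along(up) * dx_um / 8, pmax(up, 0))
    prof_v <- rec[pk[1], pk[2], ]
    upv <- Re(.fourier_upsample_1d(matrix(prof_v, ncol = 1), 8))[, 1]
    out$fwhm_vertical_um[i] <- profile_fwhm(seq_along(upv) * dz / 8, pmax(upv, 0))
  }
  out
}
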