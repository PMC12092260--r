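#' Line-scan frame (2D video-rate mode)
#'
#' In the 2D mode the 4 x 16 beam array is scanned along a line with its long
#' axis on the line, synthesizing a 1.5D receive array: `m` scan columns by 4
#' elevation rows of A-lines. Elevation offsets default to the 4 rows of a
#' 324 um pitch array centred on the imaging plane: (-486, -162, +162, +486).
#'
#' @param p 3D array `[col, row, t]` with 4 elevation rows.
#' @param step_um scan step along the line (micrometres).
#' @param dt_ns temporal sampling (ns).
#' @param elevation_offsets_um per-row elevation offsets (µm), symmetric
#'   about the imaging plane.
#' @param timestamp_s frame acquisition time (s).
#' @return An object of class `line_scan_frame`.
#' @export
line_scan_frame <- function(p, step_um, dt_ns = 16.67,
                            elevation_offsets_um = c(-486, -162, 162, 486),
                            timestamp_s = 0) {
  stopifnot(length(dim(p)) == 3L)
  if (dim(p)[2] != length(elevation_offsets_um))
    stop("one elevation offset per row required", call. = FALSE)
  if (any(sort(elevation_offsets_um) + rev(sort(elevation_offsets_um)) != 0))
    stop("elevation offsets must be symmetric about the imaging plane",
         call. = FALSE)
  structure(list(p = p, step_um = step_um, dt_ns = dt_ns,
                 elevation_offsets_um = elevation_offsets_um,
                 timestamp_s = timestamp_s),
            class = "line_scan_frame")
}

# linear-interpolation sample of signal matrix (rows = time) at fractional
# sample positions (matrix same shape)
.delay_sample <- function(sig, at) {
  n <- length(sig)
  lo <- floor(at)
  fr <- at - lo
  ok <- lo >= 1 & lo < n
  lo_c <- pmin(pmax(lo, 1L), n - 1L)
  out <- (1 - fr) * sig[lo_c] + fr * sig[lo_c + 1L]
  out[!ok] <- 0
  out
}

#' Depth-dependent elevational receive focusing
#'
#' Delay-and-sum across the 4 elevation rows with depth-dependent delays
#' `tau(z, y_e) = (sqrt(z^2 + y_e^2) - z) / c`, where the output sample at
#' time t is focused at depth `z = c t`. In-plane signals sum coherently
#' (gain up to the row count); out-of-plane arrivals are misaligned and
#' suppressed.
#'
#' @param frame a [line_scan_frame()].
#' @param c_mps sound speed (m/s).
#' @param apodization per-row weights (default uniform).
#' @return Matrix `[col, t]` of focused A-lines.
#' @export
elevation_focus <- function(frame, c_mps = 1500, apodization = NULL) {
  stopifnot(inherits(frame, "line_scan_frame"))
  d <- dim(frame$p)
  n_rows <- d[2]
  if (is.null(apodization)) apodization <- rep(1, n_rows)
  dt_s <- ns_to_s(frame$dt_ns)
  t_idx <- seq_len(d[3])
  z <- c_mps * (t_idx - 1) * dt_s                    # focal depth per sample
  out <- matrix(0, d[1], d[3])
  for (r in seq_len(n_rows)) {
    ye <- um_to_m(frame$elevation_offsets_um[r])
    tau <- (sqrt(z^2 + ye^2) - z) / c_mps            # extra path delay (s)
    at <- t_idx + tau / dt_s                         # fractional sample
    for (col in seq_len(d[1]))
      out[col, ] <- out[col, ] +
        apodization[r] * .delay_sample(frame$p[col, r, ], at)
  }
  out
}

#' 2D in-plane k-space reconstruction
#'
#' 2D analogue of the planar dispersion-shell remap: maps focused line-scan
#' data `[col, t]` to an x-z image via the `omega = c sqrt(kx^2 + kz^2)`
#' shell (implemented with a single-row 3D operator).
#'
#' @param focused matrix `[col, t]` (output of [elevation_focus()]).
#' @param step_um lateral scan step (µm).
#' @param dt_ns temporal sampling (ns).
#' @param c_mps sound speed (m/s).
#' @param nz output depth samples (default: supported by the record).
#' @return List with `image` (matrix `[col, z]`), `dx_um`, `dz_um`.
#' @export
reconstruct_2d <- function(focused, step_um, dt_ns = 16.67, c_mps = 1500,
                           nz = NULL) {
  d <- dim(focused)
  dz <- c_mps * ns_to_s(dt_ns) * 1e6
  if (is.null(nz)) nz <- floor(d[2] * dt_ns * 1e-3 * c_mps / dz)
  op <- planar_operator(d[1], 1L, nz, d[2], step_um, step_um, dz, dt_ns,
                        c_mps)
  img <- op$recon(array(focused, c(d[1], 1, d[2])))[, 1, ]
  list(image = img, dx_um = step_um, dz_um = dz)
}

#' Track a vessel's minor-axis diameter through a frame sequence
#'
#' For each 2D frame, takes the depth profile through the brightest pixel of
#' the region of interest and measures the vessel's minor-axis extent as the
#' FWHM of that profile (interpolated crossings). Frames where the profile
#' peak falls below `noise_floor` yield `NA` (vessel lost).
#'
#' @param frames list of image matrices `[x, z]` (or lists with `$image`).
#' @param vessel_roi list with `x` and `z` index ranges (each length 2).
#' @param dz_um depth pixel pitch (µm) for calibrated diameters.
#' @param noise_floor minimum peak amplitude (default 0).
#' @return Numeric vector of diameters (mm), one per frame.
#' @export
track_vessel_diameter <- function(frames, vessel_roi, dz_um,
                                  noise_floor = 0) {
  vapply(frames, function(fr) {
    img <- if (is.list(fr)) fr$image else fr
    xs <- vessel_roi$x[1]:vessel_roi$x[2]
    zs <- vessel_roi$z[1]:vessel_roi$z[2]
    sub <- img[xs, zs, drop = FALSE]
    if (max(sub) <= noise_floor) return(NA_real_)
    # profile through the vessel centre: the column with the largest
    # integrated intensity crosses the full minor axis
    centre_col <- which.max(rowSums(sub))
    prof <- sub[centre_col, ]
    up <- Re(.fourier_upsample_1d(matrix(prof, ncol = 1), 8))[, 1]
    fw <- profile_fwhm(seq_along(up) * dz_um / 8, pmax(up, 0))
    fw * 1e-3
  }, 0)
}
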