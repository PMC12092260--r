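#' Planar sensor time series
#'
#' Pressure records p(x, y, t) on the regular planar detection grid (sensor
#' plane z = 0), with sampling metadata and a per-channel validity mask for
#' subsampled acquisitions.
#'
#' @param p 3D numeric array indexed `[x, y, t]` (kPa).
#' @param dx_um,dy_um detection grid pitch (micrometres).
#' @param dt_ns temporal sampling interval (nanoseconds).
#' @param c_mps sound-speed hint (m/s, default 1500).
#' @param mask logical matrix (nx x ny) of valid channels (default all TRUE).
#' @return An object of class `sensor_time_series`.
#' @export
sensor_time_series <- function(p, dx_um, dy_um = dx_um, dt_ns = 16.67,
                               c_mps = 1500, mask = NULL) {
  stopifnot(length(dim(p)) == 3L)
  stopifnot_scalar(dt_ns, "dt_ns", positive = TRUE)
  if (!all(is.finite(p))) stop("p must be finite", call. = FALSE)
  d <- dim(p)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape must equal the spatial shape", call. = FALSE)
  structure(list(p = p, dx_um = dx_um, dy_um = dy_um, dt_ns = dt_ns,
                 c_mps = c_mps, mask = mask),
            class = "sensor_time_series")
}

#' @export
print.sensor_time_series <- function(x, ...) {
  d <- dim(x$p)
  cat(sprintf("<sensor_time_series> %d x %d channels x %d samples (dx %g um, dt %g ns, c %g m/s); %d/%d channels valid\n",
              d[1], d[2], d[3], x$dx_um, x$dt_ns, x$c_mps, sum(x$mask),
              length(x$mask)))
  invisible(x)
}

# ------------------------------------------------------------------------
# Fourier-domain planar operator.
#
# Both the forward map p0(x,y,z) -> p(x,y,t) and the one-step k-space
# reconstruction are spectral remaps along the acoustic dispersion shell
# omega = c * sqrt(kx^2 + ky^2 + kz^2):
#   forward:  P(kx,ky,omega) = [omega / (2 c^2 kz)] * P0(kx,ky,kz(omega))
#   recon:    P0(kx,ky,kz)   = [2 c^2 kz / omega]  * P(kx,ky,omega(kz))
# with kz(omega) = sign(omega) sqrt(omega^2/c^2 - k_par^2); evanescent
# components (|k_par| > |omega|/c) are zeroed and the factor 2 accounts for
# half-space (one-sided) detection. The sign coupling of kz and omega keeps
# the operator real-to-real.
#
# The off-grid spectral evaluation is a type-2 NUFFT along the remapped
# axis: the source axis is centred, deconvolved by the transform of a
# Kaiser-Bessel kernel, FFT-oversampled (factor OS), and gathered with an
# M-tap kernel; the centring shift returns as a per-output-bin phase. The
# gather is a real sparse matrix, so the adjoint is its exact transpose and
# the forward/adjoint pair satisfies the dot-product identity to rounding.
# ------------------------------------------------------------------------

.kb_os <- 1.25   # spectral oversampling factor
.kb_m <- 6       # kernel taps

.kb_beta <- function() pi * .kb_m * (1 - 1 / (2 * .kb_os))

.kb_kernel_exact <- function(x) {
  half <- .kb_m / 2
  out <- numeric(length(x))
  in_ <- abs(x) < half
  out[in_] <- besselI(.kb_beta() * sqrt(pmax(1 - (x[in_] / half)^2, 0)), 0)
  out
}

# tabulated kernel (linear interpolation on a 1e-4 grid): besselI is far too
# slow to evaluate per remap entry
.kb_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      xs <- seq(-.kb_m / 2, .kb_m / 2, by = 1e-4)
      tab <<- list(x0 = xs[1], dx = 1e-4, y = .kb_kernel_exact(xs))
    }
    tab
  }
})

.kb_kernel <- function(x) {
  tb <- .kb_table()
  ix <- (x - tb$x0) / tb$dx
  ok <- ix >= 0 & ix <= length(tb$y) - 1
  ix <- pmin(pmax(ix, 0), length(tb$y) - 1)
  lo <- floor(ix)
  f <- ix - lo
  out <- (1 - f) * tb$y[lo + 1] + f * tb$y[pmin(lo + 2, length(tb$y))]
  out[!ok] <- 0
  out
}

# Fourier transform of the kernel at centred source indices z' (units of
# source bins), fine-grid length n_pad
.kb_deconv <- function(z_centred, n_pad) {
  half <- .kb_m / 2
  xs <- seq(-half, half, by = 0.005)
  kv <- .kb_kernel(xs)
  vapply(z_centred, function(z) sum(kv * cos(2 * pi * (z / n_pad) * xs)) * 0.005, 0)
}

# Spectral remap between the depth and time axes of planar data.
# Returns the sparse gather G (n_out-bins x padded-source-bins, per lateral
# mode), the complex per-output-bin phase (centring shift), and bookkeeping.
# mode "forward": out axis omega (n_out = nt), source axis kz (padded nz);
# mode "recon":   out axis kz   (n_out = nz), source axis omega (padded nt).
.spectral_remap <- function(nx, ny, dx_m, dy_m, n_src, d_src, n_out, d_out,
                            c0, mode, taper_lo = 0.15, taper_hi = 0.3) {
  n_pad <- 2L * ceiling(.kb_os * n_src / 2)
  kx <- 2 * pi * fft_freq(nx, dx_m)
  ky <- 2 * pi * fft_freq(ny, dy_m)
  kpar2 <- outer(kx^2, ky^2, `+`)
  out_vals <- 2 * pi * fft_freq(n_out, d_out)
  src_fine_step <- 2 * pi / (n_pad * d_src * ifelse(mode == "forward", 1, 1))
  kp2 <- array(rep(kpar2, n_out), c(nx, ny, n_out))
  ov <- array(rep(out_vals, each = nx * ny), c(nx, ny, n_out))
  dc <- kp2 == 0 & ov == 0                    # on-axis zero-frequency bin
  # Near grazing incidence (kz -> 0 at fixed omega) the plane-to-volume
  # mapping diverges as omega/(c kz) = 1/cos(theta); both directions carry a
  # raised-cosine angular taper that is unity for cos(theta) >= 0.3
  # (propagation within ~72 deg of the normal) and rolls off to zero at
  # cos(theta) = 0.15, suppressing the unstable grazing band.
  taper <- function(cost) {
    t <- pmin(pmax((cost - taper_lo) / (taper_hi - taper_lo), 0), 1)
    0.5 - 0.5 * cos(pi * t)
  }
  if (mode == "forward") {
    # out: omega (rad/s); src: kz (rad/m); fine kz step 2*pi/(n_pad*dz)
    disc <- (ov / c0)^2 - kp2
    ok <- disc > 0 | dc
    src <- sign(ov) * sqrt(pmax(disc, 0))
    fine <- 2 * pi / (n_pad * d_src)
    cost <- c0 * abs(src) / pmax(abs(ov), 1e-300)
    w <- taper(cost) * abs(ov) / (2 * c0^2 * pmax(abs(src), fine / 2))
    w[dc] <- 1 / (2 * c0)                     # omega/(c kz) -> 1 on axis
    shift <- (n_src / 2) * d_src              # centring offset (m)
  } else {
    # out: kz (rad/m); src: omega (rad/s); fine omega step 2*pi/(n_pad*dt)
    src <- sign(ov) * c0 * sqrt(kp2 + ov^2)
    fine <- 2 * pi / (n_pad * d_src)
    ok <- abs(src) <= pi / d_src + 1e-9       # inside the data band
    cost <- c0 * abs(ov) / pmax(abs(src), 1e-300)
    w <- taper(cost) * 2 * c0^2 * abs(ov) / pmax(abs(src), fine / 2)
    w[dc] <- 2 * c0
    shift <- (n_src / 2) * d_src              # centring offset (s)
  }
  fb <- as.vector(src) / fine
  ok <- as.vector(ok) & abs(fb) <= n_pad / 2
  n_rows <- nx * ny * n_out
  fb[!ok] <- 0
  wv <- as.vector(w); wv[!ok] <- 0
  lo <- floor(fb)
  f <- fb - lo
  half <- .kb_m / 2
  offs <- (-half + 1L):half
  xy <- (seq_len(n_rows) - 1L) %% (nx * ny)
  idx <- matrix(0L, n_rows, length(offs))
  wt <- matrix(0, n_rows, length(offs))
  for (q in seq_along(offs)) {
    bins <- (lo + offs[q]) %% n_pad
    iq <- xy + bins * (nx * ny) + 1L
    iq[!ok] <- 0L
    idx[, q] <- iq
    wt[, q] <- wv * .kb_kernel(f - offs[q])
  }
  phase <- complex(modulus = 1, argument = numeric(n_rows))
  phase[ok] <- exp(-1i * (fb[ok] * fine) * shift)
  # centred source placement: source plane k (1-based) sits at padded plane
  # ((k - 1 - n_src/2) mod n_pad) + 1, deconvolved by the kernel transform
  zc <- (0:(n_src - 1)) - n_src / 2
  list(idx = idx, wt = wt, phase = phase, n_pad = n_pad,
       n_src_flat = nx * ny * n_pad,
       pad_pos = (zc %% n_pad) + 1L,
       deconv = 1 / .kb_deconv(zc, n_pad))
}

# apply the remap gather / its exact transpose to a complex spectrum
.remap_gather <- function(rm, z) .spec_gather_cpp(z, rm$idx, rm$wt)
.remap_scatter <- function(rm, z) .spec_scatter_cpp(z, rm$idx, rm$wt,
                                                    rm$n_src_flat)

#' Planar acoustic operator
#'
#' Precomputes the spectral machinery mapping an initial-pressure volume on an
#' `nx x ny x nz` grid to planar sensor data with `nt` time samples (and
#' back). The volume's lateral pitch must equal the sensor pitch; the depth
#' pitch `dz_um` must satisfy `dz <= c dt` so every propagating temporal
#' frequency maps inside the kz band. Voxel plane k sits at depth
#' `(k - 1) * dz`.
#'
#' @param nx,ny lateral grid size (shared by volume and sensor).
#' @param nz,dz_um depth samples and pitch of the volume grid.
#' @param nt,dt_ns time samples and sampling interval of the sensor data.
#' @param dx_um,dy_um lateral pitch (micrometres).
#' @param c_mps sound speed (m/s).
#' @param taper_lo,taper_hi valid-cone policy: raised-cosine angular taper on
#'   the plane-wave obliquity cos(theta) = c kz / omega, unity above
#'   `taper_hi` and zero below `taper_lo` (suppresses the divergent
#'   grazing-incidence band).
#' @return An object of class `planar_operator` with `$forward`, `$adjoint`
#'   and `$recon` closures operating on plain 3D arrays.
#' @export
planar_operator <- function(nx, ny, nz, nt, dx_um, dy_um = dx_um, dz_um,
                            dt_ns, c_mps = 1500, taper_lo = 0.15,
                            taper_hi = 0.3) {
  key <- paste("op", nx, ny, nz, nt, dx_um, dy_um, dz_um, dt_ns, c_mps,
               taper_lo, taper_hi, sep = "_")
  cached <- .op_cache_get(key)
  if (!is.null(cached)) return(cached)
  dx <- um_to_m(dx_um); dy <- um_to_m(dy_um); dz <- um_to_m(dz_um)
  dt <- ns_to_s(dt_ns); c0 <- c_mps
  if (dz > c0 * dt * (1 + 1e-9))
    stop(sprintf("dz (%g um) must be <= c*dt (%g um): depth grid would alias",
                 dz_um, c0 * dt * 1e6), call. = FALSE)
  if (nt * dt * c0 < nz * dz)
    stop(sprintf("temporal window too short: need nt >= %d to cover %g mm depth",
                 ceiling(nz * dz / (c0 * dt)), nz * dz * 1e3), call. = FALSE)
  fwd <- .spectral_remap(nx, ny, dx, dy, nz, dz, nt, dt, c0, "forward",
                         taper_lo, taper_hi)
  rec <- NULL    # built lazily on first recon
  sf <- dz / (nx * ny * nt * dt)     # forward overall scale
  sr <- dt / (nx * ny * nz * dz)     # recon overall scale
  self <- new.env(parent = emptyenv())
  self$nx <- nx; self$ny <- ny; self$nz <- nz; self$nt <- nt
  self$dx_um <- dx_um; self$dy_um <- dy_um; self$dz_um <- dz_um
  self$dt_ns <- dt_ns; self$c_mps <- c_mps
  self$forward <- function(p0) {
    stopifnot(all(dim(p0) == c(nx, ny, nz)))
    q <- array(0, c(nx, ny, fwd$n_pad))
    q[, , fwd$pad_pos] <- sweep(p0, 3, fwd$deconv, `*`)
    Pq <- fwd$phase * .remap_gather(fwd, as.vector(fft(q)))
    Re(fft(array(Pq, c(nx, ny, nt)), inverse = TRUE)) * sf
  }
  self$adjoint <- function(y) {
    stopifnot(all(dim(y) == c(nx, ny, nt)))
    v <- Conj(fwd$phase) * as.vector(fft(y))
    Q <- .remap_scatter(fwd, v)
    X <- fft(array(Q, c(nx, ny, fwd$n_pad)), inverse = TRUE)
    x <- Re(X[, , fwd$pad_pos, drop = FALSE])
    sweep(x, 3, fwd$deconv, `*`) * sf
  }
  self$recon <- function(y) {
    stopifnot(all(dim(y) == c(nx, ny, nt)))
    if (is.null(rec))
      rec <<- .spectral_remap(nx, ny, dx, dy, nt, dt, nz, dz, c0, "recon",
                              taper_lo, taper_hi)
    q <- array(0, c(nx, ny, rec$n_pad))
    q[, , rec$pad_pos] <- sweep(y, 3, rec$deconv, `*`)
    Q <- rec$phase * .remap_gather(rec, as.vector(fft(q)))
    Re(fft(array(Q, c(nx, ny, nz)), inverse = TRUE)) * sr
  }
  class(self) <- "planar_operator"
  .op_cache_put(key, self)
}

#' @export
print.planar_operator <- function(x, ...) {
  cat(sprintf("<planar_operator> volume %d x %d x %d (dz %g um) <-> data %d x %d x %d (dt %g ns), c = %g m/s\n",
              x$nx, x$ny, x$nz, x$dz_um, x$nx, x$ny, x$nt, x$dt_ns, x$c_mps))
  invisible(x)
}

#' Simulate planar detection of an initial pressure distribution
#'
#' Propagates p0 through a homogeneous half-space (free field, point-like
#' detectors in the z = 0 plane) to planar time-series data using the exact
#' Fourier-domain mapping on the dispersion shell. Linear in p0 and
#' time-causal.
#'
#' @param p0 a [pressure_volume()]; lateral pitch becomes the sensor pitch.
#' @param c_mps sound speed (m/s).
#' @param dt_ns temporal sampling interval (ns).
#' @param nt number of time samples; must give `nt * dt * c` at least the
#'   deepest source depth.
#' @param op optional precomputed [planar_operator()] (reused across calls).
#' @return A [sensor_time_series()].
#' @export
forward_planar <- function(p0, c_mps = 1500, dt_ns = 16.67, nt = NULL,
                           op = NULL) {
  stopifnot(inherits(p0, "pressure_volume"))
  d <- dim(p0$p0)
  if (is.null(nt)) nt <- ceiling(1.6 * d[3] * p0$dz_um / (c_mps * ns_to_s(dt_ns) * 1e6))
  if (is.null(op))
    op <- planar_operator(d[1], d[2], d[3], nt, p0$dx_um, p0$dy_um, p0$dz_um,
                          dt_ns, c_mps)
  p <- op$forward(p0$p0)
  sensor_time_series(p, p0$dx_um, p0$dy_um, dt_ns, c_mps)
}

#' Exact numerical adjoint of the planar forward operator
#'
#' Applies the transpose of [forward_planar()] composed with the channel-mask
#' projection (unmeasured channels zero-filled). The pair passes the
#' dot-product identity to ~1e-12 relative, which is the correctness contract
#' for the iterative reconstruction.
#'
#' @param data a [sensor_time_series()] (mask respected).
#' @param c_mps sound speed (m/s).
#' @param volume_shape integer length-3 output grid.
#' @param dz_um depth pitch of the output grid (default `c * dt`).
#' @param op optional precomputed [planar_operator()].
#' @return A [pressure_volume()].
#' @export
adjoint_planar <- function(data, c_mps = 1500, volume_shape = NULL,
                           dz_um = NULL, op = NULL) {
  stopifnot(inherits(data, "sensor_time_series"))
  d <- dim(data$p)
  if (is.null(dz_um)) dz_um <- c_mps * ns_to_s(data$dt_ns) * 1e6
  if (is.null(volume_shape)) volume_shape <- c(d[1], d[2], d[3])
  if (!all(volume_shape[1:2] == d[1:2]))
    stop("lateral shape mismatch between data and volume", call. = FALSE)
  if (is.null(op))
    op <- planar_operator(d[1], d[2], volume_shape[3], d[3], data$dx_um,
                          data$dy_um, dz_um, data$dt_ns, c_mps)
  y <- data$p
  if (!all(data$mask)) y <- y * array(rep(data$mask, d[3]), d)
  pressure_volume(op$adjoint(y), data$dx_um, data$dy_um, dz_um)
}

#' Apply the sensor frequency response to time-series data
#'
#' Filters every A-line by the FP sensor's acoustic response: the sinc-type
#' magnitude of [frequency_response()] combined with a second-order 50 kHz
#' low-frequency cut, applied zero-phase in the frequency domain.
#'
#' @param data a [sensor_time_series()].
#' @param spec an [fp_sensor_spec()]; requires Nyquist above `spec$f3db_mhz`.
#' @param lowcut_mhz low-frequency cut-on (default 0.05 MHz).
#' @return Filtered [sensor_time_series()].
#' @export
apply_sensor_bandwidth <- function(data, spec, lowcut_mhz = 0.05) {
  stopifnot(inherits(data, "sensor_time_series"),
            inherits(spec, "fp_sensor_spec"))
  d <- dim(data$p)
  f_nyq <- 1e3 / (2 * data$dt_ns)
  if (f_nyq <= spec$f3db_mhz)
    stop(sprintf("Nyquist (%.1f MHz) must exceed the sensor f-3dB (%.1f MHz)",
                 f_nyq, spec$f3db_mhz), call. = FALSE)
  f <- abs(fft_freq(d[3], ns_to_s(data$dt_ns))) * 1e-6   # MHz
  h <- frequency_response(spec, f)
  h <- h / ifelse(f > 0, sqrt(1 + (lowcut_mhz / pmax(f, 1e-12))^4), Inf)
  h[f == 0] <- 0
  pm <- matrix(aperm(data$p, c(3, 1, 2)), d[3], d[1] * d[2])
  pf <- Re(mvfft(mvfft(pm) * h, inverse = TRUE)) / d[3]
  data$p <- aperm(array(pf, c(d[3], d[1], d[2])), c(2, 3, 1))
  data
}
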