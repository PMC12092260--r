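# Shared fixtures, generated in code. Grids are kept small; the acceptance
# suite uses the full study sizes.

the_sensor <- function() {
  fp_sensor_spec(spacer_thickness_um = 26.6, finesse = 76.6, visibility = 0.78,
                 fsr_nm = 26.6, f3db_mhz = 31.5)
}

# dz equal to c*dt: the finest alias-free depth pitch
dz_for <- function(c_mps = 1500, dt_ns = 16.67) c_mps * dt_ns * 1e-3

# a small operator shared across forward-model tests
tiny_op <- function(nx = 16, nz = 48, nt = 64, dx = 108, c_mps = 1500,
                    dt_ns = 16.67) {
  planar_operator(nx, nx, nz, nt, dx, dx, dz_for(c_mps, dt_ns), dt_ns, c_mps)
}

# smooth phantom band-limited inside the valid acceptance cone: random
# smooth blob low-passed and cone-projected in k-space
cone_limited_phantom <- function(nx, ny, nz, dx_um, dz_um, seed = 1,
                                 cos_min = 0.45, k_frac = 0.5) {
  set.seed(seed)
  a <- array(0, c(nx, ny, nz))
  for (b in 1:4) {
    ctr <- c(runif(1, 0.3, 0.7) * nx, runif(1, 0.3, 0.7) * ny,
             runif(1, 0.3, 0.7) * nz)
    sx <- runif(1, 2, 4); sz <- runif(1, 3, 6)
    for (k in 1:nz)
      a[, , k] <- a[, , k] + exp(-(outer((1:nx - ctr[1])^2,
                                         (1:ny - ctr[2])^2, "+")) / (2 * sx^2)) *
        exp(-(k - ctr[3])^2 / (2 * sz^2))
  }
  kx <- 2 * pi * fpscan:::fft_freq(nx, dx_um * 1e-6)
  ky <- 2 * pi * fpscan:::fft_freq(ny, dx_um * 1e-6)
  kz <- 2 * pi * fpscan:::fft_freq(nz, dz_um * 1e-6)
  kzmax <- pi / (dz_um * 1e-6)
  kp <- sqrt(outer(kx^2, ky^2, "+"))
  filt <- array(0, c(nx, ny, nz))
  for (k in 1:nz) {
    kk <- sqrt(kp^2 + kz[k]^2)
    ang <- ifelse(kk == 0, 1,
                  pmin(pmax((abs(kz[k]) / kk - cos_min) / 0.1, 0), 1))
    lp <- pmin(pmax((k_frac - abs(kz[k]) / kzmax) / 0.1, 0), 1)
    filt[, , k] <- ang * lp
  }
  g <- Re(fft(fft(a) * filt, inverse = TRUE)) / (nx * ny * nz)
  pressure_volume(g, dx_um, dx_um, dz_um)
}

# the standard vessel phantom used by the compressed-sensing acceptance runs
standard_vessel_phantom <- function(nx = 96, nz = 192, dx_um = 108,
                                    dz_um = dz_for(), seed = 7) {
  vessel_tree_phantom(c(nx, nx, nz), c(dx_um, dx_um, dz_um),
                      depth_range_mm = c(0.5, 4.5), n_roots = 2,
                      root_radius_um = 150, amplitude_kpa = 10, seed = seed)
}
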