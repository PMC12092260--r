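test_that("point sources arrive at the acoustic time of flight", {
  dz <- dz_for()
  op <- planar_operator(32, 32, 256, 300, 108, 108, dz, 16.67, 1500)
  p0 <- array(0, c(32, 32, 256))
  iz <- round(5000 / dz) + 1              # 5 mm deep, on axis
  p0[16, 16, iz] <- 1
  y <- op$forward(p0)
  expect_lt(abs(which.max(abs(y[16, 16, ])) - 5000 / dz - 1), 2)  # +- dt
  # off-axis detector at ~2.4 mm lateral offset: Euclidean distance
  off <- 12 # columns from source
  dist <- sqrt(5000^2 + (off * 108)^2)
  expect_lt(abs(which.max(abs(y[16 + off, 16, ])) - dist / dz - 1), 2)
  # linearity to machine precision
  p0b <- array(0, c(32, 32, 256)); p0b[20, 12, 100] <- 2
  expect_equal(op$forward(p0 + p0b), op$forward(p0) + op$forward(p0b),
               tolerance = 1e-12)
})

test_that("forward and adjoint satisfy the dot-product identity", {
  op <- tiny_op()
  set.seed(11)
  for (i in 1:5) {
    x <- array(rnorm(16 * 16 * 48), c(16, 16, 48))
    y <- array(rnorm(16 * 16 * 64), c(16, 16, 64))
    lhs <- sum(op$forward(x) * y)
    rhs <- sum(x * op$adjoint(y))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("the adjoint of point-source data peaks at the source voxel", {
  dz <- dz_for()
  op <- planar_operator(24, 24, 96, 128, 108, 108, dz, 16.67, 1500)
  p0 <- array(0, c(24, 24, 96)); p0[12, 12, 60] <- 1
  data <- sensor_time_series(op$forward(p0), 108, 108, 16.67)
  bp <- adjoint_planar(data, 1500, c(24, 24, 96), dz, op = op)
  pk <- which(bp$p0 == max(bp$p0), arr.ind = TRUE)[1, ]
  expect_true(all(abs(pk - c(12, 12, 60)) <= 1))
  # linearity of the adjoint
  expect_equal(op$adjoint(2 * data$p), 2 * op$adjoint(data$p), tolerance = 1e-12)
})

test_that("on-axis waveform of a uniform sphere matches the closed-form N shape", {
  # 0.3 mm radius sphere, 2.2 mm deep; 9.6 mm aperture and a 16 mm time
  # window keep lateral-periodicity ghosts away from the comparison window
  dt <- 16.67; c0 <- 1500; dz <- dz_for()
  nx <- 120; nz <- 128; nt <- 640; dx <- 80
  a <- 300; w <- 80                       # half-pitch anti-aliased shell
  ctr <- c(59 * dx, 59 * dx, 2200)
  sph <- array(0, c(nx, nx, nz))
  for (k in 1:nz) {
    zz <- (k - 1) * dz - ctr[3]
    if (abs(zz) < a + 2 * w) {
      d2 <- outer(((0:(nx - 1)) * dx - ctr[1])^2,
                  ((0:(nx - 1)) * dx - ctr[2])^2, "+")
      sph[, , k] <- pmin(1, pmax(0, (a + w / 2 - sqrt(d2 + zz^2)) / w))
    }
  }
  op <- planar_operator(nx, nx, nz, nt, dx, dx, dz, dt, c0)
  s <- op$forward(sph)[60, 60, ]
  tt <- (0:(nt - 1)) * dt * 1e-9
  z0 <- 2.2e-3
  prof <- function(r) pmin(1, pmax(0, (a * 1e-6 + w * 1e-6 / 2 - r) / (w * 1e-6)))
  pe <- (z0 - c0 * tt) / (2 * z0) * prof(abs(z0 - c0 * tt))
  # band-limit both to the detection band before comparing
  lp <- exp(-((fpscan:::fft_freq(nt, dt * 1e-9)) * 1e-6 / 6)^2)
  bl <- function(x) Re(fft(fft(x) * lp, inverse = TRUE)) / nt
  win <- 70:106                           # the N arrival
  rel <- sqrt(sum((bl(s)[win] - bl(pe)[win])^2) / sum(bl(pe)[win]^2))
  expect_lt(rel, 0.05)
})

test_that("sensor bandwidth filtering is -3 dB at f3db, zero-phase and multiplicative", {
  spec <- fp_sensor_spec(f3db_mhz = 20)
  nt <- 512
  imp <- array(0, c(2, 2, nt)); imp[, , nt / 2] <- 1
  data <- sensor_time_series(imp, 108, 108, 16.67)
  filt <- apply_sensor_bandwidth(data, spec)
  sp_in <- Mod(fft(imp[1, 1, ]))
  sp_out <- Mod(fft(filt$p[1, 1, ]))
  f <- abs(fpscan:::fft_freq(nt, 16.67e-9)) * 1e-6
  i3 <- which.min(abs(f - 20))
  expect_equal(sp_out[i3] / sp_in[i3], 1 / sqrt(2), tolerance = 0.02)
  # all-zero input stays zero; double application squares the response
  zed <- sensor_time_series(array(0, c(2, 2, nt)), 108, 108, 16.67)
  expect_true(all(apply_sensor_bandwidth(zed, spec)$p == 0))
  twice <- apply_sensor_bandwidth(filt, spec)
  i_half <- which.min(abs(f - 10))
  r1 <- Mod(fft(filt$p[1, 1, ]))[i_half] / sp_in[i_half]
  r2 <- Mod(fft(twice$p[1, 1, ]))[i_half] / sp_in[i_half]
  expect_equal(r2, r1^2, tolerance = 1e-6)
  # Nyquist guard
  expect_error(apply_sensor_bandwidth(data, fp_sensor_spec(f3db_mhz = 40)),
               "Nyquist")
})

test_that("temporal windows too short for the volume are refused with the needed nt", {
  expect_error(planar_operator(8, 8, 128, 32, 108, 108, dz_for(), 16.67, 1500),
               "temporal window too short")
  expect_error(planar_operator(8, 8, 32, 64, 108, 108, 60, 16.67, 1500),
               "alias")
})
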