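test_that("vessel trees rasterize with near-analytic occupied volume and are seeded", {
  ph <- vessel_tree_phantom(c(48, 48, 64), 50, depth_range_mm = c(0.5, 3),
                            n_roots = 1, root_radius_um = 120,
                            branch_prob = 0, seed = 5)
  expect_true(all(ph$volume$p0 >= 0))
  expect_identical(ph$volume$p0,
                   vessel_tree_phantom(c(48, 48, 64), 50,
                                       depth_range_mm = c(0.5, 3),
                                       n_roots = 1, root_radius_um = 120,
                                       branch_prob = 0, seed = 5)$volume$p0)
  # occupied volume vs analytic sum pi r^2 L (single unbranched tube)
  lens <- fpscan:::tree_segment_lengths(ph$tree)
  analytic_um3 <- sum(pi * ph$tree$radii_um^2 * lens)
  occupied_um3 <- sum(ph$volume$p0 / ph$tree$amplitudes_kpa[1]) * 50^3
  expect_lt(abs(occupied_um3 - analytic_um3) / analytic_um3, 0.10)
})

test_that("a straight horizontal tube has ground-truth tortuosity 1", {
  seg <- cbind(seq(200, 2000, length.out = 10), rep(1200, 10), rep(1000, 10))
  expect_equal(tortuosity_index(seg), 1)
})

test_that("layered skin phantom builds the epidermis slab over the tree", {
  ph <- layered_skin_phantom(c(32, 32, 40), 50, epidermis_thickness_um = 200,
                             epidermis_amplitude_kpa = 5,
                             tree_params = list(depth_range_mm = c(0.6, 1.8),
                                                n_roots = 1,
                                                root_radius_um = 100),
                             seed = 2)
  expect_equal(ph$epidermis_planes, 1:4)      # 200 um at 50 um voxel
  expect_true(all(ph$volume$p0[, , 1:4] >= 5))
  # zero-amplitude slab leaves a pure vessel phantom
  ph0 <- layered_skin_phantom(c(32, 32, 40), 50, epidermis_thickness_um = 200,
                              epidermis_amplitude_kpa = 0,
                              tree_params = list(depth_range_mm = c(0.6, 1.8),
                                                 n_roots = 1,
                                                 root_radius_um = 100),
                              seed = 2)
  tree_only <- vessel_tree_phantom(c(32, 32, 40), 50,
                                   depth_range_mm = c(0.6, 1.8), n_roots = 1,
                                   root_radius_um = 100, seed = 2)
  expect_identical(ph0$volume$p0, tree_only$volume$p0)
})

test_that("point and line targets are exact and linear", {
  v1 <- point_line_targets(c(24, 24, 40), 50, points = c(600, 600, 1000))
  expect_equal(sum(v1$p0 != 0), 1)
  expect_equal(unname(which(v1$p0 != 0, arr.ind = TRUE)[1, 3]), 21)  # z = 1000/50 + 1
  v2 <- point_line_targets(c(24, 24, 40), 50, points = c(300, 900, 500))
  v12 <- point_line_targets(c(24, 24, 40), 50,
                            points = rbind(c(600, 600, 1000), c(300, 900, 500)))
  expect_equal(v12$p0, v1$p0 + v2$p0)
  expect_error(point_line_targets(c(24, 24, 40), 50, points = c(600, 600, 9000)),
               "outside")
  # grid of line targets at several depths rasterizes without error
  lines <- lapply(c(1, 4, 8, 12) * 100, function(z)
    list(from = c(100, 600, z), to = c(1100, 600, z), radius_um = 40))
  vl <- point_line_targets(c(24, 24, 280), 50, lines = lines)
  expect_gt(sum(vl$p0 > 0), 4 * 10)
})

test_that("occlusion-reperfusion sequences ramp vessels and hold the epidermis constant", {
  base <- pressure_volume(array(1, c(16, 16, 20)), 100)
  rois <- list(epidermis = array(FALSE, c(16, 16, 20)),
               DA = array(FALSE, c(16, 16, 20)),
               V1 = array(FALSE, c(16, 16, 20)))
  rois$epidermis[, , 1:2] <- TRUE
  rois$DA[, , 8:10] <- TRUE
  rois$V1[, , 14:16] <- TRUE
  seq_ <- occlusion_reperfusion_sequence(base, rois, t_occlusion_end_s = 5,
                                         onsets_s = c(DA = 5.2, V1 = 6.0),
                                         ramp_s = 2.5, fps = 5, duration_s = 12)
  tc <- roi_timecourse(seq_$frames, rois, seq_$times_s)
  epi <- tc$mean_intensity[tc$roi == "epidermis"]
  expect_lt(stats::sd(epi) / mean(epi), 1e-12)   # constant by construction
  da <- tc$mean_intensity[tc$roi == "DA"]
  v1 <- tc$mean_intensity[tc$roi == "V1"]
  # occluded level before release, >= 95% of baseline within the ramp
  expect_lt(max(da[seq_$times_s < 5.2]), 0.25)
  expect_gte(min(da[seq_$times_s >= 5.2 + 2.5]), 0.95)
  # threshold-crossing order matches ground-truth onsets
  cross <- function(x) seq_$times_s[which(x >= 0.5)[1]]
  expect_lt(cross(da), cross(v1))
  expect_error(occlusion_reperfusion_sequence(base, rois, 5,
                                              onsets_s = c(DA = 4, V1 = 6)),
               "onset")
})

test_that("sensor noise matches the per-channel NEP in the measurement band", {
  set.seed(1)
  nt <- 10000
  dat <- sensor_time_series(array(0, c(4, 3, nt)), 108, 108, 16.67)
  nep <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.1, 1.2),
                4, 3)
  noisy <- add_sensor_noise(dat, nep, bandwidth_mhz = 20, seed = 9)
  # RMS within the 20 MHz band: band-limit each A-line and compare
  f <- abs(fpscan:::fft_freq(nt, 16.67e-9)) * 1e-6
  keep <- f <= 20
  for (i in 1:4) for (j in 1:3) {
    sp <- fft(noisy$p[i, j, ])
    rms <- sqrt(sum(Mod(sp[keep])^2) / nt^2)
    expect_lt(abs(rms - nep[i, j]) / nep[i, j], 0.05)
  }
  # zero NEP leaves data unchanged; determinism under seed
  expect_identical(add_sensor_noise(dat, 0, seed = 1)$p, dat$p)
  expect_identical(add_sensor_noise(dat, nep, seed = 9)$p, noisy$p)
})
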