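test_that("CNR follows the plane-mean/background definition", {
  # synthetic slab whose plane-mean excess is 10x the noise RMS: 20 dB
  set.seed(3)
  a <- array(0, c(20, 20, 30))
  noise_roi <- array(FALSE, c(20, 20, 30)); noise_roi[, , 25:30] <- TRUE
  nvals <- rnorm(sum(noise_roi), sd = 0.1)
  nrms <- sqrt(mean(nvals^2))
  a[noise_roi] <- nvals
  a[, , 10] <- a[, , 10] + 10 * nrms          # one bright plane
  vol <- pressure_volume(a, 100)
  # background = mean of plane means; adjust expectation accordingly
  plane_means <- apply(a, 3, mean)
  expected <- 20 * log10(max(plane_means - mean(plane_means)) / nrms)
  got <- cnr(vol, noise_roi)
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)
  expect_equal(as.numeric(got), 20, tolerance = 0.5)
  # adding a constant to the whole volume leaves the contrast unchanged
  vol2 <- vol; vol2$p0 <- vol$p0 + 5
  expect_equal(attr(cnr(vol2, noise_roi), "contrast"),
               attr(got, "contrast"), tolerance = 1e-10)
  # signal-only scaling adds 6.02 dB
  vol3 <- vol; vol3$p0 <- 2 * vol$p0; vol3$p0[noise_roi] <- vol$p0[noise_roi]
  expect_equal(as.numeric(cnr(vol3, noise_roi)) - as.numeric(got), 6.02,
               tolerance = 0.1)
  expect_error(cnr(pressure_volume(array(0, c(4, 4, 4)), 100),
                   array(TRUE, c(4, 4, 4))), "degenerate")
})

test_that("a straight tube skeletonizes to about its centreline length", {
  n <- 32
  a <- array(0, c(n, n, n))
  # tube along x spanning the volume, radius 3 voxels
  for (k in 1:n) for (j in 1:n) {
    d2 <- (j - 16)^2 + (k - 16)^2
    if (d2 <= 9) a[, j, k] <- 1
  }
  vol <- pressure_volume(a, 50)
  vs <- vessel_density_vs(vol)
  skel <- attr(vs, "skeleton")
  expect_lt(abs(sum(skel) - n) / n, 0.2)            # ~ L voxels
  expect_equal(as.numeric(vs), 100 * sum(skel) / n^3)
  # two disjoint identical vessels double V_s within 10%
  b <- a
  for (k in 1:n) for (j in 1:n) {
    d2 <- (j - 6)^2 + (k - 6)^2
    if (d2 <= 9) b[, j, k] <- 1
  }
  vs2 <- vessel_density_vs(pressure_volume(b, 50))
  expect_lt(abs(as.numeric(vs2) - 2 * as.numeric(vs)) / (2 * as.numeric(vs)),
            0.10)
  # intensity scaling invariance (clustering is scale-equivariant)
  vs_scaled <- vessel_density_vs(pressure_volume(5 * a, 50))
  expect_equal(as.numeric(vs_scaled), as.numeric(vs))
  expect_warning(vessel_density_vs(pressure_volume(array(1, c(8, 8, 8)), 50)),
                 "constant")
})

test_that("V_I counts exactly the planted suprathreshold voxels and is monotone", {
  set.seed(5)
  a <- array(abs(rnorm(16^3, sd = 0.01)), c(16, 16, 16))
  roi <- array(FALSE, c(16, 16, 16)); roi[4:12, 4:12, 4:12] <- TRUE
  planted <- rbind(c(5, 5, 5), c(8, 9, 10), c(11, 6, 7))
  for (i in 1:3) a[planted[i, 1], planted[i, 2], planted[i, 3]] <- 10
  vol <- pressure_volume(a, 100)
  vi <- vascular_signal_vi(vol, roi, threshold = 1)
  expect_equal(as.numeric(vi), 3)
  # all-background ROI
  roi_bg <- array(FALSE, c(16, 16, 16)); roi_bg[14:16, 14:16, 14:16] <- TRUE
  expect_equal(as.numeric(vascular_signal_vi(vol, roi_bg, threshold = 1)), 0)
  # enlarging the ROI never decreases V_I
  bigger <- array(TRUE, c(16, 16, 16))
  expect_gte(as.numeric(vascular_signal_vi(vol, bigger, threshold = 1)),
             as.numeric(vi))
  expect_error(vascular_signal_vi(vol, array(FALSE, c(16, 16, 16))), "empty")
})

test_that("tortuosity matches closed forms and is rigid-motion invariant", {
  # straight line
  expect_equal(tortuosity_index(cbind(0:10, 0, 0)), 1)
  # semicircle: pi/2
  th <- seq(0, pi, length.out = 2000)
  expect_equal(tortuosity_index(cbind(cos(th), sin(th))), pi / 2,
               tolerance = 0.005 * pi / 2)
  # densely sampled sine arc vs quadrature oracle
  xs <- seq(0, 2 * pi, length.out = 4000)
  amp <- 0.8
  poly <- cbind(xs, amp * sin(xs))
  arc_num <- stats::integrate(function(x) sqrt(1 + (amp * cos(x))^2), 0,
                              2 * pi, rel.tol = 1e-10)$value
  expect_equal(tortuosity_index(poly), arc_num / (2 * pi), tolerance = 0.005)
  # rigid rotations/translations leave it unchanged
  set.seed(6)
  p3 <- cbind(xs, amp * sin(xs), 0.3 * xs)
  base <- tortuosity_index(p3)
  for (i in 1:10) {
    th1 <- runif(3, 0, 2 * pi)
    rz <- matrix(c(cos(th1[1]), -sin(th1[1]), 0, sin(th1[1]), cos(th1[1]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cos(th1[2]), -sin(th1[2]),
                   0, sin(th1[2]), cos(th1[2])), 3, byrow = TRUE)
    moved <- p3 %*% (rz %*% rx) + matrix(runif(3, -5, 5), nrow(p3), 3,
                                         byrow = TRUE)
    expect_equal(tortuosity_index(moved), base, tolerance = 1e-10)
  }
  expect_error(tortuosity_index(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "coincident")
})

test_that("ROI time courses are linear means with one row per frame and ROI", {
  frames <- lapply(1:5, function(i) pressure_volume(array(i, c(6, 6, 6)), 100))
  rois <- list(a = array(TRUE, c(6, 6, 6)),
               b = {m <- array(FALSE, c(6, 6, 6)); m[1:3, , ] <- TRUE; m})
  tc <- roi_timecourse(frames, rois)
  expect_equal(nrow(tc), 10)
  expect_equal(tc$mean_intensity[tc$roi == "a"], 1:5)
  expect_equal(tc$mean_intensity[tc$roi == "b"], 1:5)
  expect_error(roi_timecourse(frames, list(z = array(FALSE, c(6, 6, 6)))),
               "empty")
})
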