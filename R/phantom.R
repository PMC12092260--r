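#' Initial-pressure volume
#'
#' A 3D scalar grid of initial pressure p0 (kPa). Axis convention: dimension 1
#' is x, 2 is y, 3 is z (depth, increasing away from the sensor plane z = 0).
#'
#' @param p0 3D numeric array (kPa).
#' @param dx_um,dy_um,dz_um voxel pitch (micrometres).
#' @param origin_um length-3 offset of voxel (1,1,1) centre; default c(0,0,0),
#'   matching the acoustic operator convention that plane k sits at (k-1)*dz.
#' @return An object of class `pressure_volume`.
#' @export
pressure_volume <- function(p0, dx_um, dy_um = dx_um, dz_um = dx_um,
                            origin_um = NULL) {
  stopifnot(length(dim(p0)) == 3L)
  stopifnot_scalar(dx_um, "dx_um", positive = TRUE)
  stopifnot_scalar(dy_um, "dy_um", positive = TRUE)
  stopifnot_scalar(dz_um, "dz_um", positive = TRUE)
  if (is.null(origin_um)) origin_um <- c(0, 0, 0)
  structure(list(p0 = p0, dx_um = dx_um, dy_um = dy_um, dz_um = dz_um,
                 origin_um = origin_um),
            class = "pressure_volume")
}

#' @export
print.pressure_volume <- function(x, ...) {
  d <- dim(x$p0)
  cat(sprintf("<pressure_volume> %d x %d x %d voxels @ (%g, %g, %g) um; range [%.3g, %.3g] kPa\n",
              d[1], d[2], d[3], x$dx_um, x$dy_um, x$dz_um,
              min(x$p0), max(x$p0)))
  invisible(x)
}

# voxel-centre coordinates (um) along each axis
.vol_axis <- function(vol, axis) {
  d <- dim(vol$p0)[axis]
  pitch <- c(vol$dx_um, vol$dy_um, vol$dz_um)[axis]
  vol$origin_um[axis] + (seq_len(d) - 1) * pitch
}

# Stamp one tube segment (straight line between a and b, radius r, amplitude
# amp) into a volume array with a half-voxel anti-aliased edge; contributions
# combine by per-voxel maximum so overlapping segments do not double-count.
.stamp_segment <- function(arr, vol, a, b, r, amp) {
  v <- min(vol$dx_um, vol$dy_um, vol$dz_um)
  step <- v / 2
  len <- sqrt(sum((b - a)^2))
  nsamp <- max(2L, ceiling(len / step) + 1L)
  ts <- seq(0, 1, length.out = nsamp)
  xs <- .vol_axis(vol, 1); ys <- .vol_axis(vol, 2); zs <- .vol_axis(vol, 3)
  d <- dim(arr)
  pad <- r + v
  for (k in seq_len(nsamp)) {
    p <- a + ts[k] * (b - a)
    i0 <- findInterval(p[1] - pad, xs); i1 <- findInterval(p[1] + pad, xs) + 1L
    j0 <- findInterval(p[2] - pad, ys); j1 <- findInterval(p[2] + pad, ys) + 1L
    k0 <- findInterval(p[3] - pad, zs); k1 <- findInterval(p[3] + pad, zs) + 1L
    i0 <- max(i0, 1L); i1 <- min(i1, d[1])
    j0 <- max(j0, 1L); j1 <- min(j1, d[2])
    k0 <- max(k0, 1L); k1 <- min(k1, d[3])
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    dxv <- xs[i0:i1] - p[1]; dyv <- ys[j0:j1] - p[2]; dzv <- zs[k0:k1] - p[3]
    dist <- sqrt(outer(outer(dxv^2, dyv^2, `+`), dzv^2, `+`))
    val <- amp * pmin(1, pmax(0, (r + v / 2 - dist) / v))
    sub <- arr[i0:i1, j0:j1, k0:k1]
    arr[i0:i1, j0:j1, k0:k1] <- pmax(sub, val)
  }
  arr
}

# rasterize a vessel tree into an existing pressure_volume (returns the array)
.rasterize_tree <- function(vol, tree) {
  arr <- vol$p0
  for (s in seq_along(tree$segments)) {
    poly <- tree$segments[[s]]
    r <- tree$radii_um[s]; amp <- tree$amplitudes_kpa[s]
    for (i in seq_len(nrow(poly) - 1L))
      arr <- .stamp_segment(arr, vol, poly[i, ], poly[i + 1L, ], r, amp)
  }
  arr
}

# analytic morphometrics of a vessel tree
tree_segment_lengths <- function(tree) {
  vapply(tree$segments, function(poly)
    sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                      poly[-nrow(poly), , drop = FALSE])^2))), 0)
}

#' Branching vessel-tree phantom
#'
#' Generates a random branching vessel tree (recursive binary branching with
#' smooth random curvature and per-generation radius decay) inside the stated
#' depth range, and rasterizes it as anti-aliased tubes of initial pressure.
#' Returns both the voxel grid and the ground-truth centrelines/radii so that
#' morphometric estimates can be checked against exact values.
#'
#' @param volume_shape integer length-3 grid size (nx, ny, nz).
#' @param voxel_um isotropic-lateral voxel pitch, either scalar or length 3.
#' @param depth_range_mm vessels confined to this depth band (default c(0.5, 15),
#'   clipped to the volume).
#' @param n_roots number of root vessels (default 2).
#' @param root_radius_um starting vessel radius (default 150).
#' @param amplitude_kpa initial pressure inside vessels (default 10 kPa, a
#'   typical blood absorption signal at moderate fluence).
#' @param branch_prob probability a segment ends in a bifurcation (default 0.7).
#' @param radius_decay child/parent radius ratio (default 0.8).
#' @param curl angular jitter per step, radians (default 0.25).
#' @param max_depth_gen maximum branching generations (default 4).
#' @param seed integer seed.
#' @return List with elements `volume` (a [pressure_volume()]) and `tree`
#'   (segments, radii, amplitudes).
#' @export
vessel_tree_phantom <- function(volume_shape, voxel_um,
                                depth_range_mm = c(0.5, 15),
                                n_roots = 2L, root_radius_um = 150,
                                amplitude_kpa = 10,
                                branch_prob = 0.7, radius_decay = 0.8,
                                curl = 0.25, max_depth_gen = 4L, seed = 1L) {
  voxel_um <- rep(voxel_um, length.out = 3)
  vol <- pressure_volume(array(0, volume_shape), voxel_um[1], voxel_um[2],
                         voxel_um[3])
  ext <- volume_shape * voxel_um
  zmin <- max(depth_range_mm[1] * 1e3, 2 * root_radius_um)
  zmax <- min(depth_range_mm[2] * 1e3, ext[3] - 2 * root_radius_um)
  if (zmin >= zmax)
    stop("volume too small for the requested depth range and radii", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  segments <- list(); radii <- numeric(); gen_of <- integer()
  # grow one segment: random-walk direction, mostly lateral, gentle in z
  grow <- function(start, dir, radius, gen) {
    n_steps <- sample(6:12, 1)
    step_len <- stats::runif(1, 4, 8) * radius
    pts <- matrix(0, n_steps + 1L, 3); pts[1, ] <- start
    d <- dir / sqrt(sum(dir^2))
    for (i in seq_len(n_steps)) {
      ang <- stats::rnorm(2, 0, curl)
      # perturb direction, damping the z component to keep vessels in-band
      d <- d + c(ang[1], ang[2], stats::rnorm(1, 0, curl / 2))
      d[3] <- d[3] * 0.8
      d <- d / sqrt(sum(d^2))
      nxt <- pts[i, ] + step_len * d
      nxt[3] <- min(max(nxt[3], zmin), zmax)
      nxt[1] <- min(max(nxt[1], radius), ext[1] - radius)
      nxt[2] <- min(max(nxt[2], radius), ext[2] - radius)
      pts[i + 1L, ] <- nxt
    }
    segments[[length(segments) + 1L]] <<- pts
    radii[length(radii) + 1L] <<- radius
    gen_of[length(gen_of) + 1L] <<- gen
    if (gen < max_depth_gen && radius * radius_decay >= 1.5 * min(voxel_um) &&
        stats::runif(1) < branch_prob) {
      tip <- pts[n_steps + 1L, ]
      for (child in 1:2) {
        spread <- stats::runif(1, 0.3, 0.8) * ifelse(child == 1, 1, -1)
        cd <- d + c(spread * cos(stats::runif(1, 0, 2 * pi)),
                    spread * sin(stats::runif(1, 0, 2 * pi)),
                    stats::rnorm(1, 0, 0.1))
        grow(tip, cd, radius * radius_decay, gen + 1L)
      }
    }
  }
  for (r in seq_len(n_roots)) {
    start <- c(stats::runif(1, 0.15, 0.85) * ext[1],
               stats::runif(1, 0.15, 0.85) * ext[2],
               stats::runif(1, zmin, (zmin + zmax) / 2))
    theta <- stats::runif(1, 0, 2 * pi)
    grow(start, c(cos(theta), sin(theta), 0.1), root_radius_um, 1L)
  }
  tree <- list(segments = segments, radii_um = radii,
               amplitudes_kpa = rep(amplitude_kpa, length(radii)),
               generation = gen_of)
  vol$p0 <- .rasterize_tree(vol, tree)
  list(volume = vol, tree = tree)
}

#' Layered skin phantom
#'
#' A superficial absorbing slab (emulating the predominantly avascular,
#' melanin-pigmented epidermis) over an embedded branching vessel tree.
#'
#' @inheritParams vessel_tree_phantom
#' @param epidermis_thickness_um slab thickness (rounded to whole voxel planes).
#' @param epidermis_amplitude_kpa slab initial pressure (kPa).
#' @param tree_params list of overrides passed to [vessel_tree_phantom()].
#' @return List with `volume`, `tree`, and `epidermis_planes` (z indices).
#' @export
layered_skin_phantom <- function(volume_shape, voxel_um,
                                 epidermis_thickness_um = 200,
                                 epidermis_amplitude_kpa = 5,
                                 tree_params = list(), seed = 1L) {
  voxel_um <- rep(voxel_um, length.out = 3)
  if (epidermis_thickness_um < voxel_um[3])
    stop("epidermis thinner than one voxel plane", call. = FALSE)
  args <- utils::modifyList(
    list(volume_shape = volume_shape, voxel_um = voxel_um, seed = seed),
    tree_params)
  ph <- do.call(vessel_tree_phantom, args)
  n_planes <- round(epidermis_thickness_um / voxel_um[3])
  if (n_planes >= 1 && epidermis_amplitude_kpa != 0) {
    planes <- seq_len(n_planes)
    ph$volume$p0[, , planes] <- pmax(ph$volume$p0[, , planes],
                                     epidermis_amplitude_kpa)
  }
  ph$epidermis_planes <- seq_len(max(n_planes, 0L))
  ph
}

#' Point and line targets
#'
#' Delta-like (single-voxel) and thin-line targets for resolution and PSF
#' probing, emulating a grid of line absorbers at multiple depths.
#'
#' @param volume_shape integer length-3 grid size.
#' @param voxel_um voxel pitch (scalar or length 3).
#' @param points optional matrix (n x 3) of target positions (micrometres).
#' @param lines optional list of `list(from =, to =, radius_um =)` line specs
#'   (micrometres); radius 0 gives a one-voxel-wide line.
#' @param amplitude_kpa target amplitude (default 1).
#' @return A [pressure_volume()].
#' @export
point_line_targets <- function(volume_shape, voxel_um, points = NULL,
                               lines = NULL, amplitude_kpa = 1) {
  voxel_um <- rep(voxel_um, length.out = 3)
  vol <- pressure_volume(array(0, volume_shape), voxel_um[1], voxel_um[2],
                         voxel_um[3])
  if (!is.null(points)) {
    points <- matrix(points, ncol = 3)
    for (i in seq_len(nrow(points))) {
      idx <- integer(3)
      for (a in 1:3) {
        ax <- .vol_axis(vol, a)
        idx[a] <- which.min(abs(ax - points[i, a]))
        if (points[i, a] < ax[1] - voxel_um[a] / 2 ||
            points[i, a] > ax[length(ax)] + voxel_um[a] / 2)
          stop("target outside the volume", call. = FALSE)
      }
      vol$p0[idx[1], idx[2], idx[3]] <- vol$p0[idx[1], idx[2], idx[3]] +
        amplitude_kpa
    }
  }
  if (!is.null(lines)) {
    for (ln in lines) {
      ext <- volume_shape * voxel_um
      if (any(ln$from < 0 | ln$from > ext) || any(ln$to < 0 | ln$to > ext))
        stop("target outside the volume", call. = FALSE)
      r <- if (is.null(ln$radius_um) || ln$radius_um <= 0)
        min(voxel_um) / 2 else ln$radius_um
      vol$p0 <- .stamp_segment(vol$p0, vol, ln$from, ln$to, r, amplitude_kpa)
    }
  }
  vol
}

#' Occlusion-reperfusion 4D sequence
#'
#' Scales vascular regions of a base phantom low during an arterial occlusion
#' and ramps each region back to baseline after its own reperfusion onset
#' (artery first, downstream vessels later), while an epidermis region stays
#' constant throughout — the canonical cuff-occlusion haemodynamic response.
#'
#' @param base a [pressure_volume()] baseline scene.
#' @param rois named list of logical arrays (same shape as `base$p0`); the
#'   element named `"epidermis"`, if present, is left untouched.
#' @param t_occlusion_end_s cuff release time (s).
#' @param onsets_s named numeric vector of reperfusion onset times per
#'   vascular ROI (each >= `t_occlusion_end_s`).
#' @param ramp_s rise time from occluded level to baseline (default 2.5 s,
#'   the normal-reperfusion time scale of 2-3 s).
#' @param fps frames per second of the sequence.
#' @param duration_s total sequence duration (s).
#' @param occluded_level fraction of baseline during occlusion (default 0.2).
#' @return List with `frames` (list of [pressure_volume()]), `times_s`, and
#'   the ground-truth `onsets_s`.
#' @export
occlusion_reperfusion_sequence <- function(base, rois, t_occlusion_end_s = 5,
                                           onsets_s, ramp_s = 2.5, fps = 16.7,
                                           duration_s = 12,
                                           occluded_level = 0.2) {
  stopifnot(inherits(base, "pressure_volume"))
  if (ramp_s <= 0) stop("ramp_s must be > 0", call. = FALSE)
  vasc <- setdiff(names(rois), "epidermis")
  if (!all(vasc %in% names(onsets_s)))
    stop("onsets_s must name every vascular ROI", call. = FALSE)
  if (any(onsets_s[vasc] < t_occlusion_end_s))
    stop("reperfusion onset before occlusion end", call. = FALSE)
  times <- seq(0, duration_s, by = 1 / fps)
  level <- function(t, onset) {
    if (t < onset) return(occluded_level)
    min(1, occluded_level + (1 - occluded_level) * (t - onset) / ramp_s)
  }
  frames <- lapply(times, function(t) {
    fr <- base
    for (v in vasc) {
      s <- level(t, onsets_s[[v]])
      fr$p0[rois[[v]]] <- base$p0[rois[[v]]] * s
    }
    fr
  })
  list(frames = frames, times_s = times, onsets_s = onsets_s[vasc],
       t_occlusion_end_s = t_occlusion_end_s, ramp_s = ramp_s)
}

#' Add per-channel sensor noise to a time series
#'
#' Adds zero-mean white Gaussian noise per A-line, scaled so that the noise
#' RMS measured over the stated bandwidth equals that channel's NEP. White
#' noise of standard deviation sigma has RMS `sigma * sqrt(B / f_nyq)` in a
#' band of width B, so `sigma = NEP * sqrt(f_nyq / B)`.
#'
#' @param data a [sensor_time_series()].
#' @param nep_map matrix of per-channel NEP (kPa) matching the scan grid, or
#'   a scalar applied to all channels.
#' @param bandwidth_mhz measurement bandwidth over which NEP is defined
#'   (default 20 MHz, capped at Nyquist).
#' @param seed integer seed.
#' @return The time series with noise added.
#' @export
add_sensor_noise <- function(data, nep_map, bandwidth_mhz = 20, seed = 1L) {
  stopifnot(inherits(data, "sensor_time_series"))
  d <- dim(data$p)
  if (length(nep_map) == 1L) nep_map <- matrix(nep_map, d[1], d[2])
  if (!all(dim(nep_map) == d[1:2]))
    stop("nep_map shape does not match the scan grid", call. = FALSE)
  f_nyq <- 1e3 / (2 * data$dt_ns)          # MHz
  b <- min(bandwidth_mhz, f_nyq)
  sigma <- nep_map * sqrt(f_nyq / b)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- array(stats::rnorm(prod(d)), d) * as.vector(sigma)
  data$p <- data$p + noise
  data
}
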