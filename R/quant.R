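#' Contrast-to-noise ratio (dB)
#'
#' Contrast: the mean pixel intensity of each x-y plane is computed, the
#' volume-wide mean of those plane means is taken as the background scalar,
#' and the contrast is the peak over depth of (plane mean - background).
#' Noise: the RMS intensity within a caller-supplied ROI devoid of image
#' features. CNR = 20 log10(contrast / noise) (amplitude convention).
#'
#' @param vol a [pressure_volume()].
#' @param noise_roi logical array (same shape) or index vector selecting the
#'   feature-free noise region.
#' @param signal_roi optional logical array restricting the contrast
#'   computation to a sub-volume (plane means over that region only).
#' @return CNR in dB, with attributes `contrast` and `noise_rms`.
#' @export
cnr <- function(vol, noise_roi, signal_roi = NULL) {
  stopifnot(inherits(vol, "pressure_volume"))
  a <- vol$p0
  noise <- sqrt(mean(a[noise_roi]^2))
  if (noise == 0) stop("degenerate noise ROI (zero RMS)", call. = FALSE)
  if (!is.null(signal_roi)) {
    masked <- a
    masked[!signal_roi] <- NA
    plane_means <- apply(masked, 3, mean, na.rm = TRUE)
    plane_means[is.nan(plane_means)] <- NA
  } else {
    plane_means <- apply(a, 3, mean)
  }
  background <- mean(plane_means, na.rm = TRUE)
  contrast <- max(plane_means - background, na.rm = TRUE)
  if (contrast <= 0) stop("no plane exceeds the background", call. = FALSE)
  structure(20 * log10(contrast / noise), contrast = contrast,
            noise_rms = noise)
}

#' 3D skeletonization
#'
#' Topological curve thinning of a binary volume: simple points are removed
#' layer by layer (6 directional sub-iterations) while endpoints and
#' topology are preserved, leaving 1-voxel-wide centrelines.
#'
#' @param mask logical 3D array.
#' @return Logical 3D array of skeleton voxels.
#' @export
skeletonize3d <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  array(.skeleton3d_cpp(as.logical(mask), as.integer(dim(mask))), dim(mask))
}

#' Vessel density V_s
#'
#' Percentage of the image volume occupied by resolvable vessels: voxels are
#' clustered on intensity by k-means (fixed quantile-based initial centres,
#' so the result is deterministic and scale-equivariant), the highest-mean
#' cluster is taken as vasculature, a 3D skeleton is formed, and
#' `V_s = 100 * skeleton voxels / total voxels`.
#'
#' @param vol a [pressure_volume()].
#' @param k_clusters number of intensity clusters (default 2).
#' @return `V_s` in percent, with attributes `skeleton` (logical array),
#'   `segmentation` (logical array) and `threshold` implied by clustering.
#' @export
vessel_density_vs <- function(vol, k_clusters = 2) {
  stopifnot(inherits(vol, "pressure_volume"))
  if (k_clusters < 2) stop("k_clusters must be >= 2", call. = FALSE)
  a <- as.numeric(vol$p0)
  if (max(a) == min(a)) {
    warning("constant volume: no clusters, V_s = 0")
    return(structure(0, skeleton = array(FALSE, dim(vol$p0))))
  }
  centres <- stats::quantile(a, probs = seq(0, 1, length.out = k_clusters + 2)[
    2:(k_clusters + 1)])
  if (any(duplicated(centres)))
    centres <- seq(min(a), max(a), length.out = k_clusters + 2)[2:(k_clusters + 1)]
  km <- stats::kmeans(a, centers = matrix(centres, ncol = 1), iter.max = 50)
  fg_cluster <- which.max(km$centers)
  seg <- array(km$cluster == fg_cluster, dim(vol$p0))
  skel <- skeletonize3d(seg)
  structure(100 * sum(skel) / length(skel), skeleton = skel,
            segmentation = seg)
}

#' Suprathreshold voxel count V_I
#'
#' Number of voxels within the region of interest whose intensity exceeds
#' the background threshold. The default rule sets the threshold to the
#' volume background (mean of per-plane means) plus `k` times the noise RMS
#' of a noise ROI; an explicit `threshold` overrides it.
#'
#' @param vol a [pressure_volume()].
#' @param roi logical array or index vector defining the volume of interest.
#' @param threshold explicit intensity threshold (optional).
#' @param noise_roi noise region used by the default background rule.
#' @param k noise multiples above background (default 2).
#' @return Integer count, with attribute `threshold`.
#' @export
vascular_signal_vi <- function(vol, roi, threshold = NULL, noise_roi = NULL,
                               k = 2) {
  stopifnot(inherits(vol, "pressure_volume"))
  vals <- vol$p0[roi]
  if (length(vals) == 0) stop("empty roi", call. = FALSE)
  if (is.null(threshold)) {
    background <- mean(apply(vol$p0, 3, mean))
    noise <- if (is.null(noise_roi)) stats::sd(vol$p0) else
      sqrt(mean(vol$p0[noise_roi]^2))
    threshold <- background + k * noise
  }
  structure(sum(vals > threshold), threshold = threshold)
}

#' Tortuosity index of a centreline
#'
#' Ratio of the arc length of a polyline to the straight-line (chord)
#' distance between its endpoints; 1 for a straight vessel.
#'
#' @param centreline numeric matrix (n x 2 or n x 3) of ordered points.
#' @return Tortuosity index (>= 1 up to discretization).
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' tortuosity_index(cbind(cos(th), sin(th)))  # semicircle: pi/2
#' @export
tortuosity_index <- function(centreline) {
  m <- as.matrix(centreline)
  if (nrow(m) < 2) stop("centreline needs at least 2 points", call. = FALSE)
  chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  if (chord == 0)
    stop("coincident endpoints: tortuosity undefined", call. = FALSE)
  arc <- sum(sqrt(rowSums((m[-1, , drop = FALSE] -
                           m[-nrow(m), , drop = FALSE])^2)))
  arc / chord
}

#' ROI mean-intensity time courses
#'
#' Mean image intensity within each region of interest, per frame — the
#' standard readout for dynamic sequences (for example occlusion-reperfusion
#' responses of vascular versus epidermal regions).
#'
#' @param frames list of [pressure_volume()] (or 3D arrays).
#' @param rois named list of logical arrays or index vectors.
#' @param times_s optional frame times (s).
#' @return Data frame with columns `frame`, `time_s`, `roi`, `mean_intensity`.
#' @export
roi_timecourse <- function(frames, rois, times_s = NULL) {
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  if (is.null(times_s)) times_s <- seq_along(frames) - 1
  for (nm in names(rois))
    if (sum(if (is.logical(rois[[nm]])) rois[[nm]] else length(rois[[nm]])) == 0)
      stop(sprintf("empty roi '%s'", nm), call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(frames), function(i) {
    a <- frames[[i]]
    if (inherits(a, "pressure_volume")) a <- a$p0
    data.frame(frame = i, time_s = times_s[i], roi = names(rois),
               mean_intensity = vapply(rois, function(r) mean(a[r]), 0),
               row.names = NULL)
  }))
  out
}
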