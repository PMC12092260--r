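#' Write a scan container
#'
#' Serializes a scan's objects (sensor time series, optional ground-truth
#' pressure volume, scan pattern, metadata) into a single versioned
#' container file. The schema mirrors an HDF5-style layout — groups `sensor`
#' (array + sampling attrs + mask), `p0`, `scan`, `meta` (schema version,
#' seed, config snapshot, content hash) — stored as an RDS payload.
#'
#' @param path output file path.
#' @param sensor a [sensor_time_series()] (optional).
#' @param p0 a [pressure_volume()] ground truth (optional).
#' @param scan a `scan_pattern` (optional).
#' @param seed integer seed used to generate the data (recorded).
#' @param config arbitrary config list snapshot (recorded).
#' @return The path, invisibly.
#' @export
write_scan <- function(path, sensor = NULL, p0 = NULL, scan = NULL,
                       seed = NULL, config = NULL) {
  payload <- list(
    meta = list(schema = "fpscan-scan-v1", seed = seed, config = config,
                created = format(Sys.time(), tz = "UTC")),
    sensor = sensor, p0 = p0, scan = scan)
  payload$meta$content_hash <- .content_hash(payload[c("sensor", "p0", "scan")])
  saveRDS(payload, path)
  invisible(path)
}

#' Read a scan container
#'
#' @param path file written by [write_scan()].
#' @return List with `meta`, `sensor`, `p0`, `scan`.
#' @export
read_scan <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$meta$schema, "fpscan-scan-v1"))
    stop(sprintf("unknown scan container schema '%s' (expected fpscan-scan-v1); refusing to coerce",
                 paste(payload$meta$schema, collapse = "/")), call. = FALSE)
  payload
}

# order-stable content hash of numeric payloads (no external digest dep)
.content_hash <- function(x) {
  ser <- serialize(x, NULL)
  # 64-bit FNV-1a over the serialized bytes, reported as hex
  h <- 0xcbf29ce484222325
  # process in chunks through doubles would lose precision; fold bytes into
  # two 32-bit accumulators instead
  b <- as.integer(ser)
  a1 <- 2166136261
  for (chunk in split(b, ceiling(seq_along(b) / 65536))) {
    a1 <- (a1 + sum((chunk + 1) * seq_along(chunk))) %% 4294967291
  }
  sprintf("%.0f-%d", a1, length(b))
}

#' Export a volume as multi-page TIFF
#'
#' Writes depth planes as 32-bit float TIFF pages, intensities normalized to
#' `[0, 1]` by `max_value` (default: volume maximum).
#'
#' @param vol a [pressure_volume()].
#' @param path output path.
#' @param max_value normalization constant.
#' @return The path, invisibly.
#' @export
export_tiff <- function(vol, path, max_value = NULL) {
  stopifnot(inherits(vol, "pressure_volume"))
  if (is.null(max_value)) max_value <- max(vol$p0)
  if (max_value <= 0) max_value <- 1
  pages <- lapply(seq_len(dim(vol$p0)[3]), function(k)
    pmin(pmax(t(vol$p0[, , k]) / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a volume as NIfTI-1
#'
#' @param vol a [pressure_volume()].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
export_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "pressure_volume"))
  img <- RNifti::asNifti(vol$p0,
                         pixdim = c(vol$dx_um, vol$dy_um, vol$dz_um) / 1e3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over the projection axis within a slab, on a linear
#' intensity scale.
#'
#' @param vol a [pressure_volume()].
#' @param axis projection axis: `"z"` (x-y MIP), `"y"` (x-z) or `"x"` (y-z).
#' @param slab_mm optional length-2 range (mm) along the projection axis;
#'   default full thickness.
#' @return 2D matrix of maxima, with attribute `pixel_um` (row/col pitch).
#' @export
mip <- function(vol, axis = c("z", "y", "x"), slab_mm = NULL) {
  stopifnot(inherits(vol, "pressure_volume"))
  axis <- match.arg(axis)
  ax_i <- match(axis, c("x", "y", "z"))
  coords <- .vol_axis(vol, ax_i) * 1e-3      # mm
  if (is.null(slab_mm)) slab_mm <- range(coords)
  keep <- which(coords >= slab_mm[1] & coords <= slab_mm[2])
  if (length(keep) == 0) stop("empty slab", call. = FALSE)
  a <- switch(axis,
              z = vol$p0[, , keep, drop = FALSE],
              y = vol$p0[, keep, , drop = FALSE],
              x = vol$p0[keep, , , drop = FALSE])
  out <- apply(a, setdiff(1:3, ax_i), max)
  pitch <- c(vol$dx_um, vol$dy_um, vol$dz_um)[setdiff(1:3, ax_i)]
  structure(out, pixel_um = pitch, axis = axis, slab_mm = slab_mm)
}

#' Depth-to-colour encoded MIP
#'
#' Full-thickness (by default) x-y maximum projection where the hue encodes
#' the depth of the maximizing voxel (perceptually uniform viridis stops)
#' and the value channel carries its intensity on a linear scale.
#'
#' @param vol a [pressure_volume()].
#' @param slab_mm optional depth range (mm).
#' @param colormap palette function mapping `n` to colours (default
#'   `grDevices::hcl.colors(n, "viridis")`).
#' @param n_stops colour stops along depth (default 64).
#' @return Array `[nx, ny, 3]` of RGB in `[0, 1]`; attributes `depth_mm`
#'   (depth of maximum) and `intensity` (the greyscale MIP).
#' @export
depth_colour_mip <- function(vol, slab_mm = NULL, colormap = NULL,
                             n_stops = 64) {
  stopifnot(inherits(vol, "pressure_volume"))
  coords <- .vol_axis(vol, 3) * 1e-3
  if (is.null(slab_mm)) slab_mm <- range(coords)
  keep <- which(coords >= slab_mm[1] & coords <= slab_mm[2])
  if (length(keep) == 0) stop("empty slab", call. = FALSE)
  a <- vol$p0[, , keep, drop = FALSE]
  inten <- apply(a, c(1, 2), max)
  argdepth <- apply(a, c(1, 2), which.max)
  depth_mm <- matrix(coords[keep][argdepth], nrow(inten), ncol(inten))
  if (is.null(colormap))
    colormap <- function(n) grDevices::hcl.colors(n, "viridis")
  pal <- grDevices::col2rgb(colormap(n_stops)) / 255
  stop_idx <- pmin(pmax(1L, 1L + floor((depth_mm - slab_mm[1]) /
    max(diff(slab_mm), 1e-12) * (n_stops - 1L))), n_stops)
  vmax <- max(inten)
  if (vmax <= 0) vmax <- 1
  val <- pmin(inten / vmax, 1)
  rgb <- array(0, c(nrow(inten), ncol(inten), 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(pal[ch, stop_idx], nrow(inten)) * val
  structure(rgb, depth_mm = depth_mm, intensity = inten)
}

#' Read/write pipeline configuration
#'
#' Flat configuration (sensor, acquisition, preprocessing, reconstruction
#' sections) serialized as YAML or JSON, chosen by file extension.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @param config named list (for writing).
#' @return `read_config()` returns the list; `write_config()` the path.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}
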