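#' Interrogation beam array layout
#'
#' Geometry of the multibeam read-out: a `rows` x `cols` rectangular array of
#' focused interrogation spots with a fixed pitch. All N = rows * cols beams
#' are read out in parallel on each excitation laser pulse.
#'
#' @param rows,cols array dimensions (defaults 4 x 16, N = 64 beams).
#' @param pitch_um beam-to-beam pitch (micrometres, default 324).
#' @param spot_diameter_um 1/e^2 interrogation spot diameter (default 49).
#' @return An object of class `beam_array_layout`.
#' @export
beam_array_layout <- function(rows = 4L, cols = 16L, pitch_um = 324,
                              spot_diameter_um = 49) {
  stopifnot_scalar(pitch_um, "pitch_um", positive = TRUE)
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_beams = as.integer(rows) * as.integer(cols),
                 pitch_um = pitch_um, spot_diameter_um = spot_diameter_um,
                 footprint_mm2 = (cols * pitch_um) * (rows * pitch_um) * 1e-6),
            class = "beam_array_layout")
}

#' A-line acquisition rate
#'
#' `rate = eta * N * PRF`: N parallel beams each yield one A-line per laser
#' pulse at the pulse repetition frequency PRF; `eta` is an optional duty
#' factor (default 1, never applied silently).
#'
#' @param n_beams number of parallel interrogation beams N.
#' @param prf_hz laser pulse repetition frequency (Hz).
#' @param eta acquisition efficiency in (0, 1].
#' @return A-lines per second.
#' @examples
#' aline_rate(64, 100)   # 6400
#' aline_rate(64, 1000)  # 64000
#' @export
aline_rate <- function(n_beams, prf_hz, eta = 1) {
  if (n_beams < 1) stop("n_beams must be >= 1", call. = FALSE)
  stopifnot_scalar(prf_hz, "prf_hz", positive = TRUE)
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]", call. = FALSE)
  eta * n_beams * prf_hz
}

#' Total scan time
#'
#' @param n_alines total number of A-lines acquired.
#' @param aline_rate_hz A-line rate (A-lines per second, > 0).
#' @return Scan time T in seconds.
#' @examples
#' scan_time(34560, 6400)  # 5.4 s
#' @export
scan_time <- function(n_alines, aline_rate_hz) {
  stopifnot_scalar(aline_rate_hz, "aline_rate_hz", positive = TRUE)
  if (n_alines < 0) stop("n_alines must be >= 0", call. = FALSE)
  n_alines / aline_rate_hz
}

# Internal: pulse positions and per-pulse beam offsets for a multibeam raster.
# The layout pitch must be an integer multiple s = pitch/dx of the grid step;
# each beam then covers an s x s block of sub-steps, visited in row-major
# order (x fast), and the beam-array tile repeats across the grid.
.pattern_geometry <- function(nx, ny, dx_um, dy_um, layout) {
  sx <- layout$pitch_um / dx_um
  sy <- layout$pitch_um / dy_um
  if (abs(sx - round(sx)) > 1e-9 || abs(sy - round(sy)) > 1e-9)
    stop(sprintf(paste0("layout pitch (%g um) must be an integer multiple of the ",
                        "grid step (dx = %g, dy = %g um)"),
                 layout$pitch_um, dx_um, dy_um), call. = FALSE)
  sx <- as.integer(round(sx)); sy <- as.integer(round(sy))
  span_x <- layout$cols * sx     # grid nodes covered by one array tile in x
  span_y <- layout$rows * sy
  if (nx %% span_x != 0 || ny %% span_y != 0)
    stop(sprintf(paste0("grid (%d x %d) must be divisible by the beam-array tile ",
                        "(%d x %d nodes: cols*pitch/dx by rows*pitch/dy)"),
                 nx, ny, span_x, span_y), call. = FALSE)
  list(sx = sx, sy = sy, span_x = span_x, span_y = span_y,
       tiles_x = nx %/% span_x, tiles_y = ny %/% span_y)
}

# build a scan_pattern object from an ordered list of pulses
.make_pattern <- function(nx, ny, dx_um, dy_um, layout, pulse_nodes, prf_hz,
                          seed = NULL) {
  n_pulses <- length(pulse_nodes)
  order_idx <- unlist(pulse_nodes, use.names = FALSE)
  pulse_id <- rep(seq_len(n_pulses), vapply(pulse_nodes, length, 1L))
  ix <- (order_idx - 1L) %% nx
  iy <- (order_idx - 1L) %/% nx
  structure(list(
    nx = nx, ny = ny, dx_um = dx_um, dy_um = dy_um,
    layout = layout, prf_hz = prf_hz,
    positions = cbind(x_um = ix * dx_um, y_um = iy * dy_um),
    order = order_idx,              # node index (column-major in x) per A-line
    pulse_id = pulse_id,
    aline_times_s = (pulse_id - 1) / prf_hz,
    mask = rep(TRUE, length(order_idx)),
    seed = seed
  ), class = "scan_pattern")
}

#' @export
print.scan_pattern <- function(x, ...) {
  cat(sprintf("<scan_pattern> %d x %d grid (dx %g, dy %g um), %d A-lines (%d retained), %d pulses @ %g Hz\n",
              x$nx, x$ny, x$dx_um, x$dy_um, length(x$order), sum(x$mask),
              max(x$pulse_id), x$prf_hz))
  invisible(x)
}

#' Raster multibeam scan pattern
#'
#' Visits every node of an `nx` x `ny` detection grid exactly once, N beams
#' per laser pulse. The beam array (pitch an integer multiple s of the grid
#' step) is stepped through its s x s sub-step block in row-major order and
#' tiled across the grid, so the full grid of `nx * ny` A-lines is covered in
#' `nx * ny / N` pulses.
#'
#' @param nx,ny detection grid dimensions.
#' @param dx_um,dy_um grid step (micrometres).
#' @param layout a [beam_array_layout()].
#' @param prf_hz laser pulse repetition frequency (Hz), used for A-line
#'   timestamps.
#' @return A `scan_pattern` object.
#' @examples
#' p <- raster_scan_pattern(192, 180, 108, 108)
#' nrow(p$positions)  # 34560 detection points
#' @export
raster_scan_pattern <- function(nx, ny, dx_um, dy_um,
                                layout = beam_array_layout(), prf_hz = 100) {
  g <- .pattern_geometry(nx, ny, dx_um, dy_um, layout)
  pulses <- list()
  # beam (r, c) of tile (tx, ty) at sub-step (ux, uy) sits at node
  # x = tx*span_x + c*sx + ux, y = ty*span_y + r*sy + uy   (0-based)
  beam_c <- rep(seq_len(layout$cols) - 1L, layout$rows)
  beam_r <- rep(seq_len(layout$rows) - 1L, each = layout$cols)
  k <- 1L
  for (ty in seq_len(g$tiles_y) - 1L) for (tx in seq_len(g$tiles_x) - 1L)
    for (uy in seq_len(g$sy) - 1L) for (ux in seq_len(g$sx) - 1L) {
      x <- tx * g$span_x + beam_c * g$sx + ux
      y <- ty * g$span_y + beam_r * g$sy + uy
      pulses[[k]] <- y * nx + x + 1L
      k <- k + 1L
    }
  .make_pattern(nx, ny, dx_um, dy_um, layout, pulses, prf_hz)
}

#' Random non-overlapping multibeam scan pattern
#'
#' Same pulse set as [raster_scan_pattern()] (beams within a pulse are rigid),
#' but the pulses are visited in a uniformly random order, so no grid node is
#' ever revisited and the full pattern still covers every node exactly once.
#'
#' @inheritParams raster_scan_pattern
#' @param seed integer seed; the same seed reproduces the same order.
#' @return A `scan_pattern` object.
#' @export
random_scan_pattern <- function(nx, ny, dx_um, dy_um,
                                layout = beam_array_layout(), prf_hz = 100,
                                seed = 1L) {
  raster <- raster_scan_pattern(nx, ny, dx_um, dy_um, layout, prf_hz)
  n_pulses <- max(raster$pulse_id)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n_pulses)
  pulses <- split(raster$order, raster$pulse_id)[perm]
  .make_pattern(nx, ny, dx_um, dy_um, layout, unname(pulses), prf_hz, seed)
}

#' Subsample a scan pattern
#'
#' Retains the earliest-acquired `round(fraction * n_alines)` A-lines by
#' masking the rest, emulating extraction of the first fraction of a recorded
#' data set; the effective scan time scales by the same fraction.
#'
#' @param pattern a `scan_pattern`.
#' @param fraction retained fraction in (0, 1].
#' @return The pattern with an updated logical `mask`.
#' @export
subsample_mask <- function(pattern, fraction) {
  stopifnot(inherits(pattern, "scan_pattern"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  n <- length(pattern$order)
  keep <- round(fraction * n)
  pattern$mask <- seq_len(n) <= keep   # A-lines are stored in acquisition order
  pattern
}

#' Lateral mask matrix of a scan pattern
#'
#' Projects the per-A-line retention mask of a (possibly subsampled) scan
#' pattern onto the detection grid: TRUE where the node's A-line was
#' acquired.
#'
#' @param pattern a `scan_pattern`.
#' @return Logical `nx` x `ny` matrix.
#' @export
pattern_mask_matrix <- function(pattern) {
  stopifnot(inherits(pattern, "scan_pattern"))
  m <- matrix(FALSE, pattern$nx, pattern$ny)
  m[pattern$order[pattern$mask]] <- TRUE
  m
}

#' 2D line-scan frame schedule
#'
#' In the video-rate 2D mode the beam array, long axis along the scan line,
#' is stepped along a line of length `line_length_mm` in steps of `step_um`;
#' each laser pulse yields `rows * cols` A-lines, so a frame of
#' `(line_length/step) * rows` A-lines takes
#' `m / (cols)` pulses with m = line_length/step scan steps.
#'
#' @param line_length_mm scan-line length (mm).
#' @param step_um scan step along the line (micrometres).
#' @param layout a [beam_array_layout()]; the `cols` axis lies along the line.
#' @param prf_hz laser pulse repetition frequency (Hz).
#' @return List with `n_steps`, `alines_per_frame`, `frame_time_s` and `fps`
#'   (floored to one decimal).
#' @examples
#' frame_schedule_2d(15.55, 162, beam_array_layout(), 200)  # 30 ms, 33.3 fps
#' @export
frame_schedule_2d <- function(line_length_mm, step_um,
                              layout = beam_array_layout(), prf_hz = 200) {
  stopifnot_scalar(step_um, "step_um", positive = TRUE)
  if (step_um > line_length_mm * 1e3)
    stop("step_um exceeds the line length", call. = FALSE)
  m <- line_length_mm * 1e3 / step_um
  if (abs(m - round(m)) > 0.05 * m)
    stop("line_length must be an integral number of steps (within rounding)",
         call. = FALSE)
  m <- round(m)
  alines <- m * layout$rows
  frame_time <- alines / (layout$n_beams * prf_hz)
  list(n_steps = m, alines_per_frame = alines, frame_time_s = frame_time,
       fps = floor(10 / frame_time) / 10)
}

#' Sliding-window frame indices for dynamic 3D imaging
#'
#' Splits a continuously acquired A-line stream into overlapping
#' reconstruction windows: each frame reuses `window - advance` A-lines of the
#' previous one, with `advance = round(advance_fraction * window)`. The number
#' of frames is `n_total / advance` with final windows truncated at the end of
#' the data, and the refresh frame rate is `aline_rate / advance`.
#'
#' @param n_total_alines total A-lines in the stream.
#' @param window A-lines per reconstructed frame.
#' @param advance_fraction window advance as a fraction of the window (0, 1].
#' @return Data frame with 1-based inclusive `start`, `stop` per frame.
#' @examples
#' nrow(sliding_window_frames(153600, 7680, 0.1))  # 200 frames
#' @export
sliding_window_frames <- function(n_total_alines, window, advance_fraction) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (window > n_total_alines) stop("window exceeds the data length", call. = FALSE)
  if (advance_fraction <= 0 || advance_fraction > 1)
    stop("advance_fraction must be in (0, 1]", call. = FALSE)
  advance <- round(advance_fraction * window)
  n_frames <- floor(n_total_alines / advance)
  start <- (seq_len(n_frames) - 1L) * advance + 1L
  stop_ <- pmin(start + window - 1L, n_total_alines)
  data.frame(frame = seq_len(n_frames), start = start, stop = stop_)
}
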