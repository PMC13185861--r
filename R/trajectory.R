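#' Construct a trajectory object
#'
#' A `bot_trajectory` holds a uniformly sampled 2-D path in physical units
#' (mm), together with the sampling rate and the pixel scale used to convert
#' tracker coordinates.
#'
#' @param x,y Numeric coordinate vectors in mm (equal length, >= 2 samples,
#'   all finite).
#' @param sampling_rate Sampling rate in Hz.
#' @param pixel_scale Pixel scale in mm/px used at conversion time (kept as
#'   metadata; `x`/`y` are already in mm). Default 1.
#' @param source Identifier for the recording (file name, simulation tag).
#' @return An object of class `bot_trajectory` with fields `time` (s), `x`,
#'   `y` (mm), `sampling_rate`, `pixel_scale`, `source`.
#' @seealso [load_trajectory()], [compute_kinematics()], [welch_psd()]
#' @export
trajectory <- function(x, y, sampling_rate, pixel_scale = 1, source = "trajectory") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("too few samples: a trajectory needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory coordinates must be finite after gap handling")
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stop_if_not_scalar_number(pixel_scale, "pixel_scale", positive = TRUE)
  structure(
    list(time = (seq_along(x) - 1) / sampling_rate,
         x = x, y = y,
         sampling_rate = sampling_rate,
         pixel_scale = pixel_scale,
         source = as.character(source)[1L]),
    class = "bot_trajectory")
}

#' @export
print.bot_trajectory <- function(x, ...) {
  cat(sprintf("<bot_trajectory> %s: %d samples @ %g Hz (%.1f s), pixel scale %g mm/px\n",
              x$source, length(x$x), x$sampling_rate,
              length(x$x) / x$sampling_rate, x$pixel_scale))
  invisible(x)
}

#' Load a tracked trajectory from a CSV export
#'
#' Reads the per-frame centre-of-mass coordinates exported by a video
#' digitizing tool (columns `frame, x, y` in pixels, with or without a
#' header), converts to mm, and repairs tracking drop-outs: interior gaps of
#' at most `max_gap` frames are linearly interpolated; longer gaps are
#' reported and the trajectory is truncated to the longest contiguous valid
#' segment.
#'
#' @param path CSV file with three columns: frame index, x (px), y (px).
#'   Missing frames may appear as empty fields or NaN.
#' @param pixel_scale Pixel scale in mm/px.
#' @param sampling_rate Video frame rate in Hz.
#' @param max_gap Longest interior NA run (frames) to interpolate. Default 5.
#' @return A [trajectory()] object in mm.
#' @export
load_trajectory <- function(path, pixel_scale, sampling_rate, max_gap = 5L) {
  stop_if_not_scalar_number(pixel_scale, "pixel_scale", positive = TRUE)
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9.eE,\\s]*$", first)
  d <- utils::read.csv(path, header = has_header,
                       na.strings = c("NA", "NaN", "nan", ""))
  if (ncol(d) < 3L) stop("expected columns: frame, x, y")
  if (has_header && all(c("x_px", "y_px") %in% names(d))) {
    d <- data.frame(frame = d[[1L]], x = d$x_px, y = d$y_px)
  } else {
    names(d)[1:3] <- c("frame", "x", "y")
  }
  d <- d[order(d$frame), , drop = FALSE]
  step <- unique(diff(d$frame))
  if (length(step) > 1L || (length(step) == 1L && step[1L] != 1L))
    stop("non-constant frame step: frames must be consecutive integers")

  x <- d$x; y <- d$y
  valid <- is.finite(x) & is.finite(y)
  if (sum(valid) < 2L) stop("too few samples: fewer than 2 valid frames")

  # interpolate short interior gaps
  filled <- fill_gaps(x, y, valid, max_gap)
  x <- filled$x; y <- filled$y
  valid <- is.finite(x) & is.finite(y)

  if (!all(valid)) {
    seg <- longest_valid_run(valid)
    warning(sprintf(
      "gap longer than %d frames: kept longest contiguous segment (frames %d-%d of %d)",
      max_gap, seg[1L], seg[2L], length(x)))
    x <- x[seg[1L]:seg[2L]]; y <- y[seg[1L]:seg[2L]]
  }
  if (length(x) < 2L) stop("too few samples after gap handling")
  trajectory(x * pixel_scale, y * pixel_scale, sampling_rate, pixel_scale,
             source = basename(path))
}

fill_gaps <- function(x, y, valid, max_gap) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] || r$lengths[i] > max_gap) next
    if (i == 1L || i == length(r$values)) next  # leading/trailing gaps stay NA
    idx <- starts[i]:ends[i]
    a <- starts[i] - 1L; b <- ends[i] + 1L
    w <- (idx - a) / (b - a)
    x[idx] <- x[a] + w * (x[b] - x[a])
    y[idx] <- y[a] + w * (y[b] - y[a])
  }
  list(x = x, y = y)
}

longest_valid_run <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(starts[best], ends[best])
}

#' Describe the recording arena
#'
#' @param shape `"rectangle"` or `"circle"`.
#' @param dimensions For a rectangle, `c(width, height)` in mm; for a circle,
#'   the diameter in mm.
#' @param coverage_bin Side of the square coverage cells in mm. Default 0.1,
#'   the bin size used to grid the well when computing percent covered area.
#' @param origin Lower-left corner (rectangle) or centre (circle) in mm.
#'   Defaults to `c(0, 0)`.
#' @return An `arena_spec` object.
#' @export
arena_spec <- function(shape = c("rectangle", "circle"), dimensions,
                       coverage_bin = 0.1, origin = c(0, 0)) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  if (any(dimensions <= 0)) stop("arena dimensions must be positive")
  if (shape == "rectangle" && length(dimensions) != 2L)
    stop("rectangle needs dimensions = c(width, height)")
  if (shape == "circle" && length(dimensions) != 1L)
    stop("circle needs a single diameter")
  stop_if_not_scalar_number(coverage_bin, "coverage_bin", positive = TRUE)
  structure(list(shape = shape, dimensions = dimensions,
                 coverage_bin = coverage_bin, origin = as.numeric(origin)),
            class = "arena_spec")
}

# Half-open cell assignment: a coordinate exactly on a cell boundary belongs
# to the cell with the lower index.
cell_index <- function(u, bin) {
  i <- ceiling(u / bin) - 1L
  i[u <= 0] <- 0L
  as.integer(i)
}

arena_cells <- function(arena) {
  bin <- arena$coverage_bin
  if (arena$shape == "rectangle") {
    nx <- as.integer(ceiling(arena$dimensions[1L] / bin - 1e-9))
    ny <- as.integer(ceiling(arena$dimensions[2L] / bin - 1e-9))
    list(nx = nx, ny = ny, total = nx * ny)
  } else {
    r <- arena$dimensions[1L] / 2
    n <- as.integer(ceiling(2 * r / bin - 1e-9))
    cx <- (seq_len(n) - 0.5) * bin - r
    inside <- outer(cx^2, cx^2, "+") <= r^2  # cell-centre rule
    list(nx = n, ny = n, total = sum(inside), inside = inside)
  }
}

#' Kinematic summary of a trajectory
#'
#' Computes the kinematic read-outs of a tracked organoid: total Euclidean
#' distance travelled, mean speed, mean acceleration (magnitude of the
#' discrete velocity-vector difference, so turning counts), minimum per-step
#' speed, and percent arena coverage obtained by gridding the well into
#' square cells of side `arena$coverage_bin` and counting unique visited
#' cells against all cells of the well.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena_spec()]. Points outside the arena trigger a warning
#'   and are excluded from coverage (the denominator is always the full
#'   arena).
#' @param smooth_window Odd median-filter window (samples) applied to the
#'   per-step speed series before taking the minimum; 1 (default) disables
#'   smoothing.
#' @return A one-row `data.frame` of class `kinematic_summary` with columns
#'   `source`, `total_distance` (mm), `mean_speed` (mm/s),
#'   `mean_acceleration` (mm/s^2), `min_speed` (mm/s), `coverage_percent`.
#' @export
compute_kinematics <- function(traj, arena, smooth_window = 1L) {
  stopifnot(inherits(traj, "bot_trajectory"), inherits(arena, "arena_spec"))
  fs <- traj$sampling_rate
  dx <- diff(traj$x); dy <- diff(traj$y)
  step_len <- sqrt(dx^2 + dy^2)
  total_distance <- sum(step_len)
  speed <- step_len * fs
  vx <- dx * fs; vy <- dy * fs
  acc <- if (length(vx) >= 2L) sqrt(diff(vx)^2 + diff(vy)^2) * fs else 0
  sm <- speed
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    sm <- stats::runmed(speed, k = min(smooth_window, length(speed)))
  }

  cells <- arena_cells(arena)
  px <- traj$x - arena$origin[1L]
  py <- traj$y - arena$origin[2L]
  if (arena$shape == "circle") {
    r <- arena$dimensions[1L] / 2
    inside <- px^2 + py^2 <= r^2
    px <- px + r; py <- py + r  # shift to grid corner
  } else {
    inside <- px >= 0 & px <= arena$dimensions[1L] &
              py >= 0 & py <= arena$dimensions[2L]
  }
  if (!all(inside))
    warning("trajectory leaves the arena: coverage computed on arena cells only")
  ix <- cell_index(px[inside], arena$coverage_bin)
  iy <- cell_index(py[inside], arena$coverage_bin)
  visited <- unique(ix + iy * cells$nx)
  coverage <- 100 * length(visited) / cells$total

  structure(
    data.frame(source = traj$source,
               total_distance = total_distance,
               mean_speed = mean(speed),
               mean_acceleration = mean(acc),
               min_speed = min(sm),
               coverage_percent = coverage,
               stringsAsFactors = FALSE),
    class = c("kinematic_summary", "data.frame"))
}

#' Write a trajectory to CSV with a YAML sidecar
#'
#' The CSV has columns `frame, time_s, x_px, y_px` (coordinates divided by
#' the stored pixel scale); the sidecar records pixel scale and sampling
#' rate so [load_trajectory()] can round-trip the file.
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @param meta_path Optional YAML path (default: `path` with `.yaml`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, meta_path = NULL) {
  stopifnot(inherits(traj, "bot_trajectory"))
  d <- data.frame(frame = seq_along(traj$x),
                  time_s = traj$time,
                  x_px = traj$x / traj$pixel_scale,
                  y_px = traj$y / traj$pixel_scale)
  utils::write.csv(d, path, row.names = FALSE)
  meta_path <- meta_path %||% sub("\\.csv$", ".yaml", path)
  yaml::write_yaml(list(pixel_scale = traj$pixel_scale,
                        sampling_rate = traj$sampling_rate,
                        source = traj$source), meta_path)
  invisible(path)
}
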