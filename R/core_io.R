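#' Construct an image stack
#'
#' A time-lapse fluorescence stack with its physical calibration. Frames are
#' stored as a T x H x W array in arbitrary intensity units. The continuous
#' position of the centre of pixel (row i, column j), both 1-based, is
#' x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size, with x rightward
#' and y downward.
#'
#' @param frames numeric array T x H x W (a single matrix is promoted to
#'   T = 1), finite and non-negative.
#' @param pixel_size length of one pixel side (micrometres), > 0.
#' @param frame_interval time between frames (seconds), > 0.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) {
    frames <- array(frames, c(1, nrow(frames), ncol(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(dim(frames) < 1)) stop("empty stack: all of T, H, W must be >= 1")
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("stack intensities must be finite and non-negative")
  }
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "ImageStack: %d frame(s) of %d x %d px (%.3f um/px, %.4f s/frame)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$frames)

# sidecar metadata file next to a TIFF (pixel size etc. that plain
# grayscale TIFF tags do not carry here)
sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a grayscale TIFF stack
#'
#' Multi-page grayscale TIFF; a single page is read as T = 1. Physical
#' calibration is taken from arguments when given, otherwise from a YAML
#' sidecar file `<path>.yaml` written by [write_stack()].
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides (um, s).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("zero frames in ", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1)))) {
    stop("non-grayscale TIFF page in ", path)
  }
  scale <- 1
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop("pixel_size/frame_interval not given and no sidecar for ", path)
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  frames <- array(0, c(length(pages), H, W))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * scale
  image_stack(frames, pixel_size, frame_interval)
}

#' Write a grayscale TIFF stack with a calibration sidecar
#'
#' Intensities are stored as 32-bit float pages rescaled to [0, 1]; the
#' rescaling factor and the physical calibration go into `<path>.yaml` so
#' that [read_stack()] round-trips the stack.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  mx <- max(stack$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) stack$frames[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        frame_interval = stack$frame_interval,
                        intensity_scale = scale),
                   sidecar_path(path))
  invisible(path)
}

loc_cols <- c("frame", "x", "y", "intensity", "sigma", "channel")

#' Construct a localization table
#'
#' Per-detection records: 0-based frame index, continuous position in
#' micrometres, intensity (photons or ADU), fitted PSF standard deviation
#' (um) and a channel label. Missing optional columns (`intensity`, `sigma`,
#' `channel`) are filled with defaults.
#'
#' @param df data frame with at least columns `frame`, `x`, `y`.
#' @param pixel_size,frame_interval optional calibration metadata carried as
#'   attributes.
#' @return a data frame of class `loc_table`.
#' @export
loc_table <- function(df = NULL, pixel_size = NULL, frame_interval = NULL) {
  if (is.null(df)) {
    df <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                     intensity = numeric(0), sigma = numeric(0),
                     channel = character(0))
  }
  miss <- setdiff(c("frame", "x", "y"), names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$intensity)) df$intensity <- rep(NA_real_, nrow(df))
  if (is.null(df$sigma)) df$sigma <- rep(NA_real_, nrow(df))
  if (is.null(df$channel)) df$channel <- rep("ch0", nrow(df))
  if (nrow(df) > 0 && any(df$frame < 0)) stop("negative frame indices")
  if (nrow(df) > 0 && any(!is.na(df$sigma) & df$sigma <= 0)) {
    stop("sigma must be > 0")
  }
  df <- df[loc_cols]
  df$frame <- as.integer(df$frame)
  df$channel <- as.character(df$channel)
  attr(df, "pixel_size") <- pixel_size
  attr(df, "frame_interval") <- frame_interval
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Read a localization table from CSV
#'
#' Header columns `frame,x,y,intensity,sigma,channel`; `intensity`, `sigma`
#' and `channel` are optional. Calibration metadata written by
#' [write_localizations()] is recovered from `# key: value` comment lines.
#'
#' @param path CSV file path.
#' @return a [loc_table()].
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  meta <- list()
  con <- file(path, "r"); on.exit(close(con))
  while (length(l <- readLines(con, 1)) && startsWith(l, "#")) {
    kv <- strsplit(sub("^#\\s*", "", l), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  loc_table(df, pixel_size = meta$pixel_size,
            frame_interval = meta$frame_interval)
}

#' Write a localization table to CSV
#'
#' @param table a [loc_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "loc_table"))
  hdr <- character(0)
  for (k in c("pixel_size", "frame_interval")) {
    v <- attr(table, k)
    if (!is.null(v)) hdr <- c(hdr, sprintf("# %s: %.17g", k, v))
  }
  con <- file(path, "w"); on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  write.csv(as.data.frame(table)[loc_cols], con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write trajectories in long CSV format
#'
#' Columns `traj_id,frame,x,y` (one row per localization, time-ordered
#' within a trajectory).
#'
#' @param path CSV path.
#' @return data frame with columns traj_id, frame, x, y.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("traj_id", "frame", "x", "y"), names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_trajectories
#' @param traj trajectory data frame.
#' @export
write_trajectories <- function(traj, path) {
  write.csv(traj[c("traj_id", "frame", "x", "y")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' All pipeline tunables with their defaults. Lengths are in micrometres and
#' times in seconds throughout, except FRAP rates which are reported in
#' min^-1.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `analysis_config`.
#' @details Key fields:
#' \describe{
#'   \item{wavelet_level, detect_k}{detection operates on the level-2
#'     a-trous detail plane, thresholded at `detect_k` times the robust
#'     image noise sd (default level 2, k = 2).}
#'   \item{d_max, max_gap}{tracker link distance cap (default
#'     sqrt(4 * 5 um^2/s * dt)) and maximum blink gap in frames (2).}
#'   \item{n_fit, d_floor, fwhm}{MSD fit uses the first 4 lag points;
#'     diffusion floor 1e-5 um^2/s; spatial resolution FWHM 0.054 um feeding
#'     the slow-mobility threshold.}
#'   \item{min_detections}{a synapse counts as containing the target at
#'     >= 10 detections.}
#'   \item{density_radius}{neighbourhood radius for detection density maps,
#'     0.4 um.}
#'   \item{pair_distance}{cap for trans-synaptic domain pairing, 0.2 um.}
#'   \item{frap_r, frap_D}{bleach-spot radius (0.5 um) and free diffusion
#'     coefficient (0.1 um^2/s) fixing k_diff = D / r^2.}
#' }
#' @export
analysis_config <- function(...) {
  cfg <- list(
    pixel_size = 0.16,        # um per camera pixel
    frame_interval = 0.02,    # s
    psf_sigma = 0.1,          # um, expected PSF sd
    wavelet_level = 2L,
    detect_k = 2.0,
    fit_window = 7L,          # px, sub-pixel fit window
    d_max = sqrt(4 * 5 * 0.02),
    max_gap = 2L,
    solver = "assignment",
    n_fit = 4L,
    d_floor = 1e-5,           # um^2/s
    fwhm = 0.054,             # um, spatial resolution
    min_detections = 10L,
    min_area = 0.02,          # um^2, marker segmentation
    density_radius = 0.4,     # um
    map_pixel = 0.02,         # um, super-resolved map pixel
    pair_distance = 0.2,      # um
    frap_r = 0.5,             # um, bleach radius
    frap_D = 0.1,             # um^2/s, free diffusion coefficient
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$d_max > 0,
            cfg$max_gap >= 0, cfg$n_fit >= 2, cfg$fwhm > 0,
            cfg$detect_k > 0, cfg$frap_r > 0, cfg$frap_D > 0)
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(md5sum(f))
}
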