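#' Mean square displacement of one trajectory
#'
#' MSD at lag n frames is the average squared displacement over all ordered
#' point pairs separated by exactly n frames (overlapping windows).
#'
#' @param points data frame with columns `frame, x, y`, strictly increasing
#'   frames.
#' @param dt frame interval (s).
#' @return data frame `lag` (frames), `time` (s), `msd` (um^2), `n_pairs`;
#'   one row per lag with at least one pair, up to the trajectory span.
#' @export
compute_msd <- function(points, dt = 0.02) {
  stopifnot(nrow(points) >= 2, dt > 0)
  points <- points[order(points$frame), ]
  f <- points$frame
  n <- nrow(points)
  i <- rep(seq_len(n), n)
  j <- rep(seq_len(n), each = n)
  sel <- j > i
  lag <- f[j[sel]] - f[i[sel]]
  d2 <- (points$x[j[sel]] - points$x[i[sel]])^2 +
    (points$y[j[sel]] - points$y[i[sel]])^2
  agg <- tapply(d2, lag, mean)
  lags <- as.integer(names(agg))
  data.frame(lag = lags, time = lags * dt, msd = as.numeric(agg),
             n_pairs = as.integer(table(lag)))
}

#' Instantaneous diffusion coefficient from the first MSD points
#'
#' Unweighted least-squares line (free intercept, absorbing the
#' localization-noise offset) through the first `n_fit` lag points of the
#' MSD; the slope divided by 4 gives the 2D diffusion coefficient, floored
#' at `d_floor` so log-scale histograms stay defined for non-positive
#' slopes.
#'
#' @param msd data frame from [compute_msd()].
#' @param n_fit number of initial lag points (default 4; the trajectory
#'   must therefore have at least `n_fit + 1` positions).
#' @param d_floor lower bound for the reported D (um^2/s).
#' @return D_inst (um^2/s).
#' @export
estimate_diffusion <- function(msd, n_fit = 4, d_floor = 1e-5) {
  need <- seq_len(n_fit)
  if (!all(need %in% msd$lag)) {
    stop("msd must contain the first ", n_fit, " lags")
  }
  m <- msd[match(need, msd$lag), ]
  slope <- coef(lm(msd ~ time, data = m))[["time"]]
  max(slope / 4, d_floor)
}

#' Slow-mobility diffusion threshold
#'
#' The threshold below which a trajectory explores less than the spatial
#' resolution of the instrument during the MSD fitting window:
#' `D_threshold = fwhm^2 / (4 * n_fit * dt)`. At the conventional inputs
#' (FWHM 0.054 um, 4 fitted points, 20 ms frames) this is about
#' 9.1e-3 um^2/s, commonly rounded to ~0.01.
#'
#' @param fwhm spatial resolution, full-width at half-maximum (um).
#' @param n_fit number of MSD points fitted.
#' @param dt frame interval (s).
#' @return D_threshold (um^2/s).
#' @export
slow_threshold <- function(fwhm = 0.054, n_fit = 4, dt = 0.02) {
  stopifnot(fwhm > 0, n_fit > 0, dt > 0)
  fwhm^2 / (4 * n_fit * dt)
}

#' Per-trajectory mobility records
#'
#' Computes the MSD and the 4-point diffusion coefficient for every
#' trajectory long enough, and classifies each as slow or fast against
#' `d_threshold`.
#'
#' @param traj a `traj_table` from [link_detections()].
#' @param dt frame interval (s).
#' @param n_fit,d_floor see [estimate_diffusion()].
#' @param d_threshold slow/fast boundary (um^2/s), default
#'   [slow_threshold()] at its conventional inputs.
#' @return data frame of class `mobility_table`: `traj_id, n_points, D_inst,
#'   class`.
#' @export
compute_mobility <- function(traj, dt = 0.02, n_fit = 4, d_floor = 1e-5,
                             d_threshold = slow_threshold()) {
  sp <- split(traj[c("frame", "x", "y")], traj$traj_id)
  rows <- lapply(names(sp), function(id) {
    p <- sp[[id]]
    if (nrow(p) < n_fit + 1) return(NULL)
    msd <- compute_msd(p, dt)
    if (!all(seq_len(n_fit) %in% msd$lag)) return(NULL)
    D <- estimate_diffusion(msd, n_fit, d_floor)
    data.frame(traj_id = id, n_points = nrow(p), D_inst = D,
               class = if (D < d_threshold) "slow" else "fast")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(traj_id = character(0), n_points = integer(0),
                      D_inst = numeric(0), class = character(0))
  }
  rownames(out) <- NULL
  class(out) <- c("mobility_table", "data.frame")
  attr(out, "d_threshold") <- d_threshold
  out
}

#' Slow fraction and semi-log diffusion histogram
#'
#' @param D vector of diffusion coefficients (um^2/s) or a
#'   `mobility_table`.
#' @param d_threshold slow/fast boundary (um^2/s).
#' @param bin_width histogram bin width in log10 decades (default 0.2).
#' @return list: `slow_fraction` (in [0, 1]), `n`, and `histogram`
#'   (data frame `bin_center_log10D, count`).
#' @export
classify_and_fractions <- function(D, d_threshold = slow_threshold(),
                                   bin_width = 0.2) {
  if (is.data.frame(D)) D <- D$D_inst
  stopifnot(length(D) > 0, all(D > 0))
  lg <- log10(D)
  lo <- floor(min(lg) / bin_width) * bin_width
  hi <- ceiling(max(lg) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- table(cut(lg, breaks, include.lowest = TRUE, right = FALSE))
  list(slow_fraction = mean(D < d_threshold),
       n = length(D),
       histogram = data.frame(
         bin_center_log10D = head(breaks, -1) + bin_width / 2,
         count = as.integer(cnt)))
}

#' Confinement fit of a pooled MSD curve
#'
#' Fits the one-phase association model `MSD(t) = P * (1 - exp(-k t))` by
#' least squares. For a molecule uniformly exploring a disk of radius R the
#' MSD plateau is P = R^2, so the confinement diameter is reported as
#' `2 * sqrt(P)`. Curves where the plateau is not approached within the
#' fitted time range (k * t_max < 0.2) or where the fit fails are flagged
#' unconfined.
#'
#' @param msd data frame with columns `time` (s) and `msd` (um^2), >= 4
#'   lags.
#' @return list of class `confinement_fit`: `P` (um^2), `k` (s^-1),
#'   `confinement_diameter` (um), `converged`, `confined`.
#' @export
fit_confinement <- function(msd) {
  stopifnot(nrow(msd) >= 4)
  p0 <- max(msd$msd)
  if (p0 <= 0) stop("MSD curve is non-positive")
  k0 <- max((msd$msd[1] / msd$time[1]) / p0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ P * (1 - exp(-k * time)), data = msd,
                      start = list(P = p0, k = k0),
                      lower = c(0, 0), upper = c(20 * p0, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(P = NA_real_, k = NA_real_,
                          confinement_diameter = NA_real_,
                          converged = FALSE, confined = FALSE),
                     class = "confinement_fit"))
  }
  cf <- coef(fit)
  confined <- is.finite(cf[["k"]]) && cf[["k"]] * max(msd$time) >= 0.2
  structure(list(P = cf[["P"]], k = cf[["k"]],
                 confinement_diameter = 2 * sqrt(cf[["P"]]),
                 converged = TRUE, confined = confined),
            class = "confinement_fit")
}

#' @export
print.confinement_fit <- function(x, ...) {
  if (!x$converged) {
    cat("confinement fit: did not converge\n")
  } else {
    cat(sprintf(
      "confinement fit: plateau %.5f um^2, k %.2f /s, diameter %.1f nm%s\n",
      x$P, x$k, 1000 * x$confinement_diameter,
      if (x$confined) "" else " (unconfined)"))
  }
  invisible(x)
}

#' Membrane area explored by a trajectory set
#'
#' Rasterizes all localizations onto a grid (default pixel half the
#' resolution FWHM) and reports occupied pixel count times pixel area.
#'
#' @param traj data frame with columns x, y (um).
#' @param raster raster pixel side (um), default `fwhm / 2`.
#' @param fwhm spatial resolution (um).
#' @return explored area (um^2).
#' @export
explored_area <- function(traj, raster = fwhm / 2, fwhm = 0.054) {
  stopifnot(nrow(traj) >= 1, raster > 0)
  cells <- unique(paste(floor(traj$x / raster), floor(traj$y / raster)))
  length(cells) * raster^2
}
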