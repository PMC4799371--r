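# --- undecimated a-trous B3-spline wavelet transform ---------------------

mirror_idx <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i[i < 0] <- i[i < 0] + period
  ifelse(i >= n, period - i, i) + 1L
}

# separable convolution with the B3 kernel [1,4,6,4,1]/16 dilated by `step`
# (holes inserted between taps), mirror boundary
conv_b3 <- function(m, step) {
  k <- c(1, 4, 6, 4, 1) / 16
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W)
  for (o in -2:2) {
    tmp <- tmp + k[o + 3] * m[mirror_idx(seq_len(H) + o * step, H), ,
                              drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (o in -2:2) {
    out <- out + k[o + 3] * tmp[, mirror_idx(seq_len(W) + o * step, W),
                                drop = FALSE]
  }
  out
}

#' Undecimated a-trous wavelet transform (B3 spline)
#'
#' Decomposes an image into detail planes of increasing scale plus a smooth
#' residual. Plane 1 is dominated by pixel noise; diffraction-limited spots
#' concentrate in plane 2, which is what the spot detector thresholds.
#'
#' @param img numeric matrix.
#' @param levels number of detail planes.
#' @return list with `details` (list of matrices) and `approx`.
#' @export
atrous_wavelet <- function(img, levels = 2) {
  stopifnot(is.matrix(img), levels >= 1)
  details <- vector("list", levels)
  a <- img
  for (l in seq_len(levels)) {
    s <- conv_b3(a, 2^(l - 1))
    details[[l]] <- a - s
    a <- s
  }
  list(details = details, approx = a)
}

# robust image noise sd: 1.4826 * MAD of the first (noise-dominated) detail
# plane, rescaled by the fraction of white-noise sd that plane passes
# (0.8908 for the separable B3 kernel)
robust_noise_sd <- function(details) {
  mad(details[[1]]) / 0.8908
}

# connected components + per-component weighted centroids of a thresholded
# plane; returns data.frame(row, col, weight, size) in pixel units
labelled_centroids <- function(w, mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      weight = numeric(0), size = integer(0)))
  }
  idx <- which(mask, arr.ind = TRUE)
  l <- lab[mask]
  wt <- w[mask]
  sw <- tapply(wt, l, sum)
  data.frame(
    row = as.numeric(tapply(idx[, 1] * wt, l, sum) / sw),
    col = as.numeric(tapply(idx[, 2] * wt, l, sum) / sw),
    weight = as.numeric(sw),
    size = as.integer(table(factor(l, levels = seq_len(n)))))
}

#' Detect candidate spots by wavelet segmentation
#'
#' Per frame, the level-`level` a-trous detail plane is thresholded at
#' `k` times the robust image noise sd (1.4826 x MAD, estimated from the
#' noise-dominated first detail plane); connected components above the
#' threshold yield one candidate each, placed at the component's
#' intensity-weighted centroid.
#'
#' @param stack an [image_stack()].
#' @param level wavelet detail level (default 2).
#' @param k detection threshold in robust noise sd units (default 2).
#' @return a [loc_table()] of pixel-resolution candidates; frames where more
#'   than 1% of pixels sit at the frame maximum are flagged in attribute
#'   `saturated_frames`.
#' @export
detect_spots <- function(stack, level = 2, k = 2.0) {
  stopifnot(inherits(stack, "ImageStack"), k > 0)
  px <- stack$pixel_size
  d <- dim(stack$frames)
  out <- vector("list", d[1])
  saturated <- integer(0)
  for (t in seq_len(d[1])) {
    fm <- stack$frames[t, , ]
    mx <- max(fm)
    if (mx > 0 && mean(fm == mx) > 0.01) saturated <- c(saturated, t - 1L)
    wt <- atrous_wavelet(fm, level)
    noise <- robust_noise_sd(wt$details)
    w <- wt$details[[level]]
    mask <- w > k * noise
    cc <- labelled_centroids(w, mask)
    if (nrow(cc) > 0) {
      out[[t]] <- data.frame(frame = t - 1L,
                             x = (cc$col - 0.5) * px,
                             y = (cc$row - 0.5) * px,
                             intensity = cc$weight,
                             sigma = NA_real_,
                             channel = "ch0")
    }
  }
  tab <- loc_table(do.call(rbind, out), pixel_size = px,
                   frame_interval = stack$frame_interval)
  if (length(saturated)) {
    sm_log("warning", "saturated frames: ", paste(saturated, collapse = ","))
    attr(tab, "saturated_frames") <- saturated
  }
  tab
}

# residuals of the integrated isotropic Gaussian model on a pixel window;
# par = (N, x0, y0, sigma, offset), all positions in um
gauss_int_resid <- function(par, vals, rows, cols, px) {
  s <- abs(par[4])          # sign-free so the optimizer may cross zero
  fy <- pnorm(rows * px, par[3], s) - pnorm((rows - 1) * px, par[3], s)
  fx <- pnorm(cols * px, par[2], s) - pnorm((cols - 1) * px, par[2], s)
  as.vector(par[1] * (fy %o% fx) + par[5]) - as.vector(vals)
}

#' Refine candidate positions by sub-pixel Gaussian fitting
#'
#' Least-squares fit of an integrated isotropic 2D Gaussian (total photons,
#' x, y, sigma, offset) in a window around each candidate. Fits that fail to
#' converge or whose sigma falls outside `[0.5, 3] x psf_sigma` are dropped;
#' windows clipped at the image edge are fitted on the available pixels and
#' flagged in the `edge` column.
#'
#' @param stack an [image_stack()].
#' @param candidates a [loc_table()] of pixel-resolution candidates.
#' @param window fit window side in pixels (odd, default 7).
#' @param psf_sigma expected PSF sd (um) used for initialization and the
#'   sigma sanity range.
#' @return a [loc_table()] with fitted positions, `intensity` = fitted total
#'   photons and `sigma` = fitted PSF sd; extra column `edge`.
#' @export
refine_subpixel <- function(stack, candidates, window = 7, psf_sigma = 0.1) {
  stopifnot(inherits(stack, "ImageStack"), window >= 3)
  px <- stack$pixel_size
  d <- dim(stack$frames)
  half <- floor(window / 2)
  keep <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fr <- candidates$frame[i]
    ci <- round(candidates$y[i] / px + 0.5)
    cj <- round(candidates$x[i] / px + 0.5)
    if (ci < 1 || ci > d[2] || cj < 1 || cj > d[3]) next
    rows <- max(1, ci - half):min(d[2], ci + half)
    cols <- max(1, cj - half):min(d[3], cj + half)
    edge <- length(rows) < window || length(cols) < window
    vals <- stack$frames[fr + 1L, rows, cols]
    start <- c(max(vals) - min(vals), candidates$x[i], candidates$y[i],
               psf_sigma, min(vals))
    start[1] <- max(start[1], 1e-6) * 2 * pi * psff(psf_sigma, px)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start, fn = gauss_int_resid, vals = vals,
                           rows = rows, cols = cols, px = px,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit) || fit$info < 1 || fit$info > 4) next
    p <- fit$par
    if (!is.finite(p[4]) || abs(p[4]) < 0.5 * psf_sigma ||
        abs(p[4]) > 3 * psf_sigma || p[1] <= 0) next
    keep[[i]] <- data.frame(frame = fr, x = p[2], y = p[3],
                            intensity = p[1], sigma = abs(p[4]),
                            channel = candidates$channel[i], edge = edge)
  }
  res <- do.call(rbind, keep)
  if (is.null(res)) res <- data.frame(frame = integer(0), x = numeric(0),
                                      y = numeric(0), intensity = numeric(0),
                                      sigma = numeric(0),
                                      channel = character(0),
                                      edge = logical(0))
  tab <- loc_table(res, pixel_size = px,
                   frame_interval = stack$frame_interval)
  tab$edge <- res$edge
  tab
}

# crude amplitude-to-photons factor used only for the fit start value
psf_f <- function(sigma, px) (sigma / px)^2
psff <- psf_f

#' Pointing accuracy and spatial resolution from immobile emitters
#'
#' Groups of repeated localizations of immobile emitters (long trajectories,
#' more than 10 points each) give the pointing accuracy sigma_xy as the
#' pooled per-axis standard deviation about each group mean; the spatial
#' resolution follows the empirical full-width convention
#' FWHM = 2.3 x sigma_xy.
#'
#' @param table a [loc_table()] (or any data frame with x, y).
#' @param group grouping vector, one entry per localization (emitter or
#'   trajectory id).
#' @param min_points minimum localizations per usable group (default,
#'   groups must exceed 10 points).
#' @return list of class `precision_estimate`: `sigma_xy`,
#'   `fwhm_resolution` (= 2.3 * sigma_xy), `n_emitters`, `n_localizations`.
#' @export
estimate_resolution <- function(table, group, min_points = 10) {
  stopifnot(length(group) == nrow(table))
  counts <- table(group)
  use <- names(counts)[counts > min_points]
  if (length(use) == 0) stop("no group with more than ", min_points,
                             " localizations")
  sel <- group %in% use
  g <- factor(group[sel])
  rx <- table$x[sel] - ave(table$x[sel], g)
  ry <- table$y[sel] - ave(table$y[sel], g)
  dfree <- 2 * (length(rx) - nlevels(g))
  sigma <- sqrt(sum(rx^2 + ry^2) / dfree)
  if (sigma == 0) stop("degenerate: all localizations identical")
  structure(list(sigma_xy = sigma, fwhm_resolution = 2.3 * sigma,
                 n_emitters = nlevels(g), n_localizations = length(rx)),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "pointing accuracy %.1f nm, resolution (2.3 sigma) %.1f nm (%d emitters)\n",
    1000 * x$sigma_xy, 1000 * x$fwhm_resolution, x$n_emitters))
  invisible(x)
}

# centred running mean with shrinking windows at the edges
running_mean <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  half <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Correct lateral drift
#'
#' Fiducial mode: per-frame offsets are the mean displacement of fiducial
#' (bead) tracks from the reference frame, smoothed by a running mean, and
#' subtracted from all localizations. Correlation mode: localizations are
#' binned into 2D histograms per time block and block offsets are estimated
#' by cross-correlation against the first block (for acquisitions without
#' beads, where stable autofluorescent structures serve as the reference).
#'
#' @param table a [loc_table()].
#' @param fiducials data frame of fiducial tracks (`traj_id, frame, x, y`),
#'   required for `method = "fiducial"`.
#' @param method "fiducial" or "correlation".
#' @param smooth_window running-mean window (frames, default 10).
#' @param block_frames frames per correlation block (default 500).
#' @param bin correlation histogram bin (um, default 0.05).
#' @return list with `table` (corrected) and `drift` (a `drift_model`:
#'   data frame frame, dx, dy plus a `source` attribute). The offset at the
#'   reference (first) frame is exactly (0, 0).
#' @export
correct_drift <- function(table, fiducials = NULL,
                          method = c("fiducial", "correlation"),
                          smooth_window = 10, block_frames = 500,
                          bin = 0.05) {
  method <- match.arg(method)
  frames <- seq(min(table$frame), max(table$frame))
  if (method == "fiducial") {
    if (is.null(fiducials)) stop("fiducial tracks required")
    present <- tapply(fiducials$frame, fiducials$traj_id,
                      function(f) length(unique(f)))
    covered <- sort(unique(fiducials$frame))
    gaps <- setdiff(frames, covered)
    if (length(gaps) > smooth_window) {
      stop("fiducials lost for more than the smoothing window (",
           length(gaps), " frames)")
    }
    # per-fiducial displacement from its own first covered frame
    disp <- do.call(rbind, lapply(split(fiducials, fiducials$traj_id),
      function(f) {
        f <- f[order(f$frame), ]
        data.frame(frame = f$frame, dx = f$x - f$x[1], dy = f$y - f$y[1])
      }))
    dx <- tapply(disp$dx, factor(disp$frame, levels = frames), mean)
    dy <- tapply(disp$dy, factor(disp$frame, levels = frames), mean)
    # fill frames with no fiducial by interpolation
    dx <- approx(frames[!is.na(dx)], dx[!is.na(dx)], frames, rule = 2)$y
    dy <- approx(frames[!is.na(dy)], dy[!is.na(dy)], frames, rule = 2)$y
    src <- "fiducial"
  } else {
    blocks <- (table$frame - min(frames)) %/% block_frames
    xr <- range(table$x); yr <- range(table$y)
    bx <- seq(xr[1], xr[2] + bin, by = bin)
    by <- seq(yr[1], yr[2] + bin, by = bin)
    h2 <- function(sel) {
      ix <- findInterval(table$x[sel], bx, all.inside = TRUE)
      iy <- findInterval(table$y[sel], by, all.inside = TRUE)
      m <- matrix(0, length(by), length(bx))
      for (k in seq_along(ix)) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
      m
    }
    ref <- h2(blocks == 0)
    ub <- sort(unique(blocks))
    off <- t(vapply(ub, function(b) {
      if (b == 0) return(c(0, 0))
      xcorr_shift(ref, h2(blocks == b)) * bin
    }, numeric(2)))
    bf <- min(frames) + ub * block_frames + block_frames / 2
    dx <- approx(bf, off[, 1], frames, rule = 2)$y
    dy <- approx(bf, off[, 2], frames, rule = 2)$y
    src <- "correlation"
  }
  dx <- running_mean(dx, smooth_window)
  dy <- running_mean(dy, smooth_window)
  dx <- dx - dx[1]
  dy <- dy - dy[1]
  drift <- data.frame(frame = frames, dx = dx, dy = dy)
  attr(drift, "source") <- src
  class(drift) <- c("drift_model", "data.frame")
  ix <- match(table$frame, frames)
  corrected <- table
  corrected$x <- table$x - dx[ix]
  corrected$y <- table$y - dy[ix]
  list(table = corrected, drift = drift)
}

# sub-bin shift of image `b` relative to `a` by FFT cross-correlation with
# parabolic peak interpolation; returns c(dx, dy) in bins
xcorr_shift <- function(a, b) {
  H <- nrow(a); W <- ncol(a)
  fa <- fft(a); fb <- fft(b)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / (H * W)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den == 0) 0 else 0.5 * (m1 - p1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  di <- para(cc[wrap(pk[1] - 1, H), pk[2]], cc[pk[1], pk[2]],
             cc[wrap(pk[1] + 1, H), pk[2]])
  dj <- para(cc[pk[1], wrap(pk[2] - 1, W)], cc[pk[1], pk[2]],
             cc[pk[1], wrap(pk[2] + 1, W)])
  sh <- c(pk[2] - 1 + dj, pk[1] - 1 + di)
  sh[1] <- ifelse(sh[1] > W / 2, sh[1] - W, sh[1])
  sh[2] <- ifelse(sh[2] > H / 2, sh[2] - H, sh[2])
  -sh
}

#' Register one channel onto another from matched bead positions
#'
#' Least-squares similarity transform (translation + rotation + isotropic
#' scale, closed form) or full affine mapping channel B coordinates onto
#' channel A, from >= 3 matched bead pairs.
#'
#' @param beads_a,beads_b data frames with columns x, y (matched rows, um).
#' @param model "similarity" (default) or "affine".
#' @return list of class `channel_transform`: 2x2 matrix `M`, translation
#'   `t` (A = M b + t), `residual_rms` (um), `model`.
#' @export
register_channels <- function(beads_a, beads_b,
                              model = c("similarity", "affine")) {
  model <- match.arg(model)
  n <- nrow(beads_a)
  if (n < 3 || nrow(beads_b) != n) stop("need >= 3 matched bead pairs")
  A <- cbind(beads_a$x, beads_a$y)
  B <- cbind(beads_b$x, beads_b$y)
  if (model == "similarity") {
    ma <- colMeans(A); mb <- colMeans(B)
    Ac <- sweep(A, 2, ma); Bc <- sweep(B, 2, mb)
    S <- t(Ac) %*% Bc / n
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, d))
    R <- sv$u %*% D %*% t(sv$v)
    var_b <- sum(Bc^2) / n
    s <- sum(diag(D %*% diag(sv$d))) / var_b
    M <- s * R
    tt <- ma - as.vector(M %*% mb)
  } else {
    X <- cbind(B, 1)
    if (qr(X)$rank < 3) stop("collinear beads: full affine is degenerate")
    cf <- qr.solve(X, A)
    M <- t(cf[1:2, ])
    tt <- cf[3, ]
  }
  pred <- sweep(B %*% t(M), 2, tt, "+")
  rms <- sqrt(mean(rowSums((A - pred)^2)))
  structure(list(M = M, t = tt, residual_rms = rms, model = model,
                 n_pairs = n),
            class = "channel_transform")
}

#' Apply a channel transform to coordinates
#'
#' @param transform a `channel_transform` from [register_channels()].
#' @param xy data frame or matrix with columns x, y in the source (B) frame.
#' @return object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(transform, xy) {
  P <- if (is.data.frame(xy)) cbind(xy$x, xy$y) else xy[, 1:2, drop = FALSE]
  Q <- sweep(P %*% t(transform$M), 2, transform$t, "+")
  if (is.data.frame(xy)) {
    xy$x <- Q[, 1]; xy$y <- Q[, 2]; xy
  } else Q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
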