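#' Render a super-resolved localization map
#'
#' 2D count histogram of localization positions on a fine grid (default
#' 20 nm, matching the lateral resolution of dSTORM on cultured neurons).
#' The pixel sum equals the number of localizations.
#'
#' @param table data frame with x, y (um).
#' @param map_pixel map pixel side (um, default 0.02).
#' @param extent optional `c(xmin, ymin, xmax, ymax)` (um); defaults to the
#'   data bounding box.
#' @return object of class `superres_map`: `counts` (H x W matrix),
#'   `pixel_size`, `origin` = c(x0, y0).
#' @export
render_map <- function(table, map_pixel = 0.02, extent = NULL) {
  stopifnot(map_pixel > 0)
  if (is.null(extent)) {
    extent <- c(min(table$x), min(table$y), max(table$x), max(table$y))
  }
  x0 <- extent[1]; y0 <- extent[2]
  W <- max(1L, ceiling((extent[3] - x0) / map_pixel))
  H <- max(1L, ceiling((extent[4] - y0) / map_pixel))
  j <- pmin(pmax(floor((table$x - x0) / map_pixel) + 1, 1), W)
  i <- pmin(pmax(floor((table$y - y0) / map_pixel) + 1, 1), H)
  counts <- matrix(0, H, W)
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
  structure(list(counts = counts, pixel_size = map_pixel,
                 origin = c(x0, y0)),
            class = "superres_map")
}

#' Detect nanodomains on a super-resolved map
#'
#' Wavelet segmentation (as in [segment_marker()]) of the localization
#' count map: areas of high labelling density relative to their
#' neighbourhood become clusters. Clusters are tagged with the synapse
#' region containing their centroid when a `region_set` is supplied.
#'
#' @param map a `superres_map`.
#' @param regions optional `region_set` for synaptic tagging.
#' @param k wavelet threshold in noise-sd units (default 2).
#' @param min_area minimum cluster area (um^2, default 0.002).
#' @param level wavelet detail level.
#' @return object of class `domain_set`: `clusters` (data frame
#'   `label, x, y, area, n_px, n_loc, region`), `labels` matrix,
#'   `per_um2` (clusters per um^2 of map), the map, and `per_synapse`
#'   (data frame) when regions are given.
#' @export
detect_domains <- function(map, regions = NULL, k = 2.0, min_area = 0.002,
                           level = 2) {
  stopifnot(inherits(map, "superres_map"), k > 0)
  px <- map$pixel_size
  wt <- atrous_wavelet(map$counts, level)
  # count histograms are zero-inflated, which collapses the MAD; floor the
  # noise estimate with the plain sd of the first detail plane
  d1 <- wt$details[[1]]
  noise <- max(mad(d1), sd(d1)) / 0.8908
  w <- wt$details[[level]]
  mask <- if (noise > 0) w > k * noise else w > 0
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  min_px <- ceiling(min_area / px^2)
  keep <- integer(0)
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(sizes >= min_px)
  }
  relab <- integer(n + 1)
  relab[keep + 1] <- seq_along(keep)
  labels <- matrix(relab[lab + 1], nrow(lab), ncol(lab))
  if (length(keep) == 0) {
    clusters <- data.frame(label = integer(0), x = numeric(0),
                           y = numeric(0), area = numeric(0),
                           n_px = integer(0), n_loc = numeric(0),
                           region = integer(0))
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    l <- labels[labels > 0]
    wgt <- map$counts[labels > 0]
    sw <- tapply(wgt, l, sum)
    cx <- as.numeric(tapply((idx[, 2] - 0.5) * wgt, l, sum) / sw) * px +
      map$origin[1]
    cy <- as.numeric(tapply((idx[, 1] - 0.5) * wgt, l, sum) / sw) * px +
      map$origin[2]
    clusters <- data.frame(
      label = seq_along(keep), x = cx, y = cy,
      area = as.numeric(table(l)) * px^2,
      n_px = as.integer(table(l)),
      n_loc = as.numeric(sw),
      region = 0L)
    if (!is.null(regions)) {
      clusters$region <- as.integer(region_label_at(regions, cx, cy))
    }
  }
  out <- list(clusters = clusters, labels = labels,
              per_um2 = nrow(clusters) /
                (prod(dim(map$counts)) * px^2),
              map = map)
  if (!is.null(regions) && nrow(regions$regions) > 0) {
    out$per_synapse <- data.frame(
      label = regions$regions$label,
      n_domains = as.integer(tabulate(clusters$region[clusters$region > 0],
                                      nbins = nrow(regions$regions))))
  }
  structure(out, class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set: %d cluster(s), %.2f per um^2\n",
              nrow(x$clusters), x$per_um2))
  invisible(x)
}

# residuals of a 2D Gaussian on map pixels
# iso:  par = (A = total counts, x0, y0, s, offset), pixel-integrated so the
#       count histogram's binning does not bias sigma
# aniso: par = (A = peak, x0, y0, sx, sy, theta, offset), sampled at pixel
#       centres (integration is not separable under rotation; binning is
#       removed afterwards by Sheppard's correction)
gauss2d_resid <- function(par, vals, xs, ys, iso, px = NULL) {
  if (iso) {
    fy <- pnorm(ys + px / 2, par[3], par[4]) -
      pnorm(ys - px / 2, par[3], par[4])
    fx <- pnorm(xs + px / 2, par[2], par[4]) -
      pnorm(xs - px / 2, par[2], par[4])
    g <- par[1] * fy * fx + par[5]
  } else {
    ct <- cos(par[6]); st <- sin(par[6])
    u <- ct * (xs - par[2]) + st * (ys - par[3])
    v <- -st * (xs - par[2]) + ct * (ys - par[3])
    g <- par[1] * exp(-u^2 / (2 * par[4]^2) - v^2 / (2 * par[5]^2)) +
      par[7]
  }
  g - vals
}

#' Size a nanodomain by Gaussian fitting
#'
#' Least-squares 2D Gaussian fit on the cluster's bounding window of the
#' count map. The reported length is the full-width at half-maximum,
#' `FWHM = 2 sqrt(2 ln 2) sigma`; anisotropic fits (one sigma per axis plus
#' rotation) report the mean of the two axis FWHMs. Fits whose residuals
#' stay large relative to the fitted amplitude are flagged as poor.
#'
#' @param map a `superres_map`.
#' @param domains a `domain_set` from [detect_domains()].
#' @param label cluster label to fit.
#' @param isotropic single sigma (default) or per-axis sigmas with
#'   rotation.
#' @param pad extra pixels around the cluster bounding box.
#' @return list of class `domain_fit`: `center` (um), `fwhm_x`, `fwhm_y`,
#'   `length` (um), `amplitude`, `isotropic`, `converged`, `good_fit`
#'   (Pearson chi-square per pixel below 2), `r_squared`, `chi2`.
#' @export
fit_domain <- function(map, domains, label, isotropic = TRUE, pad = NULL) {
  cl <- domains$clusters[domains$clusters$label == label, ]
  if (nrow(cl) != 1) stop("unknown cluster label")
  if (cl$n_px < 4) stop("cluster smaller than 4 pixels")
  px <- map$pixel_size
  idx <- which(domains$labels == label, arr.ind = TRUE)
  H <- nrow(map$counts); W <- ncol(map$counts)
  # window must reach well beyond the bright core or sigma is biased low
  if (is.null(pad)) pad <- max(4, ceiling(2 * sqrt(cl$area / pi) / px))
  ri <- max(1, min(idx[, 1]) - pad):min(H, max(idx[, 1]) + pad)
  cj <- max(1, min(idx[, 2]) - pad):min(W, max(idx[, 2]) + pad)
  vals <- map$counts[ri, cj]
  xs <- matrix((cj - 0.5) * px + map$origin[1], length(ri), length(cj),
               byrow = TRUE)
  ys <- matrix((ri - 0.5) * px + map$origin[2], length(ri), length(cj))
  s0 <- max(sqrt(cl$area / pi) / 1.5, px)
  if (isotropic) {
    start <- c(sum(vals), cl$x, cl$y, s0, 0)
    lower <- c(0, -Inf, -Inf, px / 4, -Inf)
    upper <- rep(Inf, 5)
  } else {
    # moment-based start: principal axes of the intensity distribution
    wv <- pmax(as.vector(vals), 0)
    mx <- sum(wv * xs) / sum(wv); my <- sum(wv * ys) / sum(wv)
    cxx <- sum(wv * (xs - mx)^2) / sum(wv)
    cyy <- sum(wv * (ys - my)^2) / sum(wv)
    cxy <- sum(wv * (xs - mx) * (ys - my)) / sum(wv)
    th0 <- 0.5 * atan2(2 * cxy, cxx - cyy)
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2))$values
    s_major <- sqrt(max(ev[1], px^2 / 16))
    s_minor <- sqrt(max(ev[2], px^2 / 16))
    start <- c(max(vals), cl$x, cl$y, s_major, s_minor, th0, 0)
    lower <- c(0, -Inf, -Inf, px / 4, px / 4, -pi, -Inf)
    upper <- c(Inf, Inf, Inf, Inf, Inf, pi, Inf)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = gauss2d_resid, vals = vals,
                       xs = xs, ys = ys, iso = isotropic, px = px,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) {
    return(structure(list(center = c(NA, NA), fwhm_x = NA, fwhm_y = NA,
                          length = NA, amplitude = NA,
                          isotropic = isotropic, converged = FALSE,
                          good_fit = FALSE, r_squared = NA),
                     class = "domain_fit"))
  }
  p <- fit$par
  f <- 2 * sqrt(2 * log(2))
  shep <- function(s) sqrt(max(s^2 - px^2 / 12, (px / 4)^2))
  if (isotropic) {
    fwhm_x <- fwhm_y <- f * abs(p[4])
  } else {
    fwhm_x <- f * shep(abs(p[4])); fwhm_y <- f * shep(abs(p[5]))
  }
  res <- gauss2d_resid(p, vals, xs, ys, isotropic, px)
  r2 <- 1 - sum(res^2) / sum((vals - mean(vals))^2)
  # Pearson chi-square per pixel: ~1 when residuals are only counting
  # noise, inflated when the Gaussian shape itself is wrong
  mu <- as.vector(vals) + as.vector(res)
  chi2 <- mean(res^2 / pmax(mu, 0.25))
  structure(list(center = c(p[2], p[3]), fwhm_x = fwhm_x, fwhm_y = fwhm_y,
                 length = mean(c(fwhm_x, fwhm_y)), amplitude = p[1],
                 isotropic = isotropic, converged = TRUE,
                 good_fit = chi2 < 2, r_squared = r2, chi2 = chi2),
            class = "domain_fit")
}

#' @export
print.domain_fit <- function(x, ...) {
  if (!x$converged) cat("domain fit: did not converge\n")
  else cat(sprintf("domain fit: length %.1f nm (R^2 %.2f%s)\n",
                   1000 * x$length, x$r_squared,
                   if (x$good_fit) "" else ", poor fit"))
  invisible(x)
}

#' Pair apposed domains across two channels
#'
#' Optimal matching of domain centres between channels (e.g. a presynaptic
#' adhesion protein against its postsynaptic partner): minimizes the total
#' centre-to-centre distance with a fixed penalty per unmatched domain, so
#' a pair forms only within the distance cap. Each domain enters at most
#' one pair.
#'
#' @param dom_a,dom_b data frames with columns x, y (um), channels already
#'   registered into a common frame.
#' @param cap pairing distance cap (um, default 0.2).
#' @return list of class `apposed_pairs`: `pairs` (data frame
#'   `a, b, distance`), `n_paired`, `n_a_only`, `n_b_only`.
#' @export
pair_apposed <- function(dom_a, dom_b, cap = 0.2) {
  stopifnot(cap > 0)
  na <- nrow(dom_a); nb <- nrow(dom_b)
  if (na == 0 || nb == 0) {
    pairs <- data.frame(a = integer(0), b = integer(0),
                        distance = numeric(0))
  } else {
    d <- sqrt(outer(dom_a$x, dom_b$x, "-")^2 +
                outer(dom_a$y, dom_b$y, "-")^2)
    cost <- d
    cost[cost > cap] <- Inf
    m <- match_partial(cost, cap)
    sel <- which(!is.na(m))
    pairs <- data.frame(a = sel, b = m[sel],
                        distance = d[cbind(sel, m[sel])])
  }
  structure(list(pairs = pairs, n_paired = nrow(pairs),
                 n_a_only = na - nrow(pairs),
                 n_b_only = nb - nrow(pairs)),
            class = "apposed_pairs")
}
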