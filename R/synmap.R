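#' Segment synapses from a postsynaptic marker image
#'
#' Wavelet segmentation of a marker channel (e.g. a Homer1c fusion marking
#' postsynaptic densities): the level-2 a-trous detail plane is thresholded
#' at `k` times the robust noise sd, connected components are labelled and
#' regions smaller than `min_area` removed. A uniform image yields an empty
#' region set.
#'
#' @param marker 2D numeric matrix.
#' @param pixel_size um per pixel.
#' @param k threshold in noise-sd units (default 2).
#' @param min_area minimum region area (um^2, default 0.02).
#' @param level wavelet detail level.
#' @return object of class `region_set`: `labels` (H x W integer matrix,
#'   0 = background, regions numbered contiguously from 1), `regions`
#'   (data frame `label, x, y, area` with centroids in um and areas in
#'   um^2), `pixel_size`.
#' @export
segment_marker <- function(marker, pixel_size, k = 2.0, min_area = 0.02,
                           level = 2) {
  stopifnot(is.matrix(marker), pixel_size > 0, k > 0)
  wt <- atrous_wavelet(marker, level)
  noise <- robust_noise_sd(wt$details)
  w <- wt$details[[level]]
  mask <- if (noise > 0) w > k * noise else w > 0
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  min_px <- ceiling(min_area / pixel_size^2)
  keep <- integer(0)
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(sizes >= min_px)
  }
  relab <- integer(n + 1)
  relab[keep + 1] <- seq_along(keep)
  labels <- matrix(relab[lab + 1], nrow(lab), ncol(lab))
  if (length(keep) == 0) {
    regions <- data.frame(label = integer(0), x = numeric(0),
                          y = numeric(0), area = numeric(0))
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    l <- labels[labels > 0]
    regions <- data.frame(
      label = seq_along(keep),
      x = as.numeric(tapply(idx[, 2] - 0.5, l, mean)) * pixel_size,
      y = as.numeric(tapply(idx[, 1] - 0.5, l, mean)) * pixel_size,
      area = as.numeric(table(l)) * pixel_size^2)
  }
  structure(list(labels = labels, regions = regions,
                 pixel_size = pixel_size),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s), total area %.3f um^2\n",
              nrow(x$regions), sum(x$regions$area)))
  invisible(x)
}

# region label at each (x, y) position; 0 for background or out of bounds
region_label_at <- function(regions, x, y) {
  px <- regions$pixel_size
  i <- floor(y / px) + 1
  j <- floor(x / px) + 1
  H <- nrow(regions$labels); W <- ncol(regions$labels)
  ok <- i >= 1 & i <= H & j >= 1 & j <= W & is.finite(i) & is.finite(j)
  lab <- integer(length(x))
  lab[ok] <- regions$labels[cbind(i[ok], j[ok])]
  attr(lab, "out_of_bounds") <- which(!ok)
  lab
}

#' Sort localizations into synaptic and extrasynaptic pools
#'
#' A localization is synaptic iff it falls on a labelled pixel of the
#' segmented marker mask; positions outside the image count as
#' extrasynaptic and are flagged.
#'
#' @param table a [loc_table()] or any data frame with x, y (um), in the
#'   marker's coordinate frame (after drift correction / registration).
#' @param regions a `region_set` from [segment_marker()].
#' @return the input with added columns `region` (0 = extrasynaptic) and
#'   `synaptic` (logical); attribute `out_of_bounds` lists flagged row
#'   indices.
#' @export
sort_localizations <- function(table, regions) {
  lab <- region_label_at(regions, table$x, table$y)
  oob <- attr(lab, "out_of_bounds")
  if (length(oob)) sm_log("warning", length(oob),
                          " localization(s) outside image bounds")
  table$region <- as.integer(lab)
  table$synaptic <- table$region > 0
  attr(table, "out_of_bounds") <- oob
  table
}

#' Synapse-referenced detection statistics
#'
#' Computes the standard sorting metrics: the percentage of synapses
#' containing the target (at least `min_detections` detections), the
#' synaptic coverage (occupied fraction of the synaptic area, occupancy by
#' rasterizing detections at `fwhm / 2`), the percentage of synaptic
#' detections, and the synaptic enrichment (synaptic detection density over
#' extrasynaptic density on the cell footprint).
#'
#' @param table a [loc_table()] (or data frame with x, y).
#' @param regions a `region_set`.
#' @param min_detections detections needed for a synapse to count as
#'   containing the target (default 10).
#' @param fwhm spatial resolution (um) setting the coverage raster.
#' @param cell_mask optional logical H x W matrix of the cell footprint
#'   (e.g. a low-threshold marker mask); defaults to the whole image. The
#'   extrasynaptic reference area is the footprint minus the synapse
#'   regions.
#' @return list of class `synapse_metrics`: `percent_synapses_with_target`,
#'   `synaptic_coverage`, `percent_synaptic_detections`, `enrichment`,
#'   `per_synapse_counts` (data frame).
#' @export
synapse_metrics <- function(table, regions, min_detections = 10,
                            fwhm = 0.054, cell_mask = NULL) {
  if (nrow(regions$regions) == 0) stop("empty region set")
  if (nrow(table) == 0) stop("zero detections: metrics undefined")
  px <- regions$pixel_size
  lab <- region_label_at(regions, table$x, table$y)
  n_reg <- nrow(regions$regions)
  counts <- tabulate(lab[lab > 0], nbins = n_reg)
  syn <- lab > 0
  # coverage: raster cells (fwhm/2) containing synaptic detections,
  # capped by the total synaptic area
  raster <- fwhm / 2
  occ_cells <- unique(paste(floor(table$x[syn] / raster),
                            floor(table$y[syn] / raster)))
  syn_area <- sum(regions$regions$area)
  coverage <- min(100, 100 * length(occ_cells) * raster^2 / syn_area)
  if (is.null(cell_mask)) {
    cell_mask <- matrix(TRUE, nrow(regions$labels), ncol(regions$labels))
  }
  extra_area <- sum(cell_mask & regions$labels == 0) * px^2
  syn_density <- sum(syn) / syn_area
  extra_density <- sum(!syn) / extra_area
  enrichment <- if (extra_density > 0) syn_density / extra_density else Inf
  structure(list(
    percent_synapses_with_target =
      100 * sum(counts >= min_detections) / n_reg,
    synaptic_coverage = coverage,
    percent_synaptic_detections = 100 * sum(syn) / length(syn),
    enrichment = enrichment,
    per_synapse_counts = data.frame(label = seq_len(n_reg),
                                    n_detections = counts)),
    class = "synapse_metrics")
}

#' @export
print.synapse_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "synapses with target: %.1f%%  coverage: %.1f%%  ",
    "synaptic detections: %.1f%%  enrichment: %.2f\n"),
    x$percent_synapses_with_target, x$synaptic_coverage,
    x$percent_synaptic_detections, x$enrichment))
  invisible(x)
}

#' Dispersion of detections about synapse centroids
#'
#' Euclidean distances between each synaptic detection and the centroid of
#' its synapse, pooled across synapses.
#'
#' @param table data frame with x, y (um).
#' @param regions a `region_set`.
#' @return list: `distances` (um), `median`, `q25`, `q75`.
#' @export
dispersion_from_centroid <- function(table, regions) {
  lab <- region_label_at(regions, table$x, table$y)
  sel <- lab > 0
  if (!any(sel)) {
    return(list(distances = numeric(0), median = NA_real_,
                q25 = NA_real_, q75 = NA_real_))
  }
  cx <- regions$regions$x[lab[sel]]
  cy <- regions$regions$y[lab[sel]]
  d <- sqrt((table$x[sel] - cx)^2 + (table$y[sel] - cy)^2)
  list(distances = d, median = median(d),
       q25 = quantile(d, 0.25, names = FALSE),
       q75 = quantile(d, 0.75, names = FALSE))
}

#' Detection density map
#'
#' For every localization, the number of other localizations within a
#' neighbourhood radius (the focal point itself is excluded). Computed with
#' a cell-list so large dSTORM tables stay tractable.
#'
#' @param table data frame with x, y (um).
#' @param radius neighbourhood radius (um, default 0.4).
#' @return integer vector of neighbour counts, one per localization.
#' @export
density_map <- function(table, radius = 0.4) {
  stopifnot(radius > 0)
  n <- nrow(table)
  if (n == 0) return(integer(0))
  x <- table$x; y <- table$y
  cx <- floor(x / radius); cy <- floor(y / radius)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  counts <- integer(n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    cnt <- 0L
    for (ox in -1:1) for (oy in -1:1) {
      k <- paste(cx[i] + ox, cy[i] + oy)
      nb <- cells[[k]]
      if (!is.null(nb)) {
        d2 <- (x[nb] - x[i])^2 + (y[nb] - y[i])^2
        cnt <- cnt + sum(d2 <= r2)
      }
    }
    counts[i] <- cnt - 1L   # self
  }
  counts
}

#' Normalized trajectory-count time course
#'
#' Per-interval trajectory counts divided by the count in a baseline
#' interval (e.g. before a pharmacological treatment).
#'
#' @param counts vector of trajectory counts per pooled time interval.
#' @param baseline index of the baseline interval (default 1).
#' @return numeric vector of normalized counts.
#' @export
timecourse_counts <- function(counts, baseline = 1) {
  stopifnot(baseline >= 1, baseline <= length(counts))
  if (counts[baseline] <= 0) stop("zero baseline count")
  counts / counts[baseline]
}
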