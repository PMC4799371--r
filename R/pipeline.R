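#' Run the analysis pipeline end to end
#'
#' Drives the full chain on one experiment. For a tracking (uPAINT) input
#' - an image stack plus optional marker image - the stages are spot
#' detection, sub-pixel refinement, trajectory linking, mobility analysis,
#' and (with a marker) synapse segmentation and sorting metrics. For a
#' localization-table (dSTORM) input the stages are super-resolved map
#' rendering, nanodomain detection and sizing, and (with a marker) synapse
#' metrics. All intermediate tables are written as CSV into `out_dir`
#' together with a provenance record (config hash, package version). Given
#' the same config (including its seed) the outputs are identical across
#' runs.
#'
#' @param config an [analysis_config()].
#' @param inputs list with either `stack` (an [image_stack()] or TIFF path)
#'   or `table` (a [loc_table()] or CSV path), plus optional `marker`
#'   (matrix or TIFF path).
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_result` with the computed tables and
#'   metrics; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- inputs$marker
  if (is.character(marker)) marker <- read_stack(
    marker, pixel_size = config$pixel_size,
    frame_interval = config$frame_interval)$frames[1, , ]
  result <- list(config = config)
  mode <- inputs$mode %||%
    (if (!is.null(inputs$stack)) "upaint" else "dstorm")
  if (mode == "upaint" && is.null(inputs$stack)) {
    if (!is.null(inputs$table) &&
        is.null(attr(inputs$table, "frame_interval"))) {
      stop("missing frame_interval: uPAINT analysis needs time-calibrated ",
           "input")
    }
    stop("uPAINT analysis requires an image stack")
  }

  if (!is.null(inputs$stack)) {
    stack <- inputs$stack
    if (is.character(stack)) stack <- read_stack(
      stack, pixel_size = config$pixel_size,
      frame_interval = config$frame_interval)
    if (abs(stack$pixel_size - config$pixel_size) >
        1e-9 * config$pixel_size) {
      stop("inconsistent pixel metadata between config and stack")
    }
    sm_log("info", "detecting spots")
    cand <- detect_spots(stack, level = config$wavelet_level,
                         k = config$detect_k)
    locs <- refine_subpixel(stack, cand, window = config$fit_window,
                            psf_sigma = config$psf_sigma)
    write_localizations(locs, file.path(out_dir, "localizations.csv"))
    sm_log("info", "linking ", nrow(locs), " localizations")
    traj <- link_detections(locs, d_max = config$d_max,
                            max_gap = config$max_gap,
                            solver = config$solver, seed = config$seed)
    write_trajectories(traj, file.path(out_dir, "trajectories.csv"))
    d_thr <- slow_threshold(config$fwhm, config$n_fit,
                            stack$frame_interval)
    mob <- compute_mobility(traj, dt = stack$frame_interval,
                            n_fit = config$n_fit,
                            d_floor = config$d_floor,
                            d_threshold = d_thr)
    write.csv(as.data.frame(mob), file.path(out_dir, "mobility.csv"),
              row.names = FALSE, quote = FALSE)
    result$localizations <- locs
    result$trajectories <- traj
    result$mobility <- mob
    result$metrics <- list(
      n_localizations = nrow(locs),
      n_trajectories = length(unique(traj$traj_id)),
      d_threshold = d_thr)
    if (nrow(mob) > 0) {
      cf <- classify_and_fractions(mob, d_thr)
      result$metrics$slow_fraction <- cf$slow_fraction
      result$metrics$median_D <- median(mob$D_inst)
    }
    if (!is.null(marker)) {
      regions <- segment_marker(marker, config$pixel_size,
                                k = config$detect_k,
                                min_area = config$min_area)
      result$regions <- regions
      if (nrow(regions$regions) > 0 && nrow(locs) > 0) {
        sm <- synapse_metrics(locs, regions,
                              min_detections = config$min_detections,
                              fwhm = config$fwhm)
        result$synapse_metrics <- sm
        result$metrics$percent_synaptic_detections <-
          sm$percent_synaptic_detections
        result$metrics$enrichment <- sm$enrichment
      }
    }
  } else if (!is.null(inputs$table)) {
    tab <- inputs$table
    if (is.character(tab)) tab <- read_localizations(tab)
    map <- render_map(tab, map_pixel = config$map_pixel)
    regions <- NULL
    if (!is.null(marker)) {
      regions <- segment_marker(marker, config$pixel_size,
                                k = config$detect_k,
                                min_area = config$min_area)
      result$regions <- regions
    }
    doms <- detect_domains(map, regions = regions, k = config$detect_k)
    write.csv(doms$clusters, file.path(out_dir, "domains.csv"),
              row.names = FALSE, quote = FALSE)
    result$map <- map
    result$domains <- doms
    result$metrics <- list(n_localizations = nrow(tab),
                           n_clusters = nrow(doms$clusters),
                           clusters_per_um2 = doms$per_um2)
    if (!is.null(regions) && nrow(regions$regions) > 0) {
      sm <- synapse_metrics(tab, regions,
                            min_detections = config$min_detections,
                            fwhm = config$fwhm)
      result$synapse_metrics <- sm
      result$metrics$enrichment <- sm$enrichment
    }
  } else {
    stop("inputs must contain a 'stack' (uPAINT) or a 'table' (dSTORM)")
  }

  provenance <- list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("synaptomap")),
    seed = config$seed)
  jsonlite::write_json(c(result$metrics, provenance),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  for (k in names(x$metrics)) {
    v <- x$metrics[[k]]
    cat(sprintf("  %s: %s\n", k,
                if (is.numeric(v)) format(signif(v, 4)) else v))
  }
  invisible(x)
}
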