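#' Define a dendrite / synapse geometry for simulation
#'
#' A rectangular dendrite membrane patch carrying circular synaptic disks
#' (postsynaptic-density footprints), each optionally subdivided into
#' nanodomain subcentres used by the dSTORM simulator.
#'
#' @param region numeric `c(xmin, ymin, xmax, ymax)` in micrometres.
#' @param synapses data frame with columns `x`, `y`, `r` (centre and radius,
#'   um); radii 0.1-0.3 um are typical of postsynaptic densities.
#' @param domains optional list (one element per synapse) of data frames
#'   with columns `x`, `y`: nanodomain subcentres inside that synapse.
#' @return an object of class `synapse_layout`.
#' @export
synapse_layout <- function(region, synapses = NULL, domains = NULL) {
  stopifnot(length(region) == 4, region[3] > region[1], region[4] > region[2])
  if (is.null(synapses)) {
    synapses <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  }
  stopifnot(all(c("x", "y", "r") %in% names(synapses)))
  if (nrow(synapses) > 0) {
    if (any(synapses$r <= 0)) stop("synapse radii must be > 0")
    inside <- synapses$x - synapses$r >= region[1] &
      synapses$x + synapses$r <= region[3] &
      synapses$y - synapses$r >= region[2] &
      synapses$y + synapses$r <= region[4]
    if (!all(inside)) stop("synapse disks must lie inside the region")
  }
  if (!is.null(domains)) stopifnot(length(domains) == nrow(synapses))
  structure(list(region = as.numeric(region), synapses = synapses,
                 domains = domains),
            class = "synapse_layout")
}

#' Camera and PSF model for movie rendering
#'
#' @param psf_sigma PSF standard deviation (um), > 0.
#' @param photons expected photons emitted per molecule per frame.
#' @param background mean background level per pixel (photons).
#' @param read_sd Gaussian read-noise standard deviation (counts).
#' @param gain counts per photon.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(psf_sigma = 0.1, photons = 500, background = 10,
                         read_sd = 1, gain = 1) {
  stopifnot(psf_sigma > 0, photons >= 0, background >= 0, read_sd >= 0,
            gain >= 0)
  structure(list(psf_sigma = psf_sigma, photons = photons,
                 background = background, read_sd = read_sd, gain = gain),
            class = "camera_model")
}

# reflect positions into [lo, hi] (single bounce is enough when steps are
# small relative to the box; iterate to be safe)
reflect1 <- function(p, lo, hi) {
  span <- hi - lo
  while (any(p < lo | p > hi)) {
    p <- ifelse(p < lo, 2 * lo - p, p)
    p <- ifelse(p > hi, 2 * hi - p, p)
    if (span <= 0) break
  }
  p
}

#' Simulate single-particle tracking ground truth
#'
#' Molecules perform 2D Brownian motion (per-axis step variance
#' `2 * D_free * dt`) over the dendrite region with reflecting boundaries.
#' A free molecule that sits inside a synapse disk becomes trapped with
#' per-frame probability `1 - exp(-k_on * dt)`; a trapped molecule diffuses
#' with `D_trap` confined to its disk (radially reflecting) and is released
#' with probability `1 - exp(-k_off * dt)`. Bleaching removes a molecule
#' permanently with probability `1 - exp(-bleach_rate * dt)` per frame.
#'
#' @param layout a [synapse_layout()].
#' @param n_molecules number of molecules, initialized uniformly.
#' @param D_free,D_trap diffusion coefficients (um^2/s).
#' @param k_on,k_off trapping/release rates (s^-1).
#' @param bleach_rate photobleaching rate (s^-1).
#' @param n_frames number of frames.
#' @param dt frame interval (s).
#' @param seed RNG seed.
#' @return data frame of class `sim_truth` with columns
#'   `molecule, frame, x, y, state` (state `free` or `trapped`; rows stop at
#'   the bleaching frame).
#' @export
simulate_spt <- function(layout, n_molecules, D_free = 0.2, D_trap = 0.005,
                         k_on = 10, k_off = 1, bleach_rate = 0,
                         n_frames = 100, dt = 0.02, seed = 1) {
  stopifnot(inherits(layout, "synapse_layout"), n_molecules >= 1,
            D_free >= 0, D_trap >= 0, k_on >= 0, k_off >= 0,
            bleach_rate >= 0, dt > 0, n_frames >= 1)
  if (k_on > 0 && nrow(layout$synapses) == 0) {
    stop("trapping requested (k_on > 0) but layout has no synapses")
  }
  reg <- layout$region
  syn <- layout$synapses
  p_on <- 1 - exp(-k_on * dt)
  p_off <- 1 - exp(-k_off * dt)
  p_bleach <- 1 - exp(-bleach_rate * dt)
  with_seed(seed, {
    x <- runif(n_molecules, reg[1], reg[3])
    y <- runif(n_molecules, reg[2], reg[4])
    state <- rep("free", n_molecules)
    trap_id <- rep(NA_integer_, n_molecules)
    alive <- rep(TRUE, n_molecules)
    out <- vector("list", n_frames)
    sd_free <- sqrt(2 * D_free * dt)
    sd_trap <- sqrt(2 * D_trap * dt)
    which_synapse <- function(x, y) {
      hit <- rep(NA_integer_, length(x))
      for (s in seq_len(nrow(syn))) {
        d2 <- (x - syn$x[s])^2 + (y - syn$y[s])^2
        hit[is.na(hit) & d2 <= syn$r[s]^2] <- s
      }
      hit
    }
    for (t in seq_len(n_frames)) {
      if (t > 1) {
        # bleaching
        if (p_bleach > 0) alive <- alive & (runif(n_molecules) >= p_bleach)
        free <- alive & state == "free"
        trapped <- alive & state == "trapped"
        nf <- sum(free)
        if (nf > 0 && sd_free > 0) {
          x[free] <- reflect1(x[free] + rnorm(nf, 0, sd_free), reg[1], reg[3])
          y[free] <- reflect1(y[free] + rnorm(nf, 0, sd_free), reg[2], reg[4])
        }
        nt <- sum(trapped)
        if (nt > 0) {
          if (sd_trap > 0) {
            xi <- x[trapped] + rnorm(nt, 0, sd_trap)
            yi <- y[trapped] + rnorm(nt, 0, sd_trap)
          } else {
            xi <- x[trapped]; yi <- y[trapped]
          }
          # radial reflection at the disk boundary
          s <- trap_id[trapped]
          cx <- syn$x[s]; cy <- syn$y[s]; r <- syn$r[s]
          dx <- xi - cx; dy <- yi - cy
          rad <- sqrt(dx^2 + dy^2)
          over <- rad > r & rad > 0
          if (any(over)) {
            fac <- (2 * r[over] - rad[over]) / rad[over]
            fac <- pmax(fac, 0)   # large excursions land at the centre side
            dx[over] <- dx[over] * fac
            dy[over] <- dy[over] * fac
          }
          x[trapped] <- cx + dx
          y[trapped] <- cy + dy
        }
        # release, then capture (memoryless per frame)
        if (nt > 0 && p_off > 0) {
          rel <- trapped
          rel[trapped] <- runif(nt) < p_off
          state[rel] <- "free"
          trap_id[rel] <- NA_integer_
        }
        free <- alive & state == "free"
        if (any(free) && p_on > 0 && nrow(syn) > 0) {
          hit <- which_synapse(x[free], y[free])
          cap <- !is.na(hit) & runif(sum(free)) < p_on
          idx <- which(free)[cap]
          state[idx] <- "trapped"
          trap_id[idx] <- hit[cap]
        }
      }
      if (any(alive)) {
        out[[t]] <- data.frame(molecule = which(alive), frame = t - 1L,
                               x = x[alive], y = y[alive],
                               state = state[alive])
      }
    }
    truth <- do.call(rbind, out)
    truth <- truth[order(truth$molecule, truth$frame), ]
    rownames(truth) <- NULL
    class(truth) <- c("sim_truth", "data.frame")
    attr(truth, "dt") <- dt
    truth
  })
}

# expected photon count of an integrated 2D Gaussian emitter in each pixel
# of a window; positions in um, grid in px of size `px`
render_emitter <- function(frame_mat, x, y, photons, psf_sigma, px) {
  H <- nrow(frame_mat); W <- ncol(frame_mat)
  ci <- y / px + 0.5   # fractional row index of the centre
  cj <- x / px + 0.5
  halfw <- ceiling(4 * psf_sigma / px)
  i0 <- max(1, floor(ci - halfw)); i1 <- min(H, ceiling(ci + halfw))
  j0 <- max(1, floor(cj - halfw)); j1 <- min(W, ceiling(cj + halfw))
  if (i0 > i1 || j0 > j1) return(frame_mat)
  ii <- i0:i1; jj <- j0:j1
  # pixel i spans y in [(i-1)*px, i*px)
  fy <- pnorm(ii * px, y, psf_sigma) - pnorm((ii - 1) * px, y, psf_sigma)
  fx <- pnorm(jj * px, x, psf_sigma) - pnorm((jj - 1) * px, x, psf_sigma)
  frame_mat[ii, jj] <- frame_mat[ii, jj] + photons * (fy %o% fx)
  frame_mat
}

#' Render a simulated movie and marker channel
#'
#' Each emitting molecule is rendered as an integrated 2D Gaussian PSF;
#' Poisson photon noise, constant background and Gaussian read noise are
#' added (disable with `noise = FALSE` for deterministic fixtures). A
#' second, static marker image renders the synapse disks as Gaussian puncta
#' (a Homer1c-like postsynaptic marker channel).
#'
#' @param truth a `sim_truth` from [simulate_spt()].
#' @param layout the [synapse_layout()] used for the simulation.
#' @param camera a [camera_model()].
#' @param size `c(H, W)` image size in pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @param marker_photons peak marker intensity per synapse.
#' @param noise add Poisson + read noise (default TRUE).
#' @param seed RNG seed.
#' @return list with elements `stack` (an [image_stack()]) and `marker`
#'   (H x W matrix).
#' @export
render_movie <- function(truth, layout, camera, size, pixel_size,
                         frame_interval = 0.02, marker_photons = 2000,
                         noise = TRUE, seed = 1) {
  stopifnot(inherits(camera, "camera_model"), pixel_size > 0)
  H <- size[1]; W <- size[2]
  n_frames <- max(truth$frame) + 1L
  frames <- array(0, c(n_frames, H, W))
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      fm <- matrix(camera$background, H, W)
      rows <- truth[truth$frame == t - 1L, ]
      for (k in seq_len(nrow(rows))) {
        fm <- render_emitter(fm, rows$x[k], rows$y[k], camera$photons,
                             camera$psf_sigma, pixel_size)
      }
      if (noise) {
        fm <- matrix(rpois(H * W, fm), H, W)
        if (camera$read_sd > 0) {
          fm <- fm + matrix(rnorm(H * W, 0, camera$read_sd), H, W)
        }
        fm[fm < 0] <- 0
      }
      frames[t, , ] <- fm * camera$gain
    }
    marker <- matrix(0, H, W)
    syn <- layout$synapses
    for (s in seq_len(nrow(syn))) {
      marker <- render_emitter(marker, syn$x[s], syn$y[s],
                               marker_photons, syn$r[s], pixel_size)
    }
    marker <- marker + camera$background
    if (noise) {
      marker <- matrix(rpois(H * W, marker), H, W)
      if (camera$read_sd > 0) {
        marker <- marker + matrix(rnorm(H * W, 0, camera$read_sd), H, W)
      }
      marker[marker < 0] <- 0
    }
    list(stack = image_stack(frames, pixel_size, frame_interval),
         marker = marker)
  })
}

#' Simulate a dSTORM-like blink localization table
#'
#' Molecule positions are drawn as 2D normals around each synapse's
#' nanodomain subcentres (spread `domain_sd`) plus a uniform shaft
#' population over the region; each molecule emits a geometric number of
#' blinks (mean `mean_blinks`), each jittered by the localization precision.
#'
#' @param layout a [synapse_layout()]; synapses without explicit domains use
#'   their centre as a single domain.
#' @param mols_per_domain molecules per nanodomain.
#' @param domain_sd nanodomain spread (um), e.g. 0.04 for an 80-nm-scale
#'   domain.
#' @param sigma_loc localization precision sd per axis (um), >= 0.
#' @param mean_blinks mean blinks per molecule (geometric, >= 1).
#' @param shaft_density extrasynaptic molecule density (um^-2).
#' @param n_frames frames over which blinks are spread.
#' @param seed RNG seed.
#' @return a [loc_table()]; attribute `truth` holds the molecule positions.
#' @export
simulate_smlm <- function(layout, mols_per_domain = 50, domain_sd = 0.04,
                          sigma_loc = 0.02, mean_blinks = 5,
                          shaft_density = 0, n_frames = 10000, seed = 1) {
  stopifnot(inherits(layout, "synapse_layout"), sigma_loc >= 0,
            domain_sd >= 0, mean_blinks >= 1)
  reg <- layout$region
  syn <- layout$synapses
  with_seed(seed, {
    mx <- numeric(0); my <- numeric(0); msyn <- integer(0)
    for (s in seq_len(nrow(syn))) {
      dom <- if (!is.null(layout$domains)) layout$domains[[s]]
             else data.frame(x = syn$x[s], y = syn$y[s])
      for (d in seq_len(nrow(dom))) {
        mx <- c(mx, rnorm(mols_per_domain, dom$x[d], domain_sd))
        my <- c(my, rnorm(mols_per_domain, dom$y[d], domain_sd))
        msyn <- c(msyn, rep(s, mols_per_domain))
      }
    }
    if (shaft_density > 0) {
      area <- (reg[3] - reg[1]) * (reg[4] - reg[2])
      ns <- rpois(1, shaft_density * area)
      mx <- c(mx, runif(ns, reg[1], reg[3]))
      my <- c(my, runif(ns, reg[2], reg[4]))
      msyn <- c(msyn, rep(0L, ns))
    }
    n_mol <- length(mx)
    blinks <- rgeom(n_mol, 1 / mean_blinks) + 1L
    idx <- rep(seq_len(n_mol), blinks)
    n_loc <- length(idx)
    df <- data.frame(
      frame = sample.int(n_frames, n_loc, replace = TRUE) - 1L,
      x = mx[idx] + rnorm(n_loc, 0, sigma_loc),
      y = my[idx] + rnorm(n_loc, 0, sigma_loc),
      intensity = rep(1000, n_loc),
      sigma = rep(sigma_loc, n_loc),
      channel = "ch0")
    df <- df[order(df$frame), ]
    tab <- loc_table(df)
    attr(tab, "truth") <- data.frame(molecule = seq_len(n_mol), x = mx,
                                     y = my, synapse = msyn)
    tab
  })
}

#' Simulate a FRAP recovery trace
#'
#' Evaluates the diffusion-reaction recovery model [frap_model()] at the
#' given times and adds i.i.d. Gaussian noise.
#'
#' @param phi free (diffusing) fraction, in [0, 1].
#' @param k_diff characteristic diffusive rate D / r^2 (min^-1).
#' @param k_reac turnover rate of bound molecules (min^-1).
#' @param times time points in minutes (0 = bleach).
#' @param noise_sd Gaussian noise sd, >= 0.
#' @param seed RNG seed.
#' @return a [frap_trace()].
#' @export
simulate_frap <- function(phi, k_diff, k_reac, times, noise_sd = 0,
                          seed = 1) {
  stopifnot(phi >= 0, phi <= 1, k_diff >= 0, k_reac >= 0, all(times >= 0))
  if (noise_sd < 0) stop("negative noise sd")
  vals <- frap_model(times, phi, k_diff, k_reac)
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals + rnorm(length(times), 0, noise_sd))
  }
  frap_trace(times, vals)
}
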