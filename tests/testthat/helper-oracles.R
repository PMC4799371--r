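# Independent oracles and small fixture builders shared across tests.
# The brute-force matchers enumerate all feasible partial matchings; they
# share only the objective definition with the package, not its code path.

# exhaustive minimum of sum(matched cost) + penalty * (# unmatched items)
brute_force_match <- function(cost, penalty) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(energy = Inf, match = rep(NA_integer_, n))
  rec <- function(i, mt) {
    if (i > n) {
      matched <- !is.na(mt)
      e <- sum(cost[cbind(which(matched), mt[matched])]) +
        penalty * ((n - sum(matched)) + (m - sum(matched)))
      if (e < best$energy) best <<- list(energy = e, match = mt)
      return(invisible())
    }
    rec(i + 1L, c(mt, NA_integer_))
    for (j in seq_len(m)) {
      if (!(j %in% mt) && is.finite(cost[i, j])) rec(i + 1L, c(mt, j))
    }
  }
  rec(1L, integer(0))
  best
}

match_energy <- function(cost, mt, penalty) {
  matched <- !is.na(mt)
  sum(cost[cbind(which(matched), mt[matched])]) +
    penalty * ((nrow(cost) - sum(matched)) + (ncol(cost) - sum(matched)))
}

# stack with one rendered emitter per frame at fixed position, Poisson noise
one_emitter_stack <- function(x, y, n_frames = 20, photons = 800,
                              background = 20, px = 0.16, size = 48,
                              noise = TRUE, seed = 1) {
  truth <- data.frame(molecule = 1L, frame = seq_len(n_frames) - 1L,
                      x = x, y = y, state = "free")
  class(truth) <- c("sim_truth", "data.frame")
  lay <- synapse_layout(c(0, 0, size * px, size * px))
  cam <- camera_model(psf_sigma = 0.1, photons = photons,
                      background = background, read_sd = 2)
  render_movie(truth, lay, cam, c(size, size), px, noise = noise,
               seed = seed)$stack
}

# pure Brownian track as a plain data frame
brownian_track <- function(n, D, dt = 0.02) {
  data.frame(frame = seq_len(n) - 1L,
             x = cumsum(rnorm(n, 0, sqrt(2 * D * dt))),
             y = cumsum(rnorm(n, 0, sqrt(2 * D * dt))))
}

# marker image with Gaussian puncta at given centres, Poisson noise
puncta_marker <- function(centres, r = 0.25, size = 63, px = 0.16,
                          photons = 3000, background = 20, seed = 2) {
  lay <- synapse_layout(c(0, 0, size * px, size * px),
                        data.frame(x = centres$x, y = centres$y, r = r))
  truth <- data.frame(molecule = 1L, frame = 0L, x = centres$x[1],
                      y = centres$y[1], state = "free")
  class(truth) <- c("sim_truth", "data.frame")
  cam <- camera_model(photons = 0, background = background, read_sd = 2)
  render_movie(truth, lay, cam, c(size, size), px,
               marker_photons = photons, seed = seed)$marker
}
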