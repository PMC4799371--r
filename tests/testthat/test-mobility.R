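test_that("MSD closed forms: immobile and ballistic motion", {
  p0 <- data.frame(frame = 0:9, x = 1, y = 2)
  m0 <- compute_msd(p0, dt = 0.02)
  expect_true(all(m0$msd == 0))
  expect_equal(m0$lag, 1:9)
  # constant velocity v: MSD(t) = v^2 t^2 exactly
  v <- 0.5; dt <- 0.02
  pb <- data.frame(frame = 0:9, x = v * dt * (0:9), y = 0)
  mb <- compute_msd(pb, dt = dt)
  expect_equal(mb$msd, (v * mb$time)^2, tolerance = 1e-12)
})

test_that("MSD uses all overlapping pairs", {
  p <- data.frame(frame = c(0, 1, 2), x = c(0, 1, 3), y = 0)
  m <- compute_msd(p, dt = 1)
  expect_equal(m$msd[m$lag == 1], mean(c(1, 4)))
  expect_equal(m$n_pairs, c(2L, 1L))
})

test_that("diffusion estimation from the first 4 MSD points", {
  msd <- data.frame(lag = 1:4, time = (1:4) * 0.02,
                    msd = c(0.008, 0.016, 0.024, 0.032))
  expect_equal(estimate_diffusion(msd), 0.1, tolerance = 1e-12)
  # flat MSD: slope <= 0 floors at d_floor
  flat <- data.frame(lag = 1:4, time = (1:4) * 0.02, msd = rep(0.01, 4))
  expect_equal(estimate_diffusion(flat), 1e-5)
  expect_error(estimate_diffusion(msd[1:3, ]), "first 4")
})

test_that("the slow-mobility threshold follows the resolution formula", {
  expect_equal(slow_threshold(1, 1, 0.25), 1)
  expect_equal(slow_threshold(0.054, 4, 0.02), 0.054^2 / (4 * 4 * 0.02))
  # doubling the resolution FWHM quadruples the threshold
  expect_equal(slow_threshold(0.108, 4, 0.02),
               4 * slow_threshold(0.054, 4, 0.02))
})

test_that("slow fractions and the semi-log histogram", {
  cf <- classify_and_fractions(rep(1, 10), d_threshold = 0.01)
  expect_equal(cf$slow_fraction, 0)
  cf2 <- classify_and_fractions(c(0.001, 0.1), d_threshold = 0.0093)
  expect_equal(cf2$slow_fraction, 0.5)
  expect_equal(sum(cf2$histogram$count), 2)
  # monotone non-decreasing in the threshold
  set.seed(41)
  D <- 10^runif(200, -4, 0)
  fr <- vapply(c(0.001, 0.01, 0.1, 1),
               function(th) classify_and_fractions(D, th)$slow_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("D estimates are invariant under rigid motions", {
  set.seed(42)
  p <- brownian_track(30, 0.05)
  D0 <- estimate_diffusion(compute_msd(p, 0.02))
  th <- 0.7
  q <- data.frame(frame = p$frame,
                  x = cos(th) * p$x - sin(th) * p$y + 5,
                  y = sin(th) * p$x + cos(th) * p$y - 3)
  expect_equal(estimate_diffusion(compute_msd(q, 0.02)), D0,
               tolerance = 1e-9)
})

test_that("the 4-point estimator recovers D on Brownian ensembles", {
  set.seed(43)
  for (D in c(0.05, 0.1)) {
    Dh <- replicate(1500, {
      estimate_diffusion(compute_msd(brownian_track(20, D), 0.02))
    })
    expect_equal(median(Dh), D, tolerance = 0.1)
  }
})

test_that("two-population data give a bimodal semi-log histogram", {
  set.seed(44)
  Dh <- c(
    replicate(400, estimate_diffusion(
      compute_msd(brownian_track(20, 0.2), 0.02))),
    replicate(200, estimate_diffusion(
      compute_msd(brownian_track(20, 0.0005), 0.02))))
  cf <- classify_and_fractions(Dh, slow_threshold())
  expect_equal(cf$slow_fraction, 1 / 3, tolerance = 0.2)
  h <- cf$histogram
  # two local maxima separated by a valley
  fast_peak <- h$bin_center_log10D[which.max(h$count)]
  expect_equal(fast_peak, log10(0.2), tolerance = 0.5)
  valley <- h$count[h$bin_center_log10D > -2.6 & h$bin_center_log10D < -1.6]
  slow_side <- h$count[h$bin_center_log10D <= -2.6]
  expect_gt(max(slow_side), max(valley))
})

test_that("confinement fits recover exact one-phase association curves", {
  t <- (1:10) * 0.02
  msd <- data.frame(time = t, msd = 0.0036 * (1 - exp(-5 * t)))
  cf <- fit_confinement(msd)
  expect_true(cf$converged)
  expect_equal(cf$P, 0.0036, tolerance = 1e-5)
  expect_equal(cf$k, 5, tolerance = 1e-4)
  expect_equal(cf$confinement_diameter, 0.12, tolerance = 1e-5)
  # linear MSD: degenerate, flagged unconfined
  lin <- data.frame(time = t, msd = 0.004 * t)
  cl <- fit_confinement(lin)
  expect_false(cl$confined)
})

test_that("reflected Brownian motion in a disk sizes the disk diameter", {
  lay <- synapse_layout(c(0, 0, 1, 1), data.frame(x = 0.5, y = 0.5,
                                                  r = 0.06))
  tr <- simulate_spt(lay, 80, D_free = 0.005, D_trap = 0.005,
                     k_on = 1e6, k_off = 0, n_frames = 150, dt = 0.02,
                     seed = 45)
  tr <- tr[tr$state == "trapped", ]
  sp <- split(tr, tr$molecule)
  sp <- sp[vapply(sp, nrow, 0L) >= 80]
  msds <- do.call(rbind, lapply(sp, compute_msd, dt = 0.02))
  pool <- aggregate(msd ~ time, msds[msds$lag <= 60, ], mean)
  cf <- fit_confinement(pool)
  expect_true(cf$confined)
  expect_equal(cf$confinement_diameter, 0.12, tolerance = 0.1)
})

test_that("explored area counts occupied raster pixels", {
  r <- 0.054 / 2
  one <- data.frame(x = 1.0, y = 1.0)
  expect_equal(explored_area(one), r^2)
  two <- data.frame(x = c(1, 5), y = c(1, 5))
  expect_equal(explored_area(two), 2 * r^2)
  # monotone in track length
  set.seed(46)
  p <- brownian_track(200, 0.1)
  areas <- vapply(c(50, 100, 200),
                  function(n) explored_area(p[1:n, ]), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("mobility tables classify against the threshold", {
  set.seed(47)
  tr <- rbind(
    cbind(brownian_track(20, 0.2), traj_id = 1),
    cbind(brownian_track(20, 1e-5), traj_id = 2),
    cbind(brownian_track(3, 0.1), traj_id = 3))   # too short, excluded
  mob <- compute_mobility(tr, dt = 0.02)
  expect_equal(nrow(mob), 2)
  expect_equal(mob$class, c("fast", "slow"))
  expect_true(all(mob$D_inst >= 1e-5))
})
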