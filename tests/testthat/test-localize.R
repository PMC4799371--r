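test_that("blank noise frames yield essentially no candidates", {
  set.seed(21)
  st <- image_stack(array(rpois(100 * 64 * 64, 50), c(100, 64, 64)),
                    0.16, 0.02)
  det <- detect_spots(st)
  # false-positive frames must be < 1% of frames
  expect_lt(length(unique(det$frame)), 1)
})

test_that("a single rendered emitter is found once per frame within 1 px", {
  st <- one_emitter_stack(3.23, 2.87, n_frames = 40, seed = 22)
  det <- detect_spots(st)
  per_frame <- table(factor(det$frame, levels = 0:39))
  expect_true(all(per_frame == 1))
  err <- sqrt((det$x - 3.23)^2 + (det$y - 2.87)^2)
  expect_true(all(err < 0.16))
})

test_that("two emitters 10 px apart give two candidates", {
  px <- 0.16
  truth <- data.frame(molecule = c(1, 2), frame = 0L,
                      x = c(3, 3 + 10 * px), y = 3, state = "free")
  class(truth) <- c("sim_truth", "data.frame")
  lay <- synapse_layout(c(0, 0, 48 * px, 48 * px))
  mv <- render_movie(truth, lay, camera_model(photons = 800,
                                              background = 20,
                                              read_sd = 2),
                     c(48, 48), px, seed = 23)
  det <- detect_spots(mv$stack)
  expect_equal(nrow(det), 2)
})

test_that("noiseless sub-pixel refinement is exact", {
  px <- 0.16
  # emitter at fractional pixel (20.3, 31.7) in pixel units
  x0 <- (20.3 - 0.5) * px; y0 <- (31.7 - 0.5) * px
  st <- one_emitter_stack(x0, y0, n_frames = 1, size = 48,
                          noise = FALSE, seed = 1)
  ref <- refine_subpixel(st, detect_spots(st))
  expect_equal(ref$x / px, x0 / px, tolerance = 1e-3)
  expect_equal(ref$y / px, y0 / px, tolerance = 1e-3)
  expect_equal(ref$sigma, 0.1, tolerance = 1e-4)
  # emitter exactly on a pixel centre: zero offset by symmetry
  xc <- (24 - 0.5) * px
  st2 <- one_emitter_stack(xc, xc, n_frames = 1, size = 48,
                           noise = FALSE, seed = 1)
  ref2 <- refine_subpixel(st2, detect_spots(st2))
  expect_equal(ref2$x, xc, tolerance = 1e-9)
  expect_equal(ref2$y, xc, tolerance = 1e-9)
})

test_that("localization error is within a factor 2 of the CRLB scale", {
  st <- one_emitter_stack(3.23, 2.87, n_frames = 150, photons = 800,
                          background = 20, seed = 24)
  ref <- refine_subpixel(st, detect_spots(st))
  expect_gt(nrow(ref), 100)
  rmse <- sqrt(mean((ref$x - 3.23)^2 + (ref$y - 2.87)^2) / 2)
  bound <- 0.1 / sqrt(800)       # sigma_psf / sqrt(N)
  expect_lt(rmse, 2 * bound)
  expect_gt(rmse, bound / 2)
})

test_that("detection + refinement has recall and precision >= 0.9 at SNR 8", {
  px <- 0.16
  lay <- synapse_layout(c(0, 0, 64 * px, 64 * px))
  set.seed(25)
  n_frames <- 30
  truth <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    k <- 4
    data.frame(molecule = seq_len(k), frame = t - 1L,
               x = runif(k, 1, 64 * px - 1), y = runif(k, 1, 64 * px - 1),
               state = "free")
  }))
  class(truth) <- c("sim_truth", "data.frame")
  mv <- render_movie(truth, lay, camera_model(photons = 800,
                                              background = 20, read_sd = 2),
                     c(64, 64), px, seed = 25)
  ref <- refine_subpixel(mv$stack, detect_spots(mv$stack))
  hits <- 0; n_det <- nrow(ref)
  for (t in seq_len(n_frames) - 1L) {
    tt <- truth[truth$frame == t, ]
    dd <- ref[ref$frame == t, ]
    for (i in seq_len(nrow(tt))) {
      d <- sqrt((dd$x - tt$x[i])^2 + (dd$y - tt$y[i])^2)
      if (length(d) && min(d) < px) hits <- hits + 1
    }
  }
  expect_gte(hits / nrow(truth), 0.9)    # recall
  expect_gte(hits / n_det, 0.9)          # precision
})

test_that("pointing accuracy and the 2.3-sigma resolution convention", {
  # trivial arithmetic of the convention
  set.seed(26)
  g <- rep(1:30, each = 20)
  mu_x <- runif(30, 0, 5)[g]; mu_y <- runif(30, 0, 5)[g]
  tab <- data.frame(x = rnorm(600, mu_x, 0.02),
                    y = rnorm(600, mu_y, 0.02))
  pe <- estimate_resolution(tab, g)
  expect_equal(pe$fwhm_resolution, 2.3 * pe$sigma_xy)
  expect_equal(pe$sigma_xy, 0.02, tolerance = 0.05)
  # degenerate: identical localizations
  expect_error(estimate_resolution(data.frame(x = rep(1, 20),
                                              y = rep(1, 20)),
                                   rep(1, 20)),
               "degenerate")
  # too-short groups are rejected
  expect_error(estimate_resolution(tab, seq_len(600)), "no group")
})

test_that("resolution scales linearly with injected jitter (slope 2.3)", {
  set.seed(27)
  ests <- vapply(c(0.01, 0.02, 0.04), function(s) {
    g <- rep(1:20, each = 20)
    tab <- data.frame(x = rnorm(400, 0, s), y = rnorm(400, 0, s))
    estimate_resolution(tab, g)$fwhm_resolution
  }, numeric(1))
  slope <- coef(lm(ests ~ c(0.01, 0.02, 0.04)))[[2]]
  expect_equal(slope, 2.3, tolerance = 0.08)
})

test_that("fiducial drift correction recovers injected drift", {
  set.seed(28)
  nfr <- 120
  drift_x <- 0.001 * (0:(nfr - 1))    # 1 nm/frame
  drift_y <- -0.0005 * (0:(nfr - 1))
  fid <- do.call(rbind, lapply(1:3, function(id) {
    data.frame(traj_id = id, frame = 0:(nfr - 1),
               x = id + drift_x + rnorm(nfr, 0, 0.005),
               y = 2 * id + drift_y + rnorm(nfr, 0, 0.005))
  }))
  emit <- data.frame(frame = rep(0:(nfr - 1), 3),
                     x = rep(c(3, 4, 5), each = nfr) + rep(drift_x, 3),
                     y = rep(c(3, 4, 5), each = nfr) + rep(drift_y, 3))
  out <- correct_drift(loc_table(emit), fid)
  resid <- unlist(lapply(split(seq_len(nrow(emit)),
                               rep(1:3, each = nfr)), function(ii) {
    c(out$table$x[ii] - mean(out$table$x[ii]),
      out$table$y[ii] - mean(out$table$y[ii]))
  }))
  expect_lt(sqrt(mean(resid^2)), 0.005)   # below localization precision
  expect_equal(out$drift$dx[1], 0)
  expect_equal(out$drift$dy[1], 0)
  # idempotence: correcting the corrected table finds ~zero drift
  out2 <- correct_drift(out$table, local({
    f <- fid
    sp <- split(seq_len(nrow(f)), f$traj_id)
    for (ii in sp) {
      f$x[ii] <- f$x[ii] - out$drift$dx
      f$y[ii] <- f$y[ii] - out$drift$dy
    }
    f
  }))
  expect_lt(max(abs(c(out2$drift$dx, out2$drift$dy))), 0.004)
})

test_that("zero drift and redundant fiducials are handled exactly", {
  nfr <- 30
  fid1 <- data.frame(traj_id = 1, frame = 0:(nfr - 1), x = 1, y = 1)
  emit <- loc_table(data.frame(frame = 0:(nfr - 1), x = 2, y = 2))
  out <- correct_drift(emit, fid1)
  expect_equal(out$table$x, emit$x)
  expect_equal(out$table$y, emit$y)
  # two fiducials with equal drift match the single-fiducial model
  fid2 <- rbind(fid1, transform(fid1, traj_id = 2, x = 3, y = 4))
  out2 <- correct_drift(emit, fid2)
  expect_equal(out2$drift, out$drift)
})

test_that("channel registration recovers exact and noisy transforms", {
  set.seed(29)
  ba <- data.frame(x = runif(12, 0, 20), y = runif(12, 0, 20))
  # identity
  tf0 <- register_channels(ba, ba)
  expect_equal(tf0$M, diag(2), tolerance = 1e-9)
  expect_equal(tf0$residual_rms, 0, tolerance = 1e-9)
  # pure translation
  bb <- data.frame(x = ba$x - 0.1, y = ba$y + 0.2)
  tf1 <- register_channels(ba, bb)
  expect_equal(tf1$t, c(0.1, -0.2), tolerance = 1e-6)
  expect_equal(apply_transform(tf1, bb)$x, ba$x, tolerance = 1e-9)
  # noisy beads: residual on the scale of the bead noise
  bn <- data.frame(x = ba$x + rnorm(12, 0, 0.01),
                   y = ba$y + rnorm(12, 0, 0.01))
  tf2 <- register_channels(ba, bn)
  expect_equal(tf2$residual_rms, 0.014, tolerance = 0.6)
  expect_error(register_channels(ba[1:2, ], bb[1:2, ]), ">= 3")
  # collinear beads break the full affine
  col_a <- data.frame(x = 1:4, y = 2 * (1:4))
  expect_error(register_channels(col_a, col_a, model = "affine"),
               "collinear")
})
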