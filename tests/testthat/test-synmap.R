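px <- 0.16

test_that("marker segmentation finds well-separated puncta", {
  centres <- data.frame(x = c(2, 5, 8), y = c(5, 5, 5))
  marker <- puncta_marker(centres, seed = 51)
  rs <- segment_marker(marker, px)
  expect_equal(nrow(rs$regions), 3)
  # centroids within 1 px of the generating centres
  for (i in 1:3) {
    d <- sqrt((rs$regions$x - centres$x[i])^2 +
                (rs$regions$y - centres$y[i])^2)
    expect_lt(min(d), px)
  }
  expect_true(all(rs$regions$area > 0))
  expect_equal(sort(unique(as.vector(rs$labels))), 0:3)
})

test_that("blank noise and uniform images give empty region sets", {
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    blank <- matrix(rpois(63 * 63, 20), 63, 63)
    if (nrow(segment_marker(blank, px)$regions) > 0) hits <- hits + 1
  }
  expect_lte(hits, 1)    # >= 95% of seeded trials are empty
  expect_equal(nrow(segment_marker(matrix(5, 40, 40), px)$regions), 0)
})

test_that("localizations sort into synaptic and extrasynaptic pools", {
  marker <- puncta_marker(data.frame(x = 5, y = 5), seed = 52)
  rs <- segment_marker(marker, px)
  cen <- rs$regions[1, ]
  tab <- data.frame(x = c(cen$x, 0.3, -1), y = c(cen$y, 0.3, 2))
  out <- sort_localizations(tab, rs)
  expect_true(out$synaptic[1])
  expect_false(out$synaptic[2])
  expect_false(out$synaptic[3])
  expect_equal(attr(out, "out_of_bounds"), 3L)
  # uniform points hit synapses in proportion to area
  set.seed(53)
  side <- 63 * px
  u <- data.frame(x = runif(40000, 0, side), y = runif(40000, 0, side))
  frac <- mean(sort_localizations(u, rs)$synaptic)
  expect_equal(frac, sum(rs$regions$area) / side^2, tolerance = 0.1)
})

test_that("synapse metrics follow their definitions", {
  marker <- puncta_marker(data.frame(x = c(2, 7), y = c(5, 5)), seed = 54)
  rs <- segment_marker(marker, px)
  expect_equal(nrow(rs$regions), 2)
  # 12 detections in synapse 1, 5 in synapse 2 -> 50% above min 10
  set.seed(55)
  jit <- function(n, cx, cy) data.frame(x = cx + runif(n, -0.1, 0.1),
                                        y = cy + runif(n, -0.1, 0.1))
  tab <- rbind(jit(12, rs$regions$x[1], rs$regions$y[1]),
               jit(5, rs$regions$x[2], rs$regions$y[2]))
  m <- synapse_metrics(tab, rs)
  expect_equal(m$percent_synapses_with_target, 50)
  expect_equal(m$per_synapse_counts$n_detections, c(12L, 5L))
  expect_equal(m$percent_synaptic_detections, 100)
  expect_true(m$synaptic_coverage >= 0 && m$synaptic_coverage <= 100)
  expect_error(synapse_metrics(tab[0, ], rs), "zero")
})

test_that("uniform fields have enrichment 1; concentrated fields scale", {
  marker <- puncta_marker(data.frame(x = c(3, 7), y = c(4, 6)), seed = 56)
  rs <- segment_marker(marker, px)
  side <- 63 * px
  set.seed(57)
  u <- data.frame(x = runif(60000, 0, side), y = runif(60000, 0, side))
  mu <- synapse_metrics(u, rs)
  expect_equal(mu$enrichment, 1, tolerance = 0.15)
  expect_equal(mu$percent_synaptic_detections +
                 (100 - mu$percent_synaptic_detections), 100)
  # 10x denser synaptic population
  lab <- synaptomap:::region_label_at(rs, u$x, u$y)
  syn_pts <- u[lab > 0, ]
  boost <- do.call(rbind, replicate(9, syn_pts, simplify = FALSE))
  m10 <- synapse_metrics(rbind(u, boost), rs)
  expect_equal(m10$enrichment, 10, tolerance = 0.15)
})

test_that("metrics are invariant under whole-pixel rigid shifts", {
  marker <- puncta_marker(data.frame(x = c(3, 6), y = c(5, 5)), seed = 58)
  rs <- segment_marker(marker, px)
  set.seed(59)
  tab <- data.frame(x = runif(3000, 0, 63 * px), y = runif(3000, 0, 63 * px))
  m0 <- synapse_metrics(tab, rs)
  # circular shift of marker and localizations by 5 pixels preserves every
  # point-to-mask relation exactly
  sh <- 5
  marker2 <- marker[c((63 - sh + 1):63, 1:(63 - sh)), ]
  rs2 <- segment_marker(marker2, px)
  tab2 <- data.frame(x = tab$x, y = (tab$y + sh * px) %% (63 * px))
  m2 <- synapse_metrics(tab2, rs2)
  expect_equal(m2$percent_synapses_with_target,
               m0$percent_synapses_with_target)
  expect_equal(m2$percent_synaptic_detections,
               m0$percent_synaptic_detections)
  expect_equal(m2$enrichment, m0$enrichment, tolerance = 1e-6)
})

test_that("dispersion distances follow the Rayleigh geometry", {
  marker <- puncta_marker(data.frame(x = 5, y = 5), seed = 60)
  rs <- segment_marker(marker, px)
  cen <- c(rs$regions$x[1], rs$regions$y[1])
  at_cen <- data.frame(x = rep(cen[1], 10), y = rep(cen[2], 10))
  expect_true(all(dispersion_from_centroid(at_cen, rs)$distances < 1e-9))
  # ring of radius 0.1 inside the region
  th <- seq(0, 2 * pi, length.out = 50)
  ring <- data.frame(x = cen[1] + 0.1 * cos(th), y = cen[2] + 0.1 * sin(th))
  dr <- dispersion_from_centroid(ring, rs)
  expect_equal(unname(dr$distances), rep(0.1, sum(!is.na(dr$distances))),
               tolerance = 1e-9)
  # isotropic normal scatter sd s: median distance = s * sqrt(2 ln 2)
  set.seed(61)
  s <- 0.05
  sc <- data.frame(x = rnorm(8000, cen[1], s), y = rnorm(8000, cen[2], s))
  dm <- dispersion_from_centroid(sc, rs)
  expect_equal(dm$median, s * sqrt(2 * log(2)), tolerance = 0.05)
})

test_that("density maps count neighbours within the radius", {
  expect_equal(density_map(data.frame(x = 1, y = 1)), 0L)
  pair <- data.frame(x = c(0, 0.3), y = c(0, 0))
  expect_equal(density_map(pair, 0.4), c(1L, 1L))
  expect_equal(density_map(pair, 0.2), c(0L, 0L))
  # uniform Poisson field: mean count ~ lambda * pi * r^2
  set.seed(62)
  n <- 4000; side <- 10
  u <- data.frame(x = runif(n, 0, side), y = runif(n, 0, side))
  cnt <- density_map(u, 0.4)
  inner <- u$x > 0.5 & u$x < side - 0.5 & u$y > 0.5 & u$y < side - 0.5
  lambda <- n / side^2
  expect_equal(mean(cnt[inner]), lambda * pi * 0.4^2, tolerance = 0.05)
  # brute-force cross-check on a small set
  small <- u[1:60, ]
  ref <- vapply(1:60, function(i) {
    sum(sqrt((small$x - small$x[i])^2 + (small$y - small$y[i])^2) <= 0.4) - 1L
  }, 0L)
  expect_equal(density_map(small, 0.4), ref)
})

test_that("time courses normalize to the baseline interval", {
  expect_equal(timecourse_counts(c(100, 50)), c(1, 0.5))
  expect_equal(timecourse_counts(rep(7, 5)), rep(1, 5))
  expect_error(timecourse_counts(c(0, 5)), "zero baseline")
  # exponential loss is recovered in normalized counts
  set.seed(63)
  lambda <- 0.3
  counts <- rpois(6, 400 * exp(-lambda * 0:5))
  norm <- timecourse_counts(counts)
  expect_equal(log(norm[6]) / 5, -lambda, tolerance = 0.25)
})
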