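# hand-painted polar raster: disk of producer with optional consumer wedges
polar_raster <- function(radius_px, wedges = NULL, margin = 8L,
                         pixel_size = 3.027) {
  npx <- 2L * (radius_px + margin) + 1L
  ctr <- radius_px + margin + 1
  xs <- rep(seq_len(npx), each = npx) - ctr
  ys <- rep(seq_len(npx), times = npx) - ctr
  rr <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs) %% (2 * pi)
  lab <- integer(npx * npx)
  lab[rr <= radius_px] <- 1L
  if (!is.null(wedges)) for (w in seq_len(nrow(wedges))) {
    dth <- abs(((th - wedges[w, 1L] + pi) %% (2 * pi)) - pi)
    lab[rr <= radius_px & dth <= wedges[w, 2L] / 2] <- 2L
  }
  colony_raster(matrix(lab, npx, npx), pixel_size, center = c(ctr, ctr))
}

test_that("rasterization stamps occupied tiles and nothing else", {
  lat <- hex_lattice(400, 20)
  occ <- occupancy(lat)
  ras0 <- rasterize_state(occ, lat, 5)
  expect_true(all(ras0$labels == 0L))
  ctr <- which.min(rowSums(lat$xy^2))
  occ$strain[ctr] <- 2L
  ras1 <- rasterize_state(occ, lat, 5)
  expect_true(all(ras1$labels %in% c(0L, 2L)))
  # one hexagonal tile of area 3*sqrt(3)/2 * side^2
  expect_equal(sum(ras1$labels == 2L) * 25, lat$node_area, tolerance = 0.1)
})

test_that("rasterized disk area approximates the geometric disk", {
  lat <- hex_lattice(900, 20)
  occ <- occupancy(lat)
  occ$strain[sqrt(rowSums(lat$xy^2)) <= 300] <- 1L
  ras <- rasterize_state(occ, lat, 3.027)
  area <- sum(ras$labels == 1L) * 3.027^2
  expect_lt(abs(area / (pi * 300^2) - 1), 0.05)
})

test_that("edge profile matches a brute-force per-bin scan", {
  ras <- polar_raster(100)
  prof <- edge_profile(ras, 90)
  expect_true(all(abs(prof / 3.027 - 100) <= 1.5))
  # wedge pushed outward: only its bins report the larger radius
  ras2 <- polar_raster(100, margin = 30L)
  lab <- ras2$labels
  npx <- nrow(lab)
  ctr <- ras2$center
  xs <- rep(seq_len(npx), each = npx) - ctr[1L]
  ys <- rep(seq_len(npx), times = npx) - ctr[2L]
  rr <- sqrt(xs^2 + ys^2); th <- atan2(ys, xs)
  lab[rr <= 120 & abs(th) < 0.2] <- 1L
  ras2 <- colony_raster(lab, 3.027, ras2$center)
  prof2 <- edge_profile(ras2, 90)
  ang <- (seq_len(90) - 0.5) / 90 * 2 * pi - pi
  bumped <- abs(ang) < 0.15
  expect_true(all(prof2[bumped] / 3.027 > 115))
  expect_true(all(prof2[!bumped & abs(ang) > 0.35] / 3.027 < 102))
  # brute-force oracle on a random blob raster
  set.seed(30)
  lab3 <- matrix(0L, 41, 41)
  lab3[sample(41 * 41, 300)] <- 1L
  ras3 <- colony_raster(lab3, 1, center = c(21, 21))
  prof3 <- edge_profile(ras3, 12)
  want <- rep(NA_real_, 12)
  for (i in seq_len(41)) for (j in seq_len(41)) {
    if (lab3[i, j] == 0L) next
    r <- sqrt((j - 21)^2 + (i - 21)^2)
    b <- min(12, 1 + floor((atan2(i - 21, j - 21) + pi) / (2 * pi) * 12))
    if (is.na(want[b]) || r > want[b]) want[b] <- r
  }
  expect_equal(prof3, want)
  expect_error(edge_profile(colony_raster(matrix(0L, 5, 5))), "invalid input")
  expect_error(edge_profile(ras, 4), "invalid input")
})

test_that("edge-ring composition recovers wedge geometry", {
  # pure producer ring
  expect_equal(consumer_producer_ratio(polar_raster(100)), 0)
  # half consumer / half producer by half-plane
  half <- polar_raster(100, wedges = cbind(pi / 2, pi))
  expect_equal(consumer_producer_ratio(half), 1, tolerance = 0.05)
  # known total wedge angle theta -> theta / (2 pi - theta) within 3%
  g <- gen_wedge_colony(radius_px = 140, n_jackpots = 3, wedge_width = 0.5,
                        wedge_r0_frac = 0.1, seed = 41)
  th <- g$truth$total_wedge_angle
  expect_lt(abs(consumer_producer_ratio(g$raster) / (th / (2 * pi - th)) - 1),
            0.03)
  # all-consumer ring warns and returns Inf
  allc <- polar_raster(60, wedges = cbind(pi, 2 * pi + 0.1))
  expect_warning(rr <- consumer_producer_ratio(allc), "producer")
  expect_identical(rr, Inf)
})

test_that("intermixing counts wedge boundaries and scales linearly", {
  expect_equal(intermixing_index(polar_raster(100)), 0)
  mk <- function(k, radius = 120) {
    centers <- 2 * pi * (seq_len(k) - 0.5) / k
    polar_raster(radius, wedges = cbind(centers, pi / k))
  }
  r4 <- mk(4)
  samp_r <- (120 - 50)  # sampling radius in px
  want4 <- 8 / (2 * pi * samp_r * 3.027)
  expect_equal(intermixing_index(r4), want4, tolerance = 0.02)
  # doubling the wedge count doubles the index at fixed radius
  expect_equal(intermixing_index(mk(8)) / intermixing_index(mk(4)), 2,
               tolerance = 0.02)
  # per-pixel normalization differs by exactly the pixel size
  expect_equal(intermixing_index(r4, per_um = FALSE),
               intermixing_index(r4) * 3.027)
  empty_center <- colony_raster(rbind(c(0L, 0L), c(0L, 1L)), 1)
  expect_error(intermixing_index(empty_center), "invalid input")
})

test_that("jackpot counting matches definition and flood-fill oracle", {
  expect_identical(count_jackpot_events(polar_raster(100)), 0L)
  # 3 edge-reaching wedges + 2 interior blobs -> 3
  g <- gen_wedge_colony(radius_px = 120, n_jackpots = 3, interior_blobs = 2,
                        seed = 55)
  expect_identical(count_jackpot_events(g$raster), 3L)
  # oracle comparison on noisy colonies: same component rule, independent code
  for (seed in c(70, 71, 72)) {
    g2 <- gen_wedge_colony(radius_px = 90, n_jackpots = 4,
                           label_noise_rate = 0.01, seed = seed)
    got <- count_jackpot_events(g2$raster, edge_band_px = 10, min_size_px = 10)
    lab <- oracle_components(g2$raster$labels == 2L)
    prof <- edge_profile(g2$raster, 360) / g2$raster$pixel_size
    d <- dim(lab)
    xs <- rep(seq_len(d[2L]), each = d[1L]) - g2$raster$center[1L]
    ys <- rep(seq_len(d[1L]), times = d[2L]) - g2$raster$center[2L]
    rr <- sqrt(xs^2 + ys^2)
    bb <- pmin(360, 1 + floor((atan2(ys, xs) + pi) / (2 * pi) * 360))
    near_edge <- !is.na(prof[bb]) & rr >= prof[bb] - 10
    comps <- unique(lab[lab > 0L & near_edge])
    sizes <- table(lab[lab > 0L])
    want <- sum(sizes[as.character(comps)] > 10)
    expect_identical(got, as.integer(want))
  }
})

test_that("metrics are invariant under rotation and mirror flip", {
  g <- gen_wedge_colony(radius_px = 100, n_jackpots = 3, wedge_width = 0.4,
                        seed = 60)
  m0 <- pattern_metrics(g$raster)
  rot <- colony_raster(t(g$raster$labels)[ncol(g$raster$labels):1, ],
                       g$raster$pixel_size)  # 90 degree rotation
  flip <- colony_raster(g$raster$labels[nrow(g$raster$labels):1, ],
                        g$raster$pixel_size)
  for (m in list(pattern_metrics(rot), pattern_metrics(flip))) {
    expect_identical(m$jackpots, m0$jackpots)
    expect_equal(m$ratio, m0$ratio, tolerance = 0.05)
    expect_equal(m$intermixing, m0$intermixing, tolerance = 0.05)
  }
})

test_that("lattice-native and rasterized metrics agree", {
  lat <- hex_lattice(1600, 20)
  wedges <- cbind(c(0.5, 2.5, 4.5), 0.45)
  occ <- paint_wedge_occupancy(lat, 700, wedges)
  direct <- pattern_metrics_state(occ, lat)
  ras <- rasterize_state(occ, lat, 3.027)
  viaras <- pattern_metrics(ras)
  expect_identical(direct$jackpots, as.integer(viaras$jackpots))
  expect_lt(abs(direct$ratio / viaras$ratio - 1), 0.05)
})
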