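#' Generate a ground-truth labeled synthetic colony raster
#'
#' Emulates the phenomenology of a two-strain range expansion image: a
#' disk-shaped colony with a producer-dominated background, wedge-shaped
#' consumer sectors that reach the expansion edge (the spatial jackpot
#' events), optional interior consumer blobs that stop short of the edge,
#' optional concentric banding that pinches wedge width (mimicking the
#' anoxic/oxic growth rings), and salt-and-pepper label-flip noise.  The
#' returned ground-truth record is sufficient to compute every expected
#' pattern metric analytically.
#'
#' @param radius_px Colony radius in pixels.
#' @param n_jackpots Number of edge-reaching consumer wedges (ignored if
#'   \code{wedge_angles} given).
#' @param wedge_angles Optional matrix/data frame with columns
#'   \code{center}, \code{width} (radians); wedges must not overlap.
#' @param wedge_width Angular width (radians) of auto-placed wedges.
#' @param wedge_r0_frac Wedges span radii \code{[wedge_r0_frac, 1] *
#'   radius_px}.
#' @param interior_blobs Number of consumer disks strictly interior to the
#'   edge (they emulate jackpot nuclei that failed to persist).
#' @param blob_radius_px Radius of interior blobs.
#' @param band_pattern Optional list \code{list(n_bands=, pinch=)}: wedge
#'   width is multiplied by \code{pinch} inside every second concentric
#'   band, emulating the width modulation at redox transitions.
#' @param label_noise_rate Probability, per in-colony pixel, of flipping its
#'   strain label (in \code{[0, 1)}).
#' @param pixel_size um per pixel.
#' @param seed Optional seed applied before any draw.
#' @param margin_px Empty margin around the colony.
#' @return List: \code{raster} (a \code{\link{colony_raster}}) and
#'   \code{truth} (wedge geometry, expected edge-ring ratio
#'   \code{theta/(2*pi - theta)}, expected boundary count, jackpot count).
#' @export
gen_wedge_colony <- function(radius_px = 150L, n_jackpots = 3L,
                             wedge_angles = NULL, wedge_width = 0.25,
                             wedge_r0_frac = 0.3, interior_blobs = 0L,
                             blob_radius_px = 6L, band_pattern = NULL,
                             label_noise_rate = 0, pixel_size = 3.027,
                             seed = NULL, margin_px = 10L) {
  if (label_noise_rate < 0 || label_noise_rate >= 1)
    stop("invalid configuration: label_noise_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wedge_angles)) {
    if (n_jackpots > 0L) {
      offset <- stats::runif(1, 0, 2 * pi)
      centers <- (offset + 2 * pi * (seq_len(n_jackpots) - 1) / n_jackpots) %% (2 * pi)
      wedge_angles <- cbind(center = centers,
                            width = rep(wedge_width, n_jackpots))
    } else wedge_angles <- cbind(center = numeric(0), width = numeric(0))
  } else {
    wedge_angles <- as.matrix(wedge_angles)
    colnames(wedge_angles) <- c("center", "width")
  }
  nw <- nrow(wedge_angles)
  if (nw > 1L) {
    o <- order(wedge_angles[, "center"])
    ctr <- wedge_angles[o, "center"]; wid <- wedge_angles[o, "width"]
    gaps <- diff(c(ctr, ctr[1L] + 2 * pi))
    if (any(gaps < (wid + c(wid[-1L], wid[1L])) / 2))
      stop("invalid configuration: overlapping wedges")
  }

  npx <- 2L * (radius_px + margin_px) + 1L
  ctr_px <- radius_px + margin_px + 1
  xs <- rep(seq_len(npx), each = npx) - ctr_px
  ys <- rep(seq_len(npx), times = npx) - ctr_px
  rr <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs) %% (2 * pi)
  lab <- integer(npx * npx)
  lab[rr <= radius_px] <- 1L

  r0 <- wedge_r0_frac * radius_px
  in_any_wedge <- rep(FALSE, npx * npx)
  for (w in seq_len(nw)) {
    dth <- abs(((th - wedge_angles[w, "center"] + pi) %% (2 * pi)) - pi)
    half <- wedge_angles[w, "width"] / 2
    if (!is.null(band_pattern)) {
      band <- floor(rr / radius_px * band_pattern$n_bands)
      half <- half * ifelse(band %% 2 == 1, band_pattern$pinch, 1)
    }
    in_any_wedge <- in_any_wedge | (rr >= r0 & rr <= radius_px & dth <= half)
  }
  lab[in_any_wedge] <- 2L

  blobs <- NULL
  if (interior_blobs > 0L) {
    # midway between wedges (or random angles if none), well inside the edge
    base <- if (nw > 0L) wedge_angles[, "center"] + pi / max(nw, 1L)
            else stats::runif(interior_blobs, 0, 2 * pi)
    bang <- rep(base, length.out = interior_blobs)
    brad <- 0.6 * radius_px
    blobs <- cbind(x = brad * cos(bang), y = brad * sin(bang))
    for (b in seq_len(interior_blobs)) {
      d2 <- (xs - blobs[b, 1L])^2 + (ys - blobs[b, 2L])^2
      sel <- d2 <= blob_radius_px^2 & rr <= radius_px
      lab[sel] <- 2L
    }
  }

  if (label_noise_rate > 0) {
    inside <- which(lab > 0L)
    flip <- inside[stats::runif(length(inside)) < label_noise_rate]
    lab[flip] <- 3L - lab[flip]
  }

  theta <- sum(wedge_angles[, "width"])
  list(
    raster = colony_raster(matrix(lab, npx, npx), pixel_size,
                           center = c(ctr_px, ctr_px)),
    truth = list(
      n_jackpots = nw, wedge_angles = wedge_angles,
      total_wedge_angle = theta,
      expected_ratio = if (theta < 2 * pi) theta / (2 * pi - theta) else Inf,
      expected_boundaries = 2L * nw,
      radius_px = radius_px, r0_px = r0, pixel_size = pixel_size,
      interior_blobs = blobs, label_noise_rate = label_noise_rate)
  )
}

#' Generate replicate two-phase metric time series
#'
#' Continuous piecewise-linear mean trajectory (steep first phase, shallow
#' second phase, break at a transition index) plus independent Gaussian
#' noise, floored at zero since the emulated metrics (ratios, intermixing
#' indices) are non-negative.
#'
#' @param n_replicates Number of replicate series.
#' @param n_transitions Series length (transition indices 1..n).
#' @param slope1,slope2 Per-transition slopes of the two phases.
#' @param breakpoint Transition index of the break (strictly interior).
#' @param start_value Mean value at transition 1.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional seed.
#' @return List: \code{x} (1..n), \code{series} (replicates x transitions
#'   matrix), \code{mean} (noise-free trajectory), \code{truth} (generating
#'   parameters).
#' @export
gen_two_phase_series <- function(n_replicates, n_transitions, slope1, slope2,
                                 breakpoint, start_value, noise_sd = 0,
                                 seed = NULL) {
  if (breakpoint <= 1 || breakpoint >= n_transitions)
    stop("invalid configuration: breakpoint must be strictly interior")
  if (noise_sd < 0) stop("invalid configuration: noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n_transitions)
  m <- start_value + slope1 * (pmin(x, breakpoint) - 1) +
    slope2 * pmax(0, x - breakpoint)
  series <- matrix(stats::rnorm(n_replicates * n_transitions,
                                mean = rep(m, each = n_replicates),
                                sd = noise_sd),
                   n_replicates, n_transitions)
  series[series < 0] <- 0
  list(x = x, series = series, mean = m,
       truth = list(slope1 = slope1, slope2 = slope2,
                    breakpoint = breakpoint, start_value = start_value,
                    noise_sd = noise_sd))
}

#' Write a colony raster as a plain-text file
#'
#' Self-describing text format: two header lines (\code{# pixel_size <um>}
#' and \code{# center <x> <y>}) followed by one row of space-separated
#' integer labels per raster row.  Plain text keeps fixtures portable; no
#' image codec is required.
#'
#' @param raster A \code{colony_raster}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_colony_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size %.10g", raster$pixel_size),
               sprintf("# center %.10g %.10g",
                       raster$center[1L], raster$center[2L])), con)
  utils::write.table(raster$labels, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a colony raster written by \code{\link{write_colony_raster}}
#' @param path Input path.
#' @return A \code{colony_raster}.
#' @export
read_colony_raster <- function(path) {
  hdr <- readLines(path, n = 2L)
  ps <- as.numeric(strsplit(hdr[1L], " ")[[1L]][3L])
  ctr <- as.numeric(strsplit(hdr[2L], " ")[[1L]][3:4])
  lab <- as.matrix(utils::read.table(path, skip = 2L))
  dimnames(lab) <- NULL
  colony_raster(lab, ps, ctr)
}
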