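#' Labeled two-strain colony raster
#'
#' A pixel grid with labels 0 = empty, 1 = producer, 2 = consumer, a
#' physical pixel size, and the colony center in (fractional) pixel
#' coordinates.  The default pixel size, 3.027 um, matches a 5x confocal
#' tile scan at 1024 x 1024.
#'
#' @param labels Integer matrix (rows = y, columns = x) with values 0/1/2.
#' @param pixel_size Pixel edge length, um.
#' @param center Optional \code{c(x, y)} center in pixel units (1-based,
#'   matching column/row indices); defaults to the centroid of non-empty
#'   pixels.
#' @return Object of class \code{colony_raster}.
#' @export
colony_raster <- function(labels, pixel_size = 3.027, center = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) stop("invalid input: labels must be 0, 1 or 2")
  if (pixel_size <= 0) stop("invalid input: pixel_size must be positive")
  if (is.null(center)) {
    nz <- which(labels > 0L, arr.ind = TRUE)
    center <- if (nrow(nz)) c(mean(nz[, 2L]), mean(nz[, 1L]))
              else (dim(labels)[2:1] + 1) / 2
  }
  structure(list(labels = labels, pixel_size = pixel_size,
                 center = as.numeric(center)),
            class = "colony_raster")
}

#' @export
print.colony_raster <- function(x, ...) {
  cat(sprintf("colony_raster: %d x %d px (%.3f um/px), %d producer / %d consumer px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

# polar pixel coordinates relative to the raster center (px units)
.raster_polar <- function(raster) {
  d <- dim(raster$labels)
  px <- rep(seq_len(d[2L]), each = d[1L]) - raster$center[1L]
  py <- rep(seq_len(d[1L]), times = d[2L]) - raster$center[2L]
  list(r = sqrt(px^2 + py^2), theta = atan2(py, px))
}

.bin_of <- function(theta, n_bins) {
  pmin(n_bins, 1L + as.integer(floor((theta + pi) / (2 * pi) * n_bins)))
}

#' Rasterize a simulation occupancy
#'
#' Labels each pixel with the strain of the hexagonal tile it falls in,
#' provided that tile's node is occupied (this is the nearest occupied node
#' within one node spacing); all other pixels are empty.  The raster covers
#' the whole domain, centered on the lattice origin.
#'
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice}.
#' @param pixel_size Pixel edge, um (default 3.027).
#' @return A \code{colony_raster}.
#' @export
rasterize_state <- function(occ, lattice, pixel_size = 3.027) {
  if (pixel_size <= 0) stop("invalid input: pixel_size must be positive")
  R <- lattice$domain_diameter / 2 + lattice$spacing
  npx <- ceiling(2 * R / pixel_size)
  # pixel centers in um, origin at domain center
  cx <- (seq_len(npx) - (npx + 1) / 2) * pixel_size
  xs <- rep(cx, each = npx)
  ys <- rep(cx, times = npx)
  node <- .nearest_node(xs, ys, lattice)
  lab <- integer(npx * npx)
  ok <- !is.na(node)
  lab[ok] <- occ$strain[node[ok]]
  colony_raster(matrix(lab, npx, npx), pixel_size,
                center = c((npx + 1) / 2, (npx + 1) / 2))
}

# nearest lattice node by hexagonal tile membership (cube rounding);
# returns NA where the tile is outside the domain
.nearest_node <- function(x, y, lattice) {
  bad <- !is.finite(x) | !is.finite(y)
  x[bad] <- 0; y[bad] <- 0
  a <- lattice$spacing
  rf <- 2 * y / (a * sqrt(3))
  qf <- x / a - rf / 2
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fixq <- dq > dr & dq > ds
  fixr <- !fixq & dr > ds
  q[fixq] <- -r[fixq] - s[fixq]
  r[fixr] <- -q[fixr] - s[fixr]
  ax <- lattice$axial
  qoff <- min(ax[, 1L]); roff <- min(ax[, 2L])
  nq <- max(ax[, 1L]) - qoff + 1L; nr <- max(ax[, 2L]) - roff + 1L
  idx <- integer(nq * nr)
  idx[(ax[, 1L] - qoff) * nr + (ax[, 2L] - roff) + 1L] <- seq_len(lattice$n)
  out <- rep(NA_integer_, length(x))
  inside <- q >= qoff & q <= qoff + nq - 1L & r >= roff & r <= roff + nr - 1L
  key <- (q[inside] - qoff) * nr + (r[inside] - roff) + 1L
  id <- idx[key]
  id[id == 0L] <- NA_integer_
  out[inside] <- id
  out[bad] <- NA_integer_
  out
}

#' Per-angle expansion edge radius
#'
#' Operationalizes the expansion edge of a raster: the maximum radius of a
#' non-empty pixel in each angular bin.
#'
#' @param raster A \code{colony_raster}.
#' @param n_bins Number of angular bins (>= 8; default 360).
#' @return Numeric vector of per-bin maximum radii in um (\code{NA} for
#'   bins with no occupied pixel).
#' @export
edge_profile <- function(raster, n_bins = 360L) {
  if (n_bins < 8L) stop("invalid input: n_bins must be >= 8")
  occ <- raster$labels > 0L
  if (!any(occ)) stop("invalid input: empty raster")
  pol <- .raster_polar(raster)
  bins <- .bin_of(pol$theta[occ], n_bins)
  prof <- rep(NA_real_, n_bins)
  mx <- tapply(pol$r[occ], bins, max)
  prof[as.integer(names(mx))] <- mx
  prof * raster$pixel_size
}

# per-bin edge radius in px, plus polar coords, shared by the ring metrics
.edge_context <- function(raster, n_bins) {
  pol <- .raster_polar(raster)
  occ <- raster$labels > 0L
  if (!any(occ)) stop("invalid input: empty raster")
  bins <- .bin_of(pol$theta, n_bins)
  edge_px <- rep(NA_real_, n_bins)
  mx <- tapply(pol$r[occ], bins[occ], max)
  edge_px[as.integer(names(mx))] <- mx
  list(pol = pol, bins = bins, edge_px = edge_px)
}

#' Consumer-to-producer ratio in an edge ring
#'
#' Counts consumer and producer pixels inside a ring that follows the
#' per-angle expansion edge: outer boundary at the edge, inner boundary
#' \code{ring_width_px} pixels behind it (50 px = 151.35 um at the default
#' pixel size).
#'
#' @param raster A \code{colony_raster}.
#' @param ring_width_px Ring width in pixels (default 50).
#' @param n_bins Angular bins used to trace the edge.
#' @return Ratio (consumer px / producer px); \code{Inf} with a warning if
#'   the ring holds no producer pixels.
#' @export
consumer_producer_ratio <- function(raster, ring_width_px = 50L,
                                    n_bins = 360L) {
  ctx <- .edge_context(raster, n_bins)
  inner <- ctx$edge_px[ctx$bins] - ring_width_px
  in_ring <- !is.na(inner) & ctx$pol$r > inner & raster$labels > 0L
  np <- sum(raster$labels[in_ring] == 1L)
  nc <- sum(raster$labels[in_ring] == 2L)
  if (np == 0L) {
    warning("no producer pixels in edge ring; returning Inf")
    return(Inf)
  }
  nc / np
}

#' Intermixing index near the expansion edge
#'
#' Walks a closed circle sampled per angular bin at radius
#' \code{edge - offset_px} (pixels), records the strain label at each
#' sample, skips empty samples, and counts producer/consumer transitions
#' \code{N} along the closed walk.  The index is \code{N} divided by the
#' circumference of the sampling circle (\code{2 * pi * mean radius}, um by
#' default; set \code{per_um = FALSE} to normalize per pixel of
#' circumference instead).
#'
#' @param raster A \code{colony_raster}.
#' @param offset_px Radial offset behind the edge, pixels (default 50).
#' @param n_bins Angular samples.
#' @param per_um Normalize per um (default) or per pixel.
#' @return Boundaries per unit circumference.
#' @export
intermixing_index <- function(raster, offset_px = 50L, n_bins = 360L,
                              per_um = TRUE) {
  ctx <- .edge_context(raster, n_bins)
  rad <- ctx$edge_px - offset_px
  ang <- (seq_len(n_bins) - 0.5) / n_bins * 2 * pi - pi
  xs <- raster$center[1L] + rad * cos(ang)
  ys <- raster$center[2L] + rad * sin(ang)
  d <- dim(raster$labels)
  col <- round(xs); row <- round(ys)
  ok <- !is.na(rad) & rad > 0 & col >= 1 & col <= d[2L] & row >= 1 & row <= d[1L]
  lab <- rep(0L, n_bins)
  lab[ok] <- raster$labels[cbind(row[ok], col[ok])]
  lab <- lab[lab > 0L]
  if (!length(lab)) stop("invalid input: sampling circle is entirely empty")
  walk <- c(lab, lab[1L])  # closed walk
  N <- sum(diff(walk) != 0L)
  circ_px <- 2 * pi * mean(rad, na.rm = TRUE)
  N / (circ_px * if (per_um) raster$pixel_size else 1)
}

#' Count spatial jackpot events on a raster
#'
#' A spatial jackpot event is a continuous consumer region that persists to
#' the expansion edge.  Connected components of consumer pixels
#' (8-connectivity) are counted when they reach the per-angle edge band
#' (within \code{edge_band_px} pixels of the local edge radius) and exceed
#' \code{min_size_px} pixels; components ending short of the edge are
#' excluded.
#'
#' @param raster A \code{colony_raster}.
#' @param edge_band_px Band depth behind the local edge, pixels.
#' @param min_size_px Minimum component size in pixels (default 10,
#'   suppressing single-pixel noise).
#' @param n_bins Angular bins for the edge trace.
#' @return Integer count.
#' @export
count_jackpot_events <- function(raster, edge_band_px = 10L,
                                 min_size_px = 10L, n_bins = 360L) {
  if (!any(raster$labels > 0L)) stop("invalid input: empty raster")
  if (!any(raster$labels == 2L)) return(0L)
  memb <- .label_components(raster$labels == 2L)
  ctx <- .edge_context(raster, n_bins)
  at_edge <- !is.na(ctx$edge_px[ctx$bins]) &
    ctx$pol$r >= ctx$edge_px[ctx$bins] - edge_band_px &
    as.vector(raster$labels == 2L)
  sizes <- tabulate(memb[memb > 0L])
  edge_comps <- unique(memb[at_edge & memb > 0L])
  sum(sizes[edge_comps] > min_size_px)
}

# 8-connectivity component labels for a logical matrix; 0 where FALSE
.label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  memb <- integer(length(mask))
  if (!length(idx)) return(memb)
  row <- (idx - 1L) %% d[1L] + 1L
  col <- (idx - 1L) %/% d[1L] + 1L
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    ok <- r2 >= 1L & r2 <= d[1L] & c2 >= 1L & c2 <= d[2L]
    j <- (c2[ok] - 1L) * d[1L] + r2[ok]
    hit <- mask[j]
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[j][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb[idx] <- igraph::components(g)$membership
  memb
}

#' All pattern metrics for a raster
#'
#' @param raster A \code{colony_raster}.
#' @param ring_width_px,offset_px,edge_band_px,min_size_px,n_bins Passed to
#'   the individual metrics.
#' @return List: \code{ratio}, \code{intermixing}, \code{jackpots}.
#' @export
pattern_metrics <- function(raster, ring_width_px = 50L, offset_px = 50L,
                            edge_band_px = 10L, min_size_px = 10L,
                            n_bins = 360L) {
  list(ratio = consumer_producer_ratio(raster, ring_width_px, n_bins),
       intermixing = intermixing_index(raster, offset_px, n_bins),
       jackpots = count_jackpot_events(raster, edge_band_px, min_size_px,
                                       n_bins))
}

#' Pattern metrics computed directly on a lattice occupancy
#'
#' Lattice-native analogue of \code{\link{pattern_metrics}}: the edge is the
#' per-angle maximum occupied node radius, the ring/offset are in um
#' (defaults match 50 px at 3.027 um/px), intermixing samples the occupied
#' node under each angular bin at \code{edge - offset_um}, and jackpots are
#' connected consumer components (hex adjacency) touching the frontier with
#' at least \code{min_size_nodes} nodes.
#'
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice}.
#' @param ring_width_um,offset_um Ring width / sampling offset, um.
#' @param min_size_nodes Minimum jackpot size, nodes.
#' @param n_bins Angular bins.
#' @return List: \code{ratio}, \code{intermixing}, \code{jackpots}.
#' @export
pattern_metrics_state <- function(occ, lattice, ring_width_um = 151.35,
                                  offset_um = 151.35, min_size_nodes = 3L,
                                  n_bins = 360L) {
  occd <- which(occ$strain > 0L)
  if (!length(occd)) stop("invalid input: empty occupancy")
  x <- lattice$xy[occd, 1L]; y <- lattice$xy[occd, 2L]
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  bins <- .bin_of(th, n_bins)
  edge <- rep(NA_real_, n_bins)
  mx <- tapply(r, bins, max)
  edge[as.integer(names(mx))] <- mx

  in_ring <- r > edge[bins] - ring_width_um
  np <- sum(occ$strain[occd[in_ring]] == 1L)
  nc <- sum(occ$strain[occd[in_ring]] == 2L)
  ratio <- if (np == 0L) Inf else nc / np

  rad <- edge - offset_um
  ang <- (seq_len(n_bins) - 0.5) / n_bins * 2 * pi - pi
  node <- .nearest_node(rad * cos(ang), rad * sin(ang), lattice)
  ok <- !is.na(rad) & rad > 0 & !is.na(node)
  lab <- integer(n_bins)
  lab[ok] <- occ$strain[node[ok]]
  lab <- lab[lab > 0L]
  mix <- if (length(lab)) {
    walk <- c(lab, lab[1L])
    sum(diff(walk) != 0L) / (2 * pi * mean(rad, na.rm = TRUE))
  } else NA_real_

  cons <- which(occ$strain == 2L)
  jack <- 0L
  if (length(cons)) {
    sub <- lattice$adj[cons, , drop = FALSE]
    pos <- integer(lattice$n); pos[cons] <- seq_along(cons)
    from <- rep(seq_along(cons), 6L)
    to <- ifelse(is.na(sub), 0L, pos[ifelse(is.na(sub), 1L, sub)])
    keep <- to > 0L
    g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(cons) - igraph::vcount(g)))
    cm <- igraph::components(g)$membership
    frontier <- frontier_nodes(occ, lattice)
    f_comp <- unique(cm[pos[intersect(frontier, cons)]])
    sizes <- tabulate(cm)
    jack <- sum(sizes[f_comp] >= min_size_nodes)
  }
  list(ratio = ratio, intermixing = mix, jackpots = jack)
}
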