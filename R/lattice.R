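#' Build a hexagonal lattice over a circular domain
#'
#' Constructs the simulation backbone: a triangular point lattice (each node
#' is the center of a hexagonal tile of side \code{side_length}) clipped to a
#' circular domain.  Adjacent node centers are \code{sqrt(3) * side_length}
#' apart; interior nodes have exactly six neighbors.  Flat-topped axial
#' coordinates are used: a node \code{(q, r)} sits at
#' \code{x = a * (q + r/2)}, \code{y = a * sqrt(3)/2 * r} with
#' \code{a = sqrt(3) * side_length}.  The node nearest the origin is the
#' domain center.
#'
#' @param domain_diameter Domain diameter in micrometers.  Must exceed
#'   \code{2 * side_length}.
#' @param side_length Hexagon side length in micrometers (default 20, giving
#'   a center-to-center spacing of ~34.64 um).
#' @return An object of class \code{hex_lattice}: a list with \code{n} (node
#'   count), \code{xy} (n x 2 matrix of positions, um), \code{axial} (n x 2
#'   integer matrix of axial coordinates), \code{adj} (n x 6 integer matrix
#'   of neighbor node ids, \code{NA}-padded), \code{degree}, \code{spacing},
#'   \code{side_length}, \code{domain_diameter}, \code{node_area} (um^2).
#' @examples
#' lat <- hex_lattice(500, 20)
#' table(lat$degree)
#' @export
hex_lattice <- function(domain_diameter, side_length = 20) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0)
    stop("invalid configuration: side_length must be a positive number")
  if (!is.numeric(domain_diameter) || length(domain_diameter) != 1L ||
      !is.finite(domain_diameter) || domain_diameter <= 2 * side_length)
    stop("invalid configuration: domain_diameter must exceed 2 * side_length")

  a <- sqrt(3) * side_length
  R <- domain_diameter / 2
  # enumerate axial coordinates in a bounding box, keep centers inside R
  rmax <- ceiling(R / (a * sqrt(3) / 2)) + 1L
  qmax <- ceiling(R / a) + rmax + 1L
  qr <- expand.grid(q = seq.int(-qmax, qmax), r = seq.int(-rmax, rmax))
  x <- a * (qr$q + qr$r / 2)
  y <- a * (sqrt(3) / 2) * qr$r
  keep <- sqrt(x^2 + y^2) <= R
  qr <- qr[keep, , drop = FALSE]
  xy <- cbind(x = x[keep], y = y[keep])
  n <- nrow(qr)

  # integer key lookup table for neighbor resolution
  qoff <- min(qr$q); roff <- min(qr$r)
  nq <- max(qr$q) - qoff + 1L; nr <- max(qr$r) - roff + 1L
  key_of <- function(q, r) (q - qoff) * nr + (r - roff) + 1L
  idx <- integer(nq * nr)
  idx[key_of(qr$q, qr$r)] <- seq_len(n)

  nb_off <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L),
                  c(0L, -1L), c(1L, -1L), c(-1L, 1L))
  adj <- matrix(NA_integer_, n, 6L)
  for (k in 1:6) {
    qn <- qr$q + nb_off[k, 1L]; rn <- qr$r + nb_off[k, 2L]
    inside <- qn >= qoff & qn <= qoff + nq - 1L & rn >= roff & rn <= roff + nr - 1L
    id <- rep(NA_integer_, n)
    id[inside] <- idx[key_of(qn[inside], rn[inside])]
    id[!is.na(id) & id == 0L] <- NA_integer_
    adj[, k] <- id
  }
  degree <- rowSums(!is.na(adj))

  structure(list(
    n = n, xy = xy, axial = as.matrix(qr), adj = adj,
    degree = as.integer(degree), spacing = a, side_length = side_length,
    domain_diameter = domain_diameter,
    node_area = 3 * sqrt(3) / 2 * side_length^2
  ), class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf(
    "hex_lattice: %d nodes, side %g um (spacing %.3f um), domain %g um\n",
    x$n, x$side_length, x$spacing, x$domain_diameter))
  invisible(x)
}

#' @export
as.data.frame.hex_lattice <- function(x, ...) {
  data.frame(node = seq_len(x$n), x_um = x$xy[, 1L], y_um = x$xy[, 2L])
}

#' Write lattice geometry to CSV
#'
#' @param lattice A \code{hex_lattice}.
#' @param path Output CSV path (columns \code{node}, \code{x_um},
#'   \code{y_um}).
#' @return Invisibly, \code{path}.
#' @export
write_lattice_csv <- function(lattice, path) {
  utils::write.csv(as.data.frame(lattice), path, row.names = FALSE)
  invisible(path)
}

#' Create an empty occupancy state
#'
#' One super-agent at most per node; strains are mutually exclusive at a
#' node.  Strain coding: 0 = empty, 1 = producer, 2 = consumer.  The
#' \code{layers} counter holds pseudo-3D stacked biomass (cell layers above
#' the lattice-resident agent); it is 0 wherever the node is empty.
#'
#' @param lattice A \code{hex_lattice}.
#' @return An object of class \code{occupancy}: list with integer
#'   \code{strain}, numeric \code{biomass} (kg dry weight, lattice-resident
#'   agent), integer \code{layers}, and numeric \code{stack_biomass} (kg dry
#'   weight aggregated in the stacked layers, so mechanics conserve total
#'   biomass).
#' @export
occupancy <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  structure(list(
    strain = integer(lattice$n),
    biomass = numeric(lattice$n),
    layers = integer(lattice$n),
    stack_biomass = numeric(lattice$n)
  ), class = "occupancy")
}

#' Strain codes used throughout the package
#' @format Named integer vector (\code{empty}, \code{producer},
#'   \code{consumer}).
#' @export
STRAIN <- c(empty = 0L, producer = 1L, consumer = 2L)

#' Frontier (expansion edge) of an occupancy
#'
#' The expansion edge is the set of occupied nodes having at least one empty
#' neighbor.
#'
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice} it lives on.
#' @return Integer vector of frontier node ids (sorted).
#' @export
frontier_nodes <- function(occ, lattice) {
  occd <- occ$strain > 0L
  adj <- lattice$adj
  # neighbor emptiness: a node is frontier if any neighbor slot is empty
  # (NA slots are outside the domain, not empty space)
  has_empty <- rep(FALSE, lattice$n)
  for (k in 1:6) {
    nb <- adj[, k]
    ok <- !is.na(nb)
    has_empty[ok] <- has_empty[ok] | !occd[nb[ok]]
  }
  which(occd & has_empty)
}

#' Shortest occupied path from a node to the expansion edge
#'
#' Breadth-first search through occupied nodes from \code{node} to the
#' nearest frontier node (an occupied node with an empty neighbor).  Length
#' is the graph distance in nodes; a node already on the frontier has length
#' 0.  When several frontier targets or several shortest predecessors exist,
#' one is drawn uniformly with the session RNG (a draw is consumed only when
#' there is more than one candidate; candidates are ordered by node id).
#'
#' @param node Occupied node id.
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice}.
#' @param max_depth Abandon the search beyond this depth and return
#'   \code{NULL} (used by the shoving rule, which only considers paths
#'   shorter than 5 nodes).
#' @return \code{NULL} if no frontier is reachable within \code{max_depth},
#'   else a list with \code{length} (integer, edges traversed) and
#'   \code{path} (node ids from \code{node} to the frontier node, inclusive).
#' @export
shortest_path_to_edge <- function(node, occ, lattice, max_depth = Inf) {
  if (occ$strain[node] == 0L)
    stop("invalid argument: node is empty")
  adj <- lattice$adj
  occd <- occ$strain > 0L
  is_frontier <- function(v) {
    nb <- adj[v, ]
    nb <- nb[!is.na(nb)]
    any(!occd[nb])
  }
  dist <- rep(NA_integer_, lattice$n)
  dist[node] <- 0L
  level <- node
  d <- 0L
  repeat {
    hits <- level[vapply(level, is_frontier, logical(1))]
    if (length(hits)) break
    if (d >= max_depth) return(NULL)
    nxt <- integer(0)
    for (v in level) {
      nb <- adj[v, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[occd[nb] & is.na(dist[nb])]
      dist[nb] <- d + 1L
      nxt <- c(nxt, nb)
    }
    nxt <- unique(nxt)
    if (!length(nxt)) return(NULL)  # enclosed pocket with no reachable edge
    level <- nxt
    d <- d + 1L
  }
  target <- .draw_one(sort(hits))
  # backtrack: any occupied neighbor at distance - 1 lies on a shortest path
  path <- integer(d + 1L)
  path[d + 1L] <- target
  v <- target
  if (d > 0L) for (l in seq.int(d, 1L)) {
    nb <- adj[v, ]
    nb <- nb[!is.na(nb)]
    cand <- nb[!is.na(dist[nb]) & dist[nb] == l - 1L]
    v <- .draw_one(sort(cand))
    path[l] <- v
  }
  list(length = d, path = path)
}

# uniform draw among candidates; consumes RNG only when >1 candidate
.draw_one <- function(cand) {
  if (length(cand) == 1L) return(cand[1L])
  cand[sample.int(length(cand), 1L)]
}
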