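# Independent oracle implementations used across test files.  These are
# deliberately naive (dense matrices, exhaustive scans, scripted replays) and
# share no code with the package internals they check.

# grow a random connected blob of occupied nodes from the lattice center
random_blob <- function(lattice, n_nodes, strain_mix = 0.5) {
  occ <- occupancy(lattice)
  center <- which.min(rowSums(lattice$xy^2))
  sel <- center
  frontier <- center
  while (length(sel) < n_nodes) {
    nb <- unique(na.omit(as.vector(lattice$adj[frontier, ])))
    nb <- setdiff(nb, sel)
    if (!length(nb)) break
    add <- nb[runif(length(nb)) < 0.7]
    if (!length(add)) add <- nb[sample.int(length(nb), 1L)]
    sel <- c(sel, add)
    frontier <- add
  }
  sel <- sel[seq_len(min(length(sel), n_nodes))]
  occ$strain[sel] <- ifelse(runif(length(sel)) < strain_mix, 1L, 2L)
  occ$biomass[sel] <- 1e-13
  occ
}

# exhaustive frontier scan: occupied nodes with >= 1 empty in-domain neighbor
oracle_frontier <- function(occ, lattice) {
  out <- integer(0)
  for (v in which(occ$strain > 0L)) {
    nb <- lattice$adj[v, ]
    nb <- nb[!is.na(nb)]
    if (any(occ$strain[nb] == 0L)) out <- c(out, v)
  }
  out
}

# plain queue BFS distance from `node` through occupied nodes to the frontier
oracle_bfs_distance <- function(node, occ, lattice) {
  fr <- oracle_frontier(occ, lattice)
  if (node %in% fr) return(0L)
  dist <- rep(NA_integer_, lattice$n)
  dist[node] <- 0L
  queue <- node
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in lattice$adj[v, ]) {
      if (is.na(w) || occ$strain[w] == 0L || !is.na(dist[w])) next
      dist[w] <- dist[v] + 1L
      if (w %in% fr) return(dist[w])
      queue <- c(queue, w)
    }
  }
  NA_integer_
}

# scripted replay of the division/shove decision procedure, mirroring the
# documented RNG draw order (a draw only when > 1 candidate, candidates by id)
oracle_division <- function(node, occ, lattice, params, max_path = 5L) {
  draw <- function(cand) if (length(cand) == 1L) cand else
    cand[sample.int(length(cand), 1L)]
  nbrs <- function(v) { nb <- lattice$adj[v, ]; nb[!is.na(nb)] }
  m <- occ$biomass[node]
  if (occ$strain[node] == 0L || m < params$division_mass)
    return(list(occ = occ, outcome = "none"))
  half <- m / 2
  empt <- sort(nbrs(node)[occ$strain[nbrs(node)] == 0L])
  if (length(empt)) {
    d <- draw(empt)
    occ$strain[d] <- occ$strain[node]
    occ$biomass[d] <- half; occ$biomass[node] <- half
    return(list(occ = occ, outcome = "placed-adjacent"))
  }
  # full-lattice BFS distances from the divider through occupied nodes
  dist <- rep(NA_integer_, lattice$n); dist[node] <- 0L
  level <- node; d <- 0L; hits <- integer(0)
  is_front <- function(v) any(occ$strain[nbrs(v)] == 0L)
  repeat {
    hits <- level[vapply(level, is_front, logical(1))]
    if (length(hits) || d >= max_path - 1L) break
    nxt <- integer(0)
    for (v in level) for (w in nbrs(v))
      if (occ$strain[w] > 0L && is.na(dist[w])) { dist[w] <- d + 1L; nxt <- c(nxt, w) }
    nxt <- unique(nxt)
    if (!length(nxt)) break
    level <- nxt; d <- d + 1L
  }
  if (!length(hits) || d >= max_path) {
    occ$layers[node] <- occ$layers[node] + 1L
    occ$stack_biomass[node] <- occ$stack_biomass[node] + half
    occ$biomass[node] <- half
    return(list(occ = occ, outcome = "stacked"))
  }
  target <- draw(sort(hits))
  path <- integer(d + 1L); path[d + 1L] <- target
  v <- target
  if (d > 0L) for (l in seq.int(d, 1L)) {
    cand <- sort(nbrs(v)[!is.na(dist[nbrs(v)]) & dist[nbrs(v)] == l - 1L])
    v <- draw(cand); path[l] <- v
  }
  k <- length(path)
  front <- path[k]
  e <- draw(sort(nbrs(front)[occ$strain[nbrs(front)] == 0L]))
  chain <- c(path, e)  # divider, ..., frontier, new target
  for (i in seq.int(k + 1L, 3L)) {  # shift occupants one node outward
    for (f in c("strain", "biomass", "layers", "stack_biomass"))
      occ[[f]][chain[i]] <- occ[[f]][chain[i - 1L]]
  }
  vac <- path[2L]
  occ$strain[vac] <- occ$strain[node]
  occ$biomass[vac] <- half
  occ$layers[vac] <- 0L; occ$stack_biomass[vac] <- 0
  occ$biomass[node] <- half
  list(occ = occ, outcome = "shoved")
}

# dense adjacency matrix from positions (edges where distance ~ spacing)
oracle_dense_adjacency <- function(lattice) {
  n <- lattice$n
  D <- as.matrix(stats::dist(lattice$xy))
  (D > 0 & abs(D - lattice$spacing) < 1e-6 * lattice$spacing) * 1
}

# naive flood fill (4/8-connectivity) component count on a logical matrix
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1L], d[2L])
  cur <- 0L
  offs <- rbind(c(-1L,-1L), c(-1L,0L), c(-1L,1L), c(0L,-1L),
                c(0L,1L), c(1L,-1L), c(1L,0L), c(1L,1L))
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      pr <- (p - 1L) %% d[1L] + 1L; pc <- (p - 1L) %/% d[1L] + 1L
      for (o in seq_len(8L)) {
        r2 <- pr + offs[o, 1L]; c2 <- pc + offs[o, 2L]
        if (r2 < 1L || r2 > d[1L] || c2 < 1L || c2 > d[2L]) next
        q <- (c2 - 1L) * d[1L] + r2
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

# paint a polar label pattern onto an occupancy (wedges of consumer on a
# producer disk), for lattice-vs-raster agreement tests
paint_wedge_occupancy <- function(lattice, radius_um, wedges) {
  occ <- occupancy(lattice)
  r <- sqrt(rowSums(lattice$xy^2))
  th <- atan2(lattice$xy[, 2L], lattice$xy[, 1L]) %% (2 * pi)
  inside <- r <= radius_um
  occ$strain[inside] <- 1L
  for (w in seq_len(nrow(wedges))) {
    dth <- abs(((th - wedges[w, 1L] + pi) %% (2 * pi)) - pi)
    occ$strain[inside & dth <= wedges[w, 2L] / 2 & r >= 0.3 * radius_um] <- 2L
  }
  occ$biomass[occ$strain > 0L] <- 1e-13
  occ
}

# reduced-scale strain parameter sets matching the package defaults
test_producer <- function(...) strain_params("producer", ...)
test_consumer <- function(...) strain_params("consumer", ...)
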