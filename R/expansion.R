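#' Edge-directed cell shoving
#'
#' Implements the displacement rule used at division when all neighbors of a
#' dividing super-agent are occupied: the shortest occupied path from the
#' node to the expansion edge is computed
#' (\code{\link{shortest_path_to_edge}}); if it is shorter than
#' \code{max_path} nodes (< 100 um at 20 um side length), every cell along
#' the path is shoved one node outward, the frontier cell moves to a
#' uniformly drawn empty neighbor, and the node adjacent to the divider is
#' vacated.  Strain labels, biomass, and stacked layers travel with their
#' cell.  If the path is \code{>= max_path} nodes long the shove fails and
#' the state is unchanged.
#'
#' RNG draw order (each draw taken only when more than one candidate exists;
#' candidates ordered by node id): tied frontier targets, then one draw per
#' backtracked path step, then the frontier cell's empty neighbor.
#'
#' @param node Occupied node id of the divider (stays in place).
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice}.
#' @param max_path Threshold in nodes (default 5): shove succeeds only for
#'   path lengths strictly below it.
#' @return List: \code{success}; on success also \code{occ} (updated),
#'   \code{path} (divider to old frontier node), \code{vacated} (node id
#'   freed next to the divider), \code{edge_target} (node newly colonized).
#' @export
shove_toward_edge <- function(node, occ, lattice, max_path = 5L) {
  if (occ$strain[node] == 0L) stop("invalid argument: node is empty")
  sp <- shortest_path_to_edge(node, occ, lattice, max_depth = max_path - 1L)
  if (is.null(sp) || sp$length >= max_path || sp$length < 1L)
    return(list(success = FALSE))
  path <- sp$path
  k <- length(path)
  front <- path[k]
  nb <- lattice$adj[front, ]
  nb <- nb[!is.na(nb)]
  empties <- sort(nb[occ$strain[nb] == 0L])
  target <- .draw_one(empties)
  # move cells outward: frontier -> target, then each path cell one step out
  chain_from <- path[k:2L]
  chain_to <- c(target, if (k > 2L) path[k:3L] else integer(0))
  for (f in c("strain", "biomass", "layers", "stack_biomass")) {
    vals <- occ[[f]][chain_from]
    occ[[f]][chain_to] <- vals
  }
  vac <- path[2L]
  occ$strain[vac] <- 0L
  occ$biomass[vac] <- 0
  occ$layers[vac] <- 0L
  occ$stack_biomass[vac] <- 0
  list(success = TRUE, occ = occ, path = path, vacated = vac,
       edge_target = target)
}

#' Attempt division of the super-agent at a node
#'
#' If the agent's biomass has reached its strain's division mass it splits
#' 50/50: one daughter keeps the node, the other (i) occupies a uniformly
#' drawn empty neighbor if one exists, else (ii) is placed via
#' \code{\link{shove_toward_edge}} into the vacated adjacent node if the
#' expansion edge is fewer than \code{max_path} nodes away, else (iii) is
#' aggregated at the same node in a layer above (pseudo-3D stacking: the
#' layer counter increments and the daughter's mass moves to the stack).
#' Total biomass and per-node strain exclusivity are preserved in all
#' branches.
#'
#' @param node Node id holding the candidate divider.
#' @param occ An \code{occupancy}.
#' @param lattice The \code{hex_lattice}.
#' @param params The divider's \code{strain_params} (supplies
#'   \code{division_mass}).
#' @param max_path Shove distance threshold in nodes (default 5).
#' @return List: \code{occ} (updated), \code{outcome} one of
#'   \code{"none"}, \code{"placed-adjacent"}, \code{"shoved"},
#'   \code{"stacked"}, and \code{daughter_node} (NA when none/stacked).
#' @export
attempt_division <- function(node, occ, lattice, params, max_path = 5L) {
  stopifnot(inherits(params, "strain_params"))
  m <- occ$biomass[node]
  if (occ$strain[node] == 0L || m < params$division_mass)
    return(list(occ = occ, outcome = "none", daughter_node = NA_integer_))
  half <- m / 2
  nb <- lattice$adj[node, ]
  nb <- nb[!is.na(nb)]
  empties <- sort(nb[occ$strain[nb] == 0L])
  if (length(empties)) {
    d <- .draw_one(empties)
    occ$strain[d] <- occ$strain[node]
    occ$biomass[d] <- half
    occ$biomass[node] <- half
    return(list(occ = occ, outcome = "placed-adjacent", daughter_node = d))
  }
  sh <- shove_toward_edge(node, occ, lattice, max_path = max_path)
  if (sh$success) {
    occ <- sh$occ
    d <- sh$vacated
    occ$strain[d] <- occ$strain[node]
    occ$biomass[d] <- half
    occ$biomass[node] <- half
    return(list(occ = occ, outcome = "shoved", daughter_node = d))
  }
  occ$layers[node] <- occ$layers[node] + 1L
  occ$stack_biomass[node] <- occ$stack_biomass[node] + half
  occ$biomass[node] <- half
  list(occ = occ, outcome = "stacked", daughter_node = NA_integer_)
}

#' Export an occupancy snapshot as tidy CSV
#' @param occ An \code{occupancy}.
#' @param path Output path (columns node, strain, biomass, layers).
#' @return Invisibly, \code{path}.
#' @export
write_occupancy_csv <- function(occ, path) {
  occd <- which(occ$strain > 0L)
  df <- data.frame(
    node = occd,
    strain = names(STRAIN)[occ$strain[occd] + 1L],
    biomass = occ$biomass[occd],
    layers = occ$layers[occd]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
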