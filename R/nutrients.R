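#' Nutrient concentration fields on a hex lattice
#'
#' Tracks per-node concentrations (mM) of the three solutes the model
#' resolves: carbon, nitrate (no3), and nitrite (no2).  Transport is
#' node-to-node Fickian diffusion in finite-volume form: the flux between
#' two adjacent nodes is \code{D * Ledge / dist * (Cj - Ci)} per unit depth,
#' so with uniform hexagonal tiles the per-second exchange rate is
#' \code{k = D * side / (spacing * node_area)} and mass balance at each node
#' is exact by construction.  Peripheral sources are modeled as Dirichlet
#' boundary nodes (the lattice rim) re-clamped to fixed concentrations after
#' every transport step.
#'
#' @param lattice A \code{hex_lattice}.
#' @param init Named numeric: initial uniform concentration (mM) per solute.
#' @param D Named numeric: diffusion coefficient per solute (um^2/s).
#'   Defaults are small-solute-in-agar values (ions ~1.2e3, a mixed carbon
#'   substrate ~6e2 um^2/s); the source publication leaves these to its
#'   model-description reference, so they are configurable here.
#' @param boundary \code{"rim"} (all nodes with fewer than six neighbors,
#'   i.e. the domain edge), \code{"none"} (closed domain), or an integer
#'   vector of node ids.
#' @param boundary_values Named numeric, mM, clamped at boundary nodes.
#' @param source_solutes Solutes with a constant peripheral source; the rest
#'   get a no-flux rim.  Default carbon and nitrate: nitrite is produced
#'   only by the producer's metabolism and leaves the domain nowhere (a
#'   nitrite-supplemented scenario adds \code{"no2"}).
#' @param height_um Effective domain depth used to convert concentrations to
#'   amounts (agar slab depth; amounts are \code{mM * node volume in L}
#'   = mmol).
#' @return Object of class \code{nutrient_field}.
#' @export
nutrient_field <- function(lattice,
                           init = c(carbon = 22, no3 = 1, no2 = 0),
                           D = c(carbon = 600, no3 = 1200, no2 = 1200),
                           boundary = "rim",
                           boundary_values = c(carbon = 22, no3 = 1, no2 = 0),
                           source_solutes = c("carbon", "no3"),
                           height_um = 4000) {
  stopifnot(inherits(lattice, "hex_lattice"))
  sol <- c("carbon", "no3", "no2")
  init <- .complete_named(init, sol, 0)
  D <- .complete_named(D, sol, NA)
  boundary_values <- .complete_named(boundary_values, sol, 0)
  if (any(!is.finite(D)) || any(D <= 0))
    stop("invalid configuration: diffusion coefficients must be positive")
  if (any(init < 0) || any(boundary_values < 0))
    stop("invalid configuration: concentrations must be non-negative")
  bnd <- if (identical(boundary, "rim")) which(lattice$degree < 6L)
         else if (identical(boundary, "none")) integer(0)
         else as.integer(boundary)
  source_solutes <- intersect(sol, source_solutes)
  conc <- matrix(rep(init, each = lattice$n), lattice$n, 3,
                 dimnames = list(NULL, sol))
  conc[bnd, source_solutes] <-
    rep(boundary_values[source_solutes], each = length(bnd))
  structure(list(
    conc = conc, D = D, boundary = bnd, boundary_values = boundary_values,
    source_solutes = source_solutes,
    height_um = height_um,
    node_volume_L = lattice$node_area * height_um * 1e-15,
    # per-second exchange rate coefficient per solute (finite-volume form)
    k = D * lattice$side_length / (lattice$spacing * lattice$node_area),
    cache = new.env(parent = emptyenv())
  ), class = "nutrient_field")
}

.complete_named <- function(x, nms, default) {
  out <- stats::setNames(rep(default, length(nms)), nms)
  if (!is.null(names(x))) out[names(x)] <- x else out[] <- x
  out[nms]
}

#' @export
print.nutrient_field <- function(x, ...) {
  cat(sprintf("nutrient_field: %d nodes, %d boundary nodes\n",
              nrow(x$conc), length(x$boundary)))
  print(colMeans(x$conc))
  invisible(x)
}

# sparse symmetric adjacency (0/1) of a lattice, cached on the field
.adjacency_sparse <- function(lattice) {
  n <- lattice$n
  i <- rep(seq_len(n), 6L)
  j <- as.vector(lattice$adj)
  ok <- !is.na(j)
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1, dims = c(n, n))
}

#' Diffuse all solutes for one time step
#'
#' Integrates \code{dC/dt = k * sum_nb (C_nb - C)} for \code{dt} seconds.
#' Two integrators are available.  \code{"implicit"} (default) is an
#' unconditionally stable backward-Euler step solved with a cached sparse
#' Cholesky factorization; boundary nodes are eliminated as Dirichlet
#' unknowns.  \code{"explicit"} sub-steps the forward-Euler scheme at
#' \code{0.2x} its stability limit \code{1/(6k)} so any outer \code{dt} is
#' stable; boundary values are re-applied every sub-step.  Both schemes
#' conserve total solute amount exactly on a closed domain and preserve
#' non-negativity.
#'
#' @param field A \code{nutrient_field}.
#' @param lattice The \code{hex_lattice}.
#' @param dt Time step in seconds.
#' @param method \code{"implicit"} or \code{"explicit"}.
#' @return The updated \code{nutrient_field}.
#' @export
diffuse <- function(field, lattice, dt, method = c("implicit", "explicit")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "nutrient_field"), dt > 0)
  if (any(field$conc < 0))
    stop("invalid state: negative concentrations")
  A <- field$cache$A
  if (is.null(A)) A <- field$cache$A <- .adjacency_sparse(lattice)
  deg <- lattice$degree
  n <- lattice$n
  bnd <- field$boundary
  free <- if (length(bnd)) setdiff(seq_len(n), bnd) else seq_len(n)
  src <- field$source_solutes
  if (method == "implicit") {
    # solutes sharing a diffusivity and a boundary treatment share one
    # factorization and one multi-right-hand-side solve
    if (length(bnd) && is.null(field$cache$B))
      field$cache$B <- A[free, bnd, drop = FALSE]
    for (kv in unique(field$k)) {
      for (dir in c(TRUE, FALSE)) {
        cols <- names(field$k)[field$k == kv &
                               (names(field$k) %in% src) == dir]
        if (!length(cols)) next
        use_bnd <- dir && length(bnd) > 0L
        fr <- if (use_bnd) free else seq_len(n)
        key <- sprintf("chol_%.8g_%.8g_%d", kv, dt, use_bnd)
        fac <- field$cache[[key]]
        if (is.null(fac)) {
          L <- kv * (A - Matrix::Diagonal(n, deg))
          M <- Matrix::Diagonal(length(fr)) - dt * L[fr, fr, drop = FALSE]
          fac <- field$cache[[key]] <-
            Matrix::Cholesky(Matrix::forceSymmetric(M))
        }
        b <- field$conc[fr, cols, drop = FALSE]
        if (use_bnd)
          b <- b + dt * kv *
            as.matrix(field$cache$B %*% field$conc[bnd, cols, drop = FALSE])
        field$conc[fr, cols] <- as.matrix(Matrix::solve(fac, b, system = "A"))
      }
    }
  } else {
    for (s in colnames(field$conc)) {
      k <- field$k[[s]]
      clamp <- length(bnd) && s %in% src
      cvec <- field$conc[, s]
      dt_stable <- 1 / (6 * k)
      n_sub <- max(1L, ceiling(dt / (0.2 * dt_stable)))
      h <- dt / n_sub
      for (ss in seq_len(n_sub)) {
        cvec <- cvec + h * k * (as.numeric(A %*% cvec) - deg * cvec)
        if (clamp) cvec[bnd] <- field$boundary_values[[s]]
      }
      field$conc[, s] <- cvec
    }
  }
  if (length(bnd) && length(src))
    field$conc[bnd, src] <- rep(field$boundary_values[src],
                                each = length(bnd))
  field
}

#' Clamp boundary nodes to their source concentrations
#'
#' Re-applies the constant peripheral sources (defaults: carbon 22 mM,
#' nitrate 1 mM).  Only solutes listed in the field's
#' \code{source_solutes} are clamped; the rest keep a no-flux rim.  A
#' nitrite-supplemented scenario adds nitrite to the source set with a
#' positive concentration.
#'
#' @param field A \code{nutrient_field} with a non-empty boundary set.
#' @param values Optional named override of the stored boundary values (mM).
#' @return The updated field.
#' @export
apply_sources <- function(field, values = NULL) {
  stopifnot(inherits(field, "nutrient_field"))
  if (!length(field$boundary))
    stop("invalid configuration: field has no boundary nodes")
  if (!is.null(values)) {
    values <- .complete_named(values, colnames(field$conc), NA)
    keep <- is.na(values)
    values[keep] <- field$boundary_values[keep]
    if (any(values < 0))
      stop("invalid configuration: negative boundary value")
    field$boundary_values <- values
  }
  src <- field$source_solutes
  if (length(src))
    field$conc[field$boundary, src] <-
      rep(field$boundary_values[src], each = length(field$boundary))
  field
}

#' Total solute amounts in the domain
#'
#' @param field A \code{nutrient_field}.
#' @return Named numeric, mmol per solute (concentration times node volume,
#'   summed over nodes).
#' @export
solute_totals <- function(field) {
  colSums(field$conc) * field$node_volume_L
}

#' Write a field snapshot as tidy CSV (node, solute, mM)
#' @param field A \code{nutrient_field}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_field_csv <- function(field, path) {
  n <- nrow(field$conc)
  df <- data.frame(
    node = rep(seq_len(n), 3L),
    solute = rep(colnames(field$conc), each = n),
    mM = as.vector(field$conc)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
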