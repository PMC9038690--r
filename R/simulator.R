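#' Alternating anoxic/oxic environment schedule
#'
#' @param total_h Total run length in hours.
#' @param interval_h Either a single interval length (phases alternate every
#'   \code{interval_h} hours; the default 72 h / 6 h run gives six intervals
#'   per condition) or a pair \code{c(anoxic_h, oxic_h)} for asymmetric
#'   cycles such as the experimental 36 h anoxic / 12 h oxic regime.
#' @param first_phase \code{"anoxic"} or \code{"oxic"}.
#' @return Object of class \code{environment_schedule}: data frame with
#'   columns \code{phase}, \code{duration_h}, \code{t_start_h},
#'   \code{t_end_h}.
#' @export
make_schedule <- function(total_h, interval_h = 6,
                          first_phase = c("anoxic", "oxic")) {
  first_phase <- match.arg(first_phase)
  if (total_h <= 0) stop("invalid configuration: total_h must be positive")
  if (length(interval_h) == 1L) {
    if (interval_h <= 0 || abs(total_h / interval_h - round(total_h / interval_h)) > 1e-9)
      stop("invalid configuration: total_h must be a multiple of interval_h")
    nint <- as.integer(round(total_h / interval_h))
    phases <- rep(c(first_phase, setdiff(c("anoxic", "oxic"), first_phase)),
                  length.out = nint)
    dur <- rep(interval_h, nint)
  } else if (length(interval_h) == 2L) {
    cyc <- sum(interval_h)
    if (any(interval_h <= 0) || abs(total_h / cyc - round(total_h / cyc)) > 1e-9)
      stop("invalid configuration: total_h must be a multiple of the cycle length")
    ncyc <- as.integer(round(total_h / cyc))
    second <- setdiff(c("anoxic", "oxic"), first_phase)
    dmap <- c(anoxic = interval_h[1L], oxic = interval_h[2L])
    phases <- rep(c(first_phase, second), ncyc)
    dur <- as.numeric(dmap[phases])
  } else stop("invalid configuration: interval_h must have length 1 or 2")
  ends <- cumsum(dur)
  structure(data.frame(phase = phases, duration_h = dur,
                       t_start_h = c(0, ends[-length(ends)]),
                       t_end_h = ends),
            class = c("environment_schedule", "data.frame"))
}

#' Inoculate the domain center
#'
#' Occupies every node within \code{radius} of the domain center; each node
#' receives a producer with probability \code{producer_fraction} (else a
#' consumer), emulating a well-mixed 1:1 inoculum at the default 0.5.
#' Initial masses are drawn uniformly between 10 and 100 percent of the
#' strain's division mass.  Draw order (for reproducibility): one strain
#' draw per inoculated node in node-id order, then one mass draw per node in
#' the same order.
#'
#' @param lattice A \code{hex_lattice}.
#' @param radius Inoculum radius, um (must be below the domain radius).
#' @param producer_fraction Probability a node starts as producer.
#' @param producer,consumer \code{strain_params} (for division masses).
#' @return An \code{occupancy}.
#' @export
init_inoculum <- function(lattice, radius, producer_fraction = 0.5,
                          producer = strain_params("producer"),
                          consumer = strain_params("consumer")) {
  if (radius >= lattice$domain_diameter / 2)
    stop("invalid configuration: inoculum radius must be below the domain radius")
  occ <- occupancy(lattice)
  r <- sqrt(rowSums(lattice$xy^2))
  inoc <- which(r <= radius)
  strains <- ifelse(stats::runif(length(inoc)) < producer_fraction, 1L, 2L)
  mdiv <- ifelse(strains == 1L, producer$division_mass, consumer$division_mass)
  occ$strain[inoc] <- strains
  occ$biomass[inoc] <- stats::runif(length(inoc), 0.1, 1.0) * mdiv
  occ
}

#' Simulation configuration
#'
#' Bundles all tunables of a run.  Scenarios: \code{"anoxic-start"} (the
#' standard design: anoxic first phase, nitrate as the sole exogenous N
#' source), \code{"oxic-start"} (first phase oxic), and
#' \code{"nitrite-supplemented"} (nitrite supplied exogenously alongside
#' nitrate: present in the medium at \code{no2_supplement} mM from the
#' start, with the usual no-flux rim for nitrite).
#'
#' @param pH 6.5 (strong nitrite toxicity) or 7.5 (none).
#' @param scenario See above.
#' @param domain_diameter,side_length Lattice geometry, um.
#' @param total_h,interval_h,dt_s Schedule and outer time step (60 s
#'   default).
#' @param inoculum_radius Inoculum radius, um (2 mm on the full 1 cm
#'   domain).
#' @param producer_fraction Producer probability per inoculated node.
#' @param boundary_values Peripheral source concentrations, mM (carbon 22,
#'   nitrate 1, nitrite 0).
#' @param no2_supplement Initial nitrite concentration (mM) of the
#'   nitrite-supplemented scenario.  The source study does not print its
#'   supplement level; the default 0.2 mM (the nitrite inhibition constant's
#'   scale) relieves the consumer's early dependency without saturating its
#'   uptake kinetics.
#' @param D Diffusion coefficients, um^2/s.
#' @param height_um Effective domain depth for concentration-amount
#'   conversion.
#' @param producer,consumer Per-strain kinetics (\code{\link{strain_params}}).
#' @param max_path Shove distance threshold, nodes.
#' @param closed If TRUE the domain has no boundary sources (used for
#'   conservation checks).
#' @param seed Root RNG seed; all subsystem streams derive from it.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(pH = 6.5,
                              scenario = c("anoxic-start", "oxic-start",
                                           "nitrite-supplemented"),
                              domain_diameter = 10000, side_length = 20,
                              total_h = 72, interval_h = 6, dt_s = 60,
                              inoculum_radius = 2000,
                              producer_fraction = 0.5,
                              boundary_values = c(carbon = 22, no3 = 1, no2 = 0),
                              no2_supplement = 0.2,
                              D = c(carbon = 600, no3 = 1200, no2 = 1200),
                              height_um = 4000,
                              producer = strain_params("producer"),
                              consumer = strain_params("consumer"),
                              max_path = 5L, closed = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  if (dt_s <= 0) stop("invalid configuration: dt_s must be positive")
  nstep <- total_h * 3600 / dt_s
  if (abs(nstep - round(nstep)) > 1e-9)
    stop("invalid configuration: total time must be a multiple of dt_s")
  if (!pH %in% c(6.5, 7.5))
    stop("invalid configuration: pH must be 6.5 or 7.5")
  bv <- .complete_named(boundary_values, c("carbon", "no3", "no2"), 0)
  source_solutes <- c("carbon", "no3")
  # supplemented nitrite is present in the medium from the start; the rim
  # stays no-flux for nitrite (a clamp below ambient would act as a sink)
  if (scenario == "nitrite-supplemented") bv[["no2"]] <- no2_supplement
  first_phase <- if (scenario == "oxic-start") "oxic" else "anoxic"
  structure(list(
    pH = pH, scenario = scenario, domain_diameter = domain_diameter,
    side_length = side_length, total_h = total_h, interval_h = interval_h,
    dt_s = dt_s, inoculum_radius = inoculum_radius,
    producer_fraction = producer_fraction, boundary_values = bv,
    source_solutes = source_solutes,
    D = .complete_named(D, c("carbon", "no3", "no2"), NA),
    height_um = height_um, producer = producer, consumer = consumer,
    max_path = as.integer(max_path), closed = isTRUE(closed),
    first_phase = first_phase, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Reduced-domain test preset
#'
#' A 3.5 mm / 24 h configuration (0.6 mm inoculum) used for tests and
#' desk-scale experiments; all other parameters as
#' \code{\link{simulation_config}}.
#'
#' @param ... Overrides passed to \code{\link{simulation_config}}.
#' @return A \code{simulation_config}.
#' @export
reduced_config <- function(...) {
  args <- list(...)
  defaults <- list(domain_diameter = 3500, total_h = 24,
                   inoculum_radius = 600)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(simulation_config, args)
}

#' Run the agent-based range expansion simulation
#'
#' Per 60 s outer step: clamp peripheral sources, diffuse all solutes
#' (implicit finite-volume step), evaluate per-node Monod growth rates and
#' nitrite-inhibited yields under the current redox phase, update biomass by
#' explicit Euler, draw down/release nutrients stoichiometrically (growth is
#' capped by local availability), then process divisions in seeded-random
#' order with adjacent placement, edge-directed shoving, or pseudo-3D
#' stacking.  State is snapshotted at every phase transition and at the end.
#'
#' @param config A \code{simulation_config}.
#' @param verbose Print per-interval summaries.
#' @return Object of class \code{expansion_trajectory}: list with
#'   \code{config}, \code{lattice}, \code{schedule}, \code{occupancy} and
#'   \code{field} (final), \code{snapshots} (one per phase transition plus
#'   run end: clock, upcoming phase, strain/biomass/layers vectors, solute
#'   totals), \code{totals} (per-step data frame of domain solute totals in
#'   mmol, total biomass, phase), and \code{ledger} (cumulative mmol:
#'   no3 reduced by producer, no2 produced, no2 consumed by consumer;
#'   capped-growth event count).
#' @export
run_simulation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(2147483646L, 2L)

  lattice <- hex_lattice(config$domain_diameter, config$side_length)
  init <- config$boundary_values
  field <- nutrient_field(
    lattice, init = init, D = config$D,
    boundary = if (config$closed) "none" else "rim",
    boundary_values = config$boundary_values,
    source_solutes = config$source_solutes, height_um = config$height_um)

  set.seed(sub_seeds[1L])
  occ <- init_inoculum(lattice, config$inoculum_radius,
                       config$producer_fraction,
                       config$producer, config$consumer)

  schedule <- make_schedule(config$total_h, config$interval_h,
                            config$first_phase)
  nstep <- as.integer(round(config$total_h * 3600 / config$dt_s))
  t_h <- (seq_len(nstep) - 1) * config$dt_s / 3600
  phase_of_step <- as.character(
    schedule$phase[findInterval(t_h + 1e-9, schedule$t_start_h)])
  transition_after <- c(phase_of_step[-1L] != phase_of_step[-nstep], TRUE)

  vol <- field$node_volume_L
  pars <- list(config$producer, config$consumer)
  dt_h <- config$dt_s / 3600
  ledger <- c(no3_reduced = 0, no2_produced = 0, no2_consumed = 0)
  capped_events <- 0L
  totals <- matrix(0, nstep + 1L, 4L,
                   dimnames = list(NULL, c("carbon", "no3", "no2", "biomass")))
  totals[1L, ] <- c(solute_totals(field),
                    sum(occ$biomass) + sum(occ$stack_biomass))
  snapshots <- list()

  set.seed(sub_seeds[2L])
  for (step in seq_len(nstep)) {
    phase <- phase_of_step[step]
    if (!config$closed) field <- apply_sources(field)
    field <- diffuse(field, lattice, config$dt_s, method = "implicit")

    # --- growth and stoichiometric turnover (vectorized per strain) ---
    for (si in 1:2) {
      p <- pars[[si]]
      idx <- which(occ$strain == si)
      if (!length(idx)) next
      C <- field$conc[idx, "carbon"]
      no3 <- field$conc[idx, "no3"]
      no2 <- field$conc[idx, "no2"]
      mu <- growth_rate(p, phase, C, no3, no2, config$pH)
      # anoxic biomass gain is yield-limited: uptake of the N acceptor is
      # Monod-limited at mu/Y_max per unit biomass, and nitrite toxicity
      # converts that uptake to biomass at the inhibited yield Y_i, so the
      # realized growth rate is mu * Y_i / Y_max (toxicity slows growth,
      # it does not accelerate acceptor turnover)
      if (phase == "anoxic") {
        Yi <- yield_coefficient(p, no2, config$pH)
        mu <- mu * Yi / p$Y_max
      }
      dm <- occ$biomass[idx] * mu * dt_h
      need_c <- 1000 * dm / p$Y_carbon
      fac <- ifelse(need_c > 0, pmin(1, C * vol / need_c), 1)
      if (phase == "anoxic") {
        need_n <- 1000 * dm / Yi
        navail <- (if (si == 1L) no3 else no2) * vol
        fac <- pmin(fac, ifelse(need_n > 0, navail / need_n, 1))
      }
      fac <- pmax(0, pmin(1, fac))
      capped_events <- capped_events + sum(fac < 1)
      occ$biomass[idx] <- occ$biomass[idx] + fac * dm
      field$conc[idx, "carbon"] <- pmax(0, C - fac * need_c / vol)
      if (phase == "anoxic") {
        used_n <- fac * need_n
        if (si == 1L) {
          field$conc[idx, "no3"] <- pmax(0, no3 - used_n / vol)
          prod <- used_n * p$no2_per_no3
          field$conc[idx, "no2"] <- no2 + prod / vol
          ledger[["no3_reduced"]] <- ledger[["no3_reduced"]] + sum(used_n)
          ledger[["no2_produced"]] <- ledger[["no2_produced"]] + sum(prod)
        } else {
          field$conc[idx, "no2"] <- pmax(0, no2 - used_n / vol)
          ledger[["no2_consumed"]] <- ledger[["no2_consumed"]] + sum(used_n)
        }
      }
    }

    # --- divisions in seeded-random order ---
    mdiv <- c(config$producer$division_mass, config$consumer$division_mass)
    cand <- which(occ$strain > 0L)
    cand <- cand[occ$biomass[cand] >= mdiv[occ$strain[cand]]]
    if (length(cand) > 1L) cand <- cand[sample.int(length(cand))]
    for (v in cand) {
      res <- attempt_division(v, occ, lattice, pars[[occ$strain[v]]],
                              max_path = config$max_path)
      occ <- res$occ
    }

    totals[step + 1L, ] <- c(solute_totals(field),
                             sum(occ$biomass) + sum(occ$stack_biomass))
    if (transition_after[step]) {
      snapshots[[length(snapshots) + 1L]] <- list(
        t_h = t_h[step] + dt_h, phase_ending = phase,
        strain = occ$strain, biomass = occ$biomass, layers = occ$layers,
        totals = totals[step + 1L, ])
      if (verbose)
        message(sprintf("t = %5.1f h  end of %s phase  occupied nodes %d",
                        t_h[step] + dt_h, phase, sum(occ$strain > 0L)))
    }
  }

  structure(list(
    config = config, lattice = lattice, schedule = schedule,
    occupancy = occ, field = field, snapshots = snapshots,
    totals = data.frame(t_h = c(0, t_h + dt_h), totals,
                        phase = c(phase_of_step[1L], phase_of_step)),
    ledger = ledger, capped_events = capped_events
  ), class = "expansion_trajectory")
}

#' @export
print.expansion_trajectory <- function(x, ...) {
  cat(sprintf(
    "expansion_trajectory: %s, pH %.1f, %g h on %g um domain (%d nodes)\n",
    x$config$scenario, x$config$pH, x$config$total_h,
    x$config$domain_diameter, x$lattice$n))
  cat(sprintf("  occupied nodes: %d (producer %d, consumer %d), %d snapshots\n",
              sum(x$occupancy$strain > 0L), sum(x$occupancy$strain == 1L),
              sum(x$occupancy$strain == 2L), length(x$snapshots)))
  invisible(x)
}

#' Write per-step domain solute totals to CSV
#' @param traj An \code{expansion_trajectory}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_totals_csv <- function(traj, path) {
  utils::write.csv(traj$totals, path, row.names = FALSE)
  invisible(path)
}
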