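#' Kinetic parameters for one strain
#'
#' The model resolves two isogenic denitrifying strains: a nitrate-reducing
#' \emph{producer} (reduces NO3- to NO2-, cannot reduce NO2-) and a
#' nitrite-reducing \emph{consumer} (reduces NO2- onward, cannot reduce
#' NO3-).  Under oxic conditions both grow on carbon alone; under anoxic
#' conditions the producer additionally requires nitrate and the consumer
#' nitrite.  Nitrite is toxic at pH 6.5 and reduces the biomass yield on the
#' strain's nitrogen electron acceptor (see \code{\link{yield_coefficient}}).
#'
#' The source model defers its parameter table to a separate model
#' description, so defaults here are order-of-magnitude literature values
#' for \emph{Pseudomonas}-like denitrifiers on rich medium, calibrated once
#' against the qualitative regime the source figures establish (nitrate
#' strongly depleted during anoxic phases, nitrite accumulating to toxic
#' levels only at pH 7.5, a producer-led anoxic front) and fully
#' configurable: \code{mu_max} 0.25/h (an effective super-agent doubling of
#' ~2.8 h, keeping 72 h expansions at the mm scale of a real plate);
#' half-saturation 2 mM for carbon; N-acceptor half-saturation 0.1 mM
#' (producer, NO3-) and 2 mM (consumer, NO2-: nitrite must accumulate well
#' above the quasi-steady front concentration before consumer growth takes
#' off, giving the producer-first anoxic expansion pattern); maximum yield
#' 0.002 (producer) and 5e-4 (consumer) kg dry weight per mol of N acceptor
#' -- nitrite reduction transfers one electron per N against two for nitrate
#' reduction, and carries the detoxification overhead, so the consumer
#' gains far less biomass per mole while turning over nitrite rapidly --
#' with a ten-fold yield reduction under full nitrite inhibition
#' (\code{Y_min = Y_max/10}); inhibition constant 0.2 mM; division mass
#' 3.5e-13 kg (a super-agent of ~1000 cells); carbon yield 0.05 kg/mol.
#'
#' @param strain \code{"producer"} or \code{"consumer"}.
#' @param mu_max Maximum specific growth rate, 1/h (same value is used under
#'   both redox conditions, for parameter parsimony).
#' @param K_C Carbon half-saturation constant, mM.
#' @param K_N Half-saturation for the strain's N electron acceptor
#'   (nitrate for the producer, nitrite for the consumer), mM.
#' @param Y_max,Y_min Maximum/minimum biomass yield on the N acceptor,
#'   kg dry weight/mol.
#' @param K_inh Nitrite inhibition coefficient, mM.
#' @param division_mass Super-agent mass at division, kg dry weight.
#' @param Y_carbon Biomass yield on carbon, kg dry weight/mol (drawn down in
#'   both redox conditions).
#' @param no2_per_no3 Producer stoichiometry: mol NO2- released per mol NO3-
#'   reduced (default 1).
#' @return Object of class \code{strain_params}.
#' @export
strain_params <- function(strain = c("producer", "consumer"),
                          mu_max = 0.25, K_C = 2, K_N = NULL,
                          Y_max = NULL, Y_min = NULL, K_inh = 0.2,
                          division_mass = 3.5e-13, Y_carbon = 0.05,
                          no2_per_no3 = 1) {
  strain <- match.arg(strain)
  if (is.null(K_N)) K_N <- if (strain == "producer") 0.1 else 2.0
  if (is.null(Y_max)) Y_max <- if (strain == "producer") 0.002 else 5e-4
  if (is.null(Y_min)) Y_min <- Y_max / 10
  if (mu_max <= 0 || K_C <= 0 || K_N <= 0 || K_inh <= 0 ||
      division_mass <= 0 || Y_carbon <= 0)
    stop("invalid configuration: kinetic parameters must be positive")
  if (Y_min > Y_max || Y_min < 0)
    stop("invalid configuration: need 0 <= Y_min <= Y_max")
  structure(list(strain = strain, mu_max = mu_max, K_C = K_C, K_N = K_N,
                 Y_max = Y_max, Y_min = Y_min, K_inh = K_inh,
                 division_mass = division_mass, Y_carbon = Y_carbon,
                 no2_per_no3 = no2_per_no3),
            class = "strain_params")
}

#' Condition-dependent Monod growth rate
#'
#' Oxic conditions: both strains are carbon-limited,
#' \code{mu = mu_max * C/(K_C + C)}.  Anoxic conditions multiply the carbon
#' term by a Monod term in the strain's N electron acceptor: nitrate for the
#' producer, nitrite for the consumer (dual-Monod kinetics).  pH does not
#' enter the rate; nitrite toxicity acts on the yield
#' (\code{\link{yield_coefficient}}), not on \code{mu}.
#'
#' @param params A \code{strain_params}.
#' @param condition \code{"oxic"} or \code{"anoxic"}.
#' @param C,no3,no2 Concentrations, mM (vectorized).
#' @param pH Ignored by the rate; accepted for interface symmetry.
#' @return Growth rate(s) in 1/h, in \code{[0, mu_max]}.
#' @export
growth_rate <- function(params, condition = c("oxic", "anoxic"),
                        C, no3 = 0, no2 = 0, pH = 6.5) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "strain_params"))
  if (any(C < 0) || any(no3 < 0) || any(no2 < 0))
    stop("invalid argument: negative concentration")
  mu <- params$mu_max * C / (params$K_C + C)
  if (condition == "anoxic") {
    Nsub <- if (params$strain == "producer") no3 else no2
    mu <- mu * Nsub / (params$K_N + Nsub)
  }
  mu
}

#' Nitrite-inhibited biomass yield
#'
#' Biomass yield on the strain's N electron acceptor.  At pH 7.5 nitrite is
#' not toxic and the yield is \code{Y_max} regardless of nitrite.  At pH 6.5
#' the yield declines hyperbolically with local nitrite:
#' \deqn{Y = (Y_{max} - Y_{min}) \frac{K_{inh}}{K_{inh} + C_{NO2}} + Y_{min}}
#' The same expression is applied to both genotypes (the consumer pays the
#' toxicity cost too, even though it detoxifies nitrite).
#'
#' @param params A \code{strain_params}.
#' @param c_no2 Local nitrite concentration, mM (vectorized).
#' @param pH 6.5 (strong toxicity) or 7.5 (none).
#' @return Yield(s) in kg dry weight/mol, in \code{[Y_min, Y_max]}.
#' @export
yield_coefficient <- function(params, c_no2, pH = c(6.5, 7.5)) {
  stopifnot(inherits(params, "strain_params"))
  pH <- match.arg(as.character(pH[1L]), c("6.5", "7.5"))
  if (any(c_no2 < 0)) stop("invalid argument: negative concentration")
  if (pH == "7.5") return(rep(params$Y_max, length(c_no2)))
  (params$Y_max - params$Y_min) * params$K_inh / (params$K_inh + c_no2) +
    params$Y_min
}

#' Explicit-Euler biomass update
#'
#' @param biomass Biomass, kg dry weight (vectorized).
#' @param mu Growth rate, 1/h.
#' @param dt_s Time step in seconds.
#' @return Updated biomass \code{biomass * (1 + mu * dt)} with \code{dt}
#'   converted to hours.
#' @export
euler_update <- function(biomass, mu, dt_s) {
  if (any(mu < 0)) stop("invalid argument: negative growth rate")
  if (dt_s <= 0) stop("invalid argument: dt must be positive")
  biomass * (1 + mu * dt_s / 3600)
}

#' Stoichiometric nutrient consumption/production at one node
#'
#' Converts a biomass increment into local nutrient turnover.  Carbon is
#' drawn down by \code{dbiomass / Y_carbon} mol under both conditions.
#' Under anoxia the strain's N acceptor is drawn down by
#' \code{dbiomass / Y_i} mol, with \code{Y_i} the nitrite-inhibited yield at
#' the node; the producer releases \code{no2_per_no3} mol NO2- per mol NO3-
#' reduced, the consumer removes NO2-.  If local amounts cannot cover the
#' requested increment, growth is capped proportionally (never an error; the
#' event is flagged) and no concentration is driven below zero.
#'
#' @param node Node id.
#' @param params A \code{strain_params}.
#' @param dbiomass Requested biomass increment, kg dry weight (>= 0).
#' @param field A \code{nutrient_field}.
#' @param condition \code{"oxic"} or \code{"anoxic"}.
#' @param pH 6.5 or 7.5.
#' @return List: \code{field} (updated), \code{dbiomass} (realized
#'   increment, kg), \code{consumed} (named mmol: carbon, no3, no2),
#'   \code{produced_no2} (mmol), \code{capped} (logical).
#' @export
consume_and_produce <- function(node, params, dbiomass, field,
                                condition = c("oxic", "anoxic"),
                                pH = 6.5) {
  condition <- match.arg(condition)
  stopifnot(dbiomass >= 0)
  vol <- field$node_volume_L
  conc <- field$conc[node, ]
  # requested amounts in mmol (kg / (kg/mol) = mol; x1000 -> mmol)
  need_c <- 1000 * dbiomass / params$Y_carbon
  avail_c <- conc[["carbon"]] * vol
  fac <- if (need_c > 0) min(1, avail_c / need_c) else 1
  need_n <- 0
  if (condition == "anoxic" && dbiomass > 0) {
    Yi <- yield_coefficient(params, conc[["no2"]], pH)
    need_n <- 1000 * dbiomass / Yi
    n_sp <- if (params$strain == "producer") "no3" else "no2"
    fac <- min(fac, conc[[n_sp]] * vol / need_n)
  }
  fac <- max(0, min(1, fac))
  used_c <- fac * need_c
  consumed <- c(carbon = used_c, no3 = 0, no2 = 0)
  produced <- 0
  if (condition == "anoxic") {
    used_n <- fac * need_n
    if (params$strain == "producer") {
      consumed[["no3"]] <- used_n
      produced <- used_n * params$no2_per_no3
    } else {
      consumed[["no2"]] <- used_n
    }
  }
  conc[["carbon"]] <- max(0, conc[["carbon"]] - consumed[["carbon"]] / vol)
  conc[["no3"]] <- max(0, conc[["no3"]] - consumed[["no3"]] / vol)
  conc[["no2"]] <- max(0, conc[["no2"]] - consumed[["no2"]] / vol + produced / vol)
  field$conc[node, ] <- conc
  list(field = field, dbiomass = fac * dbiomass, consumed = consumed,
       produced_no2 = produced, capped = fac < 1)
}
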