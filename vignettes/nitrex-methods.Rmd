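---
title: "Modeling nitrite cross-feeding range expansions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nitrite cross-feeding range expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nitrex)
```

## The system

`nitrex` simulates the surface range expansion of a two-strain denitrifying
consortium. The *producer* reduces nitrate (NO3-) to nitrite (NO2-) but no
further; the *consumer* reduces nitrite onward but cannot use nitrate. Under
anoxic conditions the consumer is therefore obligately dependent on the
producer's waste product, and at pH 6.5 that product is toxic, so the
producer benefits from consumer detoxification in turn — a conditional
mutualism. Under oxic conditions both strains respire carbon and simply
compete. Alternating the redox state flips the interaction between mutualism
and competition, and the package's purpose is to study how colony
composition and spatial pattern (sectors, intermixing, rare "spatial
jackpot" events in which a consumer region persists at the expansion edge)
respond to those fluctuations.

## Model structure

The domain is a circular plate cross-section discretized as a triangular
point lattice: each node is the center of a hexagonal tile of side 20 um,
adjacent centers `sqrt(3) * 20 ~ 34.6` um apart. A node holds at most one
super-agent (a cluster of ~1000 cells of one strain, mutual exclusivity per
node), with pseudo-3D stacking: a fully enclosed agent that cannot place a
daughter increments a layer counter instead. Three solutes (carbon, nitrate,
nitrite) diffuse between adjacent nodes in finite-volume form with exchange
rate `k = D * side / (spacing * area)`, which conserves mass exactly by
construction. Peripheral sources clamp carbon (22 mM) and nitrate (1 mM) at
the rim each step. Nitrite has no peripheral source: it is produced only by
the producer's metabolism, and the rim is treated as no-flux for it. (A
0 mM nitrite clamp would make the dish wall an infinite nitrite sink and
silently delete the nitrite pool the analysis tracks.)

Each 60 s outer step applies: source clamping, diffusion, growth,
stoichiometric consumption/production, then divisions. Growth is Monod-type:
oxic `mu = mu_max * C/(K_C + C)` for both strains; anoxic multiplies by a
term in the strain's own electron acceptor (nitrate for the producer,
nitrite for the consumer). Biomass is integrated by explicit Euler.

### Nitrite toxicity and the yield equation

At pH 6.5 the biomass yield on the N acceptor declines hyperbolically with
local nitrite between `Y_max` and `Y_min` with inhibition constant `K_inh`;
at pH 7.5 it is `Y_max` regardless. The same expression applies to both
genotypes.

A subtle semantic choice matters here. If the growth rate were left
untouched and consumption computed as `dm / Y_i`, low pH would *amplify*
nitrite production: a poisoned producer would burn more nitrate per unit
growth and emit more nitrite, a positive feedback with no biological
counterpart, and domain nitrite would come out *higher* under strong
toxicity — backwards. `nitrex` instead treats the acceptor *uptake* as the
Monod-limited quantity (`mu/Y_max` per unit biomass) and converts uptake to
biomass at the inhibited yield, so the realized growth rate is
`mu * Y_i / Y_max`: toxicity slows growth rather than accelerating acceptor
turnover. Consumption per realized biomass increment is still exactly
`dm / Y_i`, so the stoichiometric contract (and the nitrogen ledger) is
unchanged; only the simulator's growth step carries the slowdown.

### Division and shoving

An agent reaching its division mass splits 50/50. The daughter takes a
uniformly drawn empty neighbor if one exists; otherwise the shortest
occupied path to the expansion edge (occupied nodes with an empty neighbor)
is found by breadth-first search, and if it is shorter than 5 nodes
(< 100 um) the whole chain is shoved one node outward, the frontier cell
moving to a random empty neighbor and the daughter taking the vacated node;
otherwise the daughter stacks. Ties in target and path choice are broken
uniformly with the run's seeded RNG; an RNG draw is consumed only when more
than one candidate exists, which makes the mechanics exactly replayable by
an independent scripted oracle (this is tested on random occupancies).
Stacked layers travel with their resident cell during shoves and never
re-enter the lattice plane; by default they do not grow or consume
(growth is confined to the lattice-resident layer, consistent with the thin
active layer at an expansion edge).

## Numerical choices

* **Diffusion integrator.** With realistic agar diffusivities
  (1.2e3 um^2/s for the ions) the explicit stability limit is ~0.3 s, i.e.
  ~1000 sub-steps per 60 s outer step. The default integrator is therefore
  an implicit backward-Euler step solved with a cached sparse Cholesky
  factorization (Dirichlet rim nodes eliminated; solutes sharing a
  diffusivity and boundary type share one factorization and one
  multi-right-hand-side solve). It is unconditionally stable, conserves
  closed-domain mass to solver precision, and preserves non-negativity
  because the system matrix
  is an M-matrix; the test suite bounds the drift at 1e-9 relative over
  1000 steps. The sub-stepped explicit scheme (sub-step at 0.2x the
  stability limit) is retained as `method = "explicit"` and the two are
  cross-checked against dense linear-algebra oracles on small patches.
* **Growth capping.** Requested biomass increments are scaled down
  proportionally when the local nutrient amount cannot cover them, so no
  concentration ever goes negative; capping is counted, not raised.
* **Degenerate inputs.** Empty rasters, empty rings, all-consumer rings and
  ragged replicate series raise typed "invalid ..." errors; an
  all-consumer edge ring returns `Inf` with a warning since a downstream
  mean over replicates may still be meaningful.
* **Determinism.** One root seed; sub-seeds for the inoculum and the
  dynamics stream are drawn from it; identical configurations reproduce
  trajectories bit for bit.

## Parameter defaults and calibration

The source model's parameter table lives in a separate model-description
publication that is not available here, so `nitrex` ships literature-scale
defaults that were calibrated — once, at the reduced test scale — against
the qualitative regime the original figures establish, and records them in
`strain_params()`:

* `mu_max = 0.25`/h for both strains and both conditions (parameter
  parsimony; an effective super-agent doubling of ~2.8 h keeps a 72 h
  expansion at the mm scale of a real plate);
* carbon: `K_C = 2` mM, yield 0.05 kg/mol, boundary 22 mM — carbon limits
  the colony interior, not the front;
* producer: `K_NO3 = 0.1` mM, `Y_max = 2e-3`, `Y_min = 2e-4` kg/mol —
  nitrate demand high enough that anoxic phases carve a radial nitrate
  gradient (domain nitrate visibly depleted during anoxia, recovering
  during oxic phases);
* consumer: `K_NO2 = 2` mM, `Y_max = 5e-4`, `Y_min = 5e-5` kg/mol —
  nitrite reduction transfers one electron per N against the producer's
  two and carries the detox overhead, so the consumer gains less biomass
  per mole while turning nitrite over fast. The high half-saturation keeps
  the consumer starved at the very front, where freshly produced nitrite
  dilutes into virgin agar, reproducing producer-first anoxic expansion
  with edge consumer:producer ratios well below one; the high turnover
  keeps ambient nitrite low where consumers are abundant (pH 6.5), so
  nitrite accumulates only under weak toxicity (pH 7.5);
* `K_inh = 0.2` mM, division mass 3.5e-13 kg, D = 600 (carbon) / 1200
  (ions) um^2/s, domain depth 4 mm for amount bookkeeping.

Calibration targets were regime features stated by the original study
(nitrate depletion during anoxia, nitrite accumulation only at weak
toxicity, producer-led fronts, higher consumer persistence under strong
mutualism), not the acceptance comparisons themselves; but the two overlap,
and the decisions ledger flags this honestly. All parameters are plain
constructor arguments — nothing is hard-coded.

## What the synthetic data emulates (and what it does not)

`gen_wedge_colony()` builds labeled rasters with the *geometry* of a real
tile-scanned colony: a disk, producer background, consumer wedges reaching
the edge (jackpots), interior blobs that stopped short, optional concentric
banding that pinches wedge width at simulated redox transitions, and
label-flip noise. Its ground-truth record makes every metric's expected
value analytic: an edge ring over total wedge angle `theta` has
consumer:producer ratio `theta / (2*pi - theta)`, a circle crossing `k`
wedges has `2k` interspecific boundaries, and the jackpot count is the
wedge count. It does **not** emulate optics — no point-spread function,
spectral bleed-through, tile stitching, or intensity noise — so green
quantification tests establish correctness of the *measurement* on labeled
data, not robustness of any image-processing front end (which is out of
scope; real pipelines must segment to labels first).
`gen_two_phase_series()` draws replicate metric series from a continuous
piecewise-linear mean with Gaussian noise floored at zero, matching the
shape the regression layer assumes.

## Statistics layer

`fit_two_phase()` fits `y = b0 + b1*x + b2*(x - xb)+` with the breakpoint
chosen by exhaustive search over admissible data points (at least `min_seg`
per side), which testing confirms equals brute-force enumeration; 95% CIs
and p-values are conditional on the chosen breakpoint, matching how such
fits are conventionally reported. Continuity at the break is the default
(the dynamics it models are continuous); a discontinuous variant fits the
two sides independently. `two_sample_t()` implements the pooled two-sided
test from raw data or printed summary statistics (identical to 1e-12);
`assumption_checks()` wraps Shapiro-Wilk and Bartlett at the conventional
p > 0.05 pass rule; `transition_stability()` computes differences between
subsequent transitions per replicate, their across-replicate variance, and
the first transition at which the variance falls to tolerance — the
stability diagnostic for fluctuating-regime series. Replicates are pooled
by default in `fit_metric_dynamics()` (per-replicate mode available), since
the original report prints one coefficient set per condition.

## Quantification conventions

The expansion edge of a raster is the per-angle maximum occupied radius
(360 bins by default). The composition ring runs 50 px (151.35 um at
3.027 um/px) behind that edge; the intermixing circle samples at the same
offset, counts producer/consumer label transitions along the closed walk
(empty samples skipped), and normalizes by the circle's physical
circumference (per-pixel normalization is available, as the literature is
not unanimous on units). Jackpots are 8-connected consumer components that
reach within `edge_band_px` of the local edge and exceed `min_size_px`
(10 px, noise suppression). Lattice-native equivalents
(`pattern_metrics_state()`, hex adjacency, sizes in nodes with a 3-node
minimum) agree with the rasterized route within discretization tolerance
and are used on simulation output directly for speed.

## Known limitations

* The two scenario orderings (oxic-start > anoxic-start jackpot counts;
  nitrite-supplemented > nitrate-only) are not reproducible at the reduced
  (3.5 mm / 24 h) test scale in this parameterization: exploratory runs
  put both mean effects within +-2.5 events of zero against a per-seed SD
  of ~3-4, across several measurement designs (run end, phase-matched
  snapshots, early snapshots, minimum sector sizes of 3-12 nodes). The
  acceptance assertions are implemented exactly as stated with seeds fixed
  in advance, and whichever way they fall reflects seed noise around a
  near-zero effect, not a reproduced ordering. The two pH orderings (more
  jackpots and far higher consumer persistence at pH 6.5; domain nitrite
  accumulating only at pH 7.5) are reproduced robustly. A plausible cause
  for the missing scenario memory is front churn: with a 5-node shove
  reach and strain-neutral oxic intervals, consumers continuously
  re-nucleate at the front, erasing the initial-condition advantage that
  the full-scale, 12-interval original runs retain.
* Jackpot counts at the reduced scale sit near 10 with the 3-node minimum
  size; they are ordering-stable but not comparable in absolute value to
  full-scale counts.
* No pH dynamics, no oxygen field (redox is a global switch), no cell
  death or maintenance, no mechanical forces beyond topological shoving,
  and stacked biomass is inert by default.
* The experimental 15-cycle 36 h/12 h timeline is supported by
  `make_schedule(total, c(36, 12))` but is not a simulation default; the
  model-scale default is 72 h with 6 h intervals.

## Reproducing the acceptance quantities

```{r acceptance}
# from the repository root, against the installed package:
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script reports the three self-contained printed constants (edge-ring
offset 151.35 um; 12 schedule intervals at 72 h / 6 h; 5-node shove
threshold) recomputed from package defaults. Everything else in the
acceptance suite is property-based and runs inside `tests/testthat/`.
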