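# nitrex

Agent-based simulation and spatial quantification of **nit**rite
cross-feeding **r**ange **ex**pansions.

## What this is for

Two isogenic denitrifying strains grown together on an agar surface form a
conditional mutualism: a *producer* reduces nitrate (NO3-) to nitrite
(NO2-), a *consumer* reduces nitrite onward. Under anoxic conditions the
consumer depends on the producer's waste nitrite, and at pH 6.5 nitrite is
toxic, so the producer also benefits from the consumer's detoxification;
under oxic conditions both strains simply compete for carbon. `nitrex` is
for researchers studying how alternating anoxic/oxic conditions shape the
composition and spatial self-organization of such colonies — in particular
the rare, localized **spatial jackpot events**: continuous consumer regions
that persist at the expansion edge despite producer dominance, nucleated by
favorable initial positioning rather than mutation.

The package provides:

* an **agent-based model** on a hexagonal lattice (20 um side, 1 cm
  domain): super-agent cells with Monod growth, explicit-Euler biomass
  updates, finite-volume nutrient diffusion with constant peripheral
  carbon/nitrate sources, 50/50 division with edge-directed cell shoving
  (< 5-node reach) and pseudo-3D stacking, driven by an alternating
  anoxic/oxic schedule (default 72 h, 6 h intervals, 60 s steps);
* **nitrite-toxicity yields**: at pH 6.5 the biomass yield on the N
  acceptor falls hyperbolically with local nitrite,
  `Y = (Y_max - Y_min) * K_inh / (K_inh + C_NO2) + Y_min`, and realized
  growth is slowed by `Y/Y_max`; at pH 7.5 toxicity is absent;
* **pattern metrics** for labeled colony rasters or lattice occupancies:
  consumer:producer ratio in a 50-pixel (151.35 um) edge ring, the
  intermixing index (interspecific boundaries per unit circumference near
  the edge), and jackpot-event counts (connected consumer regions reaching
  the edge);
* a **statistics layer**: two-phase (segmented) linear regression with
  exhaustive breakpoint search, pooled two-sample t-tests from raw data or
  printed summaries, Shapiro-Wilk/Bartlett assumption checks, and
  transition-to-transition stability analysis;
* **synthetic data generators** with analytic ground truth (wedge colonies,
  two-phase replicate series), so the whole pipeline is testable offline.

## Worked example

```r
library(nitrex)

# reduced-scale run: 3.5 mm domain, 24 h, alternating 6 h anoxic/oxic,
# strong mutualism (pH 6.5)
cfg  <- reduced_config(pH = 6.5, seed = 1)
traj <- run_simulation(cfg)
print(traj)
#> expansion_trajectory: anoxic-start, pH 6.5, 24 h on 3500 um domain (9283 nodes)
#>   occupied nodes: 3461 (producer 2156, consumer 1305), 4 snapshots

pattern_metrics_state(traj$occupancy, traj$lattice)
#> $ratio
#> [1] 0.4565757
#> $intermixing
#> [1] 0.01778373
#> $jackpots
#> [1] 16
```

After 24 h (four anoxic/oxic intervals) the front is producer-led but the
strong mutualism retains the consumer: about 0.46 consumer per producer in
the 151.35 um edge ring, ~0.018 interspecific boundaries per um of sampling
circumference, and 16 consumer sectors persisting to the edge — spatial
jackpot events. Matched seeds at pH 7.5 give fewer jackpots, far lower
edge ratios (~0.15), and more domain nitrite, since weak toxicity removes
the producer's need for consumer detoxification.

Fit the two-phase decay of a metric series and test a group difference:

```r
g <- gen_two_phase_series(n_replicates = 4, n_transitions = 15,
                          slope1 = -0.0374, slope2 = 0.0008,
                          breakpoint = 8, start_value = 0.7,
                          noise_sd = 0.02, seed = 1)
fit_two_phase(g$x, colMeans(g$series))
#> two-phase fit: break at x = 8; slopes -0.03788 [-0.04002, -0.03574] then
#> 0.001224 [-0.0009156, 0.003364]; r2 = 0.995

two_sample_t(summary_a = c(3.5, 1.3, 4), summary_b = c(0.75, 0.5, 4))$p
#> [1] 0.007548281
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nitrex", package = "nitrex"))')
Rscript $CLI simulate --config run.json --seed 1 --out out/
Rscript $CLI quantify --in out/ --pixel-size 3.027 --ring 50 --out metrics.csv
Rscript $CLI synth colony --jackpots 3 --noise 0.01 --out colony
Rscript $CLI fit --metrics metrics.csv --out fits.csv
```

Rasters are plain-text label grids (`write_colony_raster()` /
`read_colony_raster()`); configurations are JSON with
`simulation_config()` argument names.

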