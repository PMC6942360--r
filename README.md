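# spomdyn

Stochastic patch occupancy models (SPOMs) on **dynamic, successional
patch networks**, for testing the metapopulation intermediate-disturbance
hypothesis (MIDH): does a species' equilibrium occupancy peak at
intermediate rates of habitat-patch turnover?

The package is aimed at spatial ecologists and metapopulation modellers
who want a reproducible, fully seeded simulation experiment crossing
species traits (dispersal ability, colonization efficiency, extinction
rate, successional preference) with landscape properties (habitat
amount, disturbance frequency).

## The model

The occupancy core is Hanski's Incidence Function Model, a discrete-time
presence/absence Markov chain per patch. With patch areas `A` in
hectares and inter-patch distances `d` in metres:

    S_i  = A_i^c * sum_{j != i} p_j * exp(-alpha * d_ij) * A_j^b
    C_is = S_i^2 / (S_i^2 + y^2)              (Allee effect)
    E_is = min(1, e / A_i^x);  E_is = 1 if A_i <= e^(1/x)

Habitat succession modifies both rates through patch age `a` (steps
since patch creation). Early-successional species face rising extinction
`E_it = 1/(1+exp(-0.09 a))` and falling colonization as patches mature;
late-successional species the mirror image; mid-successional species
peak at age 50 (`E_it = exp(-0.08 a)` below 50, recentred and clamped
above). Per-step probabilities are the products `C_i = C_is * C_it`,
`E_i = E_is * E_it`; there is no rescue effect.

Landscapes are random networks of non-overlapping circular patches
(default: ~1000-ha arena, 0.5 ± 0.2 ha patches, ≥10 m edge spacing;
5/10/20% cover gives 100/200/400 patches). Each time step, a fixed
fraction of patches is destroyed (occupants die) and the same number
created at age 0, holding patch count constant — that fraction is the
*landscape dynamism*. The factorial experiment crosses 54 virtual
species (3 dispersal × 3 colonization × 2 critical-area levels × 3
successional guilds) with 3 covers and 4 dynamism levels: 648 scenario
cells, each summarized over replicate iterations as the mean fraction of
occupied patches after 100 steps, with 95% confidence intervals.

See `vignettes/spomdyn-methods.Rmd` for assumptions, parameter meanings
and design choices.

## Worked example

Occupancy of a mid-successional, high-dispersal species (id 21:
α = 0.001 m⁻¹, y = 5, A₀ = 0.05 ha) at 10% habitat cover, across four
turnover rates (20 iterations × 100 steps):

```r
library(spomdyn)
species <- build_virtual_species_set()
grid <- scenario_grid(
  species = species[species$species_id == 21, ],
  covers = 0.10, dynamisms = c(0, 0.05, 0.10, 0.20),
  iterations = 20, steps = 100, base_seed = 42
)
results <- run_experiment(grid)
results[, c("dynamism", "mean_occupancy", "ci_low", "ci_high", "extinct_fraction")]
#>   dynamism mean_occupancy ci_low ci_high extinct_fraction
#> 1     0.00         0.0553 0.0471  0.0634                0
#> 2     0.05         0.7005 0.6847  0.7163                0
#> 3     0.10         0.4550 0.4390  0.4710                0
#> 4     0.20         0.0000 0.0000  0.0000                1
```

The MIDH signature is visible directly: on a static landscape (dynamism
0) every patch matures past the species' mid-successional optimum and
only a 6% remnant is left after 100 steps; at 5% turnover per step the
landscape maintains a supply of mid-aged patches and occupancy
equilibrates around 70%; at 20% turnover patches are destroyed faster
than they become suitable and the metapopulation goes extinct in every
iteration. `plot_occupancy(results)` draws the occupancy-vs-dynamism
panel (one series per cover level, 95% CI error bars), and
`save_occupancy_figure()` writes it with a sidecar CSV of exactly the
plotted values.

Experiments can also be driven by a YAML config file
(`run_from_config("run.yaml")` writes results, per-iteration table, seed
log and a run manifest) or from a shell via the thin wrapper
`inst/scripts/spomdyn.R` (subcommands `generate-landscape`,
`list-species`, `run`, `summarize`, `plot`).

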