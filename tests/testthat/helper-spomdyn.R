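# Shared fixtures for the test suite. Everything is built in code.

# Small arena used by fast unit tests: 1000 m side (100 ha).
small_landscape <- function(cover = 0.25, seed = 1, ...) {
  generate_landscape(side = 1000, cover = cover, mean_area = 0.5,
                     sd_area = 0.2, min_dist = 10, seed = seed, ...)
}

# Hand-built 3-patch landscape with known geometry (3-4-5 triangle scaled).
triangle_landscape <- function(areas = c(0.4, 0.6, 1.2),
                               ages = c(30L, 50L, 70L)) {
  as_landscape(
    data.frame(id = 1:3, x = c(0, 300, 0), y = c(0, 0, 400),
               area = areas, age = ages),
    side = 1000
  )
}

# Per-guild reference species for pattern-recovery checks: the highest
# dispersal ability (alpha = 0.001), highest colonization efficiency
# (y = 5), smaller critical area (A0 = 0.05) member of each guild
# (ids 3, 21 and 39 of the factorial set).
reference_species_id <- c(early = 3L, mid = 21L, late = 39L)

# Run one reduced-scale scenario cell (100 iterations x 100 steps by
# default) and return the per-iteration final occupancies. Memoised so
# that several test blocks can share cells without re-simulating.
pattern_cell_cache <- new.env(parent = emptyenv())
pattern_cell <- function(preference, cover, dynamism, iterations = 100,
                         steps = 100, base_seed = 20260921) {
  key <- paste(preference, cover, dynamism, iterations, steps, base_seed,
               sep = "|")
  if (!is.null(pattern_cell_cache[[key]])) {
    return(pattern_cell_cache[[key]])
  }
  species <- build_virtual_species_set()
  species <- species[species$species_id == reference_species_id[[preference]], ]
  grid <- scenario_grid(species = species, covers = cover,
                        dynamisms = dynamism, iterations = iterations,
                        steps = steps, base_seed = base_seed)
  res <- run_experiment(grid, keep_iterations = TRUE)
  finals <- attr(res, "iterations")$final_occupancy
  pattern_cell_cache[[key]] <- list(summary = res, finals = finals)
  pattern_cell_cache[[key]]
}

# One-sided rank test helper: is `x` stochastically greater than `y`?
rank_greater_p <- function(x, y) {
  stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
}
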