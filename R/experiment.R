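# experiment: the species x cover x dynamism factorial with replicate
# iterations, per-iteration seeding and summary confidence intervals.

#' Define a factorial simulation experiment
#'
#' A scenario grid crosses a species set with habitat-cover and landscape-
#' dynamism levels. The reference configuration — 54 species, covers
#' 5/10/20 percent, dynamism 0/5/10/20 percent — yields 648 scenario cells
#' (216 per successional guild, 12 landscape scenarios).
#'
#' @param species species data frame ([build_virtual_species_set()] by
#'   default); may be any subset or user-supplied table.
#' @param covers habitat-cover fractions.
#' @param dynamisms per-step patch-turnover fractions.
#' @param iterations replicate stochastic iterations per cell.
#' @param steps time steps per iteration.
#' @param init_occupancy initial occupied fraction.
#' @param base_seed integer base seed of the whole experiment.
#' @param side,mean_area,sd_area,min_dist landscape generation parameters
#'   (see [generate_landscape()]).
#' @param initial_age_mode initial patch-age mode, see [generate_landscape()].
#' @param fresh_landscape_per_iteration if `TRUE` (default) every iteration
#'   generates its own landscape, so summary CIs reflect both landscape and
#'   demographic stochasticity; if `FALSE` one landscape per cell is reused.
#' @param extinction_rule passed to [step_rates()].
#' @return an object of class `scenario_grid`.
#' @examples
#' g <- scenario_grid(iterations = 2, steps = 5)
#' nrow(enumerate_scenarios(g))
#' @export
scenario_grid <- function(species = build_virtual_species_set(),
                          covers = c(0.05, 0.10, 0.20),
                          dynamisms = c(0, 0.05, 0.10, 0.20),
                          iterations = 500, steps = 100,
                          init_occupancy = 0.5, base_seed = 1L,
                          side = 3163, mean_area = 0.5, sd_area = 0.2,
                          min_dist = 10,
                          initial_age_mode = c("uniform0_100", "zero"),
                          fresh_landscape_per_iteration = TRUE,
                          extinction_rule = c("product", "or")) {
  stopifnot(nrow(species) >= 1, all(covers > 0 & covers < 1),
            all(dynamisms >= 0 & dynamisms <= 1), iterations >= 1, steps >= 1)
  structure(
    list(species = species, covers = covers, dynamisms = dynamisms,
         iterations = as.integer(iterations), steps = as.integer(steps),
         init_occupancy = init_occupancy, base_seed = as.integer(base_seed),
         side = side, mean_area = mean_area, sd_area = sd_area,
         min_dist = min_dist,
         initial_age_mode = match.arg(initial_age_mode),
         fresh_landscape_per_iteration = fresh_landscape_per_iteration,
         extinction_rule = match.arg(extinction_rule)),
    class = "scenario_grid"
  )
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid> ", nrow(x$species), " species x ", length(x$covers),
      " covers x ", length(x$dynamisms), " dynamism levels = ",
      nrow(x$species) * length(x$covers) * length(x$dynamisms),
      " cells\n", sep = "")
  cat("  ", x$iterations, " iterations x ", x$steps,
      " steps, base seed ", x$base_seed, "\n", sep = "")
  invisible(x)
}

#' Enumerate the cells of a scenario grid
#'
#' Cells are ordered by (species_id, cover, dynamism) and numbered 1..n;
#' each carries a derived cell seed `derive_seed(base_seed, cell)`, logged
#' so any cell can be re-run in isolation.
#'
#' @param grid a `scenario_grid`.
#' @return data frame with columns `cell, species_id, preference, cover,
#'   dynamism, cell_seed`.
#' @export
enumerate_scenarios <- function(grid) {
  sp <- grid$species[order(grid$species$species_id), , drop = FALSE]
  cells <- expand.grid(dynamism = grid$dynamisms, cover = grid$covers,
                       species_id = sp$species_id, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("species_id", "cover", "dynamism")]
  cells <- cells[order(cells$species_id, cells$cover, cells$dynamism), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells$preference <- sp$preference[match(cells$species_id, sp$species_id)]
  cells$cell <- seq_len(nrow(cells))
  cells$cell_seed <- vapply(cells$cell, function(i)
    derive_seed(grid$base_seed, i), integer(1))
  cells[, c("cell", "species_id", "preference", "cover", "dynamism",
            "cell_seed")]
}

#' Summarize final occupancies across iterations
#'
#' @param final_occupancies numeric vector of final-step occupied fractions,
#'   one per iteration (extinct runs contribute 0 and are kept in the mean).
#' @param conf confidence level for the normal-approximation interval.
#' @return a list with `mean`, `ci_low`, `ci_high` (clamped to `[0, 1]`;
#'   `NA` with a warning for a single iteration) and `extinct_fraction`.
#' @examples
#' summarize_occupancy(c(0.4, 0.6))
#' @export
summarize_occupancy <- function(final_occupancies, conf = 0.95) {
  stopifnot(length(final_occupancies) >= 1,
            all(final_occupancies >= 0 & final_occupancies <= 1))
  m <- mean(final_occupancies)
  n <- length(final_occupancies)
  if (n < 2) {
    warning("confidence interval undefined with a single iteration")
    ci <- c(NA_real_, NA_real_)
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- stats::sd(final_occupancies) / sqrt(n)
    ci <- clamp01(m + c(-1, 1) * z * se)
  }
  list(mean = m, ci_low = ci[1], ci_high = ci[2],
       extinct_fraction = mean(final_occupancies == 0))
}

run_one_cell <- function(grid, cellrow) {
  sp_row <- grid$species[grid$species$species_id == cellrow$species_id, ,
                         drop = FALSE]
  species <- as_species_params(sp_row)
  finals <- numeric(grid$iterations)
  shared_landscape <- NULL
  if (!grid$fresh_landscape_per_iteration) {
    shared_landscape <- generate_landscape(
      side = grid$side, cover = cellrow$cover, mean_area = grid$mean_area,
      sd_area = grid$sd_area, min_dist = grid$min_dist,
      seed = derive_seed(grid$base_seed, 2L * cellrow$cell),
      initial_age_mode = grid$initial_age_mode
    )
  }
  for (iter in seq_len(grid$iterations)) {
    L <- if (grid$fresh_landscape_per_iteration) {
      generate_landscape(
        side = grid$side, cover = cellrow$cover, mean_area = grid$mean_area,
        sd_area = grid$sd_area, min_dist = grid$min_dist,
        seed = derive_seed(grid$base_seed, 2L * cellrow$cell, iter),
        initial_age_mode = grid$initial_age_mode
      )
    } else {
      shared_landscape
    }
    tr <- simulate_trajectory(
      L, species, dynamism = cellrow$dynamism, steps = grid$steps,
      init_occupancy = grid$init_occupancy,
      seed = derive_seed(grid$base_seed, 2L * cellrow$cell + 1L, iter),
      extinction_rule = grid$extinction_rule
    )
    finals[iter] <- tr$occupancy[nrow(tr)]
  }
  finals
}

#' Run the full factorial experiment
#'
#' For every scenario cell, runs `grid$iterations` independent trajectories
#' (each on a freshly generated landscape by default) and summarizes the
#' final-step occupied fraction. Seeding is per (cell, iteration) via
#' [derive_seed()], so results are identical for any `workers` count and
#' reproducible from `grid$base_seed` alone.
#'
#' Cells that fail (e.g. patch-placement exhaustion under an overcrowded
#' parameterization) are recorded and skipped; the run continues and the
#' failures are attached as attribute `"failures"` and reported in a
#' warning at the end.
#'
#' @param grid a `scenario_grid`.
#' @param workers number of forked worker processes (1 = serial).
#' @param keep_iterations if `TRUE`, attach a per-iteration table
#'   (`cell, iteration, final_occupancy`) as attribute `"iterations"`.
#' @param progress print one line per completed cell (serial runs only).
#' @return a data frame with one row per cell: `cell, species_id,
#'   preference, cover, dynamism, cell_seed, n_iterations, mean_occupancy,
#'   ci_low, ci_high, extinct_fraction`.
#' @examples
#' g <- scenario_grid(species = build_virtual_species_set()[1, ],
#'                    covers = 0.05, dynamisms = c(0, 0.2),
#'                    iterations = 2, steps = 5, side = 1000)
#' run_experiment(g)
#' @export
run_experiment <- function(grid, workers = 1L, keep_iterations = FALSE,
                           progress = FALSE) {
  cells <- enumerate_scenarios(grid)
  worker <- function(i) {
    cellrow <- cells[i, ]
    res <- tryCatch(run_one_cell(grid, cellrow), error = function(e) e)
    if (progress && workers == 1L) {
      status <- if (inherits(res, "error")) "FAILED" else "ok"
      message(sprintf("cell %d/%d (species %d, cover %.2f, dynamism %.2f): %s",
                      i, nrow(cells), cellrow$species_id, cellrow$cover,
                      cellrow$dynamism, status))
    }
    res
  }
  per_cell <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(cells)), worker, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(cells)), worker)
  }

  failed <- vapply(per_cell, inherits, logical(1), "error")
  summaries <- lapply(seq_len(nrow(cells)), function(i) {
    if (failed[i]) {
      list(mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           extinct_fraction = NA_real_)
    } else if (grid$iterations >= 2) {
      summarize_occupancy(per_cell[[i]])
    } else {
      suppressWarnings(summarize_occupancy(per_cell[[i]]))
    }
  })
  out <- cbind(cells, data.frame(
    n_iterations = ifelse(failed, 0L, grid$iterations),
    mean_occupancy = vapply(summaries, `[[`, numeric(1), "mean"),
    ci_low = vapply(summaries, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(summaries, `[[`, numeric(1), "ci_high"),
    extinct_fraction = vapply(summaries, `[[`, numeric(1), "extinct_fraction")
  ))
  if (any(failed)) {
    fails <- data.frame(cell = cells$cell[failed],
                        message = vapply(per_cell[failed], conditionMessage,
                                         character(1)))
    attr(out, "failures") <- fails
    warning(sum(failed), " of ", nrow(cells), " cells failed; see attr(",
            "result, \"failures\")")
  }
  if (keep_iterations) {
    ok <- which(!failed)
    attr(out, "iterations") <- do.call(rbind, lapply(ok, function(i) {
      data.frame(cell = cells$cell[i],
                 iteration = seq_len(grid$iterations),
                 final_occupancy = per_cell[[i]])
    }))
  }
  out
}
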