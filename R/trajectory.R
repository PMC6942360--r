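# Multi-step occupancy trajectories on a dynamic landscape.

#' Simulate one stochastic occupancy trajectory
#'
#' Runs the occupancy Markov chain for `steps` time steps on a dynamic
#' landscape. Each step applies, in fixed order:
#'
#' 1. patch turnover at rate `dynamism` ([apply_turnover()]): occupants of
#'    destroyed patches die with their patch, new patches appear empty at
#'    age 0 — and are colonizable in the same step they appear;
#' 2. transition rates on the post-turnover landscape ([step_rates()]);
#' 3. the synchronous occupancy update ([step_occupancy()]);
#' 4. aging of all surviving patches ([advance_age()]).
#'
#' The initial state occupies `round(init_occupancy * N)` patches selected
#' uniformly at random. All stochastic draws (initial occupancy, turnover
#' selection, new-patch areas and positions, occupancy updates) come from
#' one stream seeded by `seed`, so a fixed seed reproduces the trajectory
#' bitwise.
#'
#' @param landscape the starting `landscape` (not modified in place).
#' @param species a `species_params` object.
#' @param dynamism fraction of patches turned over per step, in `[0, 1]`.
#' @param steps number of time steps (>= 1).
#' @param init_occupancy initial fraction of occupied patches, in `[0, 1]`.
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @param extinction_rule passed to [step_rates()].
#' @param keep_final_state if `TRUE`, attach the final landscape and
#'   occupancy vector as attributes `final_landscape` / `final_state`.
#' @return a data frame with one row per step `0..steps` and columns
#'   `step, n_patches, n_occupied, occupancy`. The last row's `occupancy`
#'   is the equilibrium-occupancy estimate for this run.
#' @examples
#' L <- generate_landscape(side = 1000, cover = 0.05, seed = 1)
#' sp <- species_params(alpha = 0.004, y = 10, A0 = 0.05, preference = "mid")
#' tr <- simulate_trajectory(L, sp, dynamism = 0.1, steps = 20, seed = 2)
#' tail(tr, 1)
#' @export
simulate_trajectory <- function(landscape, species, dynamism, steps = 100,
                                init_occupancy = 0.5, seed = NULL,
                                extinction_rule = c("product", "or"),
                                keep_final_state = FALSE) {
  stopifnot(steps >= 1, init_occupancy >= 0, init_occupancy <= 1,
            dynamism >= 0, dynamism <= 1)
  extinction_rule <- match.arg(extinction_rule)
  with_seed(seed, {
    n <- n_patches(landscape)
    k0 <- round_half_up(init_occupancy * n)
    occupied <- stats::setNames(rep(FALSE, n), landscape$patches$id)
    if (k0 > 0) occupied[sample.int(n, k0)] <- TRUE

    out <- data.frame(step = 0:steps, n_patches = NA_integer_,
                      n_occupied = NA_integer_, occupancy = NA_real_)
    record <- function(row, occ) {
      out$n_patches[row] <<- length(occ)
      out$n_occupied[row] <<- sum(occ)
      out$occupancy[row] <<- if (length(occ)) mean(occ) else 0
    }
    record(1L, occupied)

    static <- dynamism == 0
    dmat <- if (static) distance_matrix(landscape) else NULL
    for (t in seq_len(steps)) {
      if (!static) {
        tv <- apply_turnover(landscape, dynamism)
        landscape <- tv$landscape
        keep <- occupied[!(names(occupied) %in% as.character(tv$destroyed_ids))]
        occupied <- c(keep, stats::setNames(rep(FALSE, length(tv$created_ids)),
                                            tv$created_ids))
        # keep state in the landscape's (ascending-id) patch order
        occupied <- occupied[as.character(landscape$patches$id)]
        dmat <- distance_matrix(landscape)
      }
      rates <- step_rates(landscape, occupied, species, dmat, extinction_rule)
      occupied <- step_occupancy(landscape, occupied, species, rates)
      landscape <- advance_age(landscape)
      record(t + 1L, occupied)
    }
    if (keep_final_state) {
      attr(out, "final_landscape") <- landscape
      attr(out, "final_state") <- occupied
    }
    out
  })
}

#' Write a trajectory table to a delimited file
#'
#' @param trajectory data frame from [simulate_trajectory()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
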