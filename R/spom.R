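# spom_core: Incidence Function Model rates and the synchronous
# stochastic occupancy update.
#
# The model is a discrete-time, two-state (presence/absence) Markov chain
# per patch. An empty patch i is colonized with probability C_i, an
# occupied one goes extinct with probability E_i; there is no rescue
# effect (E_i does not depend on connectivity). The spatial components are
# Hanski's IFM:
#
#   S_i  = A_i^c * sum_{j != i} p_j * exp(-alpha * d_ij) * A_j^b
#   C_is = S_i^2 / (S_i^2 + y^2)                (Allee effect: exponent 2)
#   E_is = min(1, e / A_i^x), E_is = 1 when A_i <= e^(1/x)
#
# with d_ij in metres and areas in hectares, and the successional
# components C_it, E_it from the age modifiers. The combined per-step
# probabilities are C_i = C_is * C_it (colonization needs both spatial
# reachability and a suitable stage) and, by default, E_i = E_is * E_it.
# The product keeps the successional modifiers on the same footing for
# both processes; an OR rule (E_i = 1 - (1 - E_is)(1 - E_it)) is available
# but makes the modifiers' floor of 0.5 at age 0 a hard lower bound on
# extinction, which extinguishes every sigmoid-guild species.

check_state <- function(landscape, occupied) {
  ids <- landscape$patches$id
  if (length(occupied) != length(ids) ||
      (!is.null(names(occupied)) &&
       !identical(names(occupied), as.character(ids)))) {
    stop("occupancy state is not aligned with the landscape's living patches",
         call. = FALSE)
  }
  stats::setNames(as.logical(occupied), ids)
}

#' Connectivity of every patch to the occupied network
#'
#' `S_i = A_i^c * sum over occupied j != i of exp(-alpha * d_ij) * A_j^b`:
#' an exponential-dispersal-kernel, area-weighted count of occupied source
#' patches around each focal patch. Distances in metres, areas in hectares.
#'
#' @param landscape a `landscape` object.
#' @param occupied logical occupancy vector aligned with
#'   `landscape$patches` (optionally named by patch id).
#' @param species a `species_params` object (or any list with `alpha`,
#'   `b`, `c`).
#' @param dmat optional precomputed [distance_matrix()] of `landscape`.
#' @return numeric vector of non-negative connectivities, named by patch id.
#' @examples
#' L <- generate_landscape(side = 1000, cover = 0.05, seed = 1)
#' sp <- species_params(alpha = 0.004, y = 10, A0 = 0.05, preference = "mid")
#' S <- connectivity(L, rep(TRUE, n_patches(L)), sp)
#' @export
connectivity <- function(landscape, occupied, species, dmat = NULL) {
  occupied <- check_state(landscape, occupied)
  p <- landscape$patches
  if (nrow(p) == 0L) {
    return(numeric(0))
  }
  if (is.null(dmat)) dmat <- distance_matrix(landscape)
  kernel <- exp(-species$alpha * dmat)
  diag(kernel) <- 0 # the focal patch never counts as its own source
  contrib <- as.vector(kernel %*% (as.numeric(occupied) * p$area^species$b))
  stats::setNames(p$area^species$c * contrib, p$id)
}

#' Spatial colonization probability from connectivity
#'
#' `C_is = S^2 / (S^2 + y^2)`. The squared terms encode an Allee effect:
#' colonization is disproportionately unlikely at low connectivity.
#'
#' @param S connectivity value(s), non-negative.
#' @param y half-saturation constant, positive.
#' @return probability/ies in `[0, 1)`.
#' @export
colonization_spatial <- function(S, y) {
  stopifnot(all(S >= 0), y > 0)
  S^2 / (S^2 + y^2)
}

#' Spatial (area-dependent) extinction probability
#'
#' `E_is = e / A^x`, capped at 1; extinction is certain (`E_is = 1`)
#' whenever the patch area is at or below the critical area `e^(1/x)`.
#'
#' @param A patch area(s) in hectares, positive.
#' @param e extinction probability in a unit-area (1 ha) patch.
#' @param x extinction-area exponent.
#' @return probability/ies in `[0, 1]`.
#' @export
extinction_spatial <- function(A, e, x) {
  stopifnot(all(A > 0), e > 0, e <= 1, x > 0)
  pmin(1, e / A^x)
}

#' Combine spatial and successional components into per-step rates
#'
#' Colonization requires both spatial reachability and successional
#' suitability: `C_i = C_is * C_it`. Extinction components are combined
#' the same way by default: `E_i = E_is * E_it` (`extinction_rule =
#' "product"`), so the successional curves modulate both processes
#' symmetrically. The alternative `extinction_rule = "or"` treats the two
#' extinction components as independent hazards,
#' `E_i = 1 - (1 - E_is)(1 - E_it)`; because the sigmoid successional
#' curves never drop below 0.5 at age 0, the OR rule puts a floor of 0.5
#' under every early- and late-successional extinction probability and is
#' provided only for sensitivity analyses.
#'
#' @param C_is,C_it,E_is,E_it probabilities in `[0, 1]` (vectorised).
#' @param extinction_rule `"product"` (default) or `"or"`.
#' @return a list with vectors `C` and `E`, both in `[0, 1]`.
#' @examples
#' combine_rates(0.8, 0, 0.1, 0.1)$C                      # unsuitable stage
#' combine_rates(0.5, 1, 0.1, 0.1, "or")$E                # 0.19
#' @export
combine_rates <- function(C_is, C_it, E_is, E_it,
                          extinction_rule = c("product", "or")) {
  extinction_rule <- match.arg(extinction_rule)
  probs <- c(C_is, C_it, E_is, E_it)
  if (any(probs < 0 | probs > 1)) {
    stop("all rate components must be probabilities in [0, 1]", call. = FALSE)
  }
  E <- switch(extinction_rule,
    or = 1 - (1 - E_is) * (1 - E_it),
    product = E_is * E_it
  )
  list(C = clamp01(C_is * C_it), E = clamp01(E))
}

#' Per-patch transition rates for the current landscape and state
#'
#' Computes connectivity and all rate components for every living patch.
#'
#' @inheritParams connectivity
#' @param extinction_rule passed to [combine_rates()].
#' @return a data frame with one row per patch: `id, S, C_is, E_is, C_it,
#'   E_it, C, E`.
#' @export
step_rates <- function(landscape, occupied, species, dmat = NULL,
                       extinction_rule = c("product", "or")) {
  extinction_rule <- match.arg(extinction_rule)
  p <- landscape$patches
  S <- connectivity(landscape, occupied, species, dmat)
  C_is <- colonization_spatial(as.vector(S), species$y)
  E_is <- extinction_spatial(p$area, species$e, species$x)
  C_it <- colonization_modifier(species$preference, p$age)
  E_it <- extinction_modifier(species$preference, p$age)
  ce <- combine_rates(C_is, C_it, E_is, E_it, extinction_rule)
  data.frame(id = p$id, S = as.vector(S), C_is = C_is, E_is = E_is,
             C_it = C_it, E_it = E_it, C = ce$C, E = ce$E)
}

#' One synchronous stochastic occupancy update
#'
#' All patches are updated in parallel from the same pre-step state: every
#' empty patch becomes occupied with probability `C_i`, every occupied
#' patch goes extinct with probability `E_i`. One uniform deviate is drawn
#' per patch in increasing patch-id order, so trajectories are exactly
#' reproducible under a fixed seed.
#'
#' @inheritParams connectivity
#' @param rates optional precomputed [step_rates()] data frame (or any data
#'   frame with columns `C` and `E` aligned with the patches); when `NULL`
#'   the rates are computed from the current state.
#' @param extinction_rule passed to [step_rates()] when rates are computed.
#' @return the updated logical occupancy vector, named by patch id.
#' @export
step_occupancy <- function(landscape, occupied, species, rates = NULL,
                           dmat = NULL, extinction_rule = c("product", "or")) {
  occupied <- check_state(landscape, occupied)
  if (is.null(rates)) {
    rates <- step_rates(landscape, occupied, species, dmat, extinction_rule)
  }
  u <- stats::runif(length(occupied))
  newly_colonized <- !occupied & u < rates$C
  survives <- occupied & u >= rates$E
  stats::setNames(newly_colonized | survives, names(occupied))
}
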