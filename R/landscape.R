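# landscape_engine: random patch networks, turnover and aging.
#
# A landscape is a set of circular habitat patches (position in metres,
# area in hectares, age in time steps) scattered in a square arena.
# Patches are treated as points with an area attribute by the occupancy
# model; geometry only matters for the placement rule, which keeps circle
# boundaries at least `min_dist` metres apart so patches never overlap.

HECTARE_M2 <- 1e4

#' Radius (metres) of a circular patch from its area in hectares
#'
#' @param area_ha patch area(s) in hectares.
#' @return radius in metres.
#' @export
patch_radius <- function(area_ha) {
  sqrt(area_ha * HECTARE_M2 / pi)
}

# Draw n patch areas from Normal(mean_area, sd_area), truncated below by
# resampling at `floor_ha` so areas are strictly positive.
sample_patch_areas <- function(n, mean_area, sd_area, floor_ha = 0.01) {
  areas <- stats::rnorm(n, mean_area, sd_area)
  while (any(bad <- areas < floor_ha)) {
    areas[bad] <- stats::rnorm(sum(bad), mean_area, sd_area)
  }
  areas
}

# Rejection-sample positions for patches with areas `areas` (ha) so that the
# edge-to-edge distance to every already-placed patch is >= min_dist.
# existing_xy: 2-column matrix; existing_r: radii (m). Errors out when a
# patch cannot be placed within `max_tries` draws.
place_patches <- function(areas, existing_xy, existing_r, side, min_dist,
                          max_tries = 5000L) {
  n <- length(areas)
  xs <- numeric(n)
  ys <- numeric(n)
  r_new <- patch_radius(areas)
  ex <- existing_xy[, 1]
  ey <- existing_xy[, 2]
  er <- existing_r
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, 0, side)
      cy <- stats::runif(1, 0, side)
      if (length(ex) == 0L ||
          all((ex - cx)^2 + (ey - cy)^2 >= (er + r_new[i] + min_dist)^2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place patch ", i, " of ", n, " after ", max_tries,
           " attempts: the arena is too crowded for this combination of ",
           "cover, mean_area and min_dist", call. = FALSE)
    }
    xs[i] <- cx
    ys[i] <- cy
    ex <- c(ex, cx)
    ey <- c(ey, cy)
    er <- c(er, r_new[i])
  }
  cbind(x = xs, y = ys)
}

new_landscape <- function(patches, side, target_cover, mean_area, sd_area,
                          min_dist, next_id) {
  structure(
    list(patches = patches, side = side, target_cover = target_cover,
         mean_area = mean_area, sd_area = sd_area, min_dist = min_dist,
         next_id = next_id),
    class = "landscape"
  )
}

#' Generate a random patch network
#'
#' Scatters `N = round(side^2 * cover / mean_area)` circular patches in a
#' square arena of `side` x `side` metres. Patch areas are drawn from a
#' normal distribution truncated below at 0.01 ha; positions are placed by
#' rejection sampling so that circle boundaries are at least `min_dist`
#' metres apart (patches never overlap). With the default arena of
#' 3163 m (about 1000 ha) and 0.5-ha mean patches, covers of 5, 10 and 20
#' percent give 100, 200 and 400 patches.
#'
#' Patch age is the number of time steps since creation and drives habitat
#' succession. `initial_age_mode = "uniform0_100"` (default) starts the
#' landscape with ages drawn uniformly on 0..100 so that every successional
#' stage is present at time zero; `"zero"` starts all patches freshly
#' disturbed.
#'
#' @param side arena side length in metres.
#' @param cover target habitat cover as a fraction of the arena (0 < cover < 1).
#' @param mean_area,sd_area mean and standard deviation of patch area, hectares.
#' @param min_dist minimum edge-to-edge inter-patch distance, metres.
#' @param seed optional integer seed; the same seed reproduces the landscape
#'   exactly. `NULL` draws from the current RNG stream.
#' @param initial_age_mode `"uniform0_100"` or `"zero"`.
#' @param max_tries placement attempts per patch before giving up.
#' @return an object of class `landscape`: a list with a `patches` data frame
#'   (`id`, `x`, `y`, `area`, `age`) plus the generation parameters.
#' @examples
#' L <- generate_landscape(side = 1000, cover = 0.05, seed = 1)
#' n_patches(L)
#' @export
generate_landscape <- function(side = 3163, cover = 0.1, mean_area = 0.5,
                               sd_area = 0.2, min_dist = 10, seed = NULL,
                               initial_age_mode = c("uniform0_100", "zero"),
                               max_tries = 5000L) {
  stopifnot(side > 0, cover > 0, cover < 1, mean_area > 0, sd_area >= 0,
            min_dist >= 0)
  initial_age_mode <- match.arg(initial_age_mode)
  n <- round_half_up(side^2 / HECTARE_M2 * cover / mean_area)
  if (n < 1) stop("parameters imply zero patches", call. = FALSE)
  with_seed(seed, {
    areas <- sample_patch_areas(n, mean_area, sd_area)
    xy <- place_patches(areas, matrix(numeric(0), 0, 2), numeric(0),
                        side, min_dist, max_tries)
    ages <- switch(initial_age_mode,
      uniform0_100 = sample(0:100, n, replace = TRUE),
      zero = rep(0L, n)
    )
    patches <- data.frame(id = seq_len(n), x = xy[, 1], y = xy[, 2],
                          area = areas, age = as.integer(ages))
    new_landscape(patches, side, cover, mean_area, sd_area, min_dist,
                  next_id = n + 1L)
  })
}

#' Number of living patches in a landscape
#' @param landscape a `landscape` object.
#' @return integer patch count.
#' @export
n_patches <- function(landscape) {
  nrow(landscape$patches)
}

#' Realized habitat cover of a landscape
#' @param landscape a `landscape` object.
#' @return summed patch area divided by arena area (fraction).
#' @export
realized_cover <- function(landscape) {
  sum(landscape$patches$area) / (landscape$side^2 / HECTARE_M2)
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", n_patches(x), " patches in a ", round(x$side), " x ",
      round(x$side), " m arena\n", sep = "")
  cat("  target cover ", format(100 * x$target_cover), "%, realized ",
      format(round(100 * realized_cover(x), 2)), "%\n", sep = "")
  cat("  patch area ", x$mean_area, " ha (sd ", x$sd_area,
      "), min edge spacing ", x$min_dist, " m\n", sep = "")
  cat("  ages ", min(x$patches$age), "-", max(x$patches$age), " steps\n",
      sep = "")
  invisible(x)
}

#' Pairwise centroid distance matrix of a landscape
#'
#' Euclidean centre-to-centre distances in metres, as used by the dispersal
#' kernel of the connectivity measure.
#'
#' @param landscape a `landscape` object.
#' @return a symmetric `n x n` matrix with zero diagonal, with patch ids as
#'   dimnames; `0 x 0` for an empty landscape.
#' @export
distance_matrix <- function(landscape) {
  p <- landscape$patches
  if (nrow(p) == 0L) {
    return(matrix(numeric(0), 0, 0))
  }
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  dimnames(d) <- list(p$id, p$id)
  d
}

#' Destroy and create a random fraction of patches
#'
#' Landscape dynamism (disturbance) is modelled as per-step patch turnover:
#' `k = round(fraction * N)` patches chosen uniformly at random are
#' destroyed and `k` new patches are generated in their place, keeping the
#' patch count constant and the habitat cover approximately constant (new
#' areas are drawn from the same distribution, not copied). New patches
#' start at age 0 and receive fresh ids; destroyed ids are never reused.
#'
#' @param landscape a `landscape` object.
#' @param fraction fraction of patches turned over, in `[0, 1]`.
#' @param seed optional integer seed; `NULL` continues the current RNG stream.
#' @param max_tries placement attempts per new patch.
#' @return a list with elements `landscape` (the updated object),
#'   `destroyed_ids` and `created_ids`.
#' @examples
#' L <- generate_landscape(side = 1000, cover = 0.05, seed = 1)
#' tv <- apply_turnover(L, 0.2, seed = 2)
#' length(tv$destroyed_ids)
#' @export
apply_turnover <- function(landscape, fraction, seed = NULL,
                           max_tries = 5000L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- n_patches(landscape)
  k <- round_half_up(fraction * n)
  if (k == 0L) {
    return(list(landscape = landscape, destroyed_ids = integer(0),
                created_ids = integer(0)))
  }
  with_seed(seed, {
    p <- landscape$patches
    idx_out <- sample.int(n, k)
    destroyed_ids <- p$id[idx_out]
    survivors <- p[-idx_out, , drop = FALSE]
    areas <- sample_patch_areas(k, landscape$mean_area, landscape$sd_area)
    xy <- place_patches(areas,
                        cbind(survivors$x, survivors$y),
                        patch_radius(survivors$area),
                        landscape$side, landscape$min_dist, max_tries)
    created_ids <- seq.int(landscape$next_id, length.out = k)
    created <- data.frame(id = created_ids, x = xy[, 1], y = xy[, 2],
                          area = areas, age = 0L)
    landscape$patches <- rbind(survivors, created)
    rownames(landscape$patches) <- NULL
    landscape$next_id <- landscape$next_id + k
    list(landscape = landscape, destroyed_ids = destroyed_ids,
         created_ids = created_ids)
  })
}

#' Advance habitat succession by one time step
#'
#' Increments every living patch's age by one; nothing else changes.
#'
#' @param landscape a `landscape` object.
#' @return the aged `landscape`.
#' @export
advance_age <- function(landscape) {
  landscape$patches$age <- landscape$patches$age + 1L
  landscape
}

#' Write / read a landscape as a delimited table
#'
#' The table has columns `id, x_m, y_m, area_ha, age`. `read_landscape()`
#' rebuilds a `landscape` object from such a table (generation parameters
#' must be re-supplied; they are not stored in the table).
#'
#' @param landscape a `landscape` object.
#' @param path file path of the CSV table.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns a `landscape`.
#' @export
write_landscape <- function(landscape, path) {
  p <- landscape$patches
  utils::write.csv(
    data.frame(id = p$id, x_m = p$x, y_m = p$y, area_ha = p$area, age = p$age),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_landscape
#' @param side,cover,mean_area,sd_area,min_dist generation parameters to
#'   attach to the imported landscape (see [generate_landscape()]).
#' @export
read_landscape <- function(path, side, cover = NA_real_, mean_area = NA_real_,
                           sd_area = NA_real_, min_dist = 0) {
  tab <- utils::read.csv(path)
  need <- c("id", "x_m", "y_m", "area_ha", "age")
  if (!all(need %in% names(tab))) {
    stop("landscape table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  patches <- data.frame(id = as.integer(tab$id), x = tab$x_m, y = tab$y_m,
                        area = tab$area_ha, age = as.integer(tab$age))
  stopifnot(all(patches$area > 0), all(patches$age >= 0),
            all(patches$x >= 0 & patches$x <= side),
            all(patches$y >= 0 & patches$y <= side),
            !anyDuplicated(patches$id))
  new_landscape(patches, side, cover, mean_area, sd_area, min_dist,
                next_id = max(patches$id) + 1L)
}

#' Construct a landscape from a patch data frame
#'
#' For user-supplied or hand-built networks (e.g. small fixtures).
#'
#' @param patches data frame with columns `id, x, y, area, age`.
#' @param side arena side length in metres.
#' @param min_dist minimum spacing recorded on the object (not re-checked).
#' @return a `landscape` object.
#' @export
as_landscape <- function(patches, side, min_dist = 0) {
  stopifnot(all(c("id", "x", "y", "area", "age") %in% names(patches)),
            all(patches$area > 0), all(patches$age >= 0),
            !anyDuplicated(patches$id))
  patches <- patches[, c("id", "x", "y", "area", "age")]
  rownames(patches) <- NULL
  new_landscape(patches, side, target_cover = NA_real_,
                mean_area = NA_real_, sd_area = NA_real_, min_dist = min_dist,
                next_id = max(patches$id) + 1L)
}

#' Export circular patch footprints as GeoJSON
#'
#' Writes a FeatureCollection of polygonised circles (one feature per patch,
#' with `id`, `area_ha` and `age` properties) for inspection in GIS tools.
#'
#' @param landscape a `landscape` object.
#' @param path output file path.
#' @param segments number of segments used to polygonise each circle.
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(landscape, path, segments = 32L) {
  p <- landscape$patches
  theta <- seq(0, 2 * pi, length.out = segments + 1L)
  features <- lapply(seq_len(nrow(p)), function(i) {
    r <- patch_radius(p$area[i])
    ring <- cbind(p$x[i] + r * cos(theta), p$y[i] + r * sin(theta))
    list(
      type = "Feature",
      properties = list(id = p$id[i], area_ha = p$area[i], age = p$age[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) ring[j, ])))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
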