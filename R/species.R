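# species_space: virtual species = IFM parameters + successional preference.

#' Construct one virtual species
#'
#' Bundles the Incidence Function Model parameters with a successional
#' habitat preference. `e`, the extinction probability in a patch of unit
#' area (1 ha), is derived from the critical area as `e = A0^x` and cannot
#' be set directly.
#'
#' @param alpha inverse of mean dispersal distance (1/m); smaller alpha =
#'   better disperser.
#' @param y colonization half-saturation constant; with the Allee exponent,
#'   `C = S^2 / (S^2 + y^2)`. Smaller y = more efficient colonizer.
#' @param A0 critical patch area (ha) below which local extinction is certain.
#' @param x extinction-area exponent.
#' @param b emigration-area exponent (source patch area in connectivity).
#' @param c_imm immigration-area exponent (focal patch area in connectivity).
#' @param preference `"early"`, `"mid"` or `"late"` successional preference.
#' @param species_id optional integer id.
#' @return a list of class `species_params`.
#' @examples
#' sp <- species_params(alpha = 0.004, y = 10, A0 = 0.05, preference = "mid")
#' sp$e
#' @export
species_params <- function(alpha, y, A0, x = 1, b = 1, c_imm = 1,
                           preference = c("early", "mid", "late"),
                           species_id = NA_integer_) {
  preference <- match.arg(preference)
  stopifnot(alpha > 0, y > 0, A0 > 0, x > 0)
  structure(
    list(species_id = as.integer(species_id), preference = preference,
         alpha = alpha, y = y, x = x, A0 = A0, e = A0^x, b = b, c = c_imm),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> id ", x$species_id, " (", x$preference,
      "-successional)\n", sep = "")
  cat("  alpha = ", x$alpha, " (mean dispersal ", round(1 / x$alpha),
      " m), y = ", x$y, "\n", sep = "")
  cat("  A0 = ", x$A0, " ha, x = ", x$x, ", e = ", x$e,
      ", b = ", x$b, ", c = ", x$c, "\n", sep = "")
  invisible(x)
}

#' Build the full factorial virtual-species set
#'
#' The trait space crosses three dispersal abilities (alpha = 0.02, 0.004,
#' 0.001 per metre, i.e. mean dispersal distances of 50 m to 1 km), three
#' colonization efficiencies (y = 5, 10, 20), two critical areas (A0 = 0.05
#' and 0.1 ha, giving e = 0.05 and 0.1 with x = 1) and three successional
#' preferences, for 54 species: 18 IFM parameter combinations per
#' preference guild.
#'
#' Ids are assigned in blocks — early 1-18, mid 19-36, late 37-54 — and
#' within each block by increasing A0, then increasing y, then increasing
#' dispersal ability (alpha 0.02, 0.004, 0.001). Under this scheme the two
#' mid-successional species with the highest dispersal ability and y = 5
#' are ids 21 and 30.
#'
#' @param b emigration-area exponent given to every species.
#' @return a data frame with one row per species and columns
#'   `species_id, preference, alpha, y, x, A0, e, b, c`.
#' @examples
#' sp <- build_virtual_species_set()
#' nrow(sp)
#' table(sp$preference)
#' @export
build_virtual_species_set <- function(b = 1) {
  prefs <- c("early", "mid", "late")
  alphas <- c(0.02, 0.004, 0.001) # increasing dispersal ability
  ys <- c(5, 10, 20)
  A0s <- c(0.05, 0.1)
  block <- expand.grid(alpha = alphas, y = ys, A0 = A0s,
                       KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies its first factor fastest, so rows are ordered by
  # (A0, y, alpha-sequence) as documented.
  out <- do.call(rbind, lapply(seq_along(prefs), function(k) {
    data.frame(
      species_id = (k - 1L) * 18L + seq_len(18L),
      preference = prefs[k],
      alpha = block$alpha, y = block$y, x = 1,
      A0 = block$A0, e = block$A0^1, b = b, c = 1
    )
  }))
  rownames(out) <- NULL
  out
}

#' Turn one row of a species table into a `species_params` object
#'
#' @param row a one-row data frame with the columns written by
#'   [build_virtual_species_set()] / [write_species_set()].
#' @return a `species_params` object.
#' @export
as_species_params <- function(row) {
  stopifnot(nrow(row) == 1L)
  species_params(alpha = row$alpha, y = row$y, A0 = row$A0, x = row$x,
                 b = row$b, c_imm = row$c, preference = row$preference,
                 species_id = row$species_id)
}

#' Write / read a species table
#'
#' Delimited-table round trip for species sets, so user-defined species can
#' be supplied in the same format the built-in set is exported in.
#'
#' @param species a species data frame (see [build_virtual_species_set()]).
#' @param path CSV file path.
#' @return `write_species_set()` returns `path` invisibly;
#'   `read_species_set()` returns the species data frame.
#' @export
write_species_set <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_set
#' @export
read_species_set <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "preference", "alpha", "y", "x", "A0", "e", "b", "c")
  if (!all(need %in% names(tab))) {
    stop("species table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$preference %in% c("early", "mid", "late"))) {
    stop("preference must be one of early, mid, late", call. = FALSE)
  }
  if (any(abs(tab$e - tab$A0^tab$x) > 1e-12)) {
    stop("column e must equal A0^x", call. = FALSE)
  }
  tab[need]
}
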