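# Spherical single- and multi-follicle geometry, source sampling and
# ray-region intersections.  Coordinates are Cartesian micrometres with the
# follicle centre at the origin; the six cell nuclei sit on the +/-x, +/-y
# and +/-z axes at |c| = lumen radius + cell thickness / 2.

#' Species presets for the thyroid follicle models
#'
#' Mean follicle dimensions and thyroid masses used for the three
#' species-specific models: lumen diameter / cell-layer thickness / nucleus
#' diameter of 50/6/4 um (mouse), 70/8/6 um (rat) and 150/10/8 um (human),
#' surrounding-follicle shells (cell layer, outer lumen) of 6/50, 8/70 and
#' 10/150 um, and thyroid masses of 3 mg, 30 mg and 19 g.
#'
#' @param species one of `"mouse"`, `"rat"`, `"human"`.
#' @return A list with fields `lumen_diameter_um`, `cell_thickness_um`,
#'   `nucleus_diameter_um`, `surround_cell_um`, `surround_lumen_um`,
#'   `thyroid_mass_g`.
#' @export
species_preset <- function(species = c("mouse", "rat", "human")) {
  species <- match.arg(species)
  p <- switch(species,
    mouse = list(lumen_diameter_um = 50, cell_thickness_um = 6,
                 nucleus_diameter_um = 4, surround_cell_um = 6,
                 surround_lumen_um = 50, thyroid_mass_g = 3e-3),
    rat   = list(lumen_diameter_um = 70, cell_thickness_um = 8,
                 nucleus_diameter_um = 6, surround_cell_um = 8,
                 surround_lumen_um = 70, thyroid_mass_g = 30e-3),
    human = list(lumen_diameter_um = 150, cell_thickness_um = 10,
                 nucleus_diameter_um = 8, surround_cell_um = 10,
                 surround_lumen_um = 150, thyroid_mass_g = 19)
  )
  c(list(species = species), p)
}

#' Construct a follicle model
#'
#' A spherical follicle lumen surrounded by a single layer of follicle cells
#' containing six symmetrically positioned spherical nuclei (on the
#' coordinate axes, centred mid-layer).  With `with_surroundings = TRUE` the
#' model adds one layer of neighbouring follicles, collapsed into a
#' surrounding cell shell plus an outer lumen shell (no inter-follicular
#' tissue).  Beyond the outermost boundary the model is vacuum: tracks are
#' terminated there.
#'
#' @param species optional species preset name; when given, dimensions
#'   default to the preset values.
#' @param lumen_diameter_um follicle lumen diameter (um), 10-500.
#' @param cell_thickness_um follicle-cell layer thickness (um).
#' @param nucleus_diameter_um nucleus diameter (um); must not exceed the
#'   cell-layer thickness.
#' @param with_surroundings add the surrounding-follicle shells.
#' @param surround_cell_um thickness of the surrounding cell shell (um).
#' @param surround_lumen_um thickness of the outer lumen shell (um).
#' @param thyroid_mass_g whole-thyroid mass (g), used by the MIRD
#'   comparison; taken from the preset when `species` is given.
#' @return An object of class `follicle_model`.
#' @examples
#' follicle_model(species = "mouse")
#' follicle_model(lumen_diameter_um = 170, cell_thickness_um = 10,
#'                nucleus_diameter_um = 8)
#' @export
follicle_model <- function(species = NULL,
                           lumen_diameter_um = NULL,
                           cell_thickness_um = NULL,
                           nucleus_diameter_um = NULL,
                           with_surroundings = FALSE,
                           surround_cell_um = NULL,
                           surround_lumen_um = NULL,
                           thyroid_mass_g = NULL) {
  if (!is.null(species)) {
    p <- species_preset(species)
    if (is.null(lumen_diameter_um))   lumen_diameter_um <- p$lumen_diameter_um
    if (is.null(cell_thickness_um))   cell_thickness_um <- p$cell_thickness_um
    if (is.null(nucleus_diameter_um)) nucleus_diameter_um <- p$nucleus_diameter_um
    if (is.null(surround_cell_um))    surround_cell_um <- p$surround_cell_um
    if (is.null(surround_lumen_um))   surround_lumen_um <- p$surround_lumen_um
    if (is.null(thyroid_mass_g))      thyroid_mass_g <- p$thyroid_mass_g
  }
  if (is.null(lumen_diameter_um) || is.null(cell_thickness_um) ||
      is.null(nucleus_diameter_um))
    stop("either a species preset or explicit dimensions are required")
  if (lumen_diameter_um < 10 || lumen_diameter_um > 500)
    stop("lumen diameter must lie in [10, 500] um")
  if (cell_thickness_um <= 0 || nucleus_diameter_um <= 0)
    stop("all dimensions must be positive")
  if (nucleus_diameter_um > cell_thickness_um)
    stop("nucleus diameter (", nucleus_diameter_um,
         " um) exceeds the cell-layer thickness (", cell_thickness_um, " um)")
  a <- lumen_diameter_um / 2
  t <- cell_thickness_um
  rc <- a + t / 2
  centres <- rbind(c(rc, 0, 0), c(-rc, 0, 0),
                   c(0, rc, 0), c(0, -rc, 0),
                   c(0, 0, rc), c(0, 0, -rc))
  radii <- c(a, a + t)
  if (with_surroundings) {
    if (is.null(surround_cell_um) || is.null(surround_lumen_um))
      stop("with_surroundings requires surround_cell_um and surround_lumen_um")
    if (surround_cell_um <= 0 || surround_lumen_um <= 0)
      stop("surrounding shell thicknesses must be positive")
    radii <- c(radii, a + t + surround_cell_um,
               a + t + surround_cell_um + surround_lumen_um)
  }
  structure(list(
    species = if (is.null(species)) NA_character_ else species,
    lumen_radius_um = a,
    cell_thickness_um = t,
    nucleus_diameter_um = nucleus_diameter_um,
    nucleus_radius_um = nucleus_diameter_um / 2,
    nucleus_centres = centres,
    with_surroundings = with_surroundings,
    surround_cell_um = if (with_surroundings) surround_cell_um else NA_real_,
    surround_lumen_um = if (with_surroundings) surround_lumen_um else NA_real_,
    radii_um = radii,
    thyroid_mass_g = if (is.null(thyroid_mass_g)) NA_real_ else thyroid_mass_g
  ), class = "follicle_model")
}

#' @export
print.follicle_model <- function(x, ...) {
  cat(sprintf("<follicle_model>%s lumen d=%g um, cells %g um, nucleus %g um\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              2 * x$lumen_radius_um, x$cell_thickness_um,
              x$nucleus_diameter_um))
  cat(sprintf(" nested boundaries at %s um%s\n",
              paste(x$radii_um, collapse = ", "),
              if (x$with_surroundings) " (with surrounding follicles)" else ""))
  invisible(x)
}

#' Serialise a follicle model to JSON
#'
#' Geometry echo used for provenance in all file outputs.
#'
#' @param model a `follicle_model`.
#' @return A JSON string.
#' @export
model_to_json <- function(model) {
  jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA,
                   matrix = "rowmajor")
}

#' Define a source distribution
#'
#' Source compartments for the 211At decays: `lumen_uniform` (A, uniform in
#' the follicle lumen), `lumen_surface` (B, uniform on a concentric sphere
#' of given radius inside the lumen; radius 0 is a point source at the
#' centre), `cells_uniform` (C, uniform in the follicle-cell layer,
#' cytoplasm and nuclei alike), `nuclei_uniform` (D, uniform over the union
#' of the six nuclei), `surrounding_lumen_uniform` (E) and
#' `surrounding_cells_uniform` (F) for the multi-follicle model.
#'
#' @param kind source compartment, see above.
#' @param radius_um surface radius for `lumen_surface` (um).
#' @return An object of class `source_distribution`.
#' @export
source_distribution <- function(kind = c("lumen_uniform", "lumen_surface",
                                         "cells_uniform", "nuclei_uniform",
                                         "surrounding_lumen_uniform",
                                         "surrounding_cells_uniform"),
                                radius_um = NULL) {
  kind <- match.arg(kind)
  if (kind == "lumen_surface") {
    if (is.null(radius_um) || !is.numeric(radius_um) || radius_um < 0)
      stop("lumen_surface requires a non-negative radius_um")
  } else if (!is.null(radius_um)) {
    stop("radius_um is only meaningful for kind = 'lumen_surface'")
  }
  structure(list(kind = kind, radius_um = radius_um),
            class = "source_distribution")
}

#' @export
print.source_distribution <- function(x, ...) {
  cat("<source_distribution>", x$kind)
  if (!is.null(x$radius_um)) cat(sprintf(" (r = %g um)", x$radius_um))
  cat("\n")
  invisible(x)
}

is_lumen_source <- function(source)
  source$kind %in% c("lumen_uniform", "lumen_surface")

# n points uniform on the unit sphere (matrix n x 3)
unit_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  nrm <- sqrt(rowSums(v * v))
  bad <- nrm < 1e-12
  if (any(bad)) {            # essentially impossible; keep the draw valid
    v[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
    nrm[bad] <- 1
  }
  v / nrm
}

#' Sample isotropic emission directions
#'
#' @param n number of directions.
#' @return An `n x 3` matrix of unit vectors, uniform on the sphere.
#' @export
sample_direction <- function(n) unit_sphere(n)

# radii uniform-in-volume within a spherical shell [r_in, r_out]
shell_radii <- function(n, r_in, r_out) {
  (r_in^3 + stats::runif(n) * (r_out^3 - r_in^3))^(1 / 3)
}

#' Sample decay positions for a source compartment
#'
#' Uniform-in-volume sampling over the named region (exact radial CDF
#' inversion for balls and shells; for the nuclei, a nucleus is chosen
#' uniformly -- the six are congruent, so per-nucleus and per-unit-volume
#' sampling coincide).
#'
#' @param model a `follicle_model`.
#' @param source a `source_distribution`.
#' @param n number of positions.
#' @return An `n x 3` matrix of positions (um).
#' @export
sample_position <- function(model, source, n) {
  a <- model$lumen_radius_um
  b <- a + model$cell_thickness_um
  k <- source$kind
  if (k %in% c("surrounding_lumen_uniform", "surrounding_cells_uniform") &&
      !model$with_surroundings)
    stop("source '", k, "' requires a model with surrounding follicles")
  switch(k,
    lumen_uniform = shell_radii(n, 0, a) * unit_sphere(n),
    lumen_surface = {
      r <- source$radius_um
      if (r > a) stop("surface radius exceeds the lumen radius")
      if (r == 0) matrix(0, n, 3) else r * unit_sphere(n)
    },
    cells_uniform = shell_radii(n, a, b) * unit_sphere(n),
    nuclei_uniform = {
      idx <- sample.int(6L, n, replace = TRUE)
      model$nucleus_centres[idx, , drop = FALSE] +
        shell_radii(n, 0, model$nucleus_radius_um) * unit_sphere(n)
    },
    surrounding_cells_uniform =
      shell_radii(n, b, model$radii_um[3]) * unit_sphere(n),
    surrounding_lumen_uniform =
      shell_radii(n, model$radii_um[3], model$radii_um[4]) * unit_sphere(n)
  )
}

#' Ray-sphere intersection
#'
#' Forward intersection of the half-line `origin + t * direction` (t >= 0)
#' with a sphere.  Returns zero or one `(entry, exit)` interval; an origin
#' inside the sphere yields entry 0; tangent grazing counts as a miss.
#'
#' @param origin numeric length-3 ray origin (um).
#' @param direction numeric length-3 unit vector.
#' @param centre numeric length-3 sphere centre (um).
#' @param radius sphere radius (um).
#' @return A matrix with columns `entry`, `exit` and 0 or 1 rows.
#' @export
ray_sphere_segments <- function(origin, direction, centre, radius) {
  stopifnot(length(origin) == 3L, length(direction) == 3L,
            length(centre) == 3L, radius > 0)
  if (abs(sum(direction^2) - 1) > 1e-9)
    stop("direction must be a unit vector")
  q <- origin - centre
  bq <- sum(q * direction)
  disc <- bq^2 - (sum(q * q) - radius^2)
  empty <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("entry", "exit")))
  if (disc <= 0) return(empty)
  s <- sqrt(disc)
  t1 <- -bq - s; t2 <- -bq + s
  if (t2 <= 0) return(empty)
  matrix(c(max(t1, 0), t2), 1, 2,
         dimnames = list(NULL, c("entry", "exit")))
}

#' Mean chord length of a sphere
#'
#' Cauchy's theorem for convex bodies gives `2 d / 3` for a sphere of
#' diameter `d` under uniform isotropic randomness.
#'
#' @param d_um sphere diameter (um).
#' @return mean chord length (um).
#' @export
mean_chord_length <- function(d_um) {
  if (any(!is.finite(d_um)) || any(d_um <= 0))
    stop("diameter must be positive")
  2 * d_um / 3
}

#' Containment probability of a fixed-length track in a sphere
#'
#' For a point drawn uniformly in a sphere of radius `a` and an isotropic
#' direction, the probability that a straight track of length `R` ends
#' inside the sphere: `1 - 3R/(4a) + R^3/(16 a^3)` for `R <= 2a`, else 0.
#' Used as the closed-form oracle for the stopped-in-lumen fraction.
#'
#' @param track_um track length R (um), vectorised.
#' @param radius_um sphere radius a (um).
#' @return containment probability.
#' @examples
#' containment_probability(0, 25)      # 1
#' containment_probability(50, 25)     # 0
#' @export
containment_probability <- function(track_um, radius_um) {
  if (any(track_um < 0) || any(radius_um <= 0))
    stop("track length must be >= 0 and radius > 0")
  x <- track_um / (2 * radius_um)       # in units of the diameter
  p <- 1 - 1.5 * x + 0.5 * x^3
  p[x > 1] <- 0
  p
}
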