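# Physical constants used throughout (SI-ish, see unit notes at each use).
.const <- list(
  keV_to_J  = 1.602176634e-16,
  MeV_to_J  = 1.602176634e-13,
  rho_water = 1.0,   # g/cm^3
  rho_iodine = 4.94, # g/cm^3, stable 127I
  cutoff_MeV = 1e-3  # 1 keV transport cut-off
)

#' Define a transport medium
#'
#' A medium is a named density plus element mass fractions.  Only water,
#' iodine and their mixtures are used by the follicle models, but the
#' constructor is generic.
#'
#' @param name label for the medium.
#' @param density mass density in g/cm^3.
#' @param composition named numeric vector of element mass fractions,
#'   summing to 1.
#' @return An object of class `medium`.
#' @examples
#' medium("water", 1.0, c(H = 0.1119, O = 0.8881))
#' @export
medium <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("medium density must be a single positive number")
  if (any(composition < 0) || any(composition > 1))
    stop("mass fractions must lie in [0, 1]")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (within 1e-9)")
  structure(list(name = name, density = density, composition = composition),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s, density %.4f g/cm^3\n", x$name, x$density))
  comp <- paste(sprintf("%s=%.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat(" composition:", comp, "\n")
  invisible(x)
}

# Read one packaged two-column stopping-power fixture (energy MeV,
# mass stopping power MeV cm^2/g).  '#' lines are provenance.
read_stopping_table <- function(element = c("water", "iodine")) {
  element <- match.arg(element)
  fn <- system.file("extdata",
                    sprintf("alpha_%s_stopping.txt", element),
                    package = "follidose")
  if (!nzchar(fn) || !file.exists(fn))
    stop("stopping-power fixture for '", element, "' is missing; ",
         "the package installation is broken")
  tab <- utils::read.table(fn, comment.char = "#",
                           col.names = c("energy_MeV", "S_mass"))
  if (nrow(tab) < 10 || any(!is.finite(tab$energy_MeV)) ||
      any(!is.finite(tab$S_mass)) || any(tab$S_mass <= 0) ||
      is.unsorted(tab$energy_MeV, strictly = TRUE))
    stop("stopping-power fixture for '", element, "' is garbled")
  tab
}

# log-log interpolator for a mass stopping-power table
loglog_interp <- function(E, S) {
  f <- stats::approxfun(log(E), log(S), rule = 2)
  function(x) exp(f(log(x)))
}

# Build a stopping-power model for a medium described by a mass
# stopping-power function (MeV cm^2/g) and a density.  The range grid is a
# cumulative trapezoid of dE/S on a dense log grid starting at the cut-off;
# the residual range below the cut-off (a few nm) is dropped, i.e.
# R(cutoff) = 0.
build_stopping_model <- function(med, S_mass_fun, n_grid = 4000L) {
  cutoff <- .const$cutoff_MeV
  E <- exp(seq(log(cutoff), log(10), length.out = n_grid))
  S_mass <- S_mass_fun(E)                       # MeV cm^2/g
  S_lin_MeV_um <- S_mass * med$density / 1e4    # MeV/um
  # trapezoid of (dE / S) in log-energy: integrand E/S dlnE
  f <- E / S_lin_MeV_um
  dln <- diff(log(E))
  R <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dln))  # um
  structure(list(
    medium = med,
    cutoff_MeV = cutoff,
    energy_MeV = E,
    S_keV_um = S_lin_MeV_um * 1e3,
    range_um = R,
    .R_of_E = stats::approxfun(E, R, rule = 2),
    .E_of_R = stats::approxfun(R, E, rule = 2)
  ), class = "stopping_power_model")
}

#' @export
print.stopping_power_model <- function(x, ...) {
  cat(sprintf("<stopping_power_model> %s (%.4f g/cm^3)\n",
              x$medium$name, x$medium$density))
  cat(sprintf(" grid %g keV - %g MeV; R(5.867 MeV) = %.2f um, R(7.450 MeV) = %.2f um\n",
              x$cutoff_MeV * 1e3, max(x$energy_MeV),
              csda_range(x, 5.867), csda_range(x, 7.450)))
  invisible(x)
}

#' Alpha stopping-power model for liquid water
#'
#' Loads the packaged ICRU-49-style alpha/water mass stopping-power table
#' (calibrated to CSDA ranges of 48 and 70 um for the two 211At alpha lines)
#' and builds the energy-range machinery used by the transport engine.
#'
#' @return An object of class `stopping_power_model` with the energy grid
#'   (MeV), linear stopping power (keV/um) and CSDA range (um).
#' @examples
#' m <- build_water_model()
#' csda_range(m, c(5.867, 7.450))
#' @export
build_water_model <- function() build_mixture_model(0)

#' Alpha stopping-power model for a water-iodine mixture
#'
#' Models the follicle lumen loaded with a mass fraction of stable iodine.
#' Mass stopping powers are combined by Bragg additivity over the element
#' tables; the mixture density comes from mass-fraction-weighted specific
#' volumes of water (1.0 g/cm^3) and iodine (4.94 g/cm^3).  A fraction of 0
#' reproduces the pure-water model exactly.
#'
#' @param iodine_mass_fraction iodine mass fraction in `[0, 0.05]`.
#' @return An object of class `stopping_power_model`.
#' @examples
#' m2 <- build_mixture_model(0.02)
#' csda_range(m2, 7.450) < csda_range(build_water_model(), 7.450)
#' @export
build_mixture_model <- function(iodine_mass_fraction) {
  w <- iodine_mass_fraction
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 0.05)
    stop("iodine_mass_fraction must be a single value in [0, 0.05]")
  wat <- read_stopping_table("water")
  Sw <- loglog_interp(wat$energy_MeV, wat$S_mass)
  if (w == 0) {
    med <- medium("water", .const$rho_water, c(H = 0.1119, O = 0.8881))
    return(build_stopping_model(med, Sw))
  }
  iod <- read_stopping_table("iodine")
  Si <- loglog_interp(iod$energy_MeV, iod$S_mass)
  rho <- 1 / ((1 - w) / .const$rho_water + w / .const$rho_iodine)
  comp <- c(H = (1 - w) * 0.1119, O = (1 - w) * 0.8881, I = w)
  med <- medium(sprintf("water+%.3g%% iodine", 100 * w), rho, comp)
  build_stopping_model(med, function(E) (1 - w) * Sw(E) + w * Si(E))
}

check_energy_in_grid <- function(model, E) {
  if (any(E > max(model$energy_MeV) * (1 + 1e-12)))
    stop("energy above the stopping-power grid (", max(model$energy_MeV),
         " MeV)")
  if (any(E < 0)) stop("energy must be non-negative")
}

#' CSDA range
#'
#' Continuous-slowing-down range of an alpha particle of the given energy,
#' measured from the 1 keV transport cut-off (the range at the cut-off is
#' defined as zero).
#'
#' @param model a `stopping_power_model`.
#' @param E_MeV kinetic energy (MeV), vectorised.
#' @return range in micrometres.
#' @export
csda_range <- function(model, E_MeV) {
  check_energy_in_grid(model, E_MeV)
  out <- model$.R_of_E(pmax(E_MeV, model$cutoff_MeV))
  out[E_MeV <= model$cutoff_MeV] <- 0
  out
}

#' Linear stopping power
#'
#' @param model a `stopping_power_model`.
#' @param E_MeV kinetic energy (MeV), vectorised.
#' @return linear stopping power in keV/um.
#' @export
stopping_power <- function(model, E_MeV) {
  check_energy_in_grid(model, E_MeV)
  stats::approx(model$energy_MeV, model$S_keV_um, xout = E_MeV,
                rule = 2)$y
}

#' Residual energy after a path length
#'
#' CSDA bookkeeping `E_out = R^-1(R(E0) - l)`.  A result at or below the
#' 1 keV cut-off is reported as 0: the particle is considered stopped and the
#' remaining energy is deposited at the end of the step.
#'
#' @param model a `stopping_power_model`.
#' @param E0_MeV entry energy (MeV), vectorised.
#' @param pathlength_um traversed path length (um), vectorised.
#' @return residual kinetic energy (MeV).
#' @examples
#' m <- build_water_model()
#' residual_energy(m, 7.450, 0)     # 7.45
#' residual_energy(m, 5.867, 100)   # 0 (stopped)
#' @export
residual_energy <- function(model, E0_MeV, pathlength_um) {
  if (any(pathlength_um < 0)) stop("pathlength must be non-negative")
  check_energy_in_grid(model, E0_MeV)
  n <- max(length(E0_MeV), length(pathlength_um))
  E0 <- rep_len(E0_MeV, n); len <- rep_len(pathlength_um, n)
  r2 <- csda_range(model, E0) - len
  out <- numeric(n)
  ok <- r2 > 0 & E0 > model$cutoff_MeV
  out[ok] <- model$.E_of_R(r2[ok])
  out[out <= model$cutoff_MeV] <- 0
  out
}

#' Energy deposited over a track segment
#'
#' Energy imparted along a segment of given length entered at `E_entry`:
#' the difference between entry and residual energy.  Additive over
#' subdivided segments by construction and bounded by the entry energy.
#'
#' @inheritParams residual_energy
#' @param E_entry_MeV energy at the segment entrance (MeV).
#' @param segment_um segment length (um).
#' @return energy imparted (MeV).
#' @export
energy_deposited <- function(model, E_entry_MeV, segment_um) {
  E_entry_MeV - residual_energy(model, E_entry_MeV, segment_um)
}

# fast unchecked vector step used by the transport engine: E==0 stays 0
step_energy <- function(model, E_MeV, len_um) {
  r <- model$.R_of_E(E_MeV)
  r[E_MeV <= model$cutoff_MeV] <- 0
  r2 <- r - len_um
  out <- numeric(length(E_MeV))
  ok <- r2 > 0
  if (any(ok)) out[ok] <- model$.E_of_R(r2[ok])
  out[out <= model$cutoff_MeV] <- 0
  out
}
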