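# MIRD mean-dose formalism and the comparison between the macroscopic
# whole-thyroid dose and the microdosimetric nucleus dose.

#' MIRD parameters for a thyroid
#'
#' @param thyroid_mass_g thyroid mass (g); presets use 3 mg (mouse),
#'   30 mg (rat), 19 g (human).
#' @param delta_MeV mean energy emitted per nuclear transition
#'   (default 6.8 MeV for 211At incl. its alpha-emitting daughter).
#' @param phi absorbed fraction in the thyroid (default 1).
#' @param packing_fraction fraction of the gland volume occupied by
#'   follicles (default 0.70).
#' @return An object of class `mird_parameters`.
#' @export
mird_parameters <- function(thyroid_mass_g, delta_MeV = 6.8, phi = 1,
                            packing_fraction = 0.70) {
  if (!is.numeric(thyroid_mass_g) || thyroid_mass_g <= 0)
    stop("thyroid mass must be positive")
  if (phi <= 0 || phi > 1) stop("absorbed fraction must lie in (0, 1]")
  if (packing_fraction <= 0 || packing_fraction > 1)
    stop("packing fraction must lie in (0, 1]")
  structure(list(thyroid_mass_g = thyroid_mass_g, delta_MeV = delta_MeV,
                 phi = phi, packing_fraction = packing_fraction),
            class = "mird_parameters")
}

#' MIRD mean absorbed dose
#'
#' `Dbar = A * Delta * phi / m` with exact MeV-to-joule conversion.
#'
#' @param params a `mird_parameters`.
#' @param cumulated_activity total number of decays in the gland.
#' @return mean absorbed dose (Gy).
#' @export
mean_absorbed_dose <- function(params, cumulated_activity) {
  stopifnot(inherits(params, "mird_parameters"))
  if (any(cumulated_activity < 0)) stop("cumulated activity must be >= 0")
  cumulated_activity * params$delta_MeV * .const$MeV_to_J * params$phi /
    (params$thyroid_mass_g * 1e-3)
}

#' Cumulated activity for a target mean dose
#'
#' Closed-form inversion of the MIRD mean-dose equation.
#'
#' @param params a `mird_parameters`.
#' @param dose_Gy target mean absorbed dose (Gy).
#' @return number of decays.
#' @export
cumulated_activity_for_dose <- function(params, dose_Gy) {
  stopifnot(inherits(params, "mird_parameters"))
  dose_Gy * params$thyroid_mass_g * 1e-3 /
    (params$delta_MeV * .const$MeV_to_J * params$phi)
}

# follicle volumes (um^3); the "follicle" is lumen + cell layer
follicle_volumes <- function(model) {
  a <- model$lumen_radius_um
  b <- a + model$cell_thickness_um
  list(lumen = 4 / 3 * pi * a^3, follicle = 4 / 3 * pi * b^3)
}

#' Decays per follicle lumen
#'
#' Distributes the cumulated activity uniformly over the lumen volume of
#' the gland: the gland volume follows from the thyroid mass at unit
#' density, a packing fraction of it consists of follicles, and each
#' follicle contains one lumen.  The per-lumen decay count is
#' `A * V_follicle / (packing * V_thyroid)`.
#'
#' @param params a `mird_parameters`.
#' @param model a `follicle_model`.
#' @param cumulated_activity total number of decays in the gland.
#' @return expected number of decays in one follicle lumen.
#' @export
decays_per_lumen <- function(params, model, cumulated_activity) {
  stopifnot(inherits(params, "mird_parameters"),
            inherits(model, "follicle_model"))
  v <- follicle_volumes(model)
  V_thyroid_um3 <- params$thyroid_mass_g * 1e12   # unit density, 1 g = 1 cm^3
  cumulated_activity * v$follicle / (params$packing_fraction * V_thyroid_um3)
}

#' Micro-macro dose comparison
#'
#' For a gland receiving a given MIRD mean absorbed dose with the activity
#' homogeneously distributed within the follicle lumens, computes the mean
#' dose to a follicle-cell nucleus from microdosimetric mean specific
#' energies: the self term is (decays per lumen) x <z> from the
#' single-follicle lumen source; the neighbour term places the same lumen
#' decay density in the surrounding-lumen shell of the multi-follicle model
#' and multiplies by <z> from the surrounding-lumen source.  The neighbour
#' bookkeeping is a convention of this package (see the methods vignette)
#' and is reported separately from the self term.
#'
#' @param params a `mird_parameters`.
#' @param model a `follicle_model`; the surrounding-lumen shell is needed
#'   only when `mean_z_surround_Gy` is supplied.
#' @param mean_z_self_Gy mean specific energy per decay, single-follicle
#'   lumen source (Gy).
#' @param mean_z_surround_Gy optional mean specific energy per decay,
#'   surrounding-lumen source (Gy).
#' @param target_dose_Gy MIRD mean absorbed dose to the gland (default 1).
#' @return A list with the cumulated activity, decays per lumen, self,
#'   surround and total nucleus doses (Gy).
#' @export
micro_macro_comparison <- function(params, model, mean_z_self_Gy,
                                   mean_z_surround_Gy = NULL,
                                   target_dose_Gy = 1) {
  stopifnot(inherits(params, "mird_parameters"),
            inherits(model, "follicle_model"))
  if (!is.numeric(mean_z_self_Gy) || is.na(mean_z_self_Gy))
    stop("mean_z_self_Gy from a lumen-source simulation is required")
  A <- cumulated_activity_for_dose(params, target_dose_Gy)
  n_lumen <- decays_per_lumen(params, model, A)
  self <- n_lumen * mean_z_self_Gy
  surround <- 0
  n_surround <- NA_real_
  if (!is.null(mean_z_surround_Gy)) {
    if (!model$with_surroundings)
      stop("surround term requires a model with surrounding follicles")
    v <- follicle_volumes(model)
    density <- A * v$follicle / (params$packing_fraction *
                                   params$thyroid_mass_g * 1e12 * v$lumen)
    r3 <- model$radii_um[3]; r4 <- model$radii_um[4]
    V_shell <- 4 / 3 * pi * (r4^3 - r3^3)
    n_surround <- density * V_shell
    surround <- n_surround * mean_z_surround_Gy
  }
  list(cumulated_activity = A,
       decays_per_lumen = n_lumen,
       decays_in_surround_shell = n_surround,
       self_dose_Gy = self,
       surround_dose_Gy = surround,
       total_dose_Gy = self + surround,
       target_dose_Gy = target_dose_Gy,
       convention = paste("lumen-volume decay density; neighbour decays",
                          "placed in the surrounding-lumen shell at the",
                          "same density"))
}
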