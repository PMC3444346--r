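# Microdosimetric estimators: mean specific energy per decay <z> (average
# over all histories), single-hit mean specific energy <z1> (average over
# hit histories only), frequency-mean lineal energy <yF>, the single-hit
# spectra f(z1) and f(y), and the stopped-in-lumen fraction.

# unit-density spherical nucleus mass (kg) from its diameter in um
nucleus_mass_kg <- function(d_um) (pi / 6) * d_um^3 * 1e-15

#' Specific energy of a deposit
#'
#' `z = eps / m` with the target mass from a unit-density sphere of the
#' given diameter.
#'
#' @param eps_keV energy imparted (keV), vectorised.
#' @param d_um target (nucleus) diameter (um).
#' @return specific energy in Gy.
#' @examples
#' specific_energy(262, 4)   # ~1.25 Gy
#' @export
specific_energy <- function(eps_keV, d_um) {
  if (any(eps_keV < 0)) stop("energy imparted must be non-negative")
  if (d_um <= 0) stop("diameter must be positive")
  eps_keV * .const$keV_to_J / nucleus_mass_kg(d_um)
}

#' Lineal energy of a single event
#'
#' `y = eps / lbar` with the Cauchy mean chord `lbar = 2 d / 3`.
#' Defined for single energy-deposition events only (`eps > 0`).
#'
#' @param eps_keV energy imparted in one event (keV), vectorised.
#' @param d_um target diameter (um).
#' @return lineal energy in keV/um.
#' @export
lineal_energy <- function(eps_keV, d_um) {
  if (any(eps_keV <= 0))
    stop("lineal energy is defined for positive single-event deposits only")
  eps_keV / mean_chord_length(d_um)
}

# Internal constructor; the six nuclei are scored individually and the
# estimates averaged over them, implemented as pooled sums (the identity
# <z> = <z1> * M / N holds exactly with M = pooled hits / 6).  For the
# nuclei-uniform source the nuclei are both sources and targets: each decay
# is normalised to the nucleus it occurred in (divisor 1, M = pooled hits),
# which makes <z> = <z1> as almost every history hits its own nucleus.
new_microdose_summary <- function(n_histories, M_k, sum_z_k, sum_h, sum_h2,
                                  sum_z1, sum_z1_2, n_line, stopped_line,
                                  lumen_source, nucleus_diameter_um, hits,
                                  self_source = FALSE) {
  N <- n_histories
  divisor <- if (self_source) 1 else 6
  M_tot <- sum(M_k)
  mean_z <- sum(sum_z_k) / (divisor * N)
  # SEM of <z> from the per-history nucleus-averaged z (histories are iid)
  var_h <- max(sum_h2 - sum_h^2 / N, 0) / max(N - 1, 1)
  se_z <- sqrt(var_h / N)
  if (M_tot > 0) {
    mean_z1 <- sum_z1 / M_tot
    var_z1 <- max(sum_z1_2 - sum_z1^2 / M_tot, 0) / max(M_tot - 1, 1)
    se_z1 <- sqrt(var_z1 / M_tot)
  } else {
    mean_z1 <- NA_real_
    se_z1 <- NA_real_
  }
  d <- nucleus_diameter_um
  m_kg <- nucleus_mass_kg(d)
  lbar <- mean_chord_length(d)
  # exact algebraic companion of <z1>: <yF> = <z1> m / (lbar keV_to_J)
  z_to_y <- m_kg / (.const$keV_to_J * lbar)
  max_z1 <- if (!is.null(hits) && nrow(hits))
    max(hits$eps_keV) * .const$keV_to_J / m_kg else NA_real_
  structure(list(
    n_histories = N,
    hits_per_nucleus = M_k,
    M = M_tot / divisor,
    mean_z_Gy = mean_z,
    mean_z1_Gy = mean_z1,
    mean_yF_keV_um = if (M_tot > 0) mean_z1 * z_to_y else NA_real_,
    max_z1_Gy = max_z1,
    max_y_keV_um = if (!is.na(max_z1)) max_z1 * z_to_y else NA_real_,
    rel_error_z = if (mean_z > 0) se_z / mean_z else NA_real_,
    rel_error_z1 = if (M_tot > 0 && mean_z1 > 0) se_z1 / mean_z1 else NA_real_,
    se_z_Gy = se_z,
    se_z1_Gy = se_z1,
    n_per_line = n_line,
    stopped_per_line = if (lumen_source) stopped_line / N else
      rep(NA_real_, length(n_line)),
    stopped_fraction = if (lumen_source) sum(stopped_line) / N else NA_real_,
    lumen_source = lumen_source,
    nucleus_diameter_um = d,
    nucleus_mass_kg = m_kg,
    mean_chord_um = lbar
  ), class = "microdose_summary")
}

#' @export
print.microdose_summary <- function(x, ...) {
  cat("<microdose_summary>\n")
  cat(sprintf("  N = %g histories, M = %.1f hits/nucleus\n",
              x$n_histories, x$M))
  cat(sprintf("  <z>  = %.4g Gy (rel. error %.3g)\n",
              x$mean_z_Gy, x$rel_error_z))
  if (!is.na(x$mean_z1_Gy)) {
    cat(sprintf("  <z1> = %.4g Gy (rel. error %.3g), max z1 = %.3g Gy\n",
                x$mean_z1_Gy, x$rel_error_z1, x$max_z1_Gy))
    cat(sprintf("  <yF> = %.4g keV/um, max y = %.3g keV/um\n",
                x$mean_yF_keV_um, x$max_y_keV_um))
  } else {
    cat("  no hits: <z1>, <yF> undefined\n")
  }
  if (x$lumen_source)
    cat(sprintf("  stopped in lumen: %.4g%% (per line: %s)\n",
                100 * x$stopped_fraction,
                paste(sprintf("%.4g%%", 100 * x$stopped_per_line),
                      collapse = ", ")))
  invisible(x)
}

#' Single-hit spectrum
#'
#' Histogram of the pooled single-hit values over left-closed, right-open
#' bins starting at zero, normalised to unit area.  The conventional bin
#' widths are 20 mGy for `f(z1)` and 5 keV/um for `f(y)`.
#'
#' @param run a `follidose_run` (from [run_simulation()] with
#'   `keep_hits = TRUE`).
#' @param quantity `"z1"` (specific energy, Gy) or `"y"` (lineal energy,
#'   keV/um).
#' @param bin_width bin width; defaults to 0.020 Gy for `z1` and 5 keV/um
#'   for `y`.
#' @return An object of class `microdose_spectrum`: a data frame of
#'   `bin_left`, `bin_right`, `density`, with attributes `quantity`,
#'   `bin_width`, `n_events` and `max_value`.
#' @export
build_spectrum <- function(run, quantity = c("z1", "y"), bin_width = NULL) {
  quantity <- match.arg(quantity)
  hits <- if (inherits(run, "follidose_run")) run$hits else run
  if (is.null(hits) || nrow(hits) == 0L)
    stop("no hits recorded: spectrum is undefined")
  d <- if (inherits(run, "follidose_run"))
    run$config$model$nucleus_diameter_um else attr(run, "nucleus_diameter_um")
  vals <- switch(quantity,
                 z1 = specific_energy(hits$eps_keV, d),
                 y = lineal_energy(hits$eps_keV, d))
  if (is.null(bin_width)) bin_width <- switch(quantity, z1 = 0.020, y = 5)
  nbin <- ceiling(max(vals) / bin_width + 1e-12)
  nbin <- max(nbin, 1L)
  idx <- pmin(floor(vals / bin_width), nbin - 1L)   # left-closed bins
  counts <- tabulate(idx + 1L, nbin)
  out <- data.frame(bin_left = bin_width * (seq_len(nbin) - 1L),
                    bin_right = bin_width * seq_len(nbin),
                    density = counts / (length(vals) * bin_width))
  structure(out, class = c("microdose_spectrum", "data.frame"),
            quantity = quantity, bin_width = bin_width,
            n_events = length(vals), max_value = max(vals))
}

#' Stopped-in-lumen fraction
#'
#' Fraction of histories whose alpha track deposited all kinetic energy
#' inside the (central) follicle lumen, in total and split by emission
#' line.  Only meaningful for lumen sources (compartments A and B).
#'
#' @param run a `follidose_run`.
#' @return A list with `total` and `per_line` (fractions of all histories;
#'   the per-line values sum to the total).
#' @export
stopped_fraction <- function(run) {
  stopifnot(inherits(run, "follidose_run"))
  if (!is_lumen_source(run$config$source))
    stop("stopped_fraction is defined for lumen sources (A/B) only")
  list(total = run$summary$stopped_fraction,
       per_line = run$summary$stopped_per_line)
}
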