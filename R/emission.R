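# 211At alpha emission spectrum.

#' Alpha emission spectrum of 211At
#'
#' The two main alpha lines of the 211At decay (the 211At -> 207Bi branch at
#' 5.867 MeV, 42% yield, and the 211Po -> 207Pb branch at 7.450 MeV, 58%
#' yield).  One simulated history represents one decay; photons, electrons
#' and daughter recoils are neglected.
#'
#' @return An object of class `alpha_spectrum` with fields `energy_MeV` and
#'   `yield`.
#' @export
at211_spectrum <- function() {
  alpha_spectrum(energy_MeV = c(5.867, 7.450), yield = c(0.42, 0.58))
}

#' Construct an alpha emission spectrum
#'
#' @param energy_MeV line energies (MeV).
#' @param yield line probabilities, summing to 1.
#' @export
alpha_spectrum <- function(energy_MeV, yield) {
  if (length(energy_MeV) != length(yield) || length(yield) < 1L)
    stop("energy and yield must be equal-length, non-empty vectors")
  if (any(yield < 0) || abs(sum(yield) - 1) > 1e-9)
    stop("yields must be non-negative and sum to 1")
  structure(list(energy_MeV = as.numeric(energy_MeV),
                 yield = as.numeric(yield)),
            class = "alpha_spectrum")
}

#' @export
print.alpha_spectrum <- function(x, ...) {
  cat("<alpha_spectrum>\n")
  for (i in seq_along(x$energy_MeV))
    cat(sprintf("  %.3f MeV  (yield %.2f)\n", x$energy_MeV[i], x$yield[i]))
  invisible(x)
}

# draw n emission line indices
sample_emission_line <- function(spectrum, n) {
  if (length(spectrum$yield) == 2L) {
    # branch on a single uniform; cheaper and reproducible
    1L + (stats::runif(n) >= spectrum$yield[1L])
  } else {
    sample.int(length(spectrum$yield), n, replace = TRUE,
               prob = spectrum$yield)
  }
}
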