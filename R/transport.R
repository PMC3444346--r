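# Per-decay history transport: straight-line CSDA tracks through the nested
# spherical media, partitioned exactly at every region boundary (no fixed
# stepping).  The six central nuclei are scored individually.

#' Simulation configuration
#'
#' @param model a `follicle_model`.
#' @param source a `source_distribution` valid for the model.
#' @param n_histories number of decays to simulate (default 1e7, the
#'   full-table value; sweeps and acceptance runs use 1e6).
#' @param seed integer RNG seed, recorded in all outputs.
#' @param iodine_fraction stable-iodine mass fraction in the lumen
#'   region(s), in `[0, 0.05]`.
#' @param spectrum an `alpha_spectrum` (default the 211At lines).
#' @param straggling apply Gaussian (Bohr) energy straggling to nucleus
#'   chord deposits.  Default `FALSE`; the default defines all reference
#'   results.
#' @param chunk_size histories per vectorised block.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model, source,
                              n_histories = 1e7,
                              seed = 1L,
                              iodine_fraction = 0,
                              spectrum = at211_spectrum(),
                              straggling = FALSE,
                              chunk_size = 250000L) {
  stopifnot(inherits(model, "follicle_model"),
            inherits(source, "source_distribution"),
            inherits(spectrum, "alpha_spectrum"))
  if (n_histories < 1) stop("n_histories must be >= 1")
  if (source$kind %in% c("surrounding_lumen_uniform",
                         "surrounding_cells_uniform") &&
      !model$with_surroundings)
    stop("source '", source$kind, "' requires surrounding follicles")
  if (source$kind == "lumen_surface" &&
      source$radius_um > model$lumen_radius_um)
    stop("surface source radius exceeds the lumen radius")
  structure(list(model = model, source = source,
                 n_histories = as.numeric(n_histories),
                 seed = as.integer(seed),
                 iodine_fraction = iodine_fraction,
                 spectrum = spectrum,
                 straggling = isTRUE(straggling),
                 chunk_size = as.integer(chunk_size)),
            class = "simulation_config")
}

# Exact boundary partition of a bundle of rays through the nested spheres.
# Returns the 2K boundary path lengths (T) and the energy at each boundary
# (E); nested intersection intervals keep the columns sorted row-wise.
# Empty forward intersections collapse to a zero-length slot at the clipped
# closest approach, which preserves ordering and continuity.
track_boundaries <- function(model, pos, dir, E0, water_sp, lumen_sp) {
  K <- length(model$radii_um)
  n <- length(E0)
  b <- rowSums(pos * dir)
  c2 <- rowSums(pos * pos)
  Tm <- matrix(0, n, 2L * K)
  for (k in seq_len(K)) {
    r <- model$radii_um[k]
    disc <- b * b - c2 + r * r
    s <- sqrt(pmax(disc, 0))
    alpha <- pmax(-b - s, 0)
    beta <- pmax(-b + s, 0)
    miss <- disc <= 0
    if (any(miss)) {
      tstar <- pmax(-b[miss], 0)
      alpha[miss] <- tstar
      beta[miss] <- tstar
    }
    Tm[, K + 1L - k] <- alpha
    Tm[, K + k] <- beta
  }
  # slot media: for K = 2 slots are (cells, lumen, cells); for K = 4,
  # (outer lumen, surr. cells, cells, lumen, cells, surr. cells, outer lumen)
  lumen_slots <- if (K == 2L) 2L else c(1L, K, 2L * K - 1L)
  Em <- matrix(0, n, 2L * K)
  Em[, 1L] <- E0
  for (j in seq_len(2L * K - 1L)) {
    sp <- if (j %in% lumen_slots) lumen_sp else water_sp
    Em[, j + 1L] <- step_energy(sp, Em[, j], Tm[, j + 1L] - Tm[, j])
  }
  list(T = Tm, E = Em, K = K)
}

# Energy at path length t (vector) along each track.  Valid for query
# points lying in water regions (all nucleus chords do); zero-length ties at
# lumen boundaries are harmless because energy is continuous there.
energy_at <- function(trk, t, water_sp) {
  nb <- ncol(trk$T)
  j <- rowSums(trk$T <= t)           # slot index: # boundaries passed
  beyond <- t > trk$T[, nb]
  j <- pmax(pmin(j, nb - 1L), 1L)
  idx <- cbind(seq_along(t), j)
  E <- step_energy(water_sp, trk$E[idx], t - trk$T[idx])
  E[beyond] <- 0
  E
}

# Bohr straggling sigma (MeV) for a water chord of length len_um traversed
# at full effective charge: Omega^2 = 0.1569 z^2 (Z/A) x (rho l) [MeV^2],
# with rho l in g/cm^2.
bohr_sigma_MeV <- function(len_um) {
  sqrt(0.1569 * 4 * 0.55509 * len_um * 1e-4)
}

# Vectorised simulation of one chunk.  Returns per-history, per-nucleus
# energy imparted (keV), the emission line, the stopped-in-lumen flag and
# the residual energy at the outermost boundary.
simulate_chunk <- function(model, source, spectrum, n, water_sp, lumen_sp,
                           straggling = FALSE) {
  line <- sample_emission_line(spectrum, n)
  E0 <- spectrum$energy_MeV[line]
  pos <- sample_position(model, source, n)
  dir <- sample_direction(n)
  trk <- track_boundaries(model, pos, dir, E0, water_sp, lumen_sp)
  K <- trk$K
  eps <- matrix(0, n, 6L)            # keV
  rho_n <- model$nucleus_radius_um
  for (k in 1:6) {
    ctr <- model$nucleus_centres[k, ]
    q <- pos - matrix(ctr, n, 3L, byrow = TRUE)
    bq <- rowSums(q * dir)
    disc <- bq * bq - (rowSums(q * q) - rho_n^2)
    hit <- which(disc > 0)
    if (!length(hit)) next
    s <- sqrt(disc[hit])
    t2 <- -bq[hit] + s
    fwd <- t2 > 0
    hit <- hit[fwd]
    if (!length(hit)) next
    t1 <- pmax(-bq[hit] - s[fwd], 0)
    t2 <- t2[fwd]
    sub <- list(T = trk$T[hit, , drop = FALSE],
                E = trk$E[hit, , drop = FALSE], K = K)
    e1 <- energy_at(sub, t1, water_sp)
    e2 <- energy_at(sub, t2, water_sp)
    de <- pmax(e1 - e2, 0)
    if (straggling) {
      live <- de > 0 & de < e1      # crossers only; stoppers deposit all
      if (any(live)) {
        sg <- bohr_sigma_MeV(t2[live] - t1[live])
        de[live] <- pmin(pmax(de[live] + stats::rnorm(sum(live), 0, sg), 0),
                         e1[live])
      }
    }
    eps[hit, k] <- de * 1e3
  }
  stopped_lumen <- trk$E[, K + 1L] <= 0 & trk$E[, K] > 0
  list(eps_keV = eps, line = line, stopped_lumen = stopped_lumen,
       E_exit_MeV = trk$E[, 2L * K])
}

#' Trace a single fixed history
#'
#' Deterministic evaluation of one alpha track: given the decay position,
#' direction and energy, returns the energy imparted to each of the six
#' central nuclei, the stopped-in-lumen flag and the residual energy at the
#' outermost boundary.  Useful for validating the segment bookkeeping
#' against manual CSDA arithmetic.
#'
#' @param model a `follicle_model`.
#' @param position numeric length-3 decay position (um).
#' @param direction numeric length-3 unit vector.
#' @param energy_MeV initial alpha energy (MeV).
#' @param iodine_fraction iodine mass fraction in the lumen region(s).
#' @return A list with `eps_keV` (length 6), `stopped_in_lumen`,
#'   `E_exit_MeV`.
#' @export
trace_history <- function(model, position, direction, energy_MeV,
                          iodine_fraction = 0) {
  stopifnot(length(position) == 3L, length(direction) == 3L)
  if (abs(sum(direction^2) - 1) > 1e-9)
    stop("direction must be a unit vector")
  water_sp <- build_water_model()
  lumen_sp <- if (iodine_fraction > 0)
    build_mixture_model(iodine_fraction) else water_sp
  pos <- matrix(position, 1L, 3L)
  dir <- matrix(direction, 1L, 3L)
  trk <- track_boundaries(model, pos, dir, energy_MeV, water_sp, lumen_sp)
  K <- trk$K
  eps <- numeric(6L)
  for (k in 1:6) {
    seg <- ray_sphere_segments(position, direction,
                               model$nucleus_centres[k, ],
                               model$nucleus_radius_um)
    if (nrow(seg) == 0L) next
    e1 <- energy_at(trk, seg[1, 1], water_sp)
    e2 <- energy_at(trk, seg[1, 2], water_sp)
    eps[k] <- max(e1 - e2, 0) * 1e3
  }
  list(eps_keV = eps,
       stopped_in_lumen = unname(trk$E[1, K + 1L] <= 0 & trk$E[1, K] > 0),
       E_exit_MeV = unname(trk$E[1, 2L * K]))
}

#' Simulate one random history
#'
#' Samples one decay (emission line, position, direction) from the
#' configuration and transports it.
#'
#' @param config a `simulation_config`.
#' @return A list with `eps_keV` (length 6), `line`, `stopped_in_lumen`,
#'   `E_exit_MeV`.
#' @export
simulate_history <- function(config) {
  water_sp <- build_water_model()
  lumen_sp <- if (config$iodine_fraction > 0)
    build_mixture_model(config$iodine_fraction) else water_sp
  ch <- simulate_chunk(config$model, config$source, config$spectrum, 1L,
                       water_sp, lumen_sp, config$straggling)
  list(eps_keV = ch$eps_keV[1L, ], line = ch$line[1L],
       stopped_in_lumen = ch$stopped_lumen[1L],
       E_exit_MeV = ch$E_exit_MeV[1L])
}

#' Run a full simulation
#'
#' Streams `n_histories` decays through the transport engine and
#' accumulates the microdosimetric estimators.  Results are bit-reproducible
#' for identical configurations (single RNG stream seeded from
#' `config$seed`).
#'
#' @param config a `simulation_config`.
#' @param keep_hits keep the per-hit energies (needed for spectra);
#'   default `TRUE`.
#' @return An object of class `follidose_run`: the `microdose_summary`, the
#'   pooled hit energies (keV) and the configuration echo.
#' @export
run_simulation <- function(config, keep_hits = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  water_sp <- build_water_model()
  lumen_sp <- if (config$iodine_fraction > 0)
    build_mixture_model(config$iodine_fraction) else water_sp
  model <- config$model
  m_kg <- nucleus_mass_kg(model$nucleus_diameter_um)
  self_source <- config$source$kind == "nuclei_uniform"
  divisor <- if (self_source) 1 else 6
  n_total <- config$n_histories
  n_done <- 0
  M_k <- numeric(6L)                 # hits per nucleus
  sum_z_k <- numeric(6L)             # per-nucleus sums of z (Gy)
  sum_h <- 0; sum_h2 <- 0            # per-history nucleus-averaged z
  sum_z1 <- 0; sum_z1_2 <- 0         # pooled single-hit moments
  n_line <- numeric(length(config$spectrum$yield))
  stopped_line <- numeric(length(config$spectrum$yield))
  hits <- if (keep_hits) vector("list", 0L) else NULL
  while (n_done < n_total) {
    n <- min(config$chunk_size, n_total - n_done)
    ch <- simulate_chunk(model, config$source, config$spectrum, n,
                         water_sp, lumen_sp, config$straggling)
    z <- ch$eps_keV * (.const$keV_to_J / m_kg)     # Gy, n x 6
    M_k <- M_k + colSums(z > 0)
    sum_z_k <- sum_z_k + colSums(z)
    h <- rowSums(z) / divisor
    sum_h <- sum_h + sum(h)
    sum_h2 <- sum_h2 + sum(h * h)
    zpos <- z[z > 0]
    sum_z1 <- sum_z1 + sum(zpos)
    sum_z1_2 <- sum_z1_2 + sum(zpos^2)
    n_line <- n_line + tabulate(ch$line, length(n_line))
    stopped_line <- stopped_line +
      tabulate(ch$line[ch$stopped_lumen], length(n_line))
    if (keep_hits) {
      pos_idx <- which(ch$eps_keV > 0, arr.ind = TRUE)
      if (nrow(pos_idx)) {
        hits[[length(hits) + 1L]] <- data.frame(
          nucleus = pos_idx[, 2L],
          line = ch$line[pos_idx[, 1L]],
          eps_keV = ch$eps_keV[pos_idx])
      }
    }
    n_done <- n_done + n
  }
  hits <- if (keep_hits) {
    if (length(hits)) do.call(rbind, hits)
    else data.frame(nucleus = integer(), line = integer(),
                    eps_keV = numeric())
  } else NULL
  summary <- new_microdose_summary(
    n_histories = n_total, M_k = M_k, sum_z_k = sum_z_k,
    sum_h = sum_h, sum_h2 = sum_h2,
    sum_z1 = sum_z1, sum_z1_2 = sum_z1_2,
    n_line = n_line, stopped_line = stopped_line,
    lumen_source = is_lumen_source(config$source),
    nucleus_diameter_um = model$nucleus_diameter_um,
    hits = hits, self_source = self_source)
  structure(list(summary = summary, hits = hits, config = config),
            class = "follidose_run")
}

#' @export
print.follidose_run <- function(x, ...) {
  cat(sprintf("<follidose_run> %s source, %g histories (seed %d)\n",
              x$config$source$kind, x$summary$n_histories, x$config$seed))
  print(x$summary)
  invisible(x)
}
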