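# Batch sweeps, table regeneration and file output helpers.

run_one <- function(model, source, n_histories, seed, iodine_fraction = 0,
                    keep_hits = TRUE) {
  cfg <- simulation_config(model, source, n_histories = n_histories,
                           seed = seed, iodine_fraction = iodine_fraction)
  run_simulation(cfg, keep_hits = keep_hits)
}

summary_row <- function(s) {
  data.frame(mean_z_Gy = s$mean_z_Gy, mean_z1_Gy = s$mean_z1_Gy,
             mean_yF_keV_um = s$mean_yF_keV_um,
             rel_error_z = s$rel_error_z, rel_error_z1 = s$rel_error_z1,
             stopped_fraction = s$stopped_fraction,
             hits_per_nucleus = s$M)
}

#' Run a parameter sweep
#'
#' Sweeps either the follicle lumen diameter (10-500 um) at fixed nucleus
#' and cell dimensions with a lumen-uniform source, or the surface-source
#' radius (0 to the lumen radius) for a fixed model.  Failing grid points
#' are marked and the sweep continues.
#'
#' @param parameter `"lumen_diameter"` or `"surface_radius"`.
#' @param grid numeric grid of parameter values (um).
#' @param species optional species preset for the fixed model fields.
#' @param lumen_diameter_um,cell_thickness_um,nucleus_diameter_um explicit
#'   fixed model fields (used where the preset does not apply).
#' @param n_histories histories per grid point (default 1e6).
#' @param seed base seed; grid point i uses `seed + i - 1`.
#' @return A data frame with one row per grid point: the parameter value,
#'   `<z>`, `<z1>`, relative errors, stopped fraction and an `ok` flag.
#' @export
run_sweep <- function(parameter = c("lumen_diameter", "surface_radius"),
                      grid,
                      species = NULL,
                      lumen_diameter_um = NULL,
                      cell_thickness_um = NULL,
                      nucleus_diameter_um = NULL,
                      n_histories = 1e6,
                      seed = 1L) {
  parameter <- match.arg(parameter)
  if (length(grid) == 0L)
    return(data.frame(parameter = character(), value_um = numeric(),
                      mean_z_Gy = numeric(), mean_z1_Gy = numeric(),
                      mean_yF_keV_um = numeric(), rel_error_z = numeric(),
                      rel_error_z1 = numeric(), stopped_fraction = numeric(),
                      hits_per_nucleus = numeric(), ok = logical()))
  if (!is.null(species)) {
    p <- species_preset(species)
    if (is.null(lumen_diameter_um)) lumen_diameter_um <- p$lumen_diameter_um
    if (is.null(cell_thickness_um)) cell_thickness_um <- p$cell_thickness_um
    if (is.null(nucleus_diameter_um))
      nucleus_diameter_um <- p$nucleus_diameter_um
  }
  rows <- lapply(seq_along(grid), function(i) {
    v <- grid[i]
    res <- tryCatch({
      if (parameter == "lumen_diameter") {
        mod <- follicle_model(lumen_diameter_um = v,
                              cell_thickness_um = cell_thickness_um,
                              nucleus_diameter_um = nucleus_diameter_um)
        src <- source_distribution("lumen_uniform")
      } else {
        mod <- follicle_model(lumen_diameter_um = lumen_diameter_um,
                              cell_thickness_um = cell_thickness_um,
                              nucleus_diameter_um = nucleus_diameter_um)
        src <- source_distribution("lumen_surface", radius_um = v)
      }
      run <- run_one(mod, src, n_histories, seed + i - 1L, keep_hits = FALSE)
      cbind(data.frame(parameter = parameter, value_um = v),
            summary_row(run$summary), ok = TRUE)
    }, error = function(e) {
      data.frame(parameter = parameter, value_um = v, mean_z_Gy = NA,
                 mean_z1_Gy = NA, mean_yF_keV_um = NA, rel_error_z = NA,
                 rel_error_z1 = NA, stopped_fraction = NA,
                 hits_per_nucleus = NA, ok = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Regenerate the reference result tables
#'
#' Runs the 3 species x source matrix: single-follicle sources
#' (lumen-uniform A, cells-uniform C, nuclei-uniform D), the
#' surrounding-follicle sources (E, F) on the multi-follicle model, and the
#' lumen-iodine variants (0, 1, 2% mass fraction) of source A.  Emits three
#' data frames mirroring the reference tables: source-compartment
#' dependence, iodine dependence, single vs surrounding follicles.
#'
#' @param n_histories histories per cell (default 1e6; use 1e7 for
#'   final-table mode).
#' @param seed base seed, one increment per cell.
#' @param species subset of species to run.
#' @return A list of data frames `table1`, `table2`, `table3`, plus the raw
#'   per-cell rows in `cells`.
#' @export
regenerate_tables <- function(n_histories = 1e6, seed = 1L,
                              species = c("mouse", "rat", "human")) {
  species <- match.arg(species, several.ok = TRUE)
  cells <- list()
  i <- 0L
  add <- function(sp, label, row) {
    cells[[length(cells) + 1L]] <<- cbind(
      data.frame(species = sp, cell = label), row)
  }
  for (sp in species) {
    single <- follicle_model(species = sp)
    multi <- follicle_model(species = sp, with_surroundings = TRUE)
    specs <- list(
      list("A_lumen", single, source_distribution("lumen_uniform"), 0),
      list("C_cells", single, source_distribution("cells_uniform"), 0),
      list("D_nuclei", single, source_distribution("nuclei_uniform"), 0),
      list("E_surround_lumen", multi,
           source_distribution("surrounding_lumen_uniform"), 0),
      list("F_surround_cells", multi,
           source_distribution("surrounding_cells_uniform"), 0),
      list("A_lumen_iodine1", single, source_distribution("lumen_uniform"),
           0.01),
      list("A_lumen_iodine2", single, source_distribution("lumen_uniform"),
           0.02))
    for (spec in specs) {
      i <- i + 1L
      row <- tryCatch(
        summary_row(run_one(spec[[2]], spec[[3]], n_histories,
                            seed + i - 1L, iodine_fraction = spec[[4]],
                            keep_hits = FALSE)$summary),
        error = function(e)
          data.frame(mean_z_Gy = NA, mean_z1_Gy = NA, mean_yF_keV_um = NA,
                     rel_error_z = NA, rel_error_z1 = NA,
                     stopped_fraction = NA, hits_per_nucleus = NA))
      add(sp, spec[[1]], row)
    }
  }
  cells <- do.call(rbind, cells)
  pick <- function(label, col)
    cells[cells$cell == label, col][match(species,
                                          cells$species[cells$cell == label])]
  table1 <- data.frame(
    species = species,
    z_nucleus_nucleus = pick("D_nuclei", "mean_z_Gy"),
    z_nucleus_cells = pick("C_cells", "mean_z_Gy"),
    z1_nucleus_cells = pick("C_cells", "mean_z1_Gy"),
    z_nucleus_lumen = pick("A_lumen", "mean_z_Gy"),
    z1_nucleus_lumen = pick("A_lumen", "mean_z1_Gy"))
  table2 <- data.frame(
    species = species,
    z_iodine0 = pick("A_lumen", "mean_z_Gy"),
    z1_iodine0 = pick("A_lumen", "mean_z1_Gy"),
    z_iodine1 = pick("A_lumen_iodine1", "mean_z_Gy"),
    z1_iodine1 = pick("A_lumen_iodine1", "mean_z1_Gy"),
    z_iodine2 = pick("A_lumen_iodine2", "mean_z_Gy"),
    z1_iodine2 = pick("A_lumen_iodine2", "mean_z1_Gy"))
  table3 <- data.frame(
    species = species,
    z_single_lumen = pick("A_lumen", "mean_z_Gy"),
    z1_single_lumen = pick("A_lumen", "mean_z1_Gy"),
    z_single_cells = pick("C_cells", "mean_z_Gy"),
    z1_single_cells = pick("C_cells", "mean_z1_Gy"),
    z_surround_lumen = pick("E_surround_lumen", "mean_z_Gy"),
    z1_surround_lumen = pick("E_surround_lumen", "mean_z1_Gy"),
    z_surround_cells = pick("F_surround_cells", "mean_z_Gy"),
    z1_surround_cells = pick("F_surround_cells", "mean_z1_Gy"))
  list(table1 = table1, table2 = table2, table3 = table3, cells = cells)
}

#' Write a run summary as JSON
#'
#' Summary values, relative errors, the configuration echo (including the
#' resolved geometry) and the seed, for provenance.
#'
#' @param run a `follidose_run`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_run_json <- function(run, path) {
  s <- run$summary
  cfg <- run$config
  out <- list(
    summary = unclass(s)[c("n_histories", "M", "mean_z_Gy", "mean_z1_Gy",
                           "mean_yF_keV_um", "max_z1_Gy", "max_y_keV_um",
                           "rel_error_z", "rel_error_z1",
                           "stopped_fraction", "stopped_per_line")],
    config = list(source = cfg$source$kind,
                  source_radius_um = cfg$source$radius_um,
                  n_histories = cfg$n_histories, seed = cfg$seed,
                  iodine_fraction = cfg$iodine_fraction,
                  straggling = cfg$straggling,
                  spectrum = unclass(cfg$spectrum)),
    geometry = unclass(cfg$model))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Write a spectrum as CSV
#'
#' Columns: bin left edge, bin right edge, probability density.
#'
#' @param spectrum a `microdose_spectrum`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "microdose_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
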