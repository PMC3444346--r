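# History transport: segment bookkeeping, determinism, conservation.

test_that("a fixed history reproduces manual CSDA segment bookkeeping", {
  # mouse model, decay at (10,0,0) moving along +x: crosses the lumen wall
  # at path 15, enters the +x nucleus (centre 28, radius 2) at 16, leaves at
  # 20, exits the cell layer at 21.
  for (E0 in c(5.867, 7.450)) {
    got <- trace_history(mouse_model, c(10, 0, 0), c(1, 0, 0), E0)
    E_entry <- residual_energy(water, E0, 16)
    eps <- energy_deposited(water, E_entry, 4) * 1e3
    expect_lt(abs(got$eps_keV[1] - eps), 1e-6)
    expect_identical(sum(got$eps_keV[-1] > 0), 0L)
    expect_equal(got$E_exit_MeV, residual_energy(water, E0, 21),
                 tolerance = 1e-9)
    expect_false(got$stopped_in_lumen)
  }
  # same decay moving along -x: 35 um of lumen, then the -x nucleus chord
  # between path lengths 36 and 40
  got <- trace_history(mouse_model, c(10, 0, 0), c(-1, 0, 0), 5.867)
  E36 <- residual_energy(water, 5.867, 36)
  expect_lt(abs(got$eps_keV[2] - energy_deposited(water, E36, 4) * 1e3), 1e-6)
  # off-axis oblique ray, oracle via ray_sphere_segments + residual chain
  o <- c(3, -4, 2); u <- c(2, 1, -1) / sqrt(6)
  got <- trace_history(human_model, o, u, 7.450)
  for (k in 1:6) {
    seg <- ray_sphere_segments(o, u, human_model$nucleus_centres[k, ],
                               human_model$nucleus_radius_um)
    ref <- if (nrow(seg)) {
      Ein <- residual_energy(water, 7.450, seg[1, 1])
      energy_deposited(water, Ein, seg[1, 2] - seg[1, 1]) * 1e3
    } else 0
    expect_lt(abs(got$eps_keV[k] - ref), 1e-6)
  }
})

test_that("tracks stopping inside the lumen are flagged and deposit nothing", {
  # human central point source: lumen radius 75 exceeds both ranges,
  # every alpha stops in the lumen
  got <- trace_history(human_model, c(0, 0, 0), c(1, 0, 0), 7.450)
  expect_true(got$stopped_in_lumen)
  expect_identical(got$eps_keV, numeric(6))
  expect_identical(got$E_exit_MeV, 0)
  cfg <- simulation_config(human_model,
                           source_distribution("lumen_surface", radius_um = 0),
                           n_histories = 200, seed = 5)
  run <- run_simulation(cfg)
  expect_identical(run$summary$stopped_fraction, 1)
  expect_identical(run$summary$M, 0)
  expect_true(is.na(run$summary$mean_z1_Gy))     # <z1> undefined at M = 0
  expect_identical(run$summary$mean_z_Gy, 0)
})

test_that("self-irradiation always hits the source nucleus", {
  cfg <- simulation_config(mouse_model, src_D, n_histories = 300, seed = 9)
  set.seed(9)
  for (i in 1:50) {
    h <- simulate_history(cfg)
    expect_gt(sum(h$eps_keV), 0)
  }
})

test_that("energy is conserved along every track", {
  set.seed(21)
  n <- 400
  for (model in list(mouse_model,
                     follicle_model(species = "rat",
                                    with_surroundings = TRUE))) {
    src <- if (model$with_surroundings)
      source_distribution("surrounding_lumen_uniform") else src_A
    pos <- sample_position(model, src, n)
    dir <- sample_direction(n)
    E0 <- c(5.867, 7.450)[1 + (runif(n) < 0.58)]
    for (i in seq_len(n)) {
      h <- trace_history(model, pos[i, ], dir[i, ], E0[i])
      dep_nuclei <- sum(h$eps_keV) / 1e3
      expect_lte(dep_nuclei, E0[i] - h$E_exit_MeV + 1e-9)
      expect_gte(h$E_exit_MeV, 0)
      # terminated inside the model: all energy stays inside
      if (h$E_exit_MeV == 0) expect_lte(dep_nuclei, E0[i] + 1e-9)
    }
  }
})

test_that("identical seeds give bit-identical runs", {
  cfg <- simulation_config(rat_model, src_A, n_histories = 20000, seed = 123)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$summary$mean_z_Gy, r2$summary$mean_z_Gy)
  expect_identical(r1$summary$hits_per_nucleus, r2$summary$hits_per_nucleus)
  expect_identical(r1$hits, r2$hits)
  r3 <- run_simulation(simulation_config(rat_model, src_A,
                                         n_histories = 20000, seed = 124))
  expect_false(identical(r1$summary$mean_z_Gy, r3$summary$mean_z_Gy))
})

test_that("accumulator identities hold exactly", {
  run <- run_simulation(simulation_config(mouse_model, src_A,
                                          n_histories = 50000, seed = 31))
  s <- run$summary
  expect_equal(s$mean_z_Gy, s$mean_z1_Gy * s$M / s$n_histories,
               tolerance = 1e-12)
  expect_equal(s$mean_yF_keV_um,
               s$mean_z1_Gy * s$nucleus_mass_kg /
                 (1.602176634e-16 * s$mean_chord_um),
               tolerance = 1e-12)
  expect_identical(sum(s$hits_per_nucleus), as.numeric(nrow(run$hits)))
})

test_that("six-fold nucleus symmetry holds within Monte Carlo error", {
  run <- run_simulation(simulation_config(mouse_model, src_A,
                                          n_histories = 2e5, seed = 77))
  chi <- stats::chisq.test(run$summary$hits_per_nucleus)
  expect_gt(chi$p.value, 1e-3)
})

test_that("stopped fraction agrees with the closed-form containment oracle", {
  run <- run_simulation(simulation_config(rat_model, src_A,
                                          n_histories = 2e5, seed = 55),
                        keep_hits = FALSE)
  spec <- at211_spectrum()
  expected <- sum(spec$yield *
                    containment_probability(csda_range(water, spec$energy_MeV),
                                            rat_model$lumen_radius_um))
  se <- sqrt(expected * (1 - expected) / 2e5)
  expect_lt(abs(run$summary$stopped_fraction - expected), 3 * se)
  expect_equal(sum(run$summary$stopped_per_line),
               run$summary$stopped_fraction, tolerance = 1e-12)
})

test_that("standard error shrinks like 1/sqrt(n)", {
  se1 <- run_simulation(simulation_config(mouse_model, src_A,
                                          n_histories = 4e4, seed = 8),
                        keep_hits = FALSE)$summary$se_z_Gy
  se2 <- run_simulation(simulation_config(mouse_model, src_A,
                                          n_histories = 1.6e5, seed = 8),
                        keep_hits = FALSE)$summary$se_z_Gy
  expect_equal(se1 / se2, 2, tolerance = 0.3)
})

test_that("zero iodine leaves the lumen medium identical to water", {
  set.seed(3)
  pos <- sample_position(rat_model, src_A, 500)
  dir <- sample_direction(500)
  E0 <- rep(7.45, 500)
  t1 <- follidose:::track_boundaries(rat_model, pos, dir, E0, water, water)
  t2 <- follidose:::track_boundaries(rat_model, pos, dir, E0, water,
                                     build_mixture_model(0))
  expect_identical(t1$E, t2$E)
  # a 2% iodine lumen shifts the energies, as a control
  t3 <- follidose:::track_boundaries(rat_model, pos, dir, E0, water,
                                     build_mixture_model(0.02))
  expect_false(identical(t1$E, t3$E))
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(simulation_config(mouse_model,
                                 source_distribution("surrounding_cells_uniform"),
                                 n_histories = 10),
               "surrounding follicles")
  expect_error(simulation_config(mouse_model,
                                 source_distribution("lumen_surface",
                                                     radius_um = 40),
                                 n_histories = 10),
               "exceeds the lumen radius")
  expect_error(simulation_config(mouse_model, src_A, n_histories = 0),
               ">= 1")
})
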