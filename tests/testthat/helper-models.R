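# Shared fixtures: models are cheap to build (~0.1 s) but used everywhere.
water <- build_water_model()

mouse_model <- follicle_model(species = "mouse")
rat_model <- follicle_model(species = "rat")
human_model <- follicle_model(species = "human")

src_A <- source_distribution("lumen_uniform")
src_C <- source_distribution("cells_uniform")
src_D <- source_distribution("nuclei_uniform")

# independent fine-step (midpoint) integration of dE/dx, used as the oracle
# for the range-inversion bookkeeping
midpoint_residual <- function(model, E0, len_um, h = 0.01) {
  E <- E0
  steps <- ceiling(len_um / h)
  h <- len_um / steps
  for (i in seq_len(steps)) {
    S1 <- stopping_power(model, E) / 1e3          # MeV/um
    Em <- E - S1 * h / 2
    if (Em <= model$cutoff_MeV) return(0)
    E <- E - stopping_power(model, Em) / 1e3 * h
    if (E <= model$cutoff_MeV) return(0)
  }
  E
}

# acceptance-style tolerance: physics band + Monte Carlo noise
expect_close_physics <- function(value, reference, se = 0, band = 0.15) {
  expect_lt(abs(value - reference), band * abs(reference) + 3 * se)
}
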