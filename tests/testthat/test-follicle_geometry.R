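# Geometry construction, source sampling and ray intersections.

test_that("species presets resolve to the documented dimensions", {
  expect_equal(sqrt(rowSums(mouse_model$nucleus_centres^2)), rep(28, 6))
  expect_equal(rat_model$radii_um, c(35, 43))
  h <- follicle_model(species = "human", with_surroundings = TRUE)
  expect_equal(max(h$radii_um), 75 + 10 + 10 + 150)   # 245 um
  expect_equal(species_preset("rat")$thyroid_mass_g, 30e-3)
})

test_that("geometry invariants are enforced", {
  expect_error(follicle_model(lumen_diameter_um = 50, cell_thickness_um = 6,
                              nucleus_diameter_um = 8),
               "exceeds the cell-layer thickness")
  expect_error(follicle_model(lumen_diameter_um = 5, cell_thickness_um = 6,
                              nucleus_diameter_um = 4), "\\[10, 500\\]")
  expect_error(follicle_model(species = "mouse", with_surroundings = TRUE,
                              surround_cell_um = -1), "positive")
  # nuclei fit wholly inside the cell layer
  rc <- sqrt(rowSums(human_model$nucleus_centres^2))
  expect_true(all(rc - human_model$nucleus_radius_um >=
                    human_model$lumen_radius_um))
  expect_true(all(rc + human_model$nucleus_radius_um <=
                    human_model$radii_um[2]))
})

test_that("model JSON echo carries the resolved geometry", {
  j <- jsonlite::fromJSON(model_to_json(mouse_model))
  expect_equal(j$radii_um, c(25, 31))
  expect_equal(j$nucleus_diameter_um, 4)
})

test_that("position sampling is uniform over the named regions", {
  set.seed(42)
  n <- 40000
  p <- sample_position(mouse_model, src_A, n)
  r <- sqrt(rowSums(p^2))
  expect_true(all(r <= 25))
  # uniform-in-ball: |p|^3 ~ U(0, a^3), mean a^3/2
  expect_lt(abs(mean(r^3) - 25^3 / 2), 4 * 25^3 / sqrt(12 * n))
  pc <- sample_position(mouse_model, src_C, n)
  rc <- sqrt(rowSums(pc^2))
  expect_true(all(rc >= 25 & rc <= 31))
  pd <- sample_position(mouse_model, src_D, n)
  dmin <- apply(pd, 1, function(x)
    min(sqrt(colSums((t(mouse_model$nucleus_centres) - x)^2))))
  expect_true(all(dmin <= 2 + 1e-9))
  # every sample lies in exactly one region of the partition
  in_lumen <- rc < 25
  expect_false(any(in_lumen))
  # surface source: exact radius; r = 0 is a point source at the origin
  ps <- sample_position(mouse_model,
                        source_distribution("lumen_surface", radius_um = 10),
                        1000)
  expect_equal(sqrt(rowSums(ps^2)), rep(10, 1000), tolerance = 1e-12)
  p0 <- sample_position(mouse_model,
                        source_distribution("lumen_surface", radius_um = 0), 5)
  expect_identical(p0, matrix(0, 5, 3))
  expect_error(sample_position(mouse_model,
                               source_distribution("lumen_surface",
                                                   radius_um = 30), 1),
               "exceeds the lumen radius")
  expect_error(sample_position(mouse_model,
                               source_distribution("surrounding_lumen_uniform"),
                               1), "surrounding follicles")
})

test_that("directions are isotropic unit vectors", {
  set.seed(7)
  n <- 50000
  u <- sample_direction(n)
  expect_lt(max(abs(sqrt(rowSums(u^2)) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(u))), 4 / sqrt(n))
  ks <- suppressWarnings(stats::ks.test(u[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 1e-3)
})

test_that("ray-sphere intersection matches the quadratic-formula oracle", {
  seg <- ray_sphere_segments(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0), 4)
  expect_equal(unname(seg), matrix(c(0, 4), 1, 2))
  seg <- ray_sphere_segments(c(-10, 0, 0), c(1, 0, 0), c(0, 0, 0), 3)
  expect_equal(unname(seg[1, 2] - seg[1, 1]), 6)     # diameter chord
  # tangent grazing is a miss
  expect_identical(nrow(ray_sphere_segments(c(-10, 3, 0), c(1, 0, 0),
                                            c(0, 0, 0), 3)), 0L)
  set.seed(11)
  for (i in 1:200) {
    o <- runif(3, -20, 20)
    u <- sample_direction(1)[1, ]
    ctr <- runif(3, -10, 10)
    rad <- runif(1, 0.5, 8)
    seg <- ray_sphere_segments(o, u, ctr, rad)
    # oracle: roots of |o + t u - ctr|^2 = rad^2 via polyroot
    q <- o - ctr
    roots <- polyroot(c(sum(q^2) - rad^2, 2 * sum(q * u), 1))
    roots <- sort(Re(roots[abs(Im(roots)) < 1e-9]))
    fwd <- length(roots) == 2 && roots[2] > 0 && diff(roots) > 1e-12
    if (!fwd) {
      expect_identical(nrow(seg), 0L)
    } else {
      expect_identical(nrow(seg), 1L)
      expect_lt(abs(seg[1, 1] - max(roots[1], 0)), 1e-9)
      expect_lt(abs(seg[1, 2] - roots[2]), 1e-9)
      # endpoints lie on the sphere (entry only if not clipped at 0)
      for (t in seg[1, seg[1, ] > 1e-12])
        expect_lt(abs(sqrt(sum((o + t * u - ctr)^2)) - rad), 1e-9)
    }
  }
  expect_error(ray_sphere_segments(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0), 1),
               "unit vector")
})

test_that("mean chord length follows Cauchy's 2d/3", {
  expect_equal(mean_chord_length(8), 16 / 3)
  expect_equal(mean_chord_length(4), 8 / 3)
  expect_error(mean_chord_length(0), "positive")
})

test_that("containment probability matches its closed form and Monte Carlo", {
  expect_identical(containment_probability(0, 25), 1)
  expect_identical(containment_probability(50, 25), 0)
  expect_identical(containment_probability(60, 25), 0)
  expect_equal(containment_probability(48, 85), 0.5877256, tolerance = 1e-5)
  # Monte Carlo ray-casting oracle
  set.seed(99)
  n <- 200000
  a <- 35; R <- 48
  p <- shell_radii_test <- (runif(n))^(1 / 3) * a * sample_direction(n)
  u <- sample_direction(n)
  b <- rowSums(p * u)
  texit <- -b + sqrt(b^2 - rowSums(p^2) + a^2)
  phat <- mean(texit > R)
  se <- sqrt(phat * (1 - phat) / n)
  expect_lt(abs(containment_probability(R, a) - phat), 3 * se)
})
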