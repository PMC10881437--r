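ident_dvf <- function(g) vector_field(array(0, c(g$size, 3)), g)

test_that("identity field with zero radius reproduces the prior dose exactly", {
  g <- grid3d(c(8, 8, 8), spacing = c(2, 2, 2))
  set.seed(31)
  prior <- scalar_volume(array(runif(512, 0, 30), c(8, 8, 8)), g,
                         "physical_gy", n_fractions = 3)
  out <- map_prior_dose(prior, ident_dvf(g), g, mapping_config(0))
  expect_equal(out$values, prior$values, tolerance = 1e-12)
  expect_identical(out$n_fractions, 3L)
  expect_identical(out$quantity, "physical_gy")
})

test_that("a spatially constant prior dose maps exactly for any field and radius", {
  g <- grid3d(c(8, 8, 8), spacing = c(2, 2, 2))
  prior <- scalar_volume(array(12, c(8, 8, 8)), g, "physical_gy", n_fractions = 5)
  set.seed(32)
  v <- array(rnorm(prod(g$size) * 3, sd = 1), c(g$size, 3))
  dvf <- vector_field(v, g)
  for (r in c(0, 3)) {
    out <- map_prior_dose(prior, dvf, g, mapping_config(r))
    inside <- out$values[3:6, 3:6, 3:6]  # interior: homologous points in-grid
    expect_equal(inside, array(12, dim(inside)), tolerance = 1e-12)
  }
})

test_that("pure translation of a linear gradient matches the analytic resample", {
  g <- grid3d(c(20, 8, 8), spacing = c(1, 2, 2))
  xs <- axis_coords(g, 1)
  vals <- array(rep(2 + 0.5 * xs, times = 64), c(20, 8, 8))
  prior <- scalar_volume(vals, g, "physical_gy", n_fractions = 3)
  v <- array(0, c(g$size, 3)); v[, , , 1] <- 5
  dvf <- vector_field(v, g)
  out <- map_prior_dose(prior, dvf, g, mapping_config(0))
  analytic <- array(rep(2 + 0.5 * (xs + 5), times = 64), c(20, 8, 8))
  sub <- xs + 5 <= max(xs)  # away from the fill boundary
  expect_equal(out$values[sub, , ], analytic[sub, , ], tolerance = 1e-10)
})

test_that("smearing is conservative and monotone in the radius", {
  g <- grid3d(c(10, 10, 10), spacing = c(1.5, 1.5, 1.5))
  set.seed(33)
  prior <- scalar_volume(array(runif(1000, 0, 40), c(10, 10, 10)), g,
                         "physical_gy", n_fractions = 3)
  v <- array(rnorm(3000, sd = 1), c(g$size, 3))
  dvf <- vector_field(v, g)
  prev <- map_prior_dose(prior, dvf, g, mapping_config(0))
  for (r in c(1, 2, 3, 4)) {
    cur <- map_prior_dose(prior, dvf, g, mapping_config(r))
    expect_true(all(cur$values >= prev$values - 1e-12))
    prev <- cur
  }
})

test_that("restricted smearing never draws dose from outside the organ", {
  g <- grid3d(c(9, 9, 9))
  vals <- array(1, c(9, 9, 9))
  vals[8, 5, 5] <- 100  # hot voxel outside the organ, 3 mm from its edge
  prior <- scalar_volume(vals, g, "physical_gy", n_fractions = 3)
  organ <- array(FALSE, c(9, 9, 9)); organ[3:5, 3:7, 3:7] <- TRUE
  organ_mask <- mask_volume(organ, g)
  dvf <- ident_dvf(g)
  restricted <- map_prior_dose(prior, dvf, g,
                               mapping_config(3, restrict_to_structure = TRUE),
                               organ_mask)
  unrestricted <- map_prior_dose(prior, dvf, g,
                                 mapping_config(3, restrict_to_structure = FALSE))
  # voxel (5,5,5): within 3 mm of the hot voxel but it lies outside the organ
  expect_equal(restricted$values[5, 5, 5], 1)
  expect_equal(unrestricted$values[5, 5, 5], 100)
  # the direct (unsmeared) sample is still always included in the maximum
  expect_true(all(restricted$values >=
                    map_prior_dose(prior, dvf, g, mapping_config(0))$values - 1e-12))
})

test_that("per-organ EQD2 mapping composes mapping and conversion", {
  g <- grid3d(c(6, 6, 6), spacing = c(2, 2, 2))
  oar <- oar_spec("spinal_cord", 2, 70)
  zero <- scalar_volume(array(0, c(6, 6, 6)), g, "physical_gy", n_fractions = 3)
  out <- mapped_eqd2_for_oar(zero, ident_dvf(g), g, mapping_config(2), oar)
  expect_identical(out$quantity, "eqd2_gy")
  expect_equal(sum(out$values), 0)
  # a 2 Gy/fraction course maps to EQD2 equal to the physical dose
  u <- scalar_volume(array(10, c(6, 6, 6)), g, "physical_gy", n_fractions = 5)
  out2 <- mapped_eqd2_for_oar(u, ident_dvf(g), g, mapping_config(0), oar)
  expect_equal(out2$values, u$values, tolerance = 1e-12)
})

test_that("the cord's mapped EQD2 maximum is non-decreasing in the smearing radius", {
  case <- tiny_case("partial")
  oar <- default_oars()$spinal_cord
  cord <- case$masks$spinal_cord$values
  maxima <- vapply(0:4, function(r) {
    m <- mapped_eqd2_for_oar(case$prior_dose, case$dvf, case$grid,
                             mapping_config(r), oar,
                             case$prior_masks$spinal_cord)
    max(m$values[cord])
  }, 0)
  expect_true(all(diff(maxima) >= -1e-12))
})
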