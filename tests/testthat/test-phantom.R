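test_that("phantom generation is deterministic and satisfies its invariants", {
  a <- generate_phantom(phantom_config("partial", "tiny"))
  b <- generate_phantom(phantom_config("partial", "tiny"))
  expect_identical(a$prior_dose$values, b$prior_dose$values)
  expect_identical(a$dvf$values, b$dvf$values)
  expect_identical(a$masks$ptv$values, b$masks$ptv$values)
  for (case in scenario_suite(resolution = "tiny")) {
    m <- case$masks
    expect_false(any(m$spinal_cord$values & m$ptv$values))   # cord cropped out
    for (nm in c("spinal_cord", "esophagus", "ctv", "ptv"))
      expect_false(any(m[[nm]]$values & !m$body$values))     # inside the body
    expect_gt(volume_cm3(m$ptv), 5)
  }
})

test_that("overlap classes shape the two target level sets as named", {
  suite <- scenario_suite(resolution = "tiny")
  expect_setequal(names(suite), c("partial", "large", "complete"))
  comp <- suite$complete
  expect_identical(comp$masks$prior_ptv$values, comp$masks$ptv$values)
  part <- suite$partial
  expect_false(any(part$masks$prior_ptv$values & part$masks$ptv$values))
  lg <- suite$large
  expect_true(all(!lg$masks$prior_ptv$values | lg$masks$ptv$values))
  expect_gt(sum(lg$masks$ptv$values), sum(lg$masks$prior_ptv$values))
  expect_error(phantom_config("complete", prior_levels = 1, reirr_levels = 2),
               "inconsistent")
})

test_that("the sampled prior dose equals the closed form with maximum at prescription", {
  case <- generate_phantom(phantom_config("partial", "small"))
  expect_equal(max(case$prior_dose$values), case$prior_plan$prescription_gy)
  pts <- voxel_centers(case$grid)
  expect_equal(as.vector(case$prior_dose$values),
               analytic_prior_dose(case$prior_dose_params, pts),
               tolerance = 1e-12)
  # prescription attained inside the prior target box
  inbox <- analytic_prior_dose(case$prior_dose_params,
                               (case$prior_dose_params$lo + case$prior_dose_params$hi) / 2)
  expect_equal(inbox, case$prior_plan$prescription_gy)
})

test_that("radius-0 mapping matches the analytic dose at the homologous points", {
  case <- generate_phantom(phantom_config("partial", "full"))
  mapped <- map_prior_dose(case$prior_dose, case$dvf, case$grid,
                           mapping_config(0))
  pts <- voxel_centers(case$grid) + matrix(case$dvf$values, ncol = 3)
  truth <- analytic_prior_dose(case$prior_dose_params, pts)
  inside <- rep(TRUE, nrow(pts))
  for (ax in 1:3) {
    cc <- axis_coords(case$grid, ax)
    inside <- inside & pts[, ax] >= min(cc) & pts[, ax] <= max(cc)
  }
  # trilinear interpolation error bound for f = Rx * exp(-d/scale): away from
  # the target box |f''| <= Rx/scale^2 per axis (h^2/8 each); cells straddling
  # the box surface see a gradient jump of at most Rx/scale (h/4 each)
  h <- case$grid$spacing[1]
  rx <- case$prior_plan$prescription_gy; sc <- case$prior_dose_params$scale
  bound <- 3 * (h / 4 * rx / sc + h^2 / 8 * rx / sc^2)
  expect_lt(max(abs(mapped$values[inside] - truth[inside])), bound)
})

test_that("the partial-overlap cord crosses several 10-GyEQD2 isodose levels", {
  case <- generate_phantom(phantom_config("partial", "small"))
  oar <- default_oars()$spinal_cord
  mapped <- mapped_eqd2_for_oar(case$prior_dose, case$dvf, case$grid,
                                mapping_config(), oar,
                                case$prior_masks$spinal_cord)
  shells <- generate_structures(mapped, case$masks$spinal_cord, "spinal_cord")
  expect_gte(length(shells), 2)
})

test_that("a phantom case survives the directory round trip", {
  case <- generate_phantom(phantom_config("partial", "tiny"))
  dir <- withr::local_tempdir()
  write_phantom_case(case, dir)
  back <- read_phantom_case(dir)
  expect_true(grids_equal(back$grid, case$grid))
  expect_identical(back$masks$ptv$values, case$masks$ptv$values)
  expect_identical(back$prior_masks$spinal_cord$values,
                   case$prior_masks$spinal_cord$values)
  expect_equal(back$prior_dose$values, case$prior_dose$values)
  expect_identical(back$prior_dose$n_fractions, case$prior_dose$n_fractions)
  expect_equal(back$dvf$values, case$dvf$values)
  expect_equal(back$prior_dose_params$lo, case$prior_dose_params$lo)
  expect_identical(back$reirr_plan$n_fractions, case$reirr_plan$n_fractions)
})
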