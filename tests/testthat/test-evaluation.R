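grid_cube <- function(n = 10, sp = 1) grid3d(c(n, n, n), rep(sp, 3))

test_that("DVH metrics agree with the sort-and-count oracle on random structures", {
  g <- grid_cube(10)
  maxerr <- 0
  for (seed in 1:50) {
    set.seed(seed)
    dose <- scalar_volume(array(runif(1000, 0, 60), c(10, 10, 10)), g,
                          "physical_gy", n_fractions = 5)
    m <- random_mask(g, runif(1, 0.2, 0.8), seed = seed + 1000)
    if (!any(m$values)) next
    doses <- dose$values[m$values]
    w <- voxel_volume_cm3(g)
    res <- dvh_metrics(dose, m, d_percent = c(2, 50, 95, 98, 99),
                       d_cm3 = c(0.0351, 0.2), v_gy = c(20, 40))
    for (p in c(2, 50, 95, 98, 99))
      maxerr <- max(maxerr, abs(res$D_pct[[paste0("D", p, "%")]] -
        oracle_dose_at_volume(doses, w, p / 100 * length(doses) * w)))
    for (v in c(0.0351, 0.2))
      if (v <= length(doses) * w)
        maxerr <- max(maxerr, abs(res$D_cm3[[paste0("D", v, "cm3")]] -
          oracle_dose_at_volume(doses, w, v)))
    for (lvl in c(20, 40))
      maxerr <- max(maxerr, abs(res$V_gy[[paste0("V", lvl, "Gy")]] -
                                  oracle_v_at_dose(doses, lvl)))
    maxerr <- max(maxerr, abs(res$Dmax - max(doses)))
  }
  expect_lt(maxerr, 1e-9)
})

test_that("DVH point metrics honour their closed-form cases", {
  g <- grid3d(c(10, 1, 1), c(1, 1, 1))
  dose <- scalar_volume(array(1:10, c(10, 1, 1)), g, "physical_gy", n_fractions = 1)
  m <- mask_volume(array(TRUE, c(10, 1, 1)), g)
  res <- dvh_metrics(dose, m, d_percent = 100, d_cm3 = 0.005)
  expect_equal(res$Dmax, 10)
  expect_equal(res$D_cm3[["D0.005cm3"]], 6)  # hottest 5 of 10 voxels
  expect_equal(res$D_pct[["D100%"]], 1)      # minimum voxel dose
  # uniform dose: all D_x equal it, V steps at the level
  u <- scalar_volume(array(7, c(10, 1, 1)), g, "physical_gy", n_fractions = 1)
  ru <- dvh_metrics(u, m, d_percent = c(1, 50, 99), v_gy = c(6.9, 7, 7.1))
  expect_true(all(abs(ru$D_pct - 7) < 1e-12))
  expect_equal(unname(ru$V_gy), c(100, 100, 0))
  expect_warning(dvh_metrics(dose, m, d_cm3 = 99), "exceeds")
})

test_that("Paddick conformity index follows its set-count definition", {
  g <- grid_cube(10)
  tvals <- array(FALSE, c(10, 10, 10)); tvals[3:7, 3:6, 3:7] <- TRUE  # 100 vox
  target <- mask_volume(tvals, g)
  # PIV == TV
  d1 <- array(0, c(10, 10, 10)); d1[tvals] <- 10
  expect_equal(paddick_ci(scalar_volume(d1, g, "physical_gy", n_fractions = 1),
                          target, 10), 1)
  # PIV of 200 voxels fully covering the 100-voxel TV -> 0.5
  d2 <- d1; d2[3:7, 3:6, 3:7] <- 10; d2[8, 1:10, 1:10] <- 10
  stopifnot(sum(d2 >= 10) == 200)
  expect_equal(paddick_ci(scalar_volume(d2, g, "physical_gy", n_fractions = 1),
                          target, 10), 0.5)
  # disjoint PIV
  d3 <- array(0, c(10, 10, 10)); d3[9, , ] <- 10
  expect_equal(paddick_ci(scalar_volume(d3, g, "physical_gy", n_fractions = 1),
                          target, 10), 0)
  # random fields against the oracle
  for (seed in 1:10) {
    set.seed(seed)
    dv <- array(runif(1000, 0, 15), c(10, 10, 10))
    vol <- scalar_volume(dv, g, "physical_gy", n_fractions = 1)
    expect_equal(paddick_ci(vol, target, 10), oracle_paddick(dv, tvals, 10))
  }
})

test_that("homogeneity index is zero for uniform dose and scale invariant", {
  g <- grid_cube(8)
  m <- random_mask(g, 0.5, seed = 61)
  u <- scalar_volume(array(11, g$size), g, "physical_gy", n_fractions = 1)
  expect_equal(homogeneity_index(u, m), 0)
  set.seed(62)
  dv <- array(runif(512, 8, 12), g$size)
  vol <- scalar_volume(dv, g, "physical_gy", n_fractions = 1)
  h1 <- homogeneity_index(vol, m)
  vol2 <- scalar_volume(2 * dv, g, "physical_gy", n_fractions = 1)
  expect_equal(homogeneity_index(vol2, m), h1, tolerance = 1e-12)
  expect_equal(h1, oracle_hi(dv[m$values], voxel_volume_cm3(g)), tolerance = 1e-12)
})

test_that("gradient index counts the two isodose volumes", {
  g <- grid_cube(10)
  # constructed field: 100 voxels at prescription, another 100 at half
  dv <- array(0, c(10, 10, 10))
  dv[1:10, 1:10, 1] <- 10; dv[1:10, 1:10, 2] <- 5
  vol <- scalar_volume(dv, g, "physical_gy", n_fractions = 1)
  expect_equal(gradient_index(vol, 10), 2)
  # step function: both isodoses coincide
  step <- array(0, c(10, 10, 10)); step[1:3, , ] <- 10
  expect_equal(gradient_index(scalar_volume(step, g, "physical_gy",
                                            n_fractions = 1), 10), 1)
  expect_error(gradient_index(scalar_volume(array(0, c(10, 10, 10)), g,
                                            "physical_gy", n_fractions = 1), 10),
               "empty")
})

test_that("high-dose spillage counts only above-105% voxels outside the PTV", {
  g <- grid_cube(10)
  ptv <- mask_volume(array(rep(c(TRUE, FALSE), c(500, 500)), c(10, 10, 10)), g)
  dv <- array(10, c(10, 10, 10))
  vol <- scalar_volume(dv, g, "physical_gy", n_fractions = 1)
  expect_equal(high_dose_spillage(vol, ptv, 10), 0)   # nothing above 10.5
  idx <- which(!ptv$values)[1:7]
  dv2 <- array(10, c(10, 10, 10)); dv2[idx] <- 11
  vol2 <- scalar_volume(dv2, g, "physical_gy", n_fractions = 1)
  expect_equal(high_dose_spillage(vol2, ptv, 10), 0.007)
  zero <- scalar_volume(array(0, c(10, 10, 10)), g, "physical_gy", n_fractions = 1)
  expect_equal(high_dose_spillage(zero, ptv, 10), 0)
})

test_that("cumulative reporting reduces to each course alone when the other is zero", {
  g <- grid_cube(8)
  oars <- list(spinal_cord = oar_spec("spinal_cord", 2, 70))
  masks <- list(spinal_cord = random_mask(g, 0.4, seed = 71))
  set.seed(72)
  prior <- list(spinal_cord = scalar_volume(array(runif(512, 0, 40), g$size), g,
                                            "eqd2_gy"))
  zero_plan <- scalar_volume(array(0, g$size), g, "physical_gy", n_fractions = 5)
  rep0 <- cumulative_oar_report(prior, zero_plan, oars, masks)
  expect_equal(rep0$cum_dmax_eqd2,
               max(prior$spinal_cord$values[masks$spinal_cord$values]))
  expect_true(rep0$pass)
  zero_prior <- list(spinal_cord = scalar_volume(array(0, g$size), g, "eqd2_gy"))
  plan <- scalar_volume(array(10, g$size), g, "physical_gy", n_fractions = 5)
  rep1 <- cumulative_oar_report(zero_prior, plan, oars, masks)
  expect_equal(rep1$cum_dmax_eqd2, eqd2_total(10, 5, 2))
})

test_that("the smearing-radius sweep is anchored at zero and monotone", {
  case <- tiny_case("partial")
  oars <- default_oars()
  masks <- case$masks[names(oars)]
  plan_dose <- scalar_volume(array(5, case$grid$size), case$grid,
                             "physical_gy", n_fractions = 5)
  tab <- robustness_sweep(case$prior_dose, case$dvf, plan_dose, oars, masks,
                          case$prior_masks, radii_mm = 0:4)
  for (oar in names(masks)) {
    sub <- tab[tab$oar == oar, ]
    expect_equal(sub$delta_dmax_eqd2[sub$radius_mm == 0], 0)
    expect_true(all(diff(sub$delta_dmax_eqd2) >= -1e-9))
  }
  # a constant prior dose cannot gain anything from smearing
  const <- scalar_volume(array(8, case$grid$size), case$grid, "physical_gy",
                         n_fractions = 3)
  tabc <- robustness_sweep(const, case$dvf, plan_dose, oars, masks,
                           case$prior_masks, radii_mm = 0:3)
  expect_true(all(abs(tabc$delta_dmax_eqd2) < 1e-9))
})
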