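make_shell <- function(g, oar_name, level, prior_max, vox = list(c(2, 2, 2))) {
  vals <- array(FALSE, g$size)
  for (v in vox) vals[v[1], v[2], v[3]] <- TRUE
  opt_structure(oar_name, level, mask_volume(vals, g), mask_volume(vals, g),
                eqd2_prior_max = prior_max)
}

test_that("the constraint table converts budgets to physical limits", {
  g <- grid3d(c(6, 6, 6))
  oars <- list(spinal_cord = oar_spec("spinal_cord", 2, 50))
  plan <- plan_info("reirr", 5, 40)
  shells <- list(spinal_cord = list(
    make_shell(g, "spinal_cord", 10, 15, list(c(2, 2, 2))),
    make_shell(g, "spinal_cord", 40, 40, list(c(3, 3, 3)))))
  tab <- dart_constraint_table(shells, oars, plan)
  df <- as.data.frame(tab)
  # budget 50 - 40 = 10 GyEQD2 over 5 fx at alpha/beta 2 -> 10 Gy
  expect_equal(df$max_dose_gy[df$name == "spinal_cord_ge40"], 10,
               tolerance = 1e-9)
  # exhausted budget -> 0 Gy and infeasible
  shells2 <- list(spinal_cord = list(make_shell(g, "spinal_cord", 50, 50)))
  df2 <- as.data.frame(dart_constraint_table(shells2, oars, plan))
  expect_equal(df2$max_dose_gy, 0)
  expect_true(df2$infeasible)
  # limits strictly decrease with the prior-dose level
  expect_true(all(diff(df$max_dose_gy[order(df$eqd2_prior_max)]) < 0))
  expect_error(dart_constraint_table(shells, list(), plan), "spinal_cord")
})

test_that("every limit keeps the cumulative EQD2 within the tolerance", {
  case <- tiny_case("partial")
  oars <- default_oars()
  mapped <- lapply(names(oars), function(nm)
    mapped_eqd2_for_oar(case$prior_dose, case$dvf, case$grid, mapping_config(),
                        oars[[nm]], case$prior_masks[[nm]]))
  names(mapped) <- names(oars)
  shells <- lapply(names(oars), function(nm)
    generate_structures(mapped[[nm]], case$masks[[nm]], nm))
  names(shells) <- names(oars)
  tab <- dart_constraint_table(shells, oars, case$reirr_plan,
                               case$masks[names(oars)], mapped,
                               c(spinal_cord = 30, esophagus = 35))
  for (e in tab$entries) {
    if (e$infeasible) next
    tol <- oars[[e$oar]]$tolerance_eqd2
    expect_lte(eqd2_total(e$max_dose_gy, case$reirr_plan$n_fractions,
                          oars[[e$oar]]$alpha_beta) + e$eqd2_prior_max,
               tol + 1e-9)
  }
  # spatially resolved: more than two limit levels for the cord
  df <- as.data.frame(tab)
  expect_gt(length(unique(df$max_dose_gy[df$oar == "spinal_cord"])), 2)
})

test_that("the baseline table applies the fixed reduction inside the treated segment", {
  g <- grid3d(c(8, 8, 20), spacing = c(2, 2, 2))
  vals <- array(0, g$size); vals[, , 4:8] <- 20  # prior field z in [6,14] mm
  prior <- scalar_volume(vals, g, "physical_gy", n_fractions = 3)
  oar_vals <- array(FALSE, g$size); oar_vals[4, 4, ] <- TRUE
  masks <- list(spinal_cord = mask_volume(oar_vals, g, label = "spinal_cord"),
                esophagus = mask_volume(oar_vals, g, label = "esophagus"))
  plan <- plan_info("reirr", 5, 40)
  pol <- baseline_policy(margin_mm = 5)
  tab <- baseline_constraint_table(prior, masks, pol, plan)
  df <- as.data.frame(tab)
  expect_equal(df$max_dose_gy[df$name == "spinal_cord_treated"], 30 - 12)
  expect_equal(df$max_dose_gy[df$name == "spinal_cord_untreated"], 30)
  expect_equal(df$max_dose_gy[df$name == "esophagus_treated"], 35 - 25)
  # binary: exactly two limit values per organ
  for (oar in names(masks))
    expect_lte(length(unique(df$max_dose_gy[df$oar == oar])), 2)
  # treated segment grows with the margin
  tab10 <- baseline_constraint_table(prior, masks, baseline_policy(margin_mm = 10), plan)
  seg5 <- tab$entries[[1]]$mask$values
  seg10 <- tab10$entries[[1]]$mask$values
  expect_true(all(seg10 | !seg5))
  expect_gt(sum(seg10), sum(seg5))
  # prior field nowhere near: the whole organ sits at the template limit
  far <- scalar_volume(array(0, g$size), g, "physical_gy", n_fractions = 3)
  dff <- as.data.frame(baseline_constraint_table(far, masks, pol, plan))
  expect_identical(dff$name, c("spinal_cord_untreated", "esophagus_untreated"))
  expect_error(baseline_constraint_table(prior, masks,
    baseline_policy(base_limits = c(spinal_cord = 30)), plan), "esophagus")
})
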