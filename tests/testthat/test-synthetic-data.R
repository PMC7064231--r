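test_that("the default design yields 45 trees, 15 per height class", {
  trees <- simulate_trees(sim_config(seed = 1))
  expect_equal(nrow(trees), 45)
  expect_equal(as.integer(table(trees$height_class)), rep(15L, 3))
  # heights respect the strata and classes are consistent
  expect_true(all(trees$height_cm >= 30))
  expect_equal(trees$height_class, assign_height_class(trees$height_cm))
  expect_equal(trees$diameter_kind, diameter_convention(trees$height_cm))
  # derived attributes are present and coherent
  expect_equal(trees$crown_volume_cm3,
               trees$crown_area_cm2 * trees$height_cm)
  expect_true(all(trees$wood_density_g_cm3 >= 0.45 &
                    trees$wood_density_g_cm3 <= 0.9))
})

test_that("generation is a pure function of the configuration seed", {
  cfg <- sim_config(seed = 17)
  s1 <- simulate_stand(cfg)
  s2 <- simulate_stand(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_stand(sim_config(seed = 18))
  expect_false(identical(s1$trees$height_cm, s3$trees$height_cm))
})

test_that("zero noise collapses the generator onto its models", {
  cfg <- sim_config(seed = 4, n_per_class = 4, mass_cv = 0, diam_cv = 0)
  trees <- simulate_trees(cfg)
  # diameters exactly alpha * h^beta
  expect_equal(trees$diameter_cm,
               cfg$diam_alpha * trees$height_cm^cfg$diam_beta,
               tolerance = 1e-12)
  roots <- simulate_root_systems(trees, cfg)
  reg <- builtin_registry()
  for (cl in c("C1", "C2", "C3")) {
    for (tp in c("PRIMARY", "SECONDARY")) {
      s <- roots$samples[roots$samples$height_class == cl &
                           roots$samples$root_type == tp, ]
      pred <- pmax(predict(get_model(reg, cl, paste0("UNEXCAVATED_", tp)),
                           data.frame(x = s$basal_diameter_cm)), 0)
      expect_equal(s$true_dry_mass_kg, pred, tolerance = 1e-12)
    }
  }
})

test_that("exactly two primary roots per tree are excavated, with consistent field masses", {
  cfg <- sim_config(seed = 9, n_per_class = 6)
  trees <- simulate_trees(cfg)
  roots <- simulate_root_systems(trees, cfg)
  prim <- roots$samples[roots$samples$root_type == "PRIMARY", ]
  n_exc <- tapply(prim$excavated, prim$tree_id, sum)
  expect_true(all(n_exc == 2))
  exc <- roots$samples[roots$samples$excavated, ]
  # the D:F chain recovers the generated dry mass exactly
  expect_equal(dry_from_fresh(exc$fresh_mass_kg, exc$subsample_fresh_g,
                              exc$subsample_dry_g),
               exc$true_dry_mass_kg, tolerance = 1e-12)
  # secondaries are excavated iff attached to an excavated primary
  expect_true(all(is.na(roots$samples$fresh_mass_kg[!roots$samples$excavated])))
})

test_that("the reconstruction pipeline closes over a noiseless synthetic stand", {
  cfg <- sim_config(seed = 12, mass_cv = 0)
  stand <- simulate_stand(cfg)
  bgb <- suppressWarnings( # C1 quadratic clamps at tiny diameters
    reconstruct_bgb(stand$trees, stand$samples,
                    stand$crowns[c("tree_id", "dry_mass_kg")]))
  expect_equal(bgb$total_kg, stand$tree_totals$total_kg, tolerance = 1e-9)
  # mass conservation at the stand level
  expect_equal(sum(bgb$total_kg),
               sum(bgb$crown_kg) + sum(bgb$primary_kg) + sum(bgb$secondary_kg),
               tolerance = 1e-12)
  # densities follow mean per-tree mass times stem density
  mean_kg <- tapply(stand$tree_totals$total_kg,
                    stand$tree_totals$height_class, mean)
  expect_equal(stand$bgb_mg_ha,
               setNames(as.numeric(mean_kg[c("C1", "C2", "C3")] *
                                     cfg$stems_per_ha / 1000),
                        c("C1", "C2", "C3")))
})

test_that("fitting generated populations recovers the published power coefficients", {
  # additive constant-variance noise matches the fitted error model; the
  # multiplicative option leaves the scale coefficient with a sampling
  # error far above 5% (see the methods vignette)
  for (tr in published_root_power_truth) {
    pop <- sample_root_population(tr$class, tr$type, n = 200,
                                  config = sim_config(seed = 1, mass_cv = 0.05,
                                                      noise = "additive"))
    m <- fit_allometric(pop, "POWER", "y", "x")
    rel <- abs(unname(m$coefficients) - tr$coef) / tr$coef
    expect_lt(max(rel), 0.05)
  }
  # noiseless generation recovers coefficients to numerical precision
  pop0 <- sample_root_population("C2", "SECONDARY", n = 200,
                                 config = sim_config(seed = 1, mass_cv = 0))
  m0 <- fit_allometric(pop0, "POWER", "y", "x")
  expect_equal(unname(m0$coefficients), c(0.0456687, 3.4475717),
               tolerance = 1e-6)
})
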