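test_that("dry mass follows the subsample D:F conversion", {
  expect_equal(dry_from_fresh(10, 100, 100), 10)
  expect_equal(dry_from_fresh(10, 100, 40), 4)
  expect_equal(dry_from_fresh(3.6, 31.0, 12.4), 1.44)
  expect_error(dry_from_fresh(1, 50, 60), "impossible")
})

test_that("unexcavated roots are predicted from the per-class models", {
  fx <- make_reconstruction_fixture()
  out <- estimate_unexcavated(fx$samples, builtin_registry(), trees = fx$trees)
  # excavated rows use the D:F chain
  expect_equal(out$dry_mass_kg[1], 2.0 * 0.4)
  expect_equal(out$dry_mass_kg[3], 0.5 * 0.4)
  expect_equal(out$dry_mass_kg[4], 1.0 * 0.45)
  # unexcavated C1 primary at 2 cm: published power model
  expect_equal(out$dry_mass_kg[2], 0.0272117 * 2^2.5584838)
  # unexcavated C2 secondary at 1 cm: scale coefficient exactly
  expect_equal(out$dry_mass_kg[5], 0.0456687)
  # C3 primary spot value
  s <- data.frame(tree_id = "t", height_class = "C3", root_type = "PRIMARY",
                  basal_diameter_cm = 2, excavated = FALSE)
  got <- estimate_unexcavated(s, builtin_registry())$dry_mass_kg
  expect_equal(got, 0.0075510 * 2^3.1628440)
  expect_equal(got, 0.06763, tolerance = 1e-4)
  # missing model key errors informatively
  empty <- structure(list(), class = "model_registry",
                     builtin_keys = character(0))
  expect_error(estimate_unexcavated(s, empty), "C3:UNEXCAVATED_PRIMARY")
})

test_that("negative quadratic predictions are clamped to zero with a warning", {
  s <- data.frame(tree_id = "t", height_class = "C1", root_type = "SECONDARY",
                  basal_diameter_cm = 0.1, excavated = FALSE)
  raw <- predict(get_model(builtin_registry(), "C1", "UNEXCAVATED_SECONDARY"),
                 data.frame(x = 0.1))
  expect_lt(raw, 0) # the quadratic dips below zero at small diameters
  expect_warning(out <- estimate_unexcavated(s, builtin_registry()),
                 "clamped")
  expect_equal(out$dry_mass_kg, 0)
})

test_that("per-type totals sum excavated and estimated masses", {
  s <- data.frame(tree_id = c("t", "t", "t", "t"),
                  root_type = c("PRIMARY", "PRIMARY", "PRIMARY", "SECONDARY"),
                  dry_mass_kg = c(1.2, 0.8, 0.3, 0.7),
                  excavated = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(total_root_mass(s, "PRIMARY")["t"]), 2.3)
  expect_equal(unname(total_root_mass(s, "SECONDARY")["t"]), 0.7)
  s$dry_mass_kg[3] <- NA
  expect_error(total_root_mass(s, "PRIMARY"), "estimate_unexcavated")
})

test_that("tree totals are exact component sums and conserve mass", {
  expect_equal(tree_bgb(0, 0, 0)$total_kg, 0)
  expect_equal(tree_bgb(1, 2, 3)$total_kg, 6)
  expect_equal(tree_bgb(0.14, 2.50, 0)$total_kg, 2.64)
  expect_error(tree_bgb(-1, 0, 0), "non-negative")
  set.seed(8)
  b <- tree_bgb(runif(20), runif(20), runif(20))
  expect_equal(sum(b$total_kg),
               sum(b$crown_kg) + sum(b$primary_kg) + sum(b$secondary_kg),
               tolerance = 1e-12)
  expect_equal(b$total_kg, b$crown_kg + b$primary_kg + b$secondary_kg,
               tolerance = 1e-9)
})

test_that("unexcavated predictions are monotone in basal diameter for power models", {
  bd <- seq(0.5, 6, by = 0.25)
  s <- data.frame(tree_id = "t", height_class = "C2", root_type = "PRIMARY",
                  basal_diameter_cm = bd, excavated = FALSE)
  out <- estimate_unexcavated(s, builtin_registry())
  expect_true(all(diff(out$dry_mass_kg) > 0))
})

test_that("reconstruction is invariant to which roots were excavated (noiseless)", {
  cfg <- sim_config(seed = 21, n_per_class = 5, mass_cv = 0)
  trees <- simulate_trees(cfg)
  roots <- simulate_root_systems(trees, cfg)
  crowns <- roots$crowns[c("tree_id", "dry_mass_kg")]
  bgb_mixed <- suppressWarnings(reconstruct_bgb(trees, roots$samples, crowns))

  # flag every root as excavated with D:F-consistent field masses
  all_exc <- roots$samples
  all_exc$excavated <- TRUE
  all_exc$fresh_mass_kg <- all_exc$true_dry_mass_kg / cfg$df_ratio
  all_exc$subsample_fresh_g <- 100
  all_exc$subsample_dry_g <- 100 * cfg$df_ratio
  bgb_all <- reconstruct_bgb(trees, all_exc, crowns)  # no predictions here
  expect_equal(bgb_mixed$total_kg, bgb_all$total_kg, tolerance = 1e-9)
})

test_that("root-sample and crown CSV readers validate their schemas", {
  fx <- make_reconstruction_fixture()
  sp <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx$samples, sp, row.names = FALSE)
  back <- read_root_samples(sp)
  expect_equal(back$basal_diameter_cm, fx$samples$basal_diameter_cm)
  cp <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx$crowns, cp, row.names = FALSE)
  expect_equal(read_root_crowns(cp)$dry_mass_kg, fx$crowns$dry_mass_kg)
  bad <- fx$samples
  bad$root_type[1] <- "TERTIARY"
  write.csv(bad, sp, row.names = FALSE)
  expect_error(read_root_samples(sp), "PRIMARY or SECONDARY")
})
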