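# Synthetic scrub-mangrove stands.
#
# The generator emulates the sampling design the analysis assumes: 15
# destructively sampled trees per height class (45 in all), heights
# spread uniformly within each stratum, a power-law diameter-height
# link, crown radii proportional to height, truncated-normal wood
# density, and root systems in which exactly two primary roots per tree
# (with their secondary roots) are excavated while the rest carry only
# basal diameters. Root and root-crown masses are drawn from the
# built-in published models times configurable noise, so that fitting
# the same model families to generated data is a parameter-recovery
# test with a known truth.

#' Configuration for the synthetic stand generator
#'
#' Defaults mirror the study design where it is stated (15 trees per
#' class, the height strata, two excavated primaries per tree) and
#' plausible scrub-mangrove values elsewhere (see the methods vignette).
#'
#' @param seed Integer seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @param n_per_class Trees per height class (default 15).
#' @param height_bounds Per-class height ranges in cm.
#' @param diam_alpha,diam_beta,diam_cv Diameter link
#'   `D = alpha * h^beta` (cm) with multiplicative lognormal noise of
#'   coefficient of variation `diam_cv`.
#' @param crown_ratio,crown_cv Greatest crown radius as a fraction of
#'   height, with lognormal noise.
#' @param r2_frac Range of the smallest/greatest crown radius ratio.
#' @param rho_mean,rho_sd,rho_bounds Truncated-normal wood density
#'   (g cm^-3).
#' @param primary_range,secondary_range Integer ranges for the number of
#'   primary roots per tree and secondary roots per primary.
#' @param primary_bd_mean,secondary_bd_mean Per-class median basal
#'   diameters (cm) of primary and secondary roots (lognormal draws).
#' @param bd_sdlog Log-scale spread of root basal diameters.
#' @param mass_cv Coefficient of variation of the root and crown mass
#'   noise (0 = noiseless).
#' @param noise `"lognormal"` multiplicative (default; keeps masses
#'   positive) or `"additive"` normal with constant variance.
#' @param df_ratio Dry-to-fresh ratio used to synthesise the fresh and
#'   subsample masses of excavated roots.
#' @param excavated_primaries Primaries excavated per tree (default 2).
#' @param stems_per_ha Per-class stem densities used by
#'   [simulate_stand()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_class = 15L,
                       height_bounds = list(C1 = c(30, 120),
                                            C2 = c(120, 250),
                                            C3 = c(250, 800)),
                       diam_alpha = 0.05, diam_beta = 0.8, diam_cv = 0.1,
                       crown_ratio = 0.35, crown_cv = 0.1,
                       r2_frac = c(0.6, 1),
                       rho_mean = 0.65, rho_sd = 0.08,
                       rho_bounds = c(0.45, 0.9),
                       primary_range = c(4L, 8L),
                       secondary_range = c(2L, 5L),
                       primary_bd_mean = c(C1 = 1.2, C2 = 2.0, C3 = 3.0),
                       secondary_bd_mean = c(C1 = 0.4, C2 = 0.6, C3 = 0.8),
                       bd_sdlog = 0.6,
                       mass_cv = 0.1,
                       noise = c("lognormal", "additive"),
                       df_ratio = 0.45,
                       excavated_primaries = 2L,
                       stems_per_ha = c(C1 = 3000, C2 = 1200, C3 = 350)) {
  noise <- match.arg(noise)
  cfg <- as.list(environment())
  stopifnot(n_per_class >= 1, diam_cv >= 0, crown_cv >= 0, mass_cv >= 0,
            df_ratio > 0, df_ratio <= 1, excavated_primaries >= 0,
            primary_range[1] >= excavated_primaries,
            all(unlist(height_bounds) > 0))
  # the class bounds must tile the strata partition
  stopifnot(height_bounds$C1[1] >= 30, height_bounds$C1[2] <= 120,
            height_bounds$C2[1] >= 120, height_bounds$C2[2] <= 250,
            height_bounds$C3[1] >= 250)
  structure(cfg, class = "sim_config")
}

# mean-one multiplicative lognormal factor with coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

apply_mass_noise <- function(pred, cv, type) {
  if (cv == 0 || !length(pred)) return(pred)
  if (type == "lognormal") {
    pred * lognormal_factor(length(pred), cv)
  } else {
    # constant-variance noise scaled to the mean mass; floored just above
    # zero so power-model fits keep strictly positive responses
    pmax(pred + stats::rnorm(length(pred), 0, cv * mean(pred)), 1e-9)
  }
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a tree population
#'
#' Heights are uniform within each class's bounds; diameters follow the
#' configured power link with lognormal noise; crown radii scale with
#' height; wood density is truncated normal; disk mass and volume are
#' consistent with the drawn density. Derived attributes are appended
#' with the package's mensuration rules.
#'
#' @param config A [sim_config()].
#' @return A derived tree `data.frame`, `n_per_class` rows per class.
#' @examples
#' trees <- simulate_trees(sim_config(seed = 42))
#' table(trees$height_class)
#' @export
simulate_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per_class <- lapply(names(config$height_bounds), function(cl) {
    b <- config$height_bounds[[cl]]
    n <- config$n_per_class
    h <- stats::runif(n, b[1], b[2])
    d <- config$diam_alpha * h^config$diam_beta *
      lognormal_factor(n, config$diam_cv)
    r1 <- config$crown_ratio * h * lognormal_factor(n, config$crown_cv)
    r2 <- r1 * stats::runif(n, config$r2_frac[1], config$r2_frac[2])
    rho <- rtruncnorm(n, config$rho_mean, config$rho_sd,
                      config$rho_bounds[1], config$rho_bounds[2])
    vol <- stats::runif(n, 50, 200)
    data.frame(
      tree_id = sprintf("%s_%03d", cl, seq_len(n)),
      height_cm = h,
      diameter_cm = d,
      diameter_kind = diameter_convention(h),
      crown_r1_cm = r1,
      crown_r2_cm = r2,
      disk_dry_mass_g = rho * vol,
      disk_volume_cm3 = vol,
      stringsAsFactors = FALSE
    )
  })
  trees <- do.call(rbind, per_class)
  validate_tree_records(trees)
  derive_tree_attributes(trees)
}

#' Simulate root systems for a tree population
#'
#' Each tree receives a configurable number of primary roots with
#' lognormal basal diameters and, per primary, a clutch of secondary
#' roots. True dry masses come from the built-in per-class
#' unexcavated-root models times the configured noise (negative
#' quadratic predictions are clamped to zero). Exactly
#' `excavated_primaries` primaries per tree - and every secondary
#' attached to them - are flagged excavated and given fresh and
#' subsample masses consistent with the configured D:F ratio, so the
#' excavation arithmetic recovers the true dry mass exactly. Root-crown
#' masses come from the per-class published crown models on the tree's
#' own structure, clamped at zero.
#'
#' @param trees A derived tree table (see [simulate_trees()]).
#' @param config A [sim_config()].
#' @return A list with `samples` (root-sample table including the
#'   generator's `true_dry_mass_kg`) and `crowns` (`tree_id`,
#'   `dry_mass_kg`, `true_dry_mass_kg`).
#' @export
simulate_root_systems <- function(trees, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  reg <- builtin_registry()
  pred_tab <- tree_predictors(trees)
  samples <- list()
  crown_mass <- numeric(nrow(trees))

  for (i in seq_len(nrow(trees))) {
    cl <- trees$height_class[i]
    id <- trees$tree_id[i]
    n_prim <- sample(seq(config$primary_range[1], config$primary_range[2]), 1)
    prim_bd <- stats::rlnorm(n_prim, log(config$primary_bd_mean[[cl]]),
                             config$bd_sdlog)
    prim_true <- apply_mass_noise(
      predict(get_model(reg, cl, "UNEXCAVATED_PRIMARY"),
              data.frame(x = prim_bd)),
      config$mass_cv, config$noise)
    prim_exc <- seq_len(n_prim) <= config$excavated_primaries

    sec_parent <- integer(0)
    sec_bd <- numeric(0)
    for (p in seq_len(n_prim)) {
      n_sec <- sample(seq(config$secondary_range[1],
                          config$secondary_range[2]), 1)
      sec_parent <- c(sec_parent, rep(p, n_sec))
      sec_bd <- c(sec_bd, stats::rlnorm(n_sec,
                                        log(config$secondary_bd_mean[[cl]]),
                                        config$bd_sdlog))
    }
    sec_true <- apply_mass_noise(
      pmax(predict(get_model(reg, cl, "UNEXCAVATED_SECONDARY"),
                   data.frame(x = sec_bd)), 0),
      config$mass_cv, config$noise)
    sec_exc <- prim_exc[sec_parent]

    tree_samples <- data.frame(
      tree_id = id,
      height_class = cl,
      root_type = c(rep("PRIMARY", n_prim), rep("SECONDARY", length(sec_bd))),
      basal_diameter_cm = c(prim_bd, sec_bd),
      excavated = c(prim_exc, sec_exc),
      true_dry_mass_kg = c(prim_true, sec_true),
      stringsAsFactors = FALSE
    )
    # excavated roots: synthesise field masses consistent with D:F
    tree_samples$fresh_mass_kg <- ifelse(
      tree_samples$excavated, tree_samples$true_dry_mass_kg / config$df_ratio,
      NA_real_)
    tree_samples$subsample_fresh_g <- ifelse(tree_samples$excavated, 100,
                                             NA_real_)
    tree_samples$subsample_dry_g <- ifelse(tree_samples$excavated,
                                           100 * config$df_ratio, NA_real_)
    samples[[i]] <- tree_samples

    cm <- predict(get_model(reg, cl, "ROOT_CROWN"),
                  pred_tab[i, , drop = FALSE])
    crown_mass[i] <- max(apply_mass_noise(max(cm, 0), config$mass_cv,
                                          config$noise), 0)
  }

  list(
    samples = do.call(rbind, samples),
    crowns = data.frame(tree_id = trees$tree_id,
                        dry_mass_kg = crown_mass,
                        true_dry_mass_kg = crown_mass,
                        stringsAsFactors = FALSE)
  )
}

#' Simulate a whole stand with per-class densities
#'
#' Generates a tree population and its root systems, sums each tree's
#' true below-ground mass, and expands the per-class mean per-tree mass
#' by the configured stem densities into Mg ha^-1.
#'
#' @param config A [sim_config()].
#' @return A list with `trees`, `samples`, `crowns`, `tree_totals`
#'   (per-tree true BGB, kg) and `bgb_mg_ha` (named per-class densities).
#' @export
simulate_stand <- function(config) {
  trees <- simulate_trees(config)
  roots <- simulate_root_systems(trees, config)
  per_tree <- tapply(roots$samples$true_dry_mass_kg,
                     roots$samples$tree_id, sum)
  totals <- per_tree[trees$tree_id] + roots$crowns$true_dry_mass_kg
  mean_kg <- tapply(totals, trees$height_class, mean)
  dens <- mean_kg[height_classes] * config$stems_per_ha[height_classes] / 1000
  list(trees = trees, samples = roots$samples, crowns = roots$crowns,
       tree_totals = data.frame(tree_id = trees$tree_id,
                                height_class = trees$height_class,
                                total_kg = unname(totals),
                                stringsAsFactors = FALSE),
       bgb_mg_ha = stats::setNames(as.numeric(dens), height_classes))
}

#' Pooled synthetic root samples for parameter-recovery checks
#'
#' Draws root systems over enough synthetic trees to pool at least `n`
#' roots of the requested type and class, returning their basal
#' diameters and generated dry masses. Used to verify that fitting the
#' published model family to generated data recovers the generating
#' coefficients.
#'
#' @param class Height class (`"C1"`, `"C2"`, `"C3"`).
#' @param root_type `"PRIMARY"` or `"SECONDARY"`.
#' @param n Number of roots to pool (default 200).
#' @param config A [sim_config()]; its `n_per_class` is raised as needed.
#' @return A `data.frame` with columns `x` (basal diameter, cm) and `y`
#'   (dry mass, kg), `n` rows.
#' @export
sample_root_population <- function(class, root_type, n = 200,
                                   config = sim_config()) {
  class <- match.arg(class, height_classes)
  root_type <- match.arg(root_type, c("PRIMARY", "SECONDARY"))
  # roots per tree is bounded below by the configured ranges
  min_per_tree <- if (root_type == "PRIMARY") config$primary_range[1] else
    config$primary_range[1] * config$secondary_range[1]
  config$n_per_class <- max(config$n_per_class,
                            ceiling(n / min_per_tree) + 2)
  trees <- simulate_trees(config)
  roots <- simulate_root_systems(trees, config)
  s <- roots$samples
  s <- s[s$height_class == class & s$root_type == root_type, ]
  if (nrow(s) < n) stop("generator produced too few roots; raise n_per_class")
  data.frame(x = s$basal_diameter_cm[seq_len(n)],
             y = s$true_dry_mass_kg[seq_len(n)])
}
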