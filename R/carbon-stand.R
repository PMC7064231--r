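# Stand-level biomass and carbon accounting.
#
# Densities (Mg ha^-1) per height class are aggregated to stand totals,
# converted to carbon with compartment-specific fractions, scaled to
# area stocks (Gg = Mg ha^-1 * ha / 1000), and compared between the
# pooled generalist model and the per-class specific models. All
# arithmetic runs at full precision; rounding (half-up, at each table's
# printed precision) happens only at the presentation layer.

height_classes <- c("C1", "C2", "C3")

#' Carbon fractions for biomass-to-carbon conversion
#'
#' Defaults are the measured fractions for this forest type: 42.6% for
#' below-ground and 41.9% for above-ground dry biomass.
#'
#' @param bgb,agb Fractions in (0, 1).
#' @return A list with `bgb` and `agb`.
#' @export
carbon_fractions <- function(bgb = 0.426, agb = 0.419) {
  for (f in c(bgb, agb)) {
    if (!is.finite(f) || f <= 0 || f >= 1) {
      stop("carbon fractions must lie strictly between 0 and 1")
    }
  }
  list(bgb = bgb, agb = agb)
}

#' Convert biomass to carbon
#'
#' @param biomass Biomass (any mass or mass-density unit), non-negative.
#' @param fraction Carbon fraction in (0, 1).
#' @return Carbon in the same units.
#' @examples
#' to_carbon(88.26, 0.419)
#' @export
to_carbon <- function(biomass, fraction) {
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1)) {
    stop("carbon fraction must lie strictly between 0 and 1")
  }
  if (any(biomass < 0)) stop("biomass must be non-negative")
  biomass * fraction
}

#' Round half up at a fixed number of decimals
#'
#' Presentation-layer rounding used for printed-table reproduction;
#' unlike [round()], halves always move away from zero.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_class_map <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != 3) stop(what, " must be named by height class")
    names(x) <- height_classes
  }
  missing <- setdiff(height_classes, names(x))
  if (length(missing)) {
    stop(what, " is missing class(es): ", paste(missing, collapse = ", "))
  }
  if (any(x < 0)) stop(what, " must be non-negative")
  x[height_classes]
}

#' Stand summary of biomass and carbon densities
#'
#' Builds the per-class and total table of below-ground, above-ground
#' and total biomass densities (Mg ha^-1), their carbon equivalents, the
#' BGB:AGB ratio and the percentage shares of each compartment. Ratios
#' and shares with a zero denominator are reported as `NA` with a
#' warning.
#'
#' @param bgb_mg_ha,agb_mg_ha Named numeric vectors (classes `C1`, `C2`,
#'   `C3`) of per-class densities in Mg ha^-1.
#' @param fractions A [carbon_fractions()] list.
#' @return A `data.frame` with rows `C1`, `C2`, `C3`, `Total` and
#'   columns `bgb_mg_ha`, `agb_mg_ha`, `total_mg_ha`, `bgb_c_mg_ha`,
#'   `agb_c_mg_ha`, `total_c_mg_ha`, `ratio_bgb_agb`, `pct_bgb`,
#'   `pct_agb`, at full precision; class `stand_summary`.
#' @examples
#' stand_summary(c(C1 = 3.26, C2 = 15.88, C3 = 64.66),
#'               c(C1 = 4.34, C2 = 17.78, C3 = 66.14))
#' @export
stand_summary <- function(bgb_mg_ha, agb_mg_ha,
                          fractions = carbon_fractions()) {
  bgb <- as_class_map(bgb_mg_ha, "bgb_mg_ha")
  agb <- as_class_map(agb_mg_ha, "agb_mg_ha")
  bgb <- c(bgb, Total = sum(bgb))
  agb <- c(agb, Total = sum(agb))
  total <- bgb + agb
  ratio <- ifelse(agb > 0, bgb / agb, NA_real_)
  pct_bgb <- ifelse(total > 0, bgb / total * 100, NA_real_)
  if (any(agb == 0) || any(total == 0)) {
    warning("zero denominators: some ratios/shares reported as NA")
  }
  out <- data.frame(
    class = names(bgb),
    bgb_mg_ha = unname(bgb),
    agb_mg_ha = unname(agb),
    total_mg_ha = unname(total),
    bgb_c_mg_ha = to_carbon(unname(bgb), fractions$bgb),
    agb_c_mg_ha = to_carbon(unname(agb), fractions$agb),
    ratio_bgb_agb = unname(ratio),
    pct_bgb = unname(pct_bgb),
    pct_agb = unname(100 - pct_bgb),
    stringsAsFactors = FALSE
  )
  out$total_c_mg_ha <- out$bgb_c_mg_ha + out$agb_c_mg_ha
  attr(out, "fractions") <- fractions
  class(out) <- c("stand_summary", "data.frame")
  out
}

#' Area-scaled biomass and carbon stocks
#'
#' Scales a [stand_summary()]'s densities to whole-stand stocks in Gg
#' (`Gg = Mg ha^-1 x ha / 1000`), optionally splitting the below-ground
#' stock into root-crown and root (primary+secondary) components when
#' their per-class densities are supplied.
#'
#' @param summary A [stand_summary()].
#' @param area_ha Stand area in hectares (default 812).
#' @param rc_mg_ha,root_mg_ha Optional named per-class root-crown and
#'   root densities (Mg ha^-1).
#' @return A `data.frame` (class `stock_ledger`) with rows `C1`, `C2`,
#'   `C3`, `Total` and Gg columns `rc_gg`, `rc_c_gg`, `root_gg`,
#'   `root_c_gg`, `bgb_gg`, `bgb_c_gg`, `agb_gg`, `agb_c_gg`.
#' @examples
#' s <- stand_summary(c(C1 = 3.26, C2 = 15.88, C3 = 64.66),
#'                    c(C1 = 4.34, C2 = 17.78, C3 = 66.14))
#' area_stocks(s, 812)
#' @export
area_stocks <- function(summary, area_ha = 812,
                        rc_mg_ha = NULL, root_mg_ha = NULL) {
  if (!is.finite(area_ha) || area_ha <= 0) stop("area_ha must be positive")
  fr <- attr(summary, "fractions")
  if (is.null(fr)) fr <- carbon_fractions()
  gg <- function(x) x * area_ha / 1000
  opt <- function(x) {
    if (is.null(x)) rep(NA_real_, 4) else {
      x <- as_class_map(x, "density map")
      unname(c(x, sum(x)))
    }
  }
  rc <- opt(rc_mg_ha)
  rt <- opt(root_mg_ha)
  out <- data.frame(
    class = summary$class,
    rc_gg = gg(rc),
    rc_c_gg = gg(rc) * fr$bgb,
    root_gg = gg(rt),
    root_c_gg = gg(rt) * fr$bgb,
    bgb_gg = gg(summary$bgb_mg_ha),
    bgb_c_gg = gg(summary$bgb_c_mg_ha),
    agb_gg = gg(summary$agb_mg_ha),
    agb_c_gg = gg(summary$agb_c_mg_ha),
    stringsAsFactors = FALSE
  )
  attr(out, "area_ha") <- area_ha
  class(out) <- c("stock_ledger", "data.frame")
  out
}

#' Percentage shares of two compartments
#'
#' Generic two-compartment split (root crown vs roots, or BGB vs AGB)
#' per class; zero totals give `NA` shares with a warning.
#'
#' @param first,second Non-negative numeric vectors (recycled names kept).
#' @param labels Length-2 character vector naming the share columns.
#' @return A `data.frame` with the two percentage columns summing to 100
#'   where defined.
#' @examples
#' compartment_shares(c(C1 = 3.26), c(C1 = 4.34), c("bgb", "agb"))
#' @export
compartment_shares <- function(first, second, labels = c("first", "second")) {
  if (any(first < 0) || any(second < 0)) stop("shares need non-negative inputs")
  total <- first + second
  if (any(total == 0)) warning("zero totals: shares reported as NA")
  p1 <- ifelse(total > 0, first / total * 100, NA_real_)
  out <- data.frame(p1, 100 - p1)
  names(out) <- paste0("pct_", labels)
  if (!is.null(names(first))) rownames(out) <- names(first)
  out
}

#' Generalist vs size-specific below-ground biomass
#'
#' Sums per-tree total-BGB predictions from the per-class specific
#' models and from the pooled generalist power model on stem diameter,
#' and reports how much the generalist model falls short:
#' `shortfall = specific - generalist`,
#' `shortfall_pct = shortfall / specific * 100`.
#'
#' @param trees Tree table carrying `height_class` and every predictor
#'   the specific models need (`D`ameter, `h`eight, crown `V`olume,
#'   `rho`; see [tree_predictors()]).
#' @param registry Optional `model_registry` (default built-ins).
#' @param weights Optional per-tree expansion weights (e.g. stems per
#'   hectare represented by each tree), so totals come out in Mg ha^-1.
#' @return A list with `specific_total`, `generalist_total`,
#'   `shortfall` and `shortfall_pct` (units follow the inputs: kg per
#'   tree set, or Mg ha^-1 when weighted densities are used).
#' @export
generalist_vs_specific <- function(trees, registry = NULL, weights = NULL) {
  reg <- builtin_or(registry)
  pred <- tree_predictors(trees)
  if (is.null(weights)) weights <- rep(1, nrow(pred))
  spec <- numeric(nrow(pred))
  for (cl in unique(pred$height_class)) {
    rows <- pred$height_class == cl
    m <- get_model(reg, cl, "TOTAL_BGB")
    spec[rows] <- predict(m, pred[rows, , drop = FALSE])
  }
  gen <- predict(get_model(reg, "GENERALIST", "TOTAL_BGB"), pred)
  specific_total <- sum(spec * weights)
  generalist_total <- sum(gen * weights)
  shortfall <- specific_total - generalist_total
  list(
    specific_total = specific_total,
    generalist_total = generalist_total,
    shortfall = shortfall,
    shortfall_pct = if (specific_total != 0) shortfall / specific_total * 100
                    else NA_real_
  )
}

#' Predictor table for the published compartment models
#'
#' Maps a derived tree table (see [derive_tree_attributes()]) onto the
#' predictor names the registry models use: `D` (stem diameter, cm), `h`
#' (height, cm), `V` (crown volume, cm^3), `rho` (wood density,
#' g cm^-3), keeping `tree_id` and `height_class`.
#'
#' @param trees A derived tree `data.frame`.
#' @return A `data.frame` with columns `tree_id`, `height_class`, `D`,
#'   `h`, `V`, `rho`.
#' @export
tree_predictors <- function(trees) {
  need <- c("tree_id", "height_class", "diameter_cm", "height_cm",
            "crown_volume_cm3", "wood_density_g_cm3")
  miss <- setdiff(need, names(trees))
  if (length(miss)) {
    stop("tree table is missing column(s): ", paste(miss, collapse = ", "),
         "; run derive_tree_attributes() first")
  }
  data.frame(tree_id = trees$tree_id, height_class = trees$height_class,
             D = trees$diameter_cm, h = trees$height_cm,
             V = trees$crown_volume_cm3, rho = trees$wood_density_g_cm3,
             stringsAsFactors = FALSE)
}
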