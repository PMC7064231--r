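#' Assign scrub-mangrove height classes
#'
#' Stratifies trees into the three height classes used throughout the
#' package: C1 for heights of 30--120 cm, C2 for >120--250 cm and C3 for
#' >250 cm (emergent individuals reach about 800 cm). The lower class is
#' closed at 120 cm and C2 is half-open, i.e. a 120 cm tree is C1 and a
#' tree infinitesimally taller is C2.
#'
#' @param height_cm Numeric vector of total tree heights in centimetres.
#'   Heights below 30 cm fall below the smallest observed stratum and are
#'   rejected.
#' @return A character vector of class labels (`"C1"`, `"C2"`, `"C3"`).
#' @examples
#' assign_height_class(c(100, 120, 121, 800))
#' @export
assign_height_class <- function(height_cm) {
  stopifnot(is.numeric(height_cm))
  if (any(!is.finite(height_cm))) {
    stop("height_cm must be finite")
  }
  if (any(height_cm < 30)) {
    stop("height below the smallest stratum (strata: 30-120, >120-250, >250 cm)")
  }
  ifelse(height_cm <= 120, "C1", ifelse(height_cm <= 250, "C2", "C3"))
}

#' Diameter measurement convention for a given tree height
#'
#' Trees of at least 3.5 m are measured at breast height (130 cm above the
#' ground, DBH); shorter trees are measured at 30 cm above the ground
#' (basal diameter). Scrub stands are dominated by the latter.
#'
#' @param height_cm Numeric vector of total tree heights in centimetres
#'   (must be positive).
#' @return Character vector, `"DBH_130"` or `"BASAL_30"`.
#' @examples
#' diameter_convention(c(60, 349.9, 350))
#' @export
diameter_convention <- function(height_cm) {
  stopifnot(is.numeric(height_cm))
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be positive and finite")
  }
  ifelse(height_cm >= 350, "DBH_130", "BASAL_30")
}

#' Crown area from the two crown radii
#'
#' Evaluates the elliptical crown-area formula
#' \eqn{[(R_1/2) \cdot (R_2/2)] \pi} with `r1` the greatest and `r2` the
#' smallest crown radius. The halving of the two radii is applied exactly
#' as the formula is defined, so the two measurements are effectively
#' treated as diameters of the fitted ellipse.
#'
#' @param r1_cm,r2_cm Crown radii in cm, with `r1_cm >= r2_cm >= 0`.
#' @return Crown area in cm^2.
#' @examples
#' crown_area(2, 2)     # pi
#' crown_area(400, 200) # 62831.85 cm^2
#' @export
crown_area <- function(r1_cm, r2_cm) {
  stopifnot(is.numeric(r1_cm), is.numeric(r2_cm))
  if (any(r1_cm < 0) || any(r2_cm < 0)) {
    stop("crown radii must be non-negative")
  }
  if (any(r1_cm < r2_cm)) {
    stop("r1_cm must be the greatest radius (r1_cm >= r2_cm)")
  }
  (r1_cm / 2) * (r2_cm / 2) * pi
}

#' Crown volume from crown area and tree height
#'
#' @param area_cm2 Crown area in cm^2 (non-negative).
#' @param height_cm Total tree height in cm (non-negative).
#' @return Crown volume in cm^3 (`area * height`).
#' @examples
#' crown_volume(crown_area(400, 200), 300)
#' @export
crown_volume <- function(area_cm2, height_cm) {
  stopifnot(is.numeric(area_cm2), is.numeric(height_cm))
  if (any(area_cm2 < 0) || any(height_cm < 0)) {
    stop("crown area and height must be non-negative")
  }
  area_cm2 * height_cm
}

#' Wood basic density from a disk sample
#'
#' Oven-dry mass divided by green volume (water-displacement method),
#' \eqn{\rho = M/V} in g cm^-3. Values outside the plausible 0.2--1.2
#' g cm^-3 range for mangrove wood trigger a warning, not an error: field
#' samples can be unusual, and hard failure is reserved for physical
#' impossibilities.
#'
#' @param dry_mass_g Dry mass of the disk sample in g (non-negative).
#' @param volume_cm3 Green volume in cm^3 (strictly positive).
#' @return Density in g cm^-3.
#' @examples
#' wood_density(85.5, 95)
#' @export
wood_density <- function(dry_mass_g, volume_cm3) {
  stopifnot(is.numeric(dry_mass_g), is.numeric(volume_cm3))
  if (any(volume_cm3 <= 0)) {
    stop("disk volume must be strictly positive")
  }
  if (any(dry_mass_g < 0)) {
    stop("dry mass must be non-negative")
  }
  rho <- dry_mass_g / volume_cm3
  if (any(rho < 0.2 | rho > 1.2)) {
    warning("wood density outside the typical 0.2-1.2 g cm^-3 range")
  }
  rho
}

#' Dry-to-fresh mass ratio
#'
#' The D:F ratio of an oven-dried subsample, used to convert whole-root
#' fresh mass to dry mass (`dry = fresh * D:F`).
#'
#' @param dry_mass Dry mass of the subsample (any mass unit).
#' @param fresh_mass Fresh mass of the same subsample, same unit,
#'   strictly positive and at least `dry_mass`.
#' @return The dimensionless ratio in (0, 1].
#' @examples
#' dry_fresh_ratio(12.4, 31.0)
#' @export
dry_fresh_ratio <- function(dry_mass, fresh_mass) {
  stopifnot(is.numeric(dry_mass), is.numeric(fresh_mass))
  if (any(fresh_mass <= 0)) {
    stop("fresh mass must be strictly positive")
  }
  if (any(dry_mass < 0)) {
    stop("dry mass must be non-negative")
  }
  if (any(dry_mass > fresh_mass)) {
    stop("dry mass exceeds fresh mass (physically impossible)")
  }
  dry_mass / fresh_mass
}

# Required columns of a tree-inventory table.
tree_inventory_columns <- c(
  "tree_id", "height_cm", "diameter_cm", "diameter_kind",
  "crown_r1_cm", "crown_r2_cm", "disk_dry_mass_g", "disk_volume_cm3"
)

#' Read and validate a tree-inventory CSV
#'
#' One row per tree with columns `tree_id`, `height_cm`, `diameter_cm`,
#' `diameter_kind`, `crown_r1_cm`, `crown_r2_cm`, `disk_dry_mass_g`,
#' `disk_volume_cm3`. Decimal commas (as printed in some source tables)
#' are normalised to points before numeric conversion. Derived attributes
#' (height class, crown geometry, wood density) are appended via
#' [derive_tree_attributes()].
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param derive If `TRUE` (default) append derived columns.
#' @return A `data.frame` of validated tree records.
#' @export
read_tree_inventory <- function(path, derive = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(tree_inventory_columns, names(df))
  if (length(missing)) {
    stop("tree inventory is missing columns: ", paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(tree_inventory_columns, c("tree_id", "diameter_kind"))
  for (cl in num_cols) df[[cl]] <- normalize_decimal(df[[cl]])
  validate_tree_records(df)
  if (derive) df <- derive_tree_attributes(df) else df
}

# Accept "0,0236337"-style decimal commas in a column read as character.
normalize_decimal <- function(x) {
  if (is.character(x)) x <- as.numeric(gsub(",", ".", x, fixed = TRUE))
  x
}

validate_tree_records <- function(df) {
  if (anyDuplicated(df$tree_id)) stop("duplicate tree_id in inventory")
  if (any(df$height_cm <= 0) || any(df$diameter_cm <= 0)) {
    stop("heights and diameters must be positive")
  }
  if (any(df$crown_r1_cm < df$crown_r2_cm) || any(df$crown_r2_cm < 0)) {
    stop("crown radii must satisfy r1 >= r2 >= 0")
  }
  ok_kind <- df$diameter_kind %in% c("DBH_130", "BASAL_30")
  if (any(!ok_kind)) stop("diameter_kind must be DBH_130 or BASAL_30")
  expected <- diameter_convention(df$height_cm)
  if (any(df$diameter_kind != expected)) {
    bad <- df$tree_id[df$diameter_kind != expected]
    stop("diameter_kind inconsistent with height for tree(s): ",
         paste(bad, collapse = ", "))
  }
  present <- !is.na(df$disk_dry_mass_g) & !is.na(df$disk_volume_cm3)
  if (any(df$disk_dry_mass_g[present] <= 0) ||
      any(df$disk_volume_cm3[present] <= 0)) {
    stop("disk measurements must be positive when present")
  }
  invisible(df)
}

#' Append derived structural attributes to a tree table
#'
#' Adds `height_class`, `crown_area_cm2`, `crown_volume_cm3` and
#' `wood_density_g_cm3` computed with the package's mensuration rules.
#'
#' @param trees A validated tree-inventory `data.frame`.
#' @return The input with four derived columns appended.
#' @export
derive_tree_attributes <- function(trees) {
  trees$height_class <- assign_height_class(trees$height_cm)
  trees$crown_area_cm2 <- crown_area(trees$crown_r1_cm, trees$crown_r2_cm)
  trees$crown_volume_cm3 <- crown_volume(trees$crown_area_cm2, trees$height_cm)
  trees$wood_density_g_cm3 <- wood_density(trees$disk_dry_mass_g,
                                           trees$disk_volume_cm3)
  trees
}
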