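# Per-tree below-ground biomass reconstruction.
#
# Field protocol emulated here: two primary roots per tree (plus their
# secondary roots) are excavated, weighed fresh, and converted to dry
# mass through an oven-dried subsample (D:F ratio); every remaining root
# has only its basal diameter measured, and its dry mass is predicted
# from the per-class unexcavated-root equations. Total BGB per tree is
# root crown + primary + secondary.

root_sample_columns <- c(
  "tree_id", "root_type", "basal_diameter_cm", "excavated",
  "fresh_mass_kg", "subsample_fresh_g", "subsample_dry_g"
)

#' Dry mass of an excavated root from its fresh mass and a subsample
#'
#' `dry = fresh * (subsample_dry / subsample_fresh)`, the D:F conversion
#' applied root by root.
#'
#' @param fresh_mass_kg Whole-root fresh mass (kg).
#' @param subsample_fresh_g,subsample_dry_g Subsample fresh and oven-dry
#'   masses (g); the dry mass may not exceed the fresh mass.
#' @return Dry mass in kg.
#' @examples
#' dry_from_fresh(3.6, 31.0, 12.4) # 1.44
#' @export
dry_from_fresh <- function(fresh_mass_kg, subsample_fresh_g, subsample_dry_g) {
  ratio <- dry_fresh_ratio(subsample_dry_g, subsample_fresh_g)
  if (any(fresh_mass_kg < 0)) stop("fresh mass must be non-negative")
  fresh_mass_kg * ratio
}

#' Predict dry mass for unexcavated roots
#'
#' Fills `dry_mass_kg` for every unexcavated sample from the registry
#' model keyed by the tree's height class and the root type, using the
#' root's basal diameter as predictor. Excavated samples get their dry
#' mass from [dry_from_fresh()]. Negative predictions (possible for the
#' C1 secondary-root quadratic at very small diameters) are clamped to
#' zero with a warning, since dry mass is non-negative.
#'
#' @param samples Root-sample `data.frame` with columns `tree_id`,
#'   `root_type` (`"PRIMARY"`/`"SECONDARY"`), `basal_diameter_cm`,
#'   `excavated` (logical) and, for excavated rows, `fresh_mass_kg`,
#'   `subsample_fresh_g`, `subsample_dry_g`. A `height_class` column is
#'   used if present, otherwise classes are joined from `trees`.
#' @param registry A `model_registry` supplying
#'   `UNEXCAVATED_PRIMARY` / `UNEXCAVATED_SECONDARY` models per class.
#' @param trees Optional tree table with `tree_id` and `height_class`.
#' @return `samples` with a filled `dry_mass_kg` column.
#' @export
estimate_unexcavated <- function(samples, registry, trees = NULL) {
  samples <- as.data.frame(samples)
  if (is.null(samples$height_class)) {
    if (is.null(trees)) {
      stop("samples lack height_class; supply a trees table to join it from")
    }
    idx <- match(samples$tree_id, trees$tree_id)
    if (anyNA(idx)) {
      stop("tree_id(s) absent from trees table: ",
           paste(unique(samples$tree_id[is.na(idx)]), collapse = ", "))
    }
    samples$height_class <- trees$height_class[idx]
  }
  if (any(samples$basal_diameter_cm <= 0)) {
    stop("root basal diameters must be positive")
  }
  if (is.null(samples$dry_mass_kg)) samples$dry_mass_kg <- NA_real_

  exc <- which(samples$excavated)
  if (length(exc)) {
    need <- c("fresh_mass_kg", "subsample_fresh_g", "subsample_dry_g")
    if (anyNA(samples[exc, need])) {
      stop("excavated samples are missing fresh/subsample masses")
    }
    samples$dry_mass_kg[exc] <- dry_from_fresh(
      samples$fresh_mass_kg[exc],
      samples$subsample_fresh_g[exc],
      samples$subsample_dry_g[exc])
  }

  unx <- which(!samples$excavated)
  if (length(unx)) {
    key <- paste(samples$height_class[unx], samples$root_type[unx])
    for (k in unique(key)) {
      parts <- strsplit(k, " ", fixed = TRUE)[[1]]
      model <- get_model(builtin_or(registry), parts[1],
                         paste0("UNEXCAVATED_", parts[2]))
      rows <- unx[key == k]
      pred <- predict(model, data.frame(x = samples$basal_diameter_cm[rows]))
      if (any(pred < 0)) {
        warning(sprintf(
          "%d negative %s %s-root prediction(s) clamped to 0 kg",
          sum(pred < 0), parts[1], tolower(parts[2])))
        pred <- pmax(pred, 0)
      }
      samples$dry_mass_kg[rows] <- pred
    }
  }
  samples
}

builtin_or <- function(registry) {
  if (is.null(registry)) builtin_registry() else registry
}

#' Total dry root mass of one type per tree
#'
#' Sums excavated and model-estimated dry masses per tree for the given
#' root type.
#'
#' @param samples Root-sample table with `dry_mass_kg` filled (see
#'   [estimate_unexcavated()]).
#' @param root_type `"PRIMARY"` or `"SECONDARY"`.
#' @return Named numeric vector of per-tree dry masses (kg), one element
#'   per tree that has samples of that type.
#' @export
total_root_mass <- function(samples, root_type) {
  root_type <- match.arg(root_type, c("PRIMARY", "SECONDARY"))
  sub <- samples[samples$root_type == root_type, , drop = FALSE]
  if (anyNA(sub$dry_mass_kg)) {
    stop("missing dry_mass_kg for some ", root_type,
         " samples; run estimate_unexcavated() first")
  }
  tapply(sub$dry_mass_kg, sub$tree_id, sum)
}

#' Assemble per-tree below-ground biomass
#'
#' @param crown_kg,primary_kg,secondary_kg Non-negative component dry
#'   masses (kg), recycled to a common length.
#' @param tree_id Optional identifiers.
#' @return A `data.frame` with `crown_kg`, `primary_kg`, `secondary_kg`
#'   and their exact sum `total_kg`.
#' @examples
#' tree_bgb(1, 2, 3)
#' @export
tree_bgb <- function(crown_kg, primary_kg, secondary_kg, tree_id = NULL) {
  if (any(c(crown_kg, primary_kg, secondary_kg) < 0)) {
    stop("component masses must be non-negative")
  }
  out <- data.frame(crown_kg = crown_kg, primary_kg = primary_kg,
                    secondary_kg = secondary_kg)
  out$total_kg <- out$crown_kg + out$primary_kg + out$secondary_kg
  if (!is.null(tree_id)) out <- cbind(tree_id = tree_id, out)
  out
}

#' Reconstruct total below-ground biomass for a set of trees
#'
#' The full pipeline: excavated dry masses via the D:F subsample ratio,
#' unexcavated roots via the per-class registry models, per-type sums,
#' plus the root-crown mass.
#'
#' @param trees Tree table with `tree_id` and `height_class`.
#' @param samples Root-sample table (see [estimate_unexcavated()]).
#' @param crowns Root-crown table with `tree_id`, `dry_mass_kg`.
#' @param registry Optional `model_registry` (default built-ins).
#' @return A per-tree `data.frame` from [tree_bgb()] (one row per tree in
#'   `trees`, zero masses where a tree has no samples of a type).
#' @export
reconstruct_bgb <- function(trees, samples, crowns, registry = NULL) {
  samples <- estimate_unexcavated(samples, builtin_or(registry), trees = trees)
  prim <- total_root_mass(samples, "PRIMARY")
  sec <- total_root_mass(samples, "SECONDARY")
  if (any(crowns$dry_mass_kg < 0)) stop("root-crown masses must be non-negative")
  cr <- stats::setNames(crowns$dry_mass_kg, crowns$tree_id)
  ids <- trees$tree_id
  pick <- function(v) ifelse(is.na(v[as.character(ids)]), 0,
                             v[as.character(ids)])
  tree_bgb(pick(cr), pick(prim), pick(sec), tree_id = ids)
}

#' Read a root-sample CSV
#'
#' Columns: `tree_id`, `root_type`, `basal_diameter_cm`, optional
#' `length_cm`, `excavated`, and for excavated rows `fresh_mass_kg`,
#' `subsample_fresh_g`, `subsample_dry_g`. Decimal commas are accepted.
#'
#' @param path CSV path.
#' @return A validated `data.frame`.
#' @export
read_root_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(root_sample_columns, names(df))
  if (length(missing)) {
    stop("root-sample table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  for (cl in c("basal_diameter_cm", "fresh_mass_kg",
               "subsample_fresh_g", "subsample_dry_g")) {
    df[[cl]] <- normalize_decimal(df[[cl]])
  }
  df$excavated <- as.logical(df$excavated)
  if (!all(df$root_type %in% c("PRIMARY", "SECONDARY"))) {
    stop("root_type must be PRIMARY or SECONDARY")
  }
  if (any(df$basal_diameter_cm <= 0)) stop("basal diameters must be positive")
  df
}

#' Read a root-crown CSV (`tree_id`, `dry_mass_kg`)
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_root_crowns <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("tree_id", "dry_mass_kg") %in% names(df))) {
    stop("root-crown table needs tree_id and dry_mass_kg columns")
  }
  df$dry_mass_kg <- normalize_decimal(df$dry_mass_kg)
  if (any(df$dry_mass_kg < 0)) stop("root-crown masses must be non-negative")
  df
}
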