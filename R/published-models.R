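# Registry of published scrub-mangrove allometric coefficient sets.
#
# Built-in entries cover: the six per-class unexcavated-root equations
# (root dry mass ~ root basal diameter), the nine per-class below-ground
# compartment equations (root, root crown, total BGB ~ tree structure)
# and the pooled generalist total-BGB equation. Above-ground (AGB)
# equations are published only as supplementary material and are NOT
# reprinted here: the registry ships an empty AGB slot plus a JSON schema
# so users can supply those coefficients (including the log-space
# correction factor CF) themselves; inventing them would be worse than
# omitting them.
#
# Coefficients are stored both as numerics and as the exact printed
# decimal strings, so that a registry survives a JSON round-trip
# bit-exactly.

registry_compartments <- c("UNEXCAVATED_PRIMARY", "UNEXCAVATED_SECONDARY",
                           "ROOT", "ROOT_CROWN", "TOTAL_BGB", "AGB")

builtin_entry <- function(scope, compartment, form, coef_chr, predictors,
                          provenance) {
  m <- allometric_model(form, as.numeric(coef_chr), predictors,
                        scope = scope, compartment = compartment,
                        provenance = provenance)
  m$coef_chr <- coef_chr
  m
}

#' Built-in registry of published allometric models
#'
#' @return A `model_registry`: a named list of [allometric_model()]
#'   entries keyed `"<scope>:<compartment>"`, with 16 built-in entries
#'   (6 unexcavated-root, 9 below-ground compartment, 1 generalist).
#' @examples
#' reg <- builtin_registry()
#' get_model(reg, "C3", "TOTAL_BGB")
#' @export
builtin_registry <- function() {
  src_unexc <- "published unexcavated-root equations (per height class)"
  src_bgb <- "published below-ground compartment equations (per height class)"
  src_gen <- "published pooled generalist total-BGB equation"
  entries <- list(
    # unexcavated roots: response kg, predictor x = root basal diameter (cm)
    builtin_entry("C1", "UNEXCAVATED_SECONDARY", "QUADRATIC",
                  c("0.0236337", "-0.0052021", "0.0001993"), "x", src_unexc),
    builtin_entry("C1", "UNEXCAVATED_PRIMARY", "POWER",
                  c("0.0272117", "2.5584838"), "x", src_unexc),
    builtin_entry("C2", "UNEXCAVATED_SECONDARY", "POWER",
                  c("0.0456687", "3.4475717"), "x", src_unexc),
    builtin_entry("C2", "UNEXCAVATED_PRIMARY", "POWER",
                  c("0.0873721", "1.6762250"), "x", src_unexc),
    builtin_entry("C3", "UNEXCAVATED_SECONDARY", "POWER",
                  c("0.0413852", "3.7995342"), "x", src_unexc),
    builtin_entry("C3", "UNEXCAVATED_PRIMARY", "POWER",
                  c("0.0075510", "3.1628440"), "x", src_unexc),
    # below-ground compartments: D cm, h cm, V cm^3, rho g cm^-3 -> kg
    builtin_entry("C1", "ROOT", "LINEAR_MULTI",
                  c("0.114", "0.005", "-0.682"), c("h", "rho"), src_bgb),
    builtin_entry("C1", "ROOT_CROWN", "LINEAR_MULTI",
                  c("-0.021", "0.000", "0.021", "6.53E-08"),
                  c("h", "D", "V"), src_bgb),
    # printed "y = a*b*h+cD+dp" read as the linear a + b*h + c*D + d*rho,
    # matching its sibling linear models (see the methods vignette)
    builtin_entry("C1", "TOTAL_BGB", "LINEAR_MULTI",
                  c("0.038", "0.002", "0.082", "-0.3781"),
                  c("h", "D", "rho"), src_bgb),
    builtin_entry("C2", "ROOT", "POWER",
                  c("0.465", "1.024"), "D", src_bgb),
    builtin_entry("C2", "ROOT_CROWN", "LINEAR_MULTI",
                  c("0.814", "-0.003", "0.017", "7.27E-08", "-0.660"),
                  c("h", "D", "V", "rho"), src_bgb),
    builtin_entry("C2", "TOTAL_BGB", "POWER",
                  c("0.468", "1.036"), "D", src_bgb),
    builtin_entry("C3", "ROOT", "POWER_MULTI",
                  c("0.003", "-2.180", "2.572", "-0.024", "5.275"),
                  c("D", "h", "V", "rho"), src_bgb),
    builtin_entry("C3", "ROOT_CROWN", "POWER_MULTI",
                  c("8.63E-10", "1.138", "2.730", "0.117"),
                  c("D", "h", "V"), src_bgb),
    builtin_entry("C3", "TOTAL_BGB", "POWER_MULTI",
                  c("0.002", "-1.381", "2.205", "0.005", "4.263"),
                  c("D", "h", "V", "rho"), src_bgb),
    builtin_entry("GENERALIST", "TOTAL_BGB", "POWER",
                  c("0.07577", "1.98745"), "D", src_gen)
  )
  names(entries) <- vapply(entries, function(m) {
    registry_key(m$scope, m$compartment)
  }, character(1))
  structure(entries, class = "model_registry",
            builtin_keys = names(entries))
}

registry_key <- function(scope, compartment) paste0(scope, ":", compartment)

#' @export
print.model_registry <- function(x, ...) {
  cat("Model registry with", length(x), "entries:\n")
  for (k in names(x)) cat("  ", k, " [", x[[k]]$form, "]\n", sep = "")
  invisible(x)
}

#' Look up a registry model
#'
#' @param registry A `model_registry` (see [builtin_registry()]).
#' @param scope `"C1"`, `"C2"`, `"C3"` or `"GENERALIST"`.
#' @param compartment One of `UNEXCAVATED_PRIMARY`,
#'   `UNEXCAVATED_SECONDARY`, `ROOT`, `ROOT_CROWN`, `TOTAL_BGB`, `AGB`.
#' @return The matching [allometric_model()]; a missing key is an error
#'   that lists the available keys.
#' @export
get_model <- function(registry, scope, compartment) {
  key <- registry_key(scope, compartment)
  if (is.null(registry[[key]])) {
    stop("no model for key ", key, "; available: ",
         paste(names(registry), collapse = ", "))
  }
  registry[[key]]
}

#' Load a JSON model registry
#'
#' Merges user entries (typically above-ground equations, with their
#' correction factors) onto the built-in registry. Built-in entries are
#' immutable: a document attempting to override one is rejected. Each
#' JSON entry is an object
#' `{scope, compartment, form, predictors, coefficients, cf?, units?,
#' calibration_range?, provenance?}` with coefficients given as decimal
#' strings (preserved exactly) or numbers.
#'
#' @param path Path to a JSON document: either an array of entries or an
#'   object with an `entries` array. An empty document yields the
#'   built-ins only.
#' @param base Registry to merge onto (default [builtin_registry()]).
#' @return A merged `model_registry`.
#' @export
load_registry <- function(path, base = builtin_registry()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$entries)) doc <- doc$entries
  if (length(doc) == 0) return(base)
  builtin <- attr(base, "builtin_keys")
  for (i in seq_along(doc)) {
    e <- doc[[i]]
    where <- sprintf("/entries/%d", i - 1)
    for (fld in c("scope", "compartment", "form", "predictors", "coefficients")) {
      if (is.null(e[[fld]])) {
        stop(sprintf("registry entry at %s is missing field '%s'", where, fld))
      }
    }
    if (!e$compartment %in% registry_compartments) {
      stop(sprintf("unknown compartment '%s' at %s/compartment",
                   e$compartment, where))
    }
    key <- registry_key(e$scope, e$compartment)
    if (key %in% builtin) {
      stop("attempt to override built-in registry entry ", key)
    }
    coef_chr <- as.character(unlist(e$coefficients))
    m <- tryCatch(
      allometric_model(e$form, as.numeric(coef_chr),
                       as.character(unlist(e$predictors)),
                       scope = e$scope, compartment = e$compartment,
                       cf = if (!is.null(e$cf)) as.numeric(e$cf),
                       calibration_range =
                         if (!is.null(e$calibration_range))
                           as.numeric(unlist(e$calibration_range)),
                       provenance = e$provenance),
      error = function(err) {
        stop(sprintf("invalid registry entry at %s (%s): %s",
                     where, key, conditionMessage(err)), call. = FALSE)
      })
    m$coef_chr <- coef_chr
    base[[key]] <- m
  }
  base
}

#' Serialise a model registry to JSON
#'
#' Coefficients are written as their stored decimal strings when present
#' (bit-exact round-trip for the built-ins) and as 17-significant-digit
#' strings otherwise.
#'
#' @param registry A `model_registry`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  entries <- lapply(unname(registry), function(m) {
    coef_chr <- m$coef_chr
    if (is.null(coef_chr)) {
      coef_chr <- format(unname(m$coefficients), digits = 17, trim = TRUE)
    }
    e <- list(scope = m$scope, compartment = m$compartment, form = m$form,
              predictors = as.list(m$predictors),
              coefficients = as.list(coef_chr))
    if (!is.null(m$cf)) e$cf <- m$cf
    if (!is.null(m$calibration_range)) {
      e$calibration_range <- as.list(m$calibration_range)
    }
    if (!is.null(m$provenance)) e$provenance <- m$provenance
    e
  })
  jsonlite::write_json(list(entries = entries), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a model registry
#'
#' Checks coefficient arity against each entry's form, positivity of
#' power scales, and that every built-in entry still matches the
#' published digits exactly (guarding against accidental mutation).
#'
#' @param registry A `model_registry`.
#' @return A list with `ok` (logical) and `problems` (character vector);
#'   invisibly `ok = TRUE` means a clean registry.
#' @export
validate_registry <- function(registry) {
  problems <- character(0)
  ref <- builtin_registry()
  for (k in names(registry)) {
    m <- registry[[k]]
    arity <- model_arity(m$form, length(m$predictors))
    if (length(m$coefficients) != arity) {
      problems <- c(problems, sprintf("%s: coefficient arity %d != %d",
                                      k, length(m$coefficients), arity))
    }
    if (m$form %in% c("POWER", "POWER_MULTI") && m$coefficients[[1]] <= 0) {
      problems <- c(problems, sprintf("%s: power scale must be positive", k))
    }
  }
  for (k in attr(registry, "builtin_keys")) {
    if (is.null(registry[[k]]) ||
        !identical(registry[[k]]$coef_chr, ref[[k]]$coef_chr)) {
      problems <- c(problems, sprintf("%s: built-in digits altered or missing", k))
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}
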