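# Shared fixtures and independent oracles for the test suite.

# Published unexcavated-root power coefficients (scale, exponent) used as
# generating truth in recovery tests; the C1 secondary quadratic is kept
# separate.
published_root_power_truth <- list(
  list(class = "C1", type = "PRIMARY",   coef = c(0.0272117, 2.5584838)),
  list(class = "C2", type = "PRIMARY",   coef = c(0.0873721, 1.6762250)),
  list(class = "C2", type = "SECONDARY", coef = c(0.0456687, 3.4475717)),
  list(class = "C3", type = "PRIMARY",   coef = c(0.0075510, 3.1628440)),
  list(class = "C3", type = "SECONDARY", coef = c(0.0413852, 3.7995342))
)
published_root_quadratic_truth <- c(0.0236337, -0.0052021, 0.0001993)

# Exhaustive lattice-search oracle for two-parameter power fits:
# evaluates the SSE on a full (a, b) grid and returns the minimum.
grid_search_power_sse <- function(x, y, a_range, b_range, step = 1e-3) {
  a_grid <- seq(a_range[1], a_range[2], by = step)
  b_grid <- seq(b_range[1], b_range[2], by = step)
  best <- Inf
  for (b in b_grid) {
    xb <- x^b
    # still exhaustive in a: vectorised SSE over the a lattice
    sse <- colSums((outer(xb, a_grid) - y)^2)
    best <- min(best, min(sse))
  }
  best
}

# Small hand-built reconstruction fixture: two trees, one C1 and one C2,
# with a mix of excavated and unexcavated roots.
make_reconstruction_fixture <- function() {
  trees <- data.frame(
    tree_id = c("t1", "t2"),
    height_class = c("C1", "C2"),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    tree_id = c("t1", "t1", "t1", "t2", "t2"),
    root_type = c("PRIMARY", "PRIMARY", "SECONDARY", "PRIMARY", "SECONDARY"),
    basal_diameter_cm = c(1.5, 2.0, 0.8, 1.0, 1.0),
    excavated = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    fresh_mass_kg = c(2.0, NA, 0.5, 1.0, NA),
    subsample_fresh_g = c(100, NA, 50, 100, NA),
    subsample_dry_g = c(40, NA, 20, 45, NA),
    stringsAsFactors = FALSE
  )
  crowns <- data.frame(tree_id = c("t1", "t2"), dry_mass_kg = c(0.3, 0.6),
                       stringsAsFactors = FALSE)
  list(trees = trees, samples = samples, crowns = crowns)
}
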