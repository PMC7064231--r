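# scrubBGB

Below-ground biomass (BGB) allometry and blue-carbon accounting for
scrub mangrove forests.

Scrub mangroves — stunted, high-salinity stands dominated by
*Avicennia germinans* — hold roughly half of their biomass below
ground, yet almost all existing allometry for this forest type predicts
above-ground biomass only. scrubBGB is aimed at mangrove and
blue-carbon ecologists who need to (i) reconstruct per-tree BGB from
partially excavated root systems, (ii) fit and select allometric models
with the standard criteria, and (iii) scale per-class densities to
stand-level biomass and carbon stocks.

## What it implements

**Root reconstruction.** The field protocol excavates the root crown
plus two primary roots per tree (with their secondary roots); excavated
roots are converted fresh → dry via oven-dried subsamples
(`dry = fresh × D:F`), every unexcavated root is predicted from its
basal diameter with a per-height-class model, and per-tree BGB is
`crown + primary + secondary`.

**Allometric fitting and selection.** Four model families — power
`y = a·x^b`, quadratic `y = a·x² + b·x + c`, multiple linear, and
multiplicative power `y = a·D^b·h^c·V^d·ρ^e` — fitted by arithmetic-space
least squares (Levenberg–Marquardt for the nonlinear forms) and ranked
by

- adjusted R²: `1 − (1 − R²)(n − 1)/(n − k − 1)`
- RMSE: `sqrt(Σe²/n)`
- MPE: `((Σe)/n)/M_obs × 100` (negative = underestimation)
- AIC: `n·ln(Σe²/n) + 2(k + 1) + c`

**Published coefficient registry.** The per-height-class equation sets
for unexcavated roots, root / root-crown / total BGB, and the pooled
generalist model `y = 0.07577·D^1.98745`, stored digit-exactly, plus a
JSON schema for user-supplied above-ground equations.

**Stand accounting.** Per-class densities (Mg ha⁻¹) → totals, carbon
(fractions 0.426 BGB / 0.419 AGB), BGB:AGB ratios and shares, and
area-scaled stocks in Gg over the 812-ha stand.

**Synthetic stands.** A seeded generator (heights uniform within the
30–120 / >120–250 / >250 cm classes, 15 trees per class, exactly two
excavated primaries per tree, root masses from the registry models ×
configurable noise) used to validate the fitting machinery by parameter
recovery. See `vignettes/scrub-mangrove-bgb-methods.Rmd` for the model
conventions and design choices.

## Worked example

Feed the published per-class density means through the stand chain:

```r
library(scrubBGB)

s <- stand_summary(c(C1 = 3.26, C2 = 15.88, C3 = 64.66),   # BGB, Mg/ha
                   c(C1 = 4.34, C2 = 17.78, C3 = 66.14))   # AGB, Mg/ha
round_half_up(s[c("total_mg_ha", "ratio_bgb_agb", "pct_bgb")], 2)
#>   total_mg_ha ratio_bgb_agb pct_bgb
#> 1        7.60          0.75   42.89
#> 2       33.66          0.89   47.18
#> 3      130.80          0.98   49.43
#> 4      172.06          0.95   48.70

st <- area_stocks(s, 812)   # Gg = Mg/ha × ha / 1000
round_half_up(st[c("bgb_gg", "bgb_c_gg", "agb_gg", "agb_c_gg")], 2)
#>   bgb_gg bgb_c_gg agb_gg agb_c_gg
#> 1   2.65     1.13   3.52     1.48
#> 2  12.89     5.49  14.44     6.05
#> 3  52.50    22.37  53.71    22.50
#> 4  68.05    28.99  71.67    30.03
```

Rows are C1, C2, C3, Total: the stand carries 172.06 Mg ha⁻¹ of
biomass, 48.7% of it below ground, amounting to a 68.05 Gg BGB stock
(28.99 Gg C) and 71.67 Gg AGB stock (30.03 Gg C) over 812 ha.

Validate the fitter by recovering a known generating model from a
synthetic root population (additive noise, CV 5%):

```r
pop <- sample_root_population("C2", "SECONDARY", n = 200,
                              config = sim_config(seed = 1, mass_cv = 0.05,
                                                  noise = "additive"))
fit_allometric(pop, "POWER", "y", "x")
#> Allometric model [POWER]
#>   y = 0.0451382 * x^3.46555
#>   n=200 k=1 R2adj=0.9997 RMSE=0.002802 MPE=-0.607% AIC=-2347
```

The generating coefficients were (0.0456687, 3.4475717); both are
recovered within 2%.

A command-line wrapper with the same functionality ships in
`inst/scripts/scrubBGB` (subcommands `simulate`, `fit`, `reconstruct`,
`stand`, `compare`, `reproduce-tables`).

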