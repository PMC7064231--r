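---
title: "Estimating below-ground biomass and carbon in scrub mangrove stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating below-ground biomass and carbon in scrub mangrove stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrubBGB)
```

## The problem

Scrub mangroves are stunted stands — here dominated by *Avicennia
germinans* — formed where high topography and hypersaline porewater
suppress growth. Roughly half of their biomass sits below ground, yet
almost all published allometry for this forest type predicts
above-ground biomass (AGB) only. Estimating the below-ground biomass
(BGB) destructively is hard because a root system can never be dug out
completely: the practical protocol excavates the root crown plus two
primary roots per tree (with their secondary roots), weighs them fresh,
converts to dry mass through oven-dried subsamples, and *predicts* the
dry mass of every unexcavated root from its basal diameter. Per-tree
totals then calibrate height-class-specific models that predict whole
BGB from structural measurements, and those models scale the stand
inventory to densities (Mg ha⁻¹), carbon, and area-wide stocks (Gg).

scrubBGB implements that entire chain as tested, reusable functions,
ships the published per-height-class coefficient sets, and includes a
synthetic stand generator so the fitting machinery can be validated by
parameter recovery even though the original 45-tree field data were
never deposited.

## Mensuration conventions

Trees are stratified by total height into three classes: C1 spans
30–120 cm, C2 is the half-open interval (120, 250] cm, and C3 is
everything taller (emergent individuals reach about 800 cm). The lower
boundary of each interval is exclusive and the upper inclusive, so a
120 cm tree is C1; heights below 30 cm fall outside the sampled
population and are rejected rather than extrapolated.

Stem diameter follows the usual split convention: diameter at breast
height (130 cm) for trees of at least 3.5 m, basal diameter at 30 cm
for shorter trees. Crown area is the ellipse formula
$[(R_1/2)(R_2/2)]\pi$ evaluated exactly as defined, with $R_1 \ge R_2$
the two crown radii; halving radii (rather than diameters) is
unconventional, but the formula is reproduced as defined because
downstream published coefficients were calibrated against it —
re-deriving a "corrected" crown area would silently change every
prediction. Crown volume is area × height. Wood basic density is
oven-dry mass over green volume; values outside 0.2–1.2 g cm⁻³ warn
rather than fail, since field samples can be genuinely unusual while
negative or zero volumes cannot.

All internal heights are centimetres. The source material is
inconsistent here (a measurement list in metres, model footnotes in
centimetres); centimetres were adopted because the published
coefficient sets only reproduce plausible masses with heights in
centimetres, and the error from the wrong choice would be a factor of
$100^{2.2}$ in the multi-power models.

## Model forms and fitting

Four candidate forms cover every published equation:

* power, $y = a x^b$;
* second-order polynomial, $y = a x^2 + b x + c$;
* multiple linear, $y = a + \sum_i c_i x_i$;
* multiplicative power, $y = a \prod_i x_i^{e_i}$,

with response dry mass (kg) and predictors drawn from root basal
diameter $x$ (cm), stem diameter $D$ (cm), height $h$ (cm), crown
volume $V$ (cm³), and wood density $\rho$ (g cm⁻³). Fits minimise the
sum of squared residuals in arithmetic (untransformed) space — the
additive-error convention — so no log-transform bias correction is
needed. Published AGB equations fitted in log space carry a correction
factor CF in the registry, applied multiplicatively at prediction time
for those entries only.

The linear-in-coefficients forms are solved exactly by ordinary least
squares. The power forms use Levenberg–Marquardt nonlinear least
squares, seeded from a log–log OLS pre-fit; if the solver fails, the
start vector is rescaled through a fixed ladder of ±10–30% jitters
before non-convergence is declared. Convergence is a relative SSE
change below 1e-10 or 500 iterations. A deliberate test pins the
solver against an exhaustive lattice search on two-parameter problems:
the fitted SSE must never exceed the grid optimum.

### Selection criteria

Candidates are compared with four statistics:

$$R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-k-1}, \qquad
RMSE = \sqrt{\tfrac{1}{n}\sum e^2},$$
$$MPE = \frac{\sum e / n}{\bar M_{obs}} \times 100, \qquad
AIC = n \ln\!\big(\tfrac{\sum e^2}{n}\big) + 2(k+1) + c,$$

with $n$ samples and $k$ independent variables. Two sign/definition
choices are worth spelling out. SSE uses $e = y_{obs} - y_{pred}$
(sign-irrelevant); MPE uses $e = y_{pred} - y_{obs}$ so that negative
values mean underestimation, matching how the statistic is read in the
field. $R^2$ for nonlinear fits is the pseudo form
$1 - SSE/SS_{tot}$ about the observed mean — the convention consistent
with reporting $R^2_{adj}$ for power models; the squared-correlation
alternative would differ only in the third decimal for well-fitting
allometries but is not what the adjustment formula assumes. The AIC
constant $c$ is rank-invariant within a candidate set and defaults to
0; it is exposed as a parameter for users who want a specific
convention. Ranking is by ascending AIC; ties closer than 1e-9 break
by ascending RMSE, then descending $R^2_{adj}$. A perfect fit
(SSE = 0) maps to $-\infty$ AIC with a warning rather than an error,
so noiseless validation data do not crash selection.

Residual checks are delegated to standard routines: Shapiro–Wilk for
normality and a Breusch–Pagan regression of residuals on fitted values
for homoscedasticity, flagged at α = 0.05. Residuals that are zero to
machine precision are reported as "degenerate" — the tests carry no
information there.

## The published coefficient registry

`builtin_registry()` carries 16 entries: six unexcavated-root equations
(per class × root type; the C1 secondary model is the quadratic, all
others power), nine below-ground compartment equations (per class ×
{root, root crown, total}), and one pooled generalist total-BGB power
model, $y = 0.07577\,D^{1.98745}$. Coefficients are stored as the
exact printed decimal strings as well as numerics, so a JSON round-trip
preserves digits; `validate_registry()` checks the built-ins against
those digits, arity against form, and positivity of power scales.

Two registry decisions deserve a note. First, the C1 total-BGB model
is printed in a form ambiguous between a product and a sum of terms
(`a*b*h + cD + dρ`); the linear reading $a + b h + c D + d\rho$ is
adopted because every sibling model in that class is linear, a product
$a\cdot b$ of two free coefficients is unidentifiable, and the linear
reading yields masses of the right magnitude. Second, the AGB
equations exist only in supplementary material that is not reprinted
here; rather than invent coefficients, the registry ships an *empty*
AGB slot plus a documented JSON schema
(`inst/extdata/agb_registry_example.json`, clearly labelled synthetic)
that users fill from the supplement. Built-ins are immutable: a user
document that tries to override one is rejected.

Calibration ranges: models fitted in-session store the predictor range
of their fitting data and warn on extrapolation. The built-in entries
carry no range because the source tables do not print the diameter
ranges of the fitting data, so no extrapolation warning is possible
for them — a documented limitation, not an oversight.

## Root reconstruction

For each tree: excavated roots get dry mass from fresh mass × the
subsample dry:fresh ratio; unexcavated roots get the per-class model
prediction at their basal diameter; per-type sums plus the root-crown
mass give total BGB. The C1 secondary quadratic dips below zero for
basal diameters between about 0.05 and 0.17 cm; predictions there are
clamped to zero with a warning, because dry mass is non-negative and
the dip is an artefact of an unconstrained polynomial near the origin.
The two-excavated-primaries rule is a property of the sampling design,
not of the arithmetic, so reconstruction does not enforce it — the
synthetic generator does.

## The synthetic stand generator

`sim_config()` defaults encode the study design where it is stated: 15
trees per class, heights uniform within each stratum (C3 capped at the
800 cm observed maximum), exactly two excavated primaries per tree.
Everything the design does not state is a fixed, documented choice of
plausible scrub-mangrove values, not a tuning knob:

* diameter link $D = 0.05\,h^{0.8}$ with 10% lognormal noise, giving
  basal diameters of ~0.8–2.5 cm for shrubs and DBH up to ~11 cm for
  emergent trees;
* crown radius 0.35 h with 10% noise; minor:major radius ratio uniform
  on [0.6, 1];
* wood density truncated-normal, mean 0.65, sd 0.08, bounds
  [0.45, 0.9] g cm⁻³, the plausible range for *Avicennia* wood;
* 4–8 primary roots per tree, 2–5 secondaries per primary; root basal
  diameters lognormal around per-class medians (primaries 1.2/2.0/3.0
  cm for C1/C2/C3, secondaries 0.4/0.6/0.8 cm) with sdlog 0.6 — a wide
  fine-to-coarse spread, both realistic for root systems and necessary
  for the power scale to be identifiable from generated data (the
  scale coefficient is effectively the predicted mass at x = 1 cm, so
  a sample concentrated far from 1 cm cannot pin it down);
* root masses from the built-in per-class models × noise; root-crown
  masses from the per-class crown models on the tree's own structure;
* dry:fresh ratio 0.45, typical of mangrove root tissue; excavated
  roots get fresh and subsample masses exactly consistent with it, so
  the excavation arithmetic is an identity on generated data;
* stem densities (3000/1200/350 stems ha⁻¹ for C1/C2/C3) are free
  parameters — the source never prints them — used only to expand
  per-tree masses to per-hectare densities.

Two noise models are available. The default is multiplicative
lognormal (mean-one), which keeps masses positive and mimics the
variance growth of allometric data. The `additive` option adds
constant-variance normal noise (sd = CV × mean mass, floored just
above zero), matching the additive-error model the fitting assumes.
The distinction matters for validation: with multiplicative noise at
CV = 5%, the sampling error of the power *scale* under unweighted
arithmetic-space least squares is around 13% (measured over 50
replicates) because the largest masses dominate the fit — no seed can
reliably recover the scale within 5% under those conditions. With
additive noise the same recovery is comfortably within 5%, so the
parameter-recovery tests run with `noise = "additive"`; the
noiseless case recovers coefficients to 1e-6 for all four forms.

All generator output is a pure function of the configuration,
including its seed; the tree and root stages use fixed seed offsets so
each stage is individually reproducible.

What passing these tests shows — and does not show. The generator
draws from the same model families the fitter assumes, with
independent errors and known predictor distributions. Recovery under
these conditions validates the optimiser, the criteria arithmetic and
the reconstruction plumbing; it says nothing about model *adequacy*
for real root systems, where errors are correlated within trees,
diameters are measured with error, and the true mass law is not
exactly a power function.

## Stand accounting and table reproduction

`stand_summary()` aggregates per-class BGB/AGB densities to totals,
converts to carbon (fractions 0.426 below-ground, 0.419 above-ground,
both measured for comparable *Avicennia* material), and computes
BGB:AGB ratios and percentage shares; `area_stocks()` scales densities
to Gg over the stand area (812 ha by default; Gg = Mg ha⁻¹ × ha /
1000). All internal arithmetic is full precision; rounding happens
only at presentation, using round-half-up at each table's printed
precision, which is how the printed tables were evidently produced.

`reproduce_tables()` feeds the published per-class means through this
chain and compares every arithmetically determined cell with the
printed digits. Three groups of printed cells are flagged rather than
asserted, because they are internally inconsistent with the stated
inputs: the BGB-carbon column of the density table (its digits imply a
carbon fraction of ≈0.429, while the stated 0.426 chain reproduces
every carbon-stock cell exactly, so 0.426 is taken as authoritative);
the total-carbon column that sums it; and two stock cells (C1 BGB
2.64 vs computed 2.65 Gg, total BGB 68.04 vs 68.05 Gg) that were
evidently computed from unrounded per-tree data rather than the
printed densities. The reproduction report surfaces these
discrepancies instead of forcing or hiding them. Problem sizes
throughout are desk-scale — three classes, 45 synthetic trees, 200
roots per recovery fit — so the whole suite runs in seconds.

The generalist-vs-specific comparison sums per-tree total-BGB
predictions from the pooled power model and from the class-specific
models over the same trees; the shortfall percentage is
(specific − generalist)/specific × 100. On any stand generated from
the class-specific models the pooled model undershoots, reproducing
the qualitative finding that motivates size-specific equations; the
published 27% figure follows from the printed pair (22.6, 83.8).

## Known limitations

* The original 45-tree dataset is not deposited, so the regression
  fits behind the built-in coefficients cannot be re-estimated; they
  are validated by property (recovery, oracle bounds, closure), not by
  re-fit.
* Built-in models carry no calibration ranges (not printed), so
  extrapolation beyond the original diameter ranges is silent.
* Fine roots, pneumatophore-specific pools, soil carbon and the ±SE
  uncertainty columns are out of scope; aggregation handles means
  only.
* The generator is spatially implicit: no topography or salinity
  covariates, no within-stand autocorrelation.
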