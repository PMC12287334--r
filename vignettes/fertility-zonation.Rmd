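---
title: "Fuzzy-geostatistical soil fertility zonation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-geostatistical soil fertility zonation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

fertzone scores the fertility of agricultural soil from twelve measured
parameters — pH, electrical conductivity of the saturation extract (ECe,
dS/m), organic carbon (OC, %), the macronutrients N, P, K (kg/ha) and the
micronutrients S, Fe, Mn, Zn, B, Cu (mg/kg) — with a Mamdani fuzzy
inference system, interpolates the resulting 0–100 score by ordinary
kriging, delineates management zones, and validates the zonation against
multi-season crop yields. This vignette records the models, the tunable
parameters, and the design decisions taken where the methodology left
genuine choices open.

## 1. Fuzzification

Each parameter is a linguistic variable partitioned into labelled fuzzy
sets (e.g. pH into Excessive-Acid / Acid / Neutral / Alkaline). Five
membership-function families are implemented:

* **triangular** and **trapezoidal** — piecewise-linear sets used for pH,
  EC (triangular) and OC, N (trapezoidal);
* **Gaussian** $\mu(x) = e^{-\alpha (x-\beta)^2}$ — the six micronutrients,
  whose availability varies smoothly around an optimum;
* **exponential-like** rational decay $\mu(x) = 1/(1+\gamma(x-\beta)^2)$
  — phosphorus, where membership should decay quickly but with a heavier
  tail than a Gaussian;
* **S-shape** — the standard smooth S-function (0 below the lower support
  bound, $2u^2$ / $1-2(1-u)^2$ on the two halves, inflection 0.5 at the
  midpoint); potassium uses an S-shaped "High" shoulder, its inverted
  (Z-shaped) complement for "Low", and a trapezoid for the interior term.
  Interior terms cannot be monotone, so the mixed S/Z/trapezoid partition
  is the standard way to realise an "S-shaped variable".

Two published formulas required interpretation. The rational-decay form is
printed with an unbalanced parenthesis; we adopt
$1/(1+\gamma(x-\beta)^2)$, the closest well-formed reading, and keep the
family swappable per term in the configuration. The printed S-function
repeats one branch and normalises it inconsistently; we adopt the textbook
S-function normalised by the full support width, which preserves the
intended smooth-transition behaviour and the 0.5 inflection.

Supports are closed intervals; at an exact breakpoint the adjacent piece
with the larger degree wins, so coverage never collapses at a boundary.
Degenerate triangles (`alpha_min == beta`) give shoulder sets that hold
membership 1 at a domain edge.

**Breakpoints.** The study that motivated this package never printed its
term boundaries. The packaged defaults
(`inst/extdata/soil_variables.yaml`) therefore encode widely used Indian
soil-test rating conventions: OC low < 0.5 %, medium 0.5–0.75 %, high
> 0.75 %; available N low < 280 kg/ha, sufficient 280–560, high > 560;
Olsen-P class centres at 10/40/70 kg/ha; K breakpoints near 120 and
280 kg/ha; USDA salinity classes for ECe; micronutrient class centres
around the usual critical limits (Zn 0.6, B 0.5, Cu 0.2, Fe 4.5, Mn 2.0,
S 10 mg/kg). Every term is overridable through
`read_soil_variables()`; all shipped tests use the defaults.

## 2. Rule base and Mamdani engine

Rules are IF–THEN statements over the twelve variables encoded as integer
antecedent vectors (slot order pH, OC, EC, N, P, K, Fe, Mn, Zn, B, Cu, S;
0 = variable absent, *k* = required term level), with a consequent class
1–4 (Unproductive, Low, Medium, Productive), a weight in (0, 1] and an
AND/OR connective. The complete rule space for three levels over twelve
criteria is $3^{12} = 531{,}441$ combinations; expert bases are small
curated subsets. The package ships the 25 distinct published rules (two
printed rows coincide once both tables are mapped into the canonical
encoding) and accepts user rule files in either the vector CSV form or a
readable clause grammar (`IF pH is Neutral AND OM is Medium THEN fertility
is Medium`); the two forms round-trip exactly. Levels never witnessed in
the printed rules (pH level 4, EC level 3) are documented extrapolations
of the same dictionaries.

Inference is standard Mamdani: firing strength = weight × min (AND) or
max (OR) over clause degrees; each rule clips its consequent set at its
firing strength (min-implication); the output envelope is the pointwise
maximum. The output partition places four trapezoids on the score domain
centred on the published class bands — Unproductive [0, 25], Low [25, 50],
Medium [50, 75], Productive [75+] — with the interior trapezoids symmetric
about their band midpoints, so single-class envelopes defuzzify exactly to
the midpoint. The "Very high" band (90–100) exists only in classification:
no published rule outputs it, consistent with observed scores never
approaching it.

Defuzzification is the discrete centroid $\sum x_i\mu_i / \sum \mu_i$ on a
grid with step $\delta = 0.1$ (configurable). Halving $\delta$ moves no
score by more than 0.05 (tested). An input covered by no rule returns the
domain midpoint 50 with an explicit `zero_activation` flag and a warning —
never silently. Class bands are half-open, upper-closed only at 100, a
convention forced by the bands sharing endpoints.

## 3. Geostatistics

The score surface is modelled as $Z(s) = \mu + \varepsilon(s)$ with
stationary increments summarised by the semivariogram $\gamma(h)$
(nugget–sill–range parameterisation; spherical, exponential and Gaussian
families, the latter two in practical-range form reaching 95 % of the sill
at the stated range).

* **Estimator** — Matheron's moment estimator
  $\hat\gamma(h)=\frac{1}{2N(h)}\sum(z_i-z_j)^2$ with default lag width
  = extent diagonal / 15 and cutoff = half the diagonal. Each bin reports
  the *mean pair separation* as its lag, not the bin midpoint: on gridded
  designs the first bin's pairs sit well above the midpoint and the
  midpoint convention biases the short-range fit.
* **Fitting** — weighted least squares with Cressie weights $N(h)/h^2$,
  multi-start L-BFGS-B under nugget ≥ 0, partial sill ≥ 0, range > 0. The
  fitted range is bounded at twice the largest lag and the fitted partial
  sill at 20× the largest empirical semivariance: a fit cannot support
  structure far beyond what the data witnessed, and unbounded ranges send
  the sill to infinity along a flat objective ridge.
* **Ordinary kriging** — the semivariance/Lagrange system; weights sum to
  1 (checked on every solve, tolerance 1e-8). The nugget is treated as
  spatial microstructure, so prediction at a data location reproduces the
  observation with zero variance (exact interpolation); the
  measurement-error alternative is out of scope. Exact duplicate
  coordinates are averaged with a warning to keep the system nonsingular.
  With ≤ 500 data points every prediction uses the full dataset (one
  factorisation, many right-hand sides); beyond that a 32-nearest-neighbour
  local search takes over. The test suite cross-checks predictions against
  an independent covariance-form GLS formulation to 1e-6.
* **Rasters** — cell-centre registration, row-major from the north-west
  corner, square cells in projected metres, nodata −9999, serialised as
  ESRI ASCII grids (a plain-text format every GIS reads). Maps default to
  10 m resolution.
* **Model comparison** — `compare_models()` fits all three families,
  cross-validates leave-one-out (ME and RMSE), and ranks by RMSE, then
  |ME|, then the fixed family order. In simulation the three families'
  LOO RMSE typically differ by under 2 %, so the ranking is reported with
  the fitted parameters rather than treated as a strong model-selection
  statement.

**Identifiability of the study variogram.** The study reports a spherical
model with nugget 5.2, sill 42.8 and range 3500 m for a field whose
diagonal is ≈ 2.7 km. When the range exceeds the sampled domain, a single
realisation's empirical variogram plateaus near its realised within-domain
variance, which is far below the ensemble sill, and per-realisation sill
estimates are weakly identified and heavily skewed. Two consequences are
documented here: (i) the recovery experiment uses *all* available lags
(cutoff = the full diagonal) because with the default half-diagonal cutoff
the largest visible semivariance is only ≈ 60 % of the sill and the sill
is not identifiable at all; (ii) recovery statements are made about the
*average* fitted sill across replicate simulations, which is unbiased to
within a few percent, not about single realisations. For in-domain ranges
(several hundred metres at this sampling density) the median fitted sill
and range land within 25 % of the truth (tested at 20 replicates).

## 4. Zonation

`classify_raster()` applies the published five score bands (or
equal-interval display bins over the observed range for presentation).
`contiguity_smooth()` converts the fragmented cell-wise map into
management-scale zones: a majority filter over a square window (the
published "sample interval of 10" is interpreted as the window extent in
cells; even extents widen to the next odd cell so the window stays
centred, ties keep the incumbent class), then 8-connected region
labelling, then iterative merging of regions below the minimum class size
(default 20 cells) into the modal class of their boundary neighbours, ties
broken toward the lower class code, capped at 10 iterations with a
warning. Smoothing can only remove classes, never invent them. The
original tool-specific unsupervised-classification step is deliberately
re-specified this way: its internals are not reproducible from any
published description, while majority filtering + region grouping is the
standard open equivalent with the same two parameters.

## 5. Yield validation

Yield records carry a point, crop (pearl millet, wheat, mustard, barley),
season, the 1 m² quadrat mass and a provenance flag. Processing follows
the published protocol: quadrat mass × 10,000 → kg/ha; multi-season
arithmetic mean per point; Tukey IQR outlier removal (k = 1.5, quartiles
by linear interpolation — `stats::quantile` type 7; both conventions are
unstated in the source and documented here); OLS regression of mean yield
on fertility; Welch's heteroscedastic ANOVA of yield across the fertility
classes present, with Games–Howell post-hoc pairs (studentized-range
p-values on Welch degrees of freedom). Records substituted from a previous
season are retained but counted; farmer-reported records serve as the
harvested reference for the survey RMSE. The fertility value at a yield
point is read from the kriged raster cell containing the point.

That last convention matters: synthetic yields are coupled to the FIS
score *at the sample points* (yields are surveyed at the soil-sampling
grid), while validation reads the *kriged* surface. Kriging smoothing —
chiefly the fitted nugget — attenuates the raster-path regression to
R² ≈ 0.6 even when the generative coupling targets 0.92. The
coupling-recovery checks therefore regress on the generating fertility
(where the realised R² matches the target to ±0.05 across seeds), and the
pipeline's raster-path R² should be read as a smoothing-attenuated
quantity, exactly as it would be with real data.

## 6. The synthetic generator

The study's field data are not publicly available, so the generator
emulates their statistical structure:

* **Spatial structure** — per-parameter stationary Gaussian random fields
  simulated by exact Cholesky factorisation of the model covariance
  $C(h) = \mathrm{sill} - \gamma(h)$ plus independent nugget noise, at the
  250 fishnet sample locations of a 2,500 m × 1,000 m (250 ha) extent —
  one sample per hectare at cell centres, matching the survey design. The
  extent is the whole-cell 25 × 10 realisation of "250 ha"; a square
  1,581 m version would not tessellate into hectare cells. All parameters
  share the study's spherical model (nugget 5.2, sill 42.8, range 3,500 m)
  as their *latent* correlation shape; only the shape survives the
  marginal calibration.
* **Marginals** — nine parameters carry published means, SDs and skewness
  coefficients and are calibrated by a rank-preserving transform:
  standardise, adjust shape through a sinh-arcsinh map
  $z \mapsto \sinh(\mathrm{asinh}(z)+\epsilon)$ with $\epsilon$ solved so
  the realised skewness matches the target, rescale to the exact target
  mean/SD, clip to plausibility bounds at mean ± 4 SD floored at zero
  (clipping above 1 % is logged; Fe and Cu, whose published SDs are large
  relative to their means, clip a few percent at the physical floor).
  pH, EC and OC have published observed ranges but no moments; they are
  rank-mapped onto a Beta(2, 2) between those ranges. The published
  summaries are internally inconsistent — every printed observed range
  spans only ~1.4–2.3 SD, impossible for 250 samples — so moments take
  precedence where both exist and the ranges calibrate only the
  moment-free parameters.
* **Dependence** — parameters are latently independent except a positive
  OC–N coupling (latent correlation 0.6, configurable), reflecting the
  agronomic association between organic matter and mineralisable
  nitrogen; no full cross-correlation matrix was published.
* **Yields** — per crop, mean yield = intercept + slope × fertility +
  Gaussian noise with variance
  $\sigma^2 = \mathrm{var}(\mathrm{slope}\cdot f)\,(1-R^2)/R^2$, so the
  expected OLS R² equals the target (0.919, 0.890, 0.863, 0.861 for pearl
  millet, mustard, wheat, barley — the published crop ranking). Baselines
  (900 + 18·f, 1900 + 22·f, 2500 + 30·f, 1500 + 20·f kg/ha) give typical
  semi-arid productivity with wheat > mustard > barley > pearl millet and
  survey RMSEs around 200 kg/ha, inside the reported ≤ 0.34 t/ha. Season
  records are the point mean plus zero-centred deviations (so the seasonal
  mean reproduces the coupling exactly); ~5 % are flagged as
  previous-season substitutes; one farmer-reported record per point is the
  harvested reference.

What the generator does **not** emulate: measurement error distinct from
the nugget, non-stationary trends, cross-correlations beyond OC–N, and
the study's actual spatial pattern. Passing tests therefore demonstrate
that the pipeline recovers known structure of this synthetic class, not
that it reproduces the original maps.

With the default calibration the FIS scores span roughly 28–56 — the low
and moderate bands only, as in the motivating survey — and the kriged map
concentrates in the Low band; when a single class is present the Welch /
Games–Howell section of the validation report is empty rather than
fabricated.

## 7. Numerical choices and problem sizes

* Centroid grid $\delta = 0.1$; discretisation error bounded at 0.05.
* WLS multi-start from four documented initial points; convergence code
  of the best start is attached to the fitted model.
* Cholesky jitter $10^{-8}$ × partial sill; simulation capped at 8,000
  locations (dense factorisation).
* All randomness flows through explicit integer seeds; pipeline stage
  seeds derive from the master seed, and regenerating with the same seed
  is byte-identical (manifest checksums are compared in tests).
* Test problem sizes were chosen to keep the full suite under a minute on
  one core while leaving recovery statements statistically meaningful:
  250-point fields for generator checks, 10–20 replicate simulations for
  recovery medians, 20-point instances for the kriging oracle, 50
  replicates for the yield-coupling mean.

## 8. Known limitations

* The 54 unpublished rules of the original 80-rule expert base cannot be
  reconstructed; the engine runs the 25 published rules by default, so
  absolute score levels differ from the original instrument to an unknown
  degree (the published score *range* behaviour — low-to-moderate only —
  is reproduced).
* Term breakpoints are conventions, not the authors' values; swapping in
  different plausible tables shifts scores smoothly but materially.
* Per-realisation recovery of a variogram whose range exceeds the domain
  is fundamentally weak (Section 3); quantities derived from it should be
  averaged across replicates.
* Anisotropy, co-kriging, regression kriging and type-2 fuzzy sets are
  out of scope.
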