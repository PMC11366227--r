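---
title: "Water-soaking phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-soaking phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeaphen)
```

`permeaphen` implements the analysis side of a standardized immersion
assay for water soaking (WS) in strawberry: per-fruit raw measurements
in, genotype-level derived traits and comparisons out. This vignette is
the package's own account of the models it fits, the parameters that
matter, the synthetic-data design it validates itself against, and the
numerical choices made where the design was genuinely open.

## 1. The biophysical chain

A fruit immersed in deionized water takes up water osmotically through
its skin. Each fruit contributes a short gravimetric time series
(weighings at 0, 2, 4 and 6 h by default) and a refractometer reading of
its expressed juice.

- **Flow rate** `F_f` (kg s⁻¹): OLS slope of cumulative mass (kg)
  against time (s), with a free intercept. All weighings enter,
  including the pre-immersion mass at t = 0; blotting before each
  weighing shifts the level of the series, not its slope, which is why
  the intercept is left free rather than pinned at the initial mass.
- **Surface area**: the allometry `A (cm²) = 5.0756 · m^0.6547` with
  mass in grams. The coefficients produce areas in cm² from grams;
  conversion to m² (× 10⁻⁴) happens inside `derive_uptake()`. Only this
  unit reading yields permeances in the observed 10⁻⁶ m s⁻¹ range.
- **Osmotic potential** from total soluble solids:
  `Ψπ = −0.3292 − 0.0400·TSS − 0.0088·TSS² + 0.0002·TSS³` (MPa). The
  cubic is strictly decreasing and negative on the calibration range
  0–25 °Brix; inputs outside it trigger a warning. Because strawberry
  turgor is essentially zero, the fruit water potential equals `Ψπ` and
  the uptake driving force is `ΔΨ = 0 − Ψπ`, stored as a positive
  magnitude.
- **Permeance**: `P_f = F_f/(A·ΔΨ) · RT/(ρ·V̄w)` in m s⁻¹. The constant
  factor `RT/(ρ·V̄w)` ≈ 1.35 × 10⁵ J kg⁻¹ at the default constants
  `R = 8.3145` m³ Pa mol⁻¹ K⁻¹, `T = 293.15` K, `ρ = 998.2` kg m⁻³,
  `V̄w = 1.807 × 10⁻⁵` m³ mol⁻¹. The assay temperature is not part of
  the raw record, so 20 °C — the conventional lab temperature — is the
  default; all constants are overridable through `physical_constants()`
  and are recorded on every derived table.

Fruits whose mass series decreases net over the assay get a negative
flow rate and permeance. These are flagged (`uptake_flag =
"negative"`), not rejected — osmotic water loss is physically possible —
and are excluded from the log-permeance traits, with the exclusion
count reported.

Per genotype, the permeance trait is the arithmetic mean of per-fruit
permeances (matching the means ± SE convention of genotype tables); the
log-transformation for regressions is applied at the genotype-mean
level, base 10 (R² is base-invariant).

## 2. Water-soaking kinetics

WS severity is scored on the five-point ordinal scale (0 none; 1 <10%
of the surface; 2 10–<35%; 3 35–60%; 4 >60%). Score and water-soaked
area are close to linearly related, so scores are treated as numeric
for curve fitting. The time course is fitted with the lag-parameterised
(Zwietering-style) Gompertz

$$y(t) = A\exp\left(-\exp\left(\frac{Ue}{A}(\lambda - t) + 1\right)\right),$$

chosen over other modified-Gompertz forms because its parameters are
literally the assay's quantities of interest: `U` is the maximum slope
and the tangent at the inflection point `t* = λ + A/(Ue)` crosses zero
at exactly `t = λ`, the time lag until first symptoms. Two consequences
worth knowing: the curve's value at `t = λ` is `A·e^(−e) ≈ 0.066·A`
(not `A/e`, which is the value at the inflection), and with `U = 0` the
curve is flat at that same value.

**Fitting.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
five deterministic starts; bounds `0 ≤ λ ≤ span + 4 h` (reported lags
can exceed the last observation of a 6-h assay), `0 ≤ U ≤ 5` and
`0.1 ≤ A ≤ 4` on the rating scale. The best converged fit by residual
sum of squares is kept; fits are per replicate (fruit), then averaged
per genotype.

**Ordinal observations need two safeguards.** For integer-valued
courses:

1. *End categories are censored.* A score of 4 only says the soaked
   area is above the top bin edge, and 0 that it is below the first.
   Treating those values as exact drags fits steep (no bounded curve
   passes through a plateau score exactly). End-category residuals are
   therefore one-sided hinges at half a score from the category value.
2. *Plateau-jump courses are non-identifiable.* A course like
   0, 1, 3, 3 admits exact fits of unbounded steepness: the data bound
   `U` only from below. Such fits run to the rate bound, are flagged
   `status = "saturated"`, and their `λ` and `U` are excluded from
   genotype averages. The 4-h WS index is observed, not fitted, so it
   is unaffected.

With these safeguards, simulation at cultivar-like kinetics
(λ ≈ 1.1 h, U ≈ 1.2 h⁻¹, 0/2/4/6-h schedule, ordinal rounding) shows
mean recovery biases of about −0.2 h in λ and −0.1 h⁻¹ in U — small
relative to the between-collection differences of interest. The
acceptance tests check these bounds explicitly.

An all-zero course is censored rather than fitted: `λ = assay span`,
`U = 0`, `status = "no_symptoms"`.

**The 4-h index.** The single-number susceptibility index is the score
at 4 h: `ws_at_time()` returns the observed rating when 4 h is a
scheduled observation (the default and the recommended practice — 4 h
is also the operationally convenient read-out within a working day) and
the fitted curve value otherwise.

## 3. Morphometrics

- **Strain release** `(A_i − A_CM)/A_CM × 100`: shrinkage of a punch
  disc upon enzymatic isolation of the cuticular membrane. By default
  `A_i` is the projected punch cross-section; a truncated-cone mode is
  available (`truncated_cone_area()`) for deep achene depressions. The
  frustum's elliptical base is handled by its equal-area circle
  (radius √(ab)); a full elliptic-integral lateral surface would change
  shallow-depression areas by less than the measurement noise, and for
  depths ≤ 0.5 mm under a 4-mm punch the two `A_i` conventions differ
  by at most ~35% in area and usually far less, which is why the
  projected convention is the default.
- **Achene depth from silicone casts**: `depth = 1.19 × cast depth`
  (zero-intercept calibration, r² = 0.98); the slope is configurable.
- **Cuticle mass per area**: disc masses (CM, dewaxed CM) divided by
  the excised area, in g m⁻²; wax = CM − DCM.
- **Microcracking**: percentage of mask pixels infiltrated by the
  fluorescent tracer. Masks are consumed pre-thresholded (logical or
  0/1); the optional grayscale helper thresholds at a configurable
  intensity but is declared non-authoritative, since the acquisition
  software's thresholding is instrument-specific.

## 4. The synthetic panel generator

The generator exists so that every pipeline stage can be validated by
parameter recovery. Its defaults describe a three-collection greenhouse
panel: 64 cultivars/breeding clones, a segregating F2 of 76, and 32
wild *Fragaria* accessions (optionally a 31-genotype second-season
cultivar resample), 10 fruit per genotype, scored and weighed at 0, 2,
4, 6 h.

**Latent structure.** Genotype log₁₀-permeance is normal per collection
(lognormal permeance, matching the observed tailing of raw permeances
and normality after log transformation). 60% of the log-permeance
variance sits between genotypes, 40% within (between fruit); genotype
tables in the field report only means ± SE, so this split is a stated
assumption, configurable. A latent WS severity (in rating units at the
index time) is a linear function of genotype log-permeance plus
Gaussian noise, scaled so the latent correlation equals `ws_coupling`
exactly.

**Severity → kinetics.** The plateau is the scale top (`A = 4`): water
soaking eventually covers the fruit, and intermediate plateaus would
make most ordinal courses non-identifiable. The rate follows
`U = 0.6 + 0.3 × severity` and the lag is then solved in closed form so
the noiseless curve passes through the severity value at 4 h
(`solve_gompertz_lag()`). Higher severity therefore means shorter lag
and faster rise — the sign pattern observed among the three WS metrics —
while the genotype's expected 4-h score equals its severity by
construction. This link is invented plumbing: it is the simplest
monotone map consistent with the observed correlation signs. One
consequence: because a single Gompertz with `A = 4` must pass through
the ~2-rating 4-h score with a ~1.2 h⁻¹ rate, the generator's lags run
near 2 h, somewhat longer than typical printed collection means — the
printed (mean λ, mean U, mean 4-h score) triples of real collections
are not jointly consistent with any one such curve, and the generator
resolves the tension in favour of the 4-h score, which anchors the
headline regression.

**Fruit level.** Fruit jitter: log-permeance (the within-genotype
share), mass (lognormal, CV 0.15), TSS (SD 0.5 °Brix), lag (SD 0.35 h)
and rate (SD 0.12 h⁻¹). Uptake series invert the permeance relation
exactly and add i.i.d. weighing noise (SD 5 mg — a realistic balance-
plus-blotting figure; the signal over 6 h is hundreds of mg). WS
courses sample the fruit's curve at the schedule and round to the
integer scale.

**Collection calibration.** The latent log-permeance means
(−5.74/−5.86/−5.57 for cultivars/F2/species, season-2023 cultivars
−6.02) put mean permeances near 1.8/1.4/2.7 × 10⁻⁶ m s⁻¹ and were
chosen, through the severity coupling, so the realized collection means
of the 4-h index reproduce the characteristic values 2.1/1.8/2.4 and
their ordering (species > cultivars > F2). Wild species get small
(3 g, CV 0.8) and variable fruit and more variable TSS; cultivars 15 g,
F2 10 g. One known deviation from real panels: because the species
collection is simultaneously small-fruited and most permeable, the
pooled genotype-level flux-density–area correlation is mildly negative
(≈ −0.25) rather than flat; within collections, and on panels without
that deliberate co-variation, it is zero as the size-independent latent
implies.

**Coupling calibration.** The default `ws_coupling` is not a free
number: it is solved from the target pipeline R² (0.46 by default) by
inverting the attenuation the pipeline itself introduces,
`ρ² k_x k_y = R²_target`, with closed-form reliability factors:
`k_x` from the sampling variance of log₁₀ of a mean of `m` lognormal
fruit permeances, and `k_y` from the fruit-level lag/rate jitter
propagated through the Gompertz slope at 4 h plus ordinal
discretisation variance 1/12 per fruit (`calibrated_coupling()`). With
the defaults this gives ρ ≈ 0.71, and the pipeline-estimated R²
averages ≈ 0.46–0.47 across seeds with a seed-to-seed SD of ≈ 0.065 at
172 genotypes. Setting `ws_coupling = 0` produces null panels whose
estimated R² matches the null expectation `1/(n−1)`.

**What passing tests do and do not show.** The generator emulates the
statistical skeleton real panels are analysed under: latent lognormal
permeance, noisy gravimetric series, ordinal scoring of a sigmoid
course, collection structure. It does not emulate microcrack formation,
weather or greenhouse drivers, rater drift, within-fruit spatial
heterogeneity, or season-by-genotype interaction beyond a mean shift —
so recovery results validate the pipeline's estimators, not any
biological claim about real fruit.

## 5. Statistical layer

- Genotype summaries: arithmetic mean, SE (absent at n = 1), n per
  trait, long format; `genotype_trait_matrix()` pivots to the wide
  genotype × trait table the correlation/regression layer consumes.
- Pearson correlation tables per collection × season plus a pooled
  "grand mean" block over all genotype-season rows; stars at
  0.05/0.01/0.001, `ns` otherwise; constant traits give `NA` rather
  than an error.
- The headline regression `ws_index ~ log10_permeance` by OLS, with R²
  reported as a fraction and percentage; `tidy()`/`glance()` methods.
- Group comparisons: Tukey HSD on all pairs (via `aov` +
  `TukeyHSD`), pairwise two-sided Mann–Whitney U tests — unadjusted by
  default, as is conventional for the ordinal score tables; Holm or
  Bonferroni available behind `p_adjust` — and Dunnett's many-to-one
  comparison against a named control through the multivariate-t
  implementation in `multcomp`.
- Compact letter displays use the insert–absorb algorithm, letters
  ordered by group mean; every call self-audits the letters against its
  own p-value matrix and aborts on inconsistency, so a returned display
  is consistent by construction.
- `distribution_report()` produces fixed-width histogram bins
  (configurable width), empirical quantiles, and normal-probability
  pairs at plotting positions `(i − 0.5)/n`.

## 6. Numerical choices and degenerate inputs

- Two-point uptake series: slope is the difference quotient, r² = 1 by
  convention.
- Zero time span or fewer than two weighings: rejected, naming the
  fruit.
- Gompertz multistart tie-break: equal-RSS fits keep the first (gentler
  initialisations come first); an essentially exact fit (RSS < 10⁻¹⁰)
  stops the search.
- Test and simulation problem sizes: recovery checks run 20–50 seeded
  replicates at 172 genotypes × 10 fruit (or reduced panels where the
  property is size-independent), sizes at which Monte-Carlo error is
  comfortably below the asserted tolerances.

## 7. Known limitations

- The severity→kinetics link and the 60/40 variance split are
  assumptions, not estimates; both are configurable and documented as
  such.
- Time lag and rate recovered from 4-point ordinal courses carry small
  negative biases (Section 2) and genuinely saturated courses carry no
  rate information at all; analyses of λ and U should expect some
  excluded fruit.
- The generator's lag level (~2 h) is a structural consequence of
  anchoring the 4-h score with a scale-top plateau (Section 4).
- Hue-angle skin colour and image acquisition for microcrack masks are
  out of scope; masks enter pre-binarised.
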