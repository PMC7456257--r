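---
title: "Outermost crown profiles by quantile regression and boundary regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outermost crown profiles by quantile regression and boundary regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownprofile)
```

## The estimation problem

A conifer sapling's crown is measured branch by branch: for each branch,
the distance from the tree tip to the branch base (`L`, m), the chord
length (`BC`, cm), the insertion angle (`VA`, degrees) and the diameter
(`BD`, mm). From these the package derives the branch tip's position in
crown coordinates:

* depth into the crown `DINC = L − BC·cos(VA)` (the chord's projection on
  the trunk is subtracted; angles above 90° project negatively, so
  `DINC > L` is possible),
* relative depth `RDINC = DINC/CL ∈ [0, 1]` with `CL` the crown length,
* outer crown radius `OCR = BC·sin(VA)` (m).

The *outermost crown profile* is the upper envelope of the
`(RDINC, OCR)` cloud — the silhouette a sapling presents to light — not
the mean radius at each depth. Estimating an envelope rather than a mean
is what drives every methodological choice below.

## Profile forms

Four parametric radius equations are supported (`profile_forms()`); the
workhorse is the covariate power-exponential form

$$\mathrm{OCR} = a_1\,\mathrm{DBH}^{a_2}\,
  \mathrm{RDINC}^{(a_3 + a_4 \mathrm{CR})} e^{a_5\,\mathrm{RDINC}},$$

with DBH in cm and `CR = CL/HT` the crown ratio. The equation is zero at
the tip, unimodal on `(0, 1]` when `a3 + a4·CR > 0 > a5`, and its maximum
has the closed form

$$t^\* = \min\!\left(1, \frac{a_3 + a_4\,\mathrm{CR}}{-a_5}\right),$$

which `inflection_point()` implements (with a `monotone` flag when
`a5 ≥ 0` leaves no interior maximum). In this crown-profile literature
that depth of maximum radius is called the *inflection point*; true
second-derivative inflections are deliberately not computed. Note `t*`
is linear in CR, so the mean of per-sapling depths equals the depth at
the mean crown ratio.

The Kozak-type variable-exponent forms are implemented exactly as
printed. Two of their quirks are documented rather than repaired: the
basic form's base `X = (1-(1-RDINC)^{0.5})/(1-p^{0.5})` is monotone in
RDINC, so the claim that the radius peaks at `RDINC = p` is not
algebraically consistent with the formula — we treat `p` as a shape
parameter, nothing more; and the modified form's exponent
`c5·(1-RDINC)` vanishes at the crown base, where the value is computed
as its limit `c1·DBH^{c2}`.

`crown_ratio()` defines CR as CL/HT. The source material names the
quantity without writing the formula; CL/HT is the standard forestry
definition and is consistent with every crown-ratio value (≤ 1) quoted
alongside tree sizes in the study's figures.

## Mean fits and quantile fits

`fit_ols()` estimates any form by nonlinear least squares
(Levenberg-Marquardt via `minpack.lm`, 20 multiplicative-U(0.5, 2)
perturbed starts, seed-controlled), on the largest branch per whorl by
default — the candidate-model comparison protocol — with the study's
goodness-of-fit statistics: `R²adj = 1 − (1−R²)(n−1)/(n−p)` and
`RMSE = √(SSE/(n−1))`. The `n−1` RMSE denominator follows the study's
printed definition, not the more common `n−p`; with n in the hundreds
the difference is cosmetic, but exact reproduction matters more than
convention here.

`fit_quantile()` minimises the exact pinball loss
`ρ_τ(u) = u·(τ − 1{u<0})` summed over all branches (quantile models use
the full cloud, not per-whorl maxima). The optimiser is a homotopy:
BFGS on a smoothed loss `τu + ε·softplus(−u/ε)` with ε decreasing from
0.1 to 10⁻⁶ of the mean radius, followed by Nelder-Mead polish cycles on
the exact loss. Two numerical details matter:

* the finite-difference gradient step must shrink with ε
  (`max(10⁻⁹, ε/10)`); with the default step the gradient of the nearly
  kinked loss is pure truncation error and the fit stalls about 10⁻³
  away from the optimum;
* the reported `loss_value` is always the exact pinball loss, so any
  optimiser can be compared on it. The test suite holds the fits to the
  solutions of an independent interior-point implementation
  (`quantreg::nlrq`) at matching loss.

One-parameter location models are polished by golden-section search plus
a snap to nearby observations, where a pinball optimum always sits —
this is the sort-based-quantile oracle route used in testing.

`fit_quantile_grid()` fits τ = 0.50 … 0.99 (step 0.01, 50 levels by
default), warm-starting each level at the previous solution. Failures
are recorded per level without aborting the grid. Quantile crossing of
the fitted curves is *measured* (`crossing_fraction()`), never silently
reordered: an envelope method should expose, not hide, where its
per-level fits disagree.

## Polynomial frontier estimation

For each sapling, `fit_polynomial_frontier()` finds the degree-`p`
polynomial of minimal area over the support (default `[0, 1]`, the
biological range of relative depth) subject to lying on or above every
branch tip. This is a linear program in the coefficients; since they are
sign-free, the package solves the dual —
`max y'λ s.t. V'λ = c, λ ≥ 0` — with a dense two-phase simplex using
Bland's rule, and recovers the coefficients from the supporting points
named by the optimal basis. Two properties follow by construction: the
envelope invariant (no data point above the fitted polynomial beyond
10⁻⁹, enforced by an intercept lift absorbing LP round-off) and
nestedness (minimised area nonincreasing in degree).

A minimal-area envelope need not exist: if the cloud does not span the
support, the polynomial can tilt its area to −∞ while clearing every
point. This is reported as an error and the affected degree is skipped
during selection. Between data points a point-cloud envelope may also
dip below the cloud's piecewise-linear interpolant; this is audited on a
201-point grid and reported (`audit$n_dips`), not constrained away.

`select_degree()` scores degrees 0…20 (capped at `n−1`) with the
slack-sum criteria `AIC(p) = log Σ(φ̂(xᵢ)−yᵢ) + (p+1)/n` and
`BIC(p) = log Σ(φ̂(xᵢ)−yᵢ) + log(n)(p+1)/(2n)`, takes the AIC minimiser
and, when AIC and BIC disagree, the smaller of the two degrees. The
slack sum is floored at 10⁻³⁰⁰ so that degrees interpolating the cloud
exactly remain comparable, with ties resolved toward parsimony. A
practical caveat the test suite documents: slack-based criteria are
informative about the envelope's shape only when some points lie close
to it; under heavy one-sided depletion the slack term keeps rewarding
extra degrees and selection becomes unstable. The degree-recovery test
therefore uses mild depletion (Beta(12, 1)); under the stand generator's
default heavier noise, per-sapling degree choice varies more.

## Quantile selection against the boundary

`select_strip_quantile()` evaluates every fitted quantile curve at each
sapling's (DBH, CR) on the 10,001-point relative-depth grid
(`rdinc_grid()`, step 10⁻⁴), clamps negative radii to zero (radii are
physical lengths), and computes the mean absolute distance to the
sapling's own frontier on the same grid. Per sapling the smallest-distance
quantile wins, ties resolved toward the larger quantile (the outermost
curve is the object of interest). Two strip summaries are reported side
by side because the procedure can be read two ways: the mean of
per-sapling best quantiles rounded to the grid (`tau_mean`), and the
quantile minimising the column mean of the sapling-by-quantile distance
matrix (`tau_argmin`). When they disagree the print method says so; no
preference is imposed.

## Crown morphology comparison

`crown_metrics_table()` compares strips at fixed crown ratio 0.80
(approximately the sample mean) across DBH 0.5–5.0 cm: depth of maximum
radius, largest radius, and upper-crown volume
`V = π·CL·∫₀^{t*} r(t)² dt` by composite Simpson quadrature on ≥ 2,001
points. "Upper crown" is taken as tip-to-inflection, `[0, t*]` — the
source never defines the region, so it is a parameter (`region`) with
that default. Volumes use a common crown length (default 1.76 m, the
pooled sample mean) for both strips so that differences reflect profile
shape, not an assumed height allometry.

The size trend of the volume contrast deserves care. With the
power-exponential form, the ratio of strip volumes scales as
`DBH^{2(a2_u − a2_c)}`, so the *proportional* contrast
(`d_upper_volume_rel`) is monotone in DBH whenever the two strips' DBH
exponents differ — decreasing, for the packaged selected-quantile
coefficient sets. The *absolute* contrast in m³ is the difference of two
growing power functions and need not be monotone; with the same
coefficient sets it peaks near DBH 3.6 cm. Both columns are reported;
the qualitative claim that the uncut strip's volume advantage shrinks
with sapling size is a statement about the proportional contrast.

`annual_growth_compare()` summarises the per-sapling sample-branch
annual length increments by year and strip and applies a two-sided
Welch two-sample t-test per year. The Welch choice is ours: the source
reports per-year significance without naming a test, and unequal
variances between treatments are plausible. P-values are unadjusted (one
planned comparison per year), with a Holm-adjusted column added for
transparency.

## The synthetic stand generator

`generate_stand()` emulates the study conditions: 49 shelterwood-cut and
30 uncut saplings; DBH, HT and branch angles from truncated normals
matched to the published per-strip means and standard deviations (DBH
truncated to the (0.5, 5) cm sampling window, HT above 1.3 m, VA to
(5°, 160°), the observed range); crown ratio from CL/HT means (0.771 and
0.739, SD 0.08); whorls every 0.15 m (matching the published
whorl-per-sapling counts); 2–4 branches per whorl. Each branch's true
envelope radius comes from the packaged selected-quantile coefficient
sets, and the observed radius is depleted one-sidedly:
`OCR = r* · u, u ~ Beta(4, 1.5)`. The Beta family on (0, 1] is the
simplest noise that keeps every observation on or below the envelope
with tunable depletion; the defaults give a mean observed/envelope ratio
of about 0.73 (crowns are mostly interior to their silhouette) while the
99th percentile of `u` is ≈ 0.99, so the τ = 0.99 quantile curve of the
observations essentially coincides with the envelope and envelope
recovery through `fit_quantile()` is well posed. Raw measurements are
back-solved (`bc = ocr/sin(va)`, `l = rdinc·cl + bc·cos(va)`) so that
reading the written CSVs reproduces the intended geometry bit-exactly.

What the generator does **not** emulate: within-crown correlation of
branch sizes, azimuthal asymmetry, spatial competition between
neighbours, crown damage, or any light model. Passing the recovery tests
therefore shows the estimation chain is correct under the assumed noise
structure, not that the Beta depletion model is true of real crowns.

`generate_growth_series()` assigns one sample branch per sapling (fifth
whorl where present) annual increments with equal pre-treatment strip
means (11.35 cm/yr) and diverging-then-crossing post-treatment means
anchored to the published 2013/2014 values, with SD 2.5 cm/yr.

## Problem sizes and budgets

The test suite runs study-scale problems: stands of 49 + 30 saplings
(≈ 2,700 branches), the full 50-level quantile grid for the end-to-end
selection check, 10⁶-point argmax oracles for the closed-form depth of
maximum radius, 1,000 random frontier instances for the envelope
invariant, and 100 seeded replicates for degree selection. The whole
suite completes in a few minutes on one core; the acceptance script is
instantaneous (closed forms cross-checked on a 10⁵-point grid).

## Known limitations

* Quantile-grid fits are local optimisations of a non-convex problem;
  multi-start plus warm-starting makes them reproducible under a fixed
  seed, not provably global. The exact-loss audit and the interior-point
  cross-check bound the practical gap.
* The frontier is estimated per sapling from few points (one per
  branch), so the selected polynomial degree is variable under heavy
  depletion; strip-level conclusions rest on the quantile curves, with
  the frontier only arbitrating *which* quantile.
* No standard errors are provided for quantile fits, and the reported
  OLS coefficient table does not attempt to reproduce published standard
  errors (a numerical-Hessian flag only).
* Reproducing the study's numerical tables end-to-end requires its
  supplementary measurement data converted to the documented CSV
  dialect; the packaged fixtures carry only the published coefficient
  tables.
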