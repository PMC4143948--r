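---
title: "Models and methods for quantitative CAZ analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative CAZ analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazquant)
```

`cazquant` analyses direct stochastic optical reconstruction microscopy
(dSTORM) data of the cytomatrix at the active zone (CAZ) of *Drosophila*
neuromuscular junctions, and models the short-term plasticity of the evoked
currents those synapses produce. This vignette is the package's account of
the models it implements, the parameters that matter, and the design choices
made where the methods left genuine freedom.

## The analysis pipeline

A dSTORM experiment yields a *localization table*: one row per fitted
single-fluorophore emission with nanometre coordinates, a camera frame index
and a photon count. The pipeline is:

1. **Filter** localizations to spots with strictly more than 1,000 photons.
2. **Render** the table at 10 nm per pixel (half-open binning: a coordinate
   on a bin edge belongs to the higher pixel).
3. **Segment** CAZ regions: Gaussian-blur the rendering (1 px s.d.), take a
   minimal-intensity mask at 0.15 counts, keep 8-connected components of at
   least 300 px, and count the *unblurred* localizations whose pixel falls
   inside each component. Images whose isolated-spot background exceeds 2.3
   single spots per µm² are excluded.
4. **Cluster** the localizations of each region with the density-gradient
   algorithm (below); group clusters into CAZ-units by the 4-in-200-nm rule.
5. **Quantify**: convert localization counts into molecule estimates with the
   titration-calibrated conversion factor.

## Density-gradient clustering

The *density* of a localization is the number of other localizations within
an Eps-environment of radius 20 nm (Eps roughly matches the radius of an
electron-dense CAZ filament with the antibody complex attached). The focal
localization is not counted — it must *enclose* k others — but
`cluster_params(count_self = TRUE)` switches conventions, since the
historical phrasing admits both readings.

A localization is a **cluster centre** iff no Eps-neighbour has a strictly
higher density and its own density is strictly greater than k = 16 (a value
above the noise floor but below the typical within-cluster density of 12–18).
Two deterministic tie-breaks are layered on top: on density plateaus only
the point smallest in (x, y, index) order remains a candidate, and a
candidate within Eps of an already-accepted centre of equal or higher
density is suppressed, so exactly one centre survives per plateau.

**Expansion** proceeds from each centre (in decreasing centre-density
order), examining Eps-neighbours of core members. A neighbour joins only if
its density is *strictly lower* than the member that discovered it; a
joining member with density above k is itself a core object and keeps
expanding, anything else is a boundary point. A density increase along the
path ends the cluster, which is what separates adjacent clusters at density
saddles instead of merging them. Clusters are disjoint; the frontier is
processed in decreasing discoverer-density order so results are
deterministic.

Each cluster of at least 3 non-collinear members gets a **minimum-area
enclosing ellipse** (Khachiyan's algorithm, with the final ellipse rescaled
minutely so containment of every member is exact). "Tightly fitted" is read
as minimum-area because it is the only parameter-free reading; the shape
statistic is short/long radius and the area is πab. Clusters whose centres
have at least 4 cluster centres (including their own) within a 200 nm circle
seed **CAZ-units**; connected components of seeded clusters form the units,
and sub-threshold neighbour clusters are attached by default (configurable,
since the sources do not say whether they belong).

**Radial profiles** sum pixel intensities into annuli around the
intensity-weighted centre of mass and divide by each annulus area; per-unit
profiles are averaged into mean ± s.e.m. curves.

## Protein counting by antibody titration

Localization counts cannot be read as molecule counts: a molecule is
detected through a primary antibody carrying on average 1.59 secondary
F(ab')₂ fragments, each fluorophore is localized many times (mean 16.1), and
neither the primary epitopes nor the secondary binding sites are saturated
under working conditions. The calibration runs two titrations — diluting the
fluorophore-labelled secondary at fixed primary, and diluting the primary at
fixed secondary — plus a measurement of isolated primaries.

Per-CAZ localization counts at each dilution are histogrammed and their mean
taken as the maximum-likelihood Poisson rate (identical to the arithmetic
mean; a histogram least-squares fit is kept as a cross-check because the
original weighting is unstated). Dilution series are fitted with the
one-site logistic (Hill coefficient fixed at 1). On the concentration-
fraction scale d ∈ (0, 1] used throughout this package (1 = working
concentration) the response *rises* with d:

$$L(d) = L_2 + (L_1 - L_2)\,\frac{1}{1 + d_0/d}$$

with L₁ the saturated count, L₂ the single-antibody count (the high-dilution
asymptote) and d₀ the half-saturation fraction. Points are weighted by their
inverse squared standard errors; with counts spanning two orders of
magnitude an unweighted fit lets the top of the curve dominate and biases
L₂.

The **conversion factor** (molecules per localization) is the product

$$C \;=\; \frac{1}{L_E}\cdot\frac{L_1^{\mathrm{(prim)}}}{L^{\mathrm{(prim)}}_{\mathrm{exp}}}\cdot\frac{L_1^{\mathrm{(sec)}}}{L^{\mathrm{(sec)}}_{100\%}}$$

— the reciprocal localizations per isolated primary, corrected for
incomplete primary-epitope occupancy at the working dilution and for
incomplete secondary decoration in the CAZ at 100% labelled secondary. In
the uncancelled form L₂ appears once in numerator and once in denominator
(L_E = L₂ × secondaries-per-primary); the first-order quadrature error
propagation therefore counts the relative error of L₂ twice, treating the
two occurrences as independent. With the published calibration statistics
(`brp_calibration()`) this yields C = 0.134 ± 0.028 and 137 ± 29 molecules
for the average CAZ-unit; genotype tables use the factor rounded to 0.134.
Quadrature independence is an assumption; counts are lower bounds since
epitope shielding and fixation losses are not modelled.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, plus a ground-truth record sufficient to score every estimator.
All randomness flows from one seed.

**Labeling chain.** A molecule is occupied by a primary with probability
d/(d + 9.07·10⁻⁴) of the primary concentration fraction (the half-saturation
follows from the published primary titration: saturated count 198.9 versus
70.7 at the 1/2,000 working dilution). A bound primary carries
1 + Bernoulli(0.59) secondaries — the simplest distribution with the
published mean 1.59. In the crowded CAZ a secondary is detected with the
saturable probability d/(d + 0.225) of the labelled-secondary fraction
(from 992.5 measured at 100% versus the 1,212.2 asymptote); isolated
antibodies are fully decorated, matching the isolated-primary measurement of
25.6 = 1.59 × 16.1. A detected fluorophore yields 1 + Geometric
localizations with mean 16.1 — at least one localization, overdispersed as
photoswitching statistics are; the family is configurable (geometric,
shifted Poisson, fixed) because only the mean is constrained. Each
fluorophore is displaced ~6.5 nm (s.d.) from its epitope, the size of the
primary-plus-F(ab')₂ complex, and each localization is displaced by
isotropic Gaussian noise of the localization precision (default 7.16 nm).
Localizations of one fluorophore occupy a consecutive burst of camera
frames, which is what nearest-neighbour precision estimation relies on.

With this chain the pipeline is self-consistent: at working conditions a
molecule yields on average 0.355 × 1.59 × 0.816 × 16.1 ≈ 7.4 localizations,
the reciprocal of the conversion factor, so ~137.5 molecules produce ~1,020
localizations per unit.

**Unit geometry.** A unit holds Poisson(14.5) elliptical clusters of
1 + Poisson(6) molecules placed uniformly inside planted ellipses
(long/short radii ~10/5 nm, the epitope spread of a single CAZ filament;
fitted enclosing ellipses come out near 30 × 20 nm because they absorb
linkage and localization noise). Unclustered molecules are added at 26% of
unit content. Cluster centres are dart-thrown with a hard-core separation of
40 nm inside a 100 nm disc, unclustered content inside a 130 nm disc: these
compact defaults were chosen so that a default unit reliably forms a single
contiguous ≥300 px mask component at the standard thresholds — units built
from ~40 visible antibody spikes fragment when spread over the full 200 nm
disc. The resulting default region area (~0.05 µm²) is below the ~0.1 µm²
of real CAZ-units; real units are contiguous at larger size because real
Brp immunoreactivity is not purely spike-like. This is the main respect in
which passing segmentation tests understate difficulty on real data.

**Clustering-recovery studies** use a different, documented configuration:
clusters planted directly at the localization level (Poisson(52)
localizations per cluster), centre separation 60 nm in a 150 nm disc, and
the 26% unclustered fraction as spatially uniform localizations over the
200 nm disc. The mechanistic antibody chain is deliberately bypassed there:
a single labelled free molecule yields a >16-localization spike that *is* a
density cluster, so with mechanistic labeling the planted cluster count is
not the quantity the algorithm is being scored against. The study measures
algorithmic recovery — resolvable clusters against diffuse background — not
photophysics.

**Titrations** are generated at the count level: per-CAZ counts are Poisson
draws about the logistic mean implied by the labeling chain. This is the
distributional model the downstream Poisson fit assumes and makes the
generator's mean curve follow the logistic exactly; a mechanistic
zero-truncated compound draw was tried and rejected because conditioning on
visibility distorts the mid-dilution shape away from the fitted family.

**Background** is uniform single localizations at 78 per µm². For quality
control, "isolated single spots" are sub-threshold mask components of at
least 10 px (antibody-sized; chance coincidences of two or three background
localizations span only 4–8 px) lying farther than 400 nm from any CAZ
region, so satellite fragments of a synapse are not counted as unspecific
background.

## Localization precision

Two estimators are implemented. The **pooled-histogram** method selects
isolated antibody spots (mask components of 16–100 px with second-moment
axis ratio ≥ 0.95), aligns each spot's localizations to its centre of mass,
rescales deviations by √(k/(k−1)) to undo the centre-of-mass shrinkage of a
k-localization group, pools everything into a 4 nm 2D histogram and fits a
*bin-integrated* 2D Gaussian by nonlinear least squares (fitting bin
integrals rather than densities removes the σ²+bin²/12 discretization bias,
which matters at σ = 3 nm). The reported precision is (σₓ+σᵧ)/2; an
all-identical-points group is flagged degenerate with σ below the histogram
resolution. Localizations are gathered from the accepted component dilated
by 3 px, because the blurred mask understates the emitter's support and
clipping the distribution tails biases the estimate downward. A residual
−2 to −4% bias remains at σ ≈ 7 nm with ~15-localization spots: the
ellipticity and size gates preferentially reject groups whose realized
spread is large, a compact-selection effect intrinsic to the selection
criteria; the validation suite therefore asserts unbiasedness of the
seed-averaged estimate within 5%. The **NeNA** method histograms distances between each
localization and its nearest neighbour in the following frame and fits the
correlation peak d/(2σ²)·exp(−d²/4σ²) plus a linear term for uncorrelated
neighbours; repeated emissions of one fluorophore carry the precision twice,
which is where the factor 4 = 2·(2σ²)/... in the exponent comes from. A
fitted correlation weight below 0.05 is reported as "no correlation peak".

## Vesicle-pool models of short-term plasticity

Evoked current trains (100 pulses at 60 Hz) with biphasic recovery (probes
at 25 ms – 100 s) are described by two constrained mean-field models.
**Model 1**: a readily releasable pool (capacity N, occupancy n₁) refilled
from a finite supply pool (N₀) with flux k₊₁·(n₀/N₀)·(N−n₁) − k₋₁·n₁; the
supply exchanges with an external reservoir at k₊₀/k₋₀. **Model 2** adds a
small pool N₂ with high release probability p_vr2, refilled at
k₂·(n₁/N₁)·(N₂−n₂) from the larger low-probability pool. The exact kinetic
equations of the original constrained models are not printed in the sources
this package follows; the free-site-limited, supply-occupancy-scaled flux
above is this package's documented choice, and with k₊₀ = k₋₀ = 0 it is a
closed system: pool contents plus cumulative release are conserved exactly.

Release probability uses a single-exponential residual-facilitation
variable: every stimulus deposits one unit of facilitation decaying with
τ_F = 100 ms, and p(t) = clamp(p_base·(1 + γ_eff·F(t)), 0, 1) with
p_base = 1 − e^(−α). The calcium-scale facilitation parameter γ = 0.4 µm⁻¹
maps to the dimensionless gain through a configurable length scale
(default 1 µm, i.e. gain 0.4); the mapping is isolated in
`facilitated_pvr()` so a fuller biophysical form can be swapped in. The
constrained parameters (N₀, k₋₁, k₊₀, k₋₀, quantal size) are required
configuration inputs with documented placeholder defaults on the scale of
reported neuromuscular-junction estimates — they are not measured values.

At each pulse the released fraction p·n₁ (plus p₂·n₂ for model 2) sets the
amplitude; between pulses the pools relax. Integration is an
exponential-Euler stepper: within a substep the supply occupancy is frozen
and the fast pool equation is solved in closed form, the transfer is capped
at the available supply (refill stalls as the supply empties), and substep
lengths scale with the slow rates only. Agreement with a stiff ODE solver
is a few 10⁻⁴ relative; the suite checks it against `deSolve::lsoda` and
against a per-vesicle stochastic simulation. Recovery amplitudes are
*independent* single-pulse probes of the post-train state (monotone in the
interval when γ = 0); whether facilitation survives into the probes is
configurable and defaults to reset-with-pools-carried-over.

**Fitting** minimizes the unweighted sum of squared residuals over the
concatenated train and recovery amplitudes in the three free parameters
(α, N or N₁, k₊₁) — the weighting of train versus recovery points is
unstated in the sources, so the simplest choice is used. Optimization is
Nelder–Mead on log-parameters with a polishing restart (tolerance 10⁻¹⁴ for
noiseless self-consistency; 10⁻¹⁰ suffices for noisy data); uncertainties
come from the finite-difference Hessian of the residual sum.

The **paired-pulse rule** measures the second amplitude from its peak to the
mono-exponential extrapolation of the first response's decaying tail (fitted
between the first peak and the second stimulus, skipping the
rise-contaminated top 25%). On overlapping responses the rule itself
deviates from the planted amplitude ratio (the superposed peak shifts); the
tests therefore compare the implementation against an analytic application
of the same rule, not against the planted ratio.

## Numerical choices and degenerate inputs

* Coordinates are 0-based nanometres from the top-left corner; pixels are
  half-open intervals; the rendered pixel sum equals the localization count.
* Gaussian blur uses a truncated (4σ), renormalized separable kernel with
  zero padding: total intensity is conserved except within 4σ of the border.
* Connected components are 8-connected (the sources are silent; documented).
* The enclosing-ellipse iteration stops at Khachiyan tolerance 10⁻⁶ or
  2,000 iterations; the final rescale guarantees containment regardless.
* Fewer than 3 or collinear members → degenerate-cluster flag, no ellipse.
* Empty dilution lists, negative counts, missing photon columns, tables
  without frames (NeNA), and zero outside-region area all raise explicit
  errors rather than silently passing through.
* Problem sizes in the validation suite (100 clustering seeds, 50
  calibration and 50 fitting replicates, 600–1,000 synthetic antibodies,
  ≤5,000-point density instances) were chosen as the smallest studies whose
  sampling error is well below the tolerances being asserted.

## Known limitations

* Simulation starts at the localization level: no camera frames, PSF or
  EMCCD noise, no drift, no multi-channel registration, no 3D.
* Default synthetic units are more compact than real CAZ-units (above).
* The facilitation form and the constrained rate values are placeholders
  standing in for the original constrained models, whose equations are not
  reproduced in text form; conclusions about absolute fitted rates should
  not be drawn from the defaults.
* Epitope shielding and fixation losses are not modelled; molecule counts
  are lower bounds by construction.
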