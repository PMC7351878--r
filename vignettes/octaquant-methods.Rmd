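---
title: "Quantifying choroidal neovascularization on OCT angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal neovascularization on OCT angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The problem

Neovascular age-related macular degeneration (nAMD) is driven by the growth
of an abnormal vascular network — a choroidal neovascularization (CNV) —
under or into the retina. Anti-VEGF injections suppress exudation, and
en-face OCT angiography (OCT-A) images the CNV's blood flow directly. Four
scalar biomarkers summarize the lesion on a binarized en-face flow image:

* **FD** — the box-counting (Kolmogorov capacity) fractal dimension of the
  skeletonized network, an index of branching complexity in [0, 2];
* **LAC** — lacunarity, the normalized variance of box masses, an index of
  structural nonuniformity (0 for translation-invariant patterns);
* **SA** — blood-flow surface area in mm²;
* **VD** — vessel density, the flow fraction of the delineated lesion region.

`octaquant` implements the full chain from raster image to these biomarkers,
simulates a treat-and-extend (TAE) anti-VEGF cohort in which injection
burden is coupled to baseline morphology, applies the standard outcome
classifications, and provides the statistical layer (repeatability ICC,
exact nonparametric tests, binary GLMs with ROC discrimination) used to
relate baseline morphology to outcome.

## Image quantification

### Binarization and delineation

The flow signal is segmented deterministically: a 3×3 median filter
(a vectorized sorting-network implementation), a global Otsu threshold,
morphological opening with a 3×3 disc, and removal of 8-connected
components below 50 px. Each stage is parameterized and can be disabled;
an inversion flag handles dark-on-bright sources symmetrically. A
constant image yields an empty mask with a warning rather than an error.

Delineation assumes a single dominant lesion (multifocal CNV is out of
scope): the largest 8-connected component is kept together with any
component intersecting its 20 px dilated envelope, and the analysis region
is the filled convex hull of the retained flow. The hull is the VD
denominator by design; a bounding-box denominator would systematically
lower VD for oblong lesions, and the hull is the tighter convex region
that does not presume lesion shape. SA counts flow pixels only, never the
hull, so SA is additive over disjoint components.

### Skeletonization

Centerlines are extracted with Zhang–Suen parallel thinning (no installed
image package provides 2-D topological thinning, so the package carries
its own vectorized implementation). The skeleton is a subset of the mask
and preserves the number of 8-connected components, which the test suite
checks on both geometric fixtures and synthetic lesions.

### Multi-origin box counting

Box sizes follow the power-of-two series R = 2, 4, …, up to the largest
power of two not exceeding half the smaller image dimension (reading
"half image size" as half the side length; fewer than three sizes is an
error). For each size the grid is evaluated at four deterministic origin
offsets — (0,0), (R/2,0), (0,R/2), (R/2,R/2) — and the per-origin
occupied-box counts N(R) are fitted by OLS of log N on log R; the
reported FD is the mean of per-origin slopes (a minimum-count aggregation
is a documented alternative). FD is clipped to [0, 2] with a flag.

One numerical choice deserves emphasis. A naively shifted grid adds
partial boxes at the image edges: a filled square then reads
(S/R + 1)² boxes instead of (S/R)² at shifted origins, which biases the
fitted slope to ≈1.93 — a bias that does *not* vanish with image size,
because the largest box (R = S/2) always inflates 2 → 3 boxes per
dimension. The package therefore anchors one tiling of ceil(W/R) ×
ceil(H/R) boxes at the image origin and lets shifted origins relabel
pixels cyclically (box index `((coord + offset) div R) mod n_boxes`).
Every origin then uses the same number of boxes, a translation-invariant
pattern gives identical counts at every origin, a filled square measures
exactly 2.0 and a straight line exactly 1.0, and subset monotonicity
(A ⊆ B ⇒ N_A ≤ N_B) holds exactly for patterns in the same raster.
Calibration on analytic fractals (Sierpinski triangle order 7, Koch curve
order 5) lands within ±0.08 of the similarity dimensions.

### Lacunarity

Box masses are recorded on the same grids as FD (the package assumes the
original analysis shared the grids; an independent gliding box is the
documented alternative), over all boxes intersecting the lesion bounding
box, empty boxes included. Masses are coverage-normalized — the pixel
count in a box is divided by the fraction of the bounding box the box
covers — so partial edge boxes do not masquerade as structural gaps and a
fully occupied region has Λ = 0 exactly at every size and origin.
Λ(R) = σ²/µ² per (size, origin) and LAC is the mean over sizes with
µ > 0 and origins; the plain σ²/µ² form is used rather than the 1 + σ²/µ²
variant.

## The synthetic data generator

No patient images or records are available, so the generator is a
first-class module that emulates the study conditions.

**Vessel trees.** A seeded stochastic branching process grows segments
from a central root: per-step branching probability, caliber decay per
generation (0.85, from a 60 µm trunk down to a 6 µm floor), per-generation
length decay, direction wander, and a single `complexity` knob in [0, 1]
that drives branching density and depth. Growth stops at a total
centerline length budget of 165 mm per mm² of lesion area, which keeps
the space-filling fraction — and therefore the measured FD at a given
complexity — roughly independent of lesion size. At complexity 0 the tree
is a single unbranched trunk chain. Anti-VEGF pruning is modeled by
`prune_tree()`: segments below a caliber threshold are removed with their
descendants, the trunk always survives.

**Rasterization.** Segments are drawn as anti-aliased strokes of width
caliber/pixel-pitch (clamped at 1.3 px so capillaries stay resolvable on
the 320 px / 4.5 mm grid of a swept-source en-face scan), composited by
maximum, with multiplicative-plus-additive speckle at a configurable
fraction of the dynamic range, quantized to 8 bits.

**Calibration.** The mean measured FD and fill factor as functions of
complexity (measured once on a seeded grid at 0.8 mm radius) are stored
as an interpolation table that inverts a target (FD, SA) draw into
(complexity, radius). Measured skeleton FD saturates near 1.30–1.5 at
clinical lesion scales — a genuine property of box counting on curvilinear
skeletons confined to a small fraction of the raster — so high-FD draws
compress onto the upper end of the measurable range; the monotonicity
property (Spearman ρ > 0.9 of FD and SA against complexity) is therefore
validated on the generator's monotone operating range, complexity 0–0.6,
which is the range the cohort mapping uses.

**The TAE cohort.** Baseline FD is truncated-normal on [1.2, 1.6] around
1.47 (SD 0.08) and baseline SA log-normal with median 0.62 mm² and IQR
matched to 0.28–1.52 (σ_log = 1.25). A per-visit Bernoulli activity
process has logistic log-odds α₀ + β_FD (FD − 1.47) + β_logSA (log SA −
log 0.62), with defaults α₀ = −0.65, β_FD = −22, β_logSA = −1.2: smaller,
less complex lesions are more active, so both couplings are negative; a
serial carry-over term is exposed but off by default (no serial
correlation). The TAE schedule loads at weeks 0/4/8, starts its interval
at 8 weeks, steps by ±2 weeks between 4 and 12, and treats at every
visit. Only the ±2-week rule is externally fixed; the other schedule
constants are configuration keys whose defaults make an always-inactive
patient receive exactly 7 injections in year one (weeks 0, 4, 8, 16, 26,
38, 50) and an always-active patient 12 — reproducing the observed median
(7) and maximum (12). α₀ and the couplings were calibrated once, on
table-level simulations, so that the median injection count is 7, the
regular-burden fraction ≈ 44%, and the burden-class separation of
baseline FD/SA matches the observed group medians; they were not adjusted
afterwards. BCVA (integer ETDRS letters, clamped to [0, 100]) and central
macular thickness trajectories are built so that roughly 63% of patients
are good anatomic responders and 63% good functional responders, with a
19% dropout rate before month 12; burden is classified for completers
only, as the cutoff is defined over a full year of observation.

Imaging assessments occur at baseline (twice, for repeatability), week 12
and week 52: the baseline tree, its pruned version (responders lose the
two finest caliber levels, others one) and a regrown, slightly enlarged
lesion. The 3-month evaluation falls between TAE visits, so assessments
are a separate table from injection visits — every injection-visit row
has `injection = TRUE`, preserving the treat-at-every-visit invariant.

**What passing tests do and do not show.** The generator reproduces the
marginal distributions, effect directions and magnitudes of the target
cohort profile, but real OCT-A data differ in ways the simulation does not
attempt: projection artifacts, signal loss under pigment epithelium
detachments, motion artifacts, vessel loops/anastomoses (the generator
produces trees), and measurement error that correlates with disease state.
Green tests validate the estimators and the pipeline logic, not device
physics.

## Outcomes

* Activity at a visit: ≥5-letter BCVA loss with intra/subretinal fluid, or
  macular hemorrhage, or fluid at two consecutive visits, or a CMT
  increase with fluid.
* Anatomic response (after the loading dose): good iff fluid fully
  resolves or CMT decreases by more than 100 µm. The two clauses overlap
  when fluid resolves but CMT falls ≤ 100 µm; resolution takes precedence
  (good), because the good-responder definition is disjunctive. At exactly
  100 µm the response is bad (the good clause requires *more than* 100).
* Functional response: ≥5-letter gain at 12 months; undefined for
  non-completers.
* Burden: ≥8 injections before week 52 is regular, ≤7 extended; the
  horizon is configurable.

## Statistics

* **ICC**: two-way mixed-effects, absolute-agreement, mean-of-2
  ICC(A,k) from the ANOVA mean squares, with the F-based McGraw–Wong
  interval for ICC(A,1) stepped up by Spearman–Brown (the interval method
  is a package choice; duplicated repeats give exactly 1 with a
  degenerate interval).
* **Paired tests**: exact signed-rank null up to n = 25 non-zero
  tie-free pairs (normal approximation beyond), exact binomial sign test;
  zero differences dropped, all-zero data gives p = 1 with a warning.
* **Mann–Whitney**: exact for tie-free groups of ≤12 each, otherwise the
  tie-corrected normal approximation. The U statistic equals
  AUC · n₁ · n₂ on tie-free data, which the tests assert as an identity.
* **Binary GLMs**: logistic regression with Wald intervals; the odds
  ratio is reported per configurable predictor unit (0.01 FD units by
  default — an FD odds ratio quoted per full FD unit would be absurdly
  small, and the unit only rescales reporting, never the fit). Partial
  log-odds functions use a natural (restricted) cubic spline basis
  (df = 3 by default) anchored at the median predictor value with
  pointwise Wald bands; the linear fit supplies the OR table.
  Quasi-separation is flagged and the interval reported unbounded.
* **ROC/AUC**: rank-based AUC with DeLong intervals (via pROC), fixed
  direction (cases score higher), qualitative bands: >0.80 very good,
  0.70–0.80 good, 0.50–0.70 weak.

No multiplicity correction is applied, matching the analysis this package
reproduces.

## Problem sizes and determinism

Every stochastic step takes an explicit seed and restores the caller's
RNG state; identical configuration and seed give byte-identical tables,
images and result JSON, which an acceptance test asserts. The shipped
validation uses a 64-patient cohort with ~250 images of 320×320 px, 200
null cohorts for type-I calibration and 200 cohorts of n = 200 for Wald
coverage — sizes chosen to match the emulated study's scale while keeping
the whole suite comfortably desk-runnable.

## Known limitations

* Measured skeleton FD saturates near 1.5 on 320 px rasters; between-patient
  contrast in measured FD is partly mediated by lesion size.
* Lacunarity magnitudes on synthetic skeletons (≈1–9) are not calibrated
  to any particular instrument's scale; only identities and orderings are
  asserted.
* The activity process is a statistical stand-in (logistic Bernoulli), not
  a biophysical model of VEGF dynamics; fluid is a flag, not a geometry.
* Tall pigment-epithelium-detachment shadowing, projection artifacts and
  multifocal lesions are out of scope.
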