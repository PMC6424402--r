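---
title: "Quantifying polar flagellar ejection: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polar flagellar ejection: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(flagrelics)
```

Polarly flagellated γ-proteobacteria (*Plesiomonas*, *Vibrio*,
*Shewanella*, *Pseudomonas*) shed their Na⁺-driven flagella when
nutrients run out, leaving "relic" ring structures in the outer
membrane. Establishing that picture quantitatively requires several
small, bespoke analyses: spatial statistics of motor/relic placement at
the cell pole, population-level flagellation accounting, statistics of
where shed filaments break, swim-track velocimetry, periplasmic
morphometrics, and symmetry/correlation operations on cryo-ET
subtomogram averages. This vignette documents how `flagrelics`
implements each of them, which parameters matter, and what the
synthetic-data generators do and do not emulate.

## Spatial statistics of pole patterns

### The Clark–Evans ratio and the pole-area convention

The dispersal statistic is the Clark–Evans nearest-neighbour ratio

$$R \;=\; \frac{\bar d_{\mathrm{NN}}}{1/(2\sqrt{\rho})},$$

the observed mean nearest-neighbour distance over its expectation under
complete spatial randomness at density $\rho = n/A$. $R \approx 1$
indicates randomness, values between 1 and the hexagonal-lattice maximum
2.1491 indicate a uniform grid, and $R < 1$ indicates clustering.
Motors and relics are pooled for the statistic: both occupy the same
placement grid (per-label histograms remain available via
`nnHistogram()`).

The pole area $A$ follows the max-coordinate ellipse convention:
coordinates are re-centred and the ellipse semi-axes are the maximal
absolute centred x and y plus one C-ring diameter (45 nm, the steric
footprint of a motor), so the outermost structures' footprints are
inside the ellipse. The annotation origin is not meaningful in the
source data, so the package re-centres on the point **centroid**; this
is a package convention, recorded in the `poleGeometry()` output.
Poles with fewer than `minStructuresPerPole = 5` structures ("more than
four") are excluded, and exclusions are reported rather than silently
dropped.

No edge correction is applied. The uncorrected ratio is biased for
small $n$ in a bounded window, which is why the null model matters: the
constrained random cohort (`synthesizeNullCohort()`) is pushed through
the *identical* measurement — including re-deriving the ellipse from
the synthesized points rather than reusing the generating ellipse — so
data and null share whatever bias the procedure has.

```{r ce-null}
templates <- lapply(1:20, function(k) {
  simulatePole(patternModel("grid", sample(5:10, 1),
                            semiAxes = runif(2, 150, 300),
                            latticeSpacing = 64, jitterSD = 6),
               poleId = paste0("tmpl", k))
})
nulls <- synthesizeNullCohort(templates, nPoles = 500, seed = 2)
ceCohort(nulls)$cohortMean
```

### Why the null templates are grid-like

The null cohort is "constrained by the same number of structures and
pole area as the real data", so the templates must resemble real poles.
Observed poles are hexagonal-grid-like with a mean nearest-neighbour
spacing of 64 nm and 5–10 structures, which puts their
convention-measured areas around 3–5 × 10⁴ nm². The template generator
therefore uses the grid model at 64 nm spacing (6 nm jitter) clipped to
pole ellipses with semi-axes in 150–300 nm. At these pole areas the
uncorrected null calibrates to a cohort mean of ≈ 1.0, which is the
behaviour the statistic needs for the data/null comparison to be fair.
Uniform-filled templates on much larger ellipses would instead show the
uncorrected small-$n$ bias directly (cohort means of 1.2 and above at
$n \le 10$): the calibration is a property of the *procedure at the
data's scale*, not of randomness in general.

### Pattern generators

All generators are deterministic given `(parameters, seed)` and place
exactly `nPoints` points inside the model ellipse:

* **uniform** — complete spatial randomness (the null).
* **hardcore** — random sequential adsorption with a 45 nm exclusion
  diameter (one C-ring) and a retry cap of 10⁴ per point; saturation is
  an error reporting the achieved count. This encodes the
  steric-clash-only hypothesis: `expectedNNHardcore()` shows such
  packings have mean spacing barely above 45 nm, well short of the
  observed 64 nm.
* **grid** — the `nPoints` hexagonal lattice sites closest to the pole
  centre, with isotropic Gaussian jitter (resampled while outside the
  ellipse). Hexagonal because it is the lattice the Clark–Evans maximum
  2.1491 refers to.
* **cluster** — a Thomas process (uniform parents, Gaussian offspring),
  the standard $R < 1$ alternative; any clustered generator would do.

## Population accounting

`meanFlagellaCI()` gives the Student-t interval on per-cell counts
(pooled across replicates by default, per-replicate averaging
available). `absoluteFlagella()` scales the mean by CFU × volume; CFU
uncertainty is not propagated because none is reported for it — the
interval reflects the count uncertainty only. `occupancyPercentages()`
recomputes pole occupancy classes (both / filaments only / relics only /
neither) from per-pole or aggregated counts; the printed class counts at
OD 0.25 and OD 1.0 ship in
`inst/extdata/pole_occupancy_counts.tsv`.

The simulator (`simulatePopulation()`) is an exact event-driven
birth–death process per cell on top of logistic culture growth, in two
modes: **polar_ejection** (per-flagellum ejection at rate
`ejectionRate` once OD passes `triggerOD`) and
**peritrichous_dilution** (no ejection; a tracked lineage keeps a
Binomial(k, ½) share at each division). The published record gives no
rates, so defaults were chosen once for qualitative realism and are
flagged in the configuration: growth ln 2/(19 min) ≈ 2.19 h⁻¹ (the
printed fresh-medium doubling time), trigger OD 0.8 (where swimming
collapses), initial counts Poisson(5) (≈ 5 filaments per flagellated
pole at low OD), assembly 0.5 cell⁻¹ h⁻¹ and ejection 2 flagellum⁻¹ h⁻¹
(fast enough that loss outpaces assembly after the trigger). The mean
trajectory of the process obeys $\dot m = a - e\,m$, which the test
suite uses as an independent oracle.

### Hook-end statistics

A filament has two ends and carries a hook on exactly one of them iff
it was released at the hook–rod junction. Exhaustive enumeration over a
base-of-hook population therefore gives a hooked-end fraction of
exactly ½ — the fingerprint of determinate ejection — while
mid-filament shearing gives 0. `hookEndFraction()` enumerates all ends
by default and samples uniformly without replacement when
`endsSampled` is smaller.

### Swim tracks

`trackSpeed()` is path length over elapsed time (net displacement is
reported alongside); for 10 s tracks of run-dominated swimmers the two
are close, and path length is robust to curvature. The motility
threshold for "active swimmer" is not stated in the source data;
the package default is 5 µm/s, configurable and echoed in the summary
output. The track generator draws a constant ground-truth speed per
track and bends the heading by Gaussian noise per frame, so the
path-length estimator recovers the configured speed exactly in the
noiseless limit — a deliberate design so parameter-recovery tests are
sharp.

## Periplasmic morphometrics

`summarizeDistances()` reports n, mean, median, quartiles
(linear-interpolation convention, `quantile` type 7 — fixed so results
are bit-reproducible) and the range (max − min) of
inner-membrane-to-outer-disk distances per structure class.
`compareRanges()` reports only the difference and its direction — the
published comparison (ranges of 13.9 nm at relics vs 7.9 nm at motors)
is descriptive, so no test statistic is attached. The simulator draws
from uniform distributions parametrised by (mean, full range), making
the configured range the large-sample limit of the observed one.

## Density-map operations

Maps are `DensityMap` objects (3D voxel array + per-axis voxel size in
nm) read and written as little-endian mode-2 MRC2014. Lengths are
Ångström in MRC headers and nm everywhere inside the package; the
conversion happens once at the file boundary (2.713 Å pixels become
0.2713 nm voxels). Anisotropic voxels are accepted at input with a
warning but rejected by the symmetry operations — rotational averaging
assumes isotropy; resample first.

* `rotationalSymmetrize(map, n)` averages over the cyclic group about z
  through the grid centre, with bilinear in-plane interpolation (the
  identity term is taken verbatim). On phantoms with voxel-scale
  features the interpolation error is at the percent level (relative
  RMS ≲ 0.05 for invariance/idempotence checks); sub-10⁻³ agreement
  would require Fourier-space rotation, which is out of proportion for
  C-n averaging of subtomogram averages.
* `detectSymmetryOrder()` averages an azimuthal profile over an annulus
  band and z window, Fourier-transforms it, and returns the candidate
  order (default 2–20) with maximal power. Profiles with relative
  modulation below 2% are declared rotationally smooth (`NA` +
  no-symmetry flag) rather than assigned an arbitrary order; the
  threshold sits well above the ~0.1% azimuthal ripple that grid
  interpolation introduces and well below the ≥ 40% modulation of a
  subunit ring.
* `fsc()` computes per-shell normalized cross-correlation of Fourier
  coefficients, shells one Fourier voxel thick; `resolutionAt()` takes
  1/frequency at the first crossing below the threshold (0.5 by
  convention here), linearly interpolated between shells, and returns
  `NA` with a warning when the curve never crosses (beyond Nyquist).
* `compositeMerge()` is the masked weighted average
  $(w_t T + w_b B)/(w_t + w_b)$ used to stitch independently refined
  top-ring and cytoplasmic averages; zero-weight voxels become the
  solvent value and are counted. The exact masks used in published
  composites are unpublished; only the merge contract is implemented,
  with `softZMask()` providing cosine-edged z masks.

### Phantoms

`buildPhantom()` realises the printed motor/relic geometry as a
synthetic map: an outer-membrane slab pierced by a 15 nm aperture, a
44 nm T-ring 19 nm below it with `nSubunits` azimuthal bumps (13 in
vivo; 1 means an unmodulated, rotationally smooth ring), and optionally
a plug density (1.5, above membrane level) occluding the aperture — the
relic state, since no relic was observed without a plug. Edges are
erf-smoothed with SD one voxel so half-maximum crossings sit exactly at
the specified geometry, and the membrane is confined to the inscribed
cylinder so rotations never push density off the grid. SNR is defined
as the RMS of the non-zero noise-free voxels over the Gaussian noise
SD. `measureRing()` inverts the construction from the map alone (axial
profile peaks for the offset, radial profile peak for the ring, half
plateau crossing for the aperture, with parabolic sub-voxel
refinement), recovering the 44/19/15 nm geometry within one voxel and
reporting plugged apertures as occluded.

What the phantoms deliberately do **not** emulate: tomographic
projection artifacts (missing wedge, CTF), alignment errors, or the
heterogeneity of real subtomogram sets. Passing phantom tests therefore
validates the post-processing operations, not the upstream
reconstruction pipeline.

## Problem sizes and reproducibility

The default analysis and test sizes — 500-pole null cohorts, 100-pole
cluster cohorts, 150–400 simulated cells, 56³ phantoms — are the sizes
the corresponding desk-scale analyses themselves use; the whole test
suite and the acceptance script run in well under a minute each on one
core. Every stochastic function takes an explicit seed and restores the
caller's RNG state; a `runConfig` fixes the seed and analysis constants
for a pipeline run, and the CLI wrapper logs the seed, a config
fingerprint, and input checksums for every stage, so two runs with the
same configuration and inputs are byte-identical.

## Known limitations

* The Clark–Evans procedure has no edge correction by design; absolute
  per-pole ratios carry small-sample bias and are only interpretable
  against the matched null cohort.
* The cohort size of the original pole data set is reported
  inconsistently in its source (70/71/74); the package always reports
  its own included-pole count alongside the cohort mean.
* Population-model rates are illustrative; only qualitative contrasts
  (decline after trigger vs. dilution) are meaningful.
* `readDensityMap()` supports MRC modes 0, 1 and 2 with default axis
  order only.
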