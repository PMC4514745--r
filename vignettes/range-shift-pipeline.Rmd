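---
title: "Projecting species range shifts with stacked presence-only envelope models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting species range shifts with stacked presence-only envelope models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Archived, presence-only occurrence records (museum and aggregator data) are
the only distribution evidence available for most small-bodied vertebrates at
regional scales. `sdmshift` implements a complete pipeline from such records
to projected range change under an altered future environment: bioclimatic
envelope models are fitted per species against environmental covariates,
projected onto two time slices of those covariates (a current slice and a
future slice in which the "dynamic" covariates have been updated), and the
resulting per-species maps are stacked into biodiversity composites and
community-assemblage structure. The modelling assumption throughout is niche
conservatism: the fitted envelope is held fixed and only the environment
moves.

## The model and its stages

**Occurrence handling.** Coordinates reported with fewer than five decimal
places (in longitude/latitude mode) are discarded, and records are spatially
thinned to at most one record per species within a 1-km radius, which damps
the strong collection-site clustering typical of archived data. Thinning is
greedy in a deterministic order — records sorted by (species, catalogue id,
x, y), first of each conflict cluster kept — because which duplicate survives
is otherwise arbitrary and reproducibility matters more than any particular
choice. Two records conflict when their separation is at most the radius, so
exact duplicates are the degenerate case of the same rule.

**Target-group pseudo-absences.** Presence-only data carry no absences, so a
surrogate is constructed from the records themselves: every unique location
holding a record of some *other* species, with no record of the target
species within 1 km, becomes a pseudo-absence. Sites visited by collectors
who found only non-target species are the best available evidence of
detectable absence, and they inherit the survey-effort geography, which
partially cancels sampling bias on both sides of the classifier. Class sizes
are left unbalanced — the per-species presence/absence ratios of real
archives vary by two orders of magnitude and the classifier sees that
imbalance honestly.

**Envelope model.** The per-species classifier is a bagged ensemble of
classification trees with per-split feature subsetting (random forest,
via the randomForest package), grown to at least 500 trees with library
defaults otherwise. Evaluation is out of bag: each point is scored only by
trees that did not sample it, giving an internally cross-validated AUC,
class-wise correct fractions at the symmetric 0.5 vote threshold, and pooled
accuracy. The class-wise fractions carry neutral names
(`frac_presence_correct`, `frac_absence_correct`) because the
sensitivity/specificity labels are applied inconsistently in parts of the
applied literature. Variable importance is permutation importance on the
out-of-bag points rather than split-impurity importance, which is known to
inflate covariates with many categories.

**Projection and smoothing.** The fitted ensemble is applied to a regular
5-km lattice of points attributed with both covariate slices; static layers
must be bit-identical between slices (this is validated, not assumed). The
ensemble presence-vote fraction at each point is the relative index of
occurrence (RIO), a ranking in [0, 1] — deliberately never relabelled a
probability, since vote fractions are not calibrated. Lattice predictions
are interpolated to a 1-km raster by inverse-distance weighting (power 2, 12
nearest neighbours — the common GIS defaults; both configurable). IDW is a
convex combination, so RIO bounds survive smoothing, and the surface is
exact at the lattice points. The neighbour-count form of IDW was chosen over
a fixed search radius; the choice is surfaced in the configuration.

**Change analysis.** Surfaces are thresholded at RIO ≥ 0.5 into binary
ranges; the two slices partition each species' map into loss, gain,
persistence and absent. Shift metrics per species: presence areas per slice,
net change, two percent-change formulations reported side by side (net
change over the first-slice area, and turnover — changed pixels over the
second-slice area — because published tables in this literature are not
always derivable from one formula), and shifts of the median pixel-centre
northing, median elevation and median coast distance of presence pixels.
Deltas are future minus current, divided by 9 decades for per-decade rates.
Areas and medians are computed on the 1-km smoothed raster, not the 5-km
lattice. Empty presence sets leave metrics `NA`, never zero.

**Composites and communities.** Binary ranges are summed cellwise into
richness maps per slice; their difference (ΔBio) and the difference of the
cellwise mean RIO across species (ΔRIO) summarise net biodiversity movement.
Drivers of a composite are ranked by a tree-ensemble regression of the
composite at the lattice points on the covariates, again with permutation
importance. Community structure is derived by sampling 50,000 uniform random
points, correlating species' RIO values there (pairs with Pearson r ≥ 0.25
classified likely co-occurring, r < −0.25 exclusive — boundary conventions
are inclusive on the positive side, strict on the negative), and clustering
species on the dissimilarity 1 − ρ² (squared Spearman correlation) with
complete linkage — the classical variable-clustering construction. Because
the source analyses do not state a correlation flavour or linkage, both are
options, not constants. Group labels are arbitrary, so memberships are
compared across slices after matching groups by maximal Jaccard overlap
(greedy, ties broken lexicographically and flagged); a pure relabelling
reports no change.

## The synthetic study system

Everything above is testable only if the truth is known, so the generator
builds landscapes where it is. Fields are analytic — a linear south-to-north
trend plus a fixed sum of low-frequency cosine waves — evaluated on a planar
equal-area grid in km ("latitude" is northing, matching the km units in
which range shifts are reported). The future slice evaluates each dynamic
field at `(x, y − drift_km)` plus an optional additive offset, so the
imposed drift is exact at any resolution. A species' true occurrence
probability is a product of per-layer Gaussian (bell) responses — smooth,
unimodal, the standard simulation choice, and learnable by tree ensembles.
Records are drawn proportional to that probability (optionally times a
sampling-bias field that affects only where records are collected, never the
truth) and jittered within cells.

The default scenario — the study conditions for all end-to-end tests — is a
160 × 160 km landscape at 1-km resolution with two dynamic layers
(temperature-like, cooling northward ~0.1 units/km; growing-season-like) and
two static layers (elevation-like terrain; coast distance, also the terrain
inputs of the shift metrics), a 15-km northward drift (three lattice
spacings), and four species sampled 400 records each: a specialist tracking
the dynamic gradient (its fitted range must move ~15 km north), a specialist
on static terrain (control: it must not move by more than one lattice
spacing), a broad generalist, and a warm-edge species. Several species are
always simulated together so the target-group pseudo-absence rule has
non-target records to draw on.

Two generator choices deserve their rationale. First, the elevation field
uses wavelengths of 30–70 km — several oscillations across the extent — so
terrain structure is identifiable from the latitudinal climate trend; with
near-extent-scale wavelengths a realisation can be almost collinear with the
dynamic gradient, and the static-control species then has no identifiable
static driver for the ensemble to find. Second, sampling draws cells with
replacement, so the effective number of unique presences after 1-km thinning
(~360–380 of 400 draws) is what the training set sees, mirroring how
duplicate archive records collapse.

What the generator does *not* emulate: real collection-effort geography
(roads, rivers, towns), categorical covariates (their registry handling,
native factor presentation to the learner, and routing of labels unseen at
training to the largest training category are exercised with hand-built
stacks in the unit tests), observation error in coordinates beyond cell
jitter, and interannual variability. Passing end-to-end tests therefore
demonstrates that the machinery recovers a known signal under clean
conditions — not that real archived data meet those conditions.

## Numerical choices and degenerate inputs

* Thresholds are inclusive where the conventions say so: RIO ≥ 0.5 is
  presence; correlation ≥ 0.25 co-occurs; < −0.25 excludes.
* AUC is the Mann-Whitney rank statistic with ties split; points never out
  of bag (essentially impossible at 500 trees) are excluded with a count.
* A cell coincident with a lattice point (squared distance < 1e-18) takes
  the point's exact value in IDW.
* Grid alignment uses exact origin/resolution/dimension equality; static
  layers must be bit-identical between slices.
* Single-class or nearly empty training sets, all-zero sampling surfaces,
  constant composites, and degenerate (zero-variance) RIO surfaces are
  errors or flagged exclusions, never silent zeros.
* All randomness flows from one top-level seed via fixed per-stage offsets,
  so each stage is individually reproducible and reruns produce
  checksum-identical artifacts.

## Problem sizes

The default scenario sizes keep a full pipeline run (four species, two
slices, 1,089 lattice points, 25,600 output cells) around half a minute on
one core; the five-seed recovery experiment runs in about two minutes. The
community sampling default of 50,000 points is capped at ten points per
unmasked cell on small synthetic masks, where fewer points already give
correlation estimates within 0.01 of the full-raster value.

## Known limitations

* Raster I/O is plain-text headered ASCII grid; the container is a
  lightweight matrix-plus-geometry class, adequate for the planar
  equal-area frames used here but not a general GIS substrate.
* Longitude/latitude inputs are supported for the occurrence operations
  (great-circle distances); raster math is planar only, so geographic
  rasters must be projected upstream.
* The pipeline models each species independently: no dispersal limits,
  no biotic interactions, no adaptation — the usual envelope-model caveats
  apply to any ecological reading of its outputs.
* Percent-change conventions differ across published tables; both supported
  formulations are reported, and published tables are treated as data, not
  re-derived.
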