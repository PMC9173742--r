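---
title: "Quantifying local and long-range rabies-labeled inputs to VTA dopamine neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local and long-range rabies-labeled inputs to VTA dopamine neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Monosynaptic rabies tracing labels the presynaptic partners of a defined
starter population — here, dopamine (DA) neurons of the ventral tegmental
area (VTA) expressing a mutant TVA receptor (TC66T, mCherry-fused) and the
rabies glycoprotein. Because wild-type TVA leaks enough in Cre-negative
cells to seed thousands of spurious local infections, inputs near the
injection site have historically been unquantifiable; the attenuated TC66T
receptor reduces that background to a handful of cells per brain and makes
the local input landscape measurable. The quantitative questions this
package answers, given per-cell tables (region, hemisphere, coordinates,
marker flags), are:

* what fraction of inputs lies in each of 57 quantified regions, and how do
  local and long-range inputs split;
* how efficient was tracing (the convergence index: long-range inputs per
  starter cell);
* where GABAergic, DAergic and serotonergic inputs arise (marker-conditional
  maps with per-10,000 normalization);
* which input regions covary across brains (ensemble embedding, aggregated
  distances, hierarchical clusters), and whether two cohorts are comparable
  (mixing diagnostic);
* how axonal innervation from an input region distributes along the VTA
  medial–lateral axis (100-bin intensity profiles).

Every stage is exercised end-to-end on a synthetic cohort generator that
emulates the statistical structure of such experiments, so the pipeline is
testable without any external data.

## The region catalog

The catalog (`load_default_catalog()`) fixes the frame of reference: 57
regions, 22 long-range and 35 local, with midline flags (DR, RMg, MnR —
their left/right populations cannot be separated), VTA-subnucleus flags
(PBP, PN, IF, Rli) and serotonergic B-group annotations (B3 = RMg,
B5 = PnO, B6 = mRT, B7 = DR, B8 = MnR, B9 = PMnR). "Local" follows the
tracing convention: within ~1 mm of the injection site, plus the posterior
ventral midbrain regardless of distance. The PAG is classed local, in line
with its appearance among the lateral-projecting local cluster.

Two reconstruction caveats are deliberate and documented rather than
hidden. The published record never prints the 22-region long-range list in
one table; the shipped list is assembled from the cluster narratives and
the precursor studies' region sets, and ships as a versioned CSV so edits
are configuration, not code. Likewise the carrier regions for the B5 and
B9 serotonergic groups ("pons" and "pontine tegmentum") are mapped once to
PnO and PMnR.

## The synthetic cohort model

`generator_config()` / `generate_cohort()` implement a hierarchical
counting model per brain:

1. starter count uniform on [900, 2400], assigned to subnuclei at
   58/27/5/8/2% (PBP/PN/IF/SNc/Rli);
2. long-range input total Poisson(convergence index × starters), with the
   convergence index defaulting to 8; the local total is Poisson with mean
   chosen so the expected local share is `local_fraction` (default 0.46),
   giving ~23,000 inputs per brain at the defaults;
3. region counts multinomial within each locality class around a default
   composition whose pinned entries are back-solved from printed totals
   (VTA subnuclei ~10% of all inputs, substantia nigra ~6%, DR ~10% so
   that its Tph2+ cells land at ~376 per 10,000) and whose remaining
   entries are plausible fill, normalized within class;
4. between-brain covariance from a projection-archetype mixture: each
   region loads 0.9 on one of three archetypes (lateral / uniform /
   medial, the cluster structure reported for this circuit) and 0.05 on
   the others; each brain draws a Dirichlet(2, 2, 2) archetype mixture
   that multiplies the composition, with additional multiplicative
   log-normal noise of SD `noise_scale` (default 0.1);
5. marker flags Bernoulli per region: GAD rates back-solved so the
   expected GABAergic composition matches the printed per-region shares of
   local inhibition (SNr 20.1%, VTA PBP 19.3%, SNc 10.5%, ...); TH 0.40 in
   the VTA subnuclei, SNc and RRF; Tph2 between 0.20 and 0.37 across the
   B-groups with the DR highest;
6. coordinates (x medial–lateral, y dorsal–ventral, z anterior–posterior,
   micrometres) for starters (Gaussian around the right-hemisphere
   injection site) and local inputs (region-flavoured uniform boxes);
   long-range inputs omit coordinates. The third coordinate goes beyond a
   minimal 2-D cell record because the DA-connectivity regions of interest
   are defined by anterior–posterior × medial–lateral predicates.

Cre-negative control brains are Poisson draws (means 2.67 for TC66T, 3183
for wild-type TVA, ~0 with no AAV) placed uniformly over local regions.

What the generator does *not* emulate: spatial point-process structure
within regions, atlas-registered geometry, anisotropic injection spread,
section-level censoring, or any anatomical realism beyond the counting
model. Passing tests therefore demonstrate that the pipeline's arithmetic,
filtering rules and statistical machinery recover planted parameters — not
that the biological conclusions would replicate on new animals.

## Counting conventions

* Starters are never inputs, whatever their markers; fractions exclude
  them from numerator and denominator.
* Fractions use either all 57 regions or the long-range set as
  denominator; rows sum to 1 in the former case by construction.
* The convergence index counts only long-range inputs, which keeps it
  comparable across TVA variants with different local background.
* Midline regions are never split by hemisphere; ipsi/contra are defined
  relative to the recorded injection hemisphere (right).
* Ellipse summaries use coordinate means and per-axis sample SDs (n−1);
  SEMs are sample-SD based throughout.
* Group comparisons use the pooled-variance unpaired t-test (equal-n
  design); Welch is available as an option.
* Regions or ROIs with no eligible denominator cells yield missing values,
  not zeros, and drop out of cross-brain means.
* The TVA-spread sphere for the DA–DA map has no published radius; the
  default 500 µm is an assumption exposed as a parameter, as are the ROI
  boundaries (AP −3600 µm, ML 500 µm).

## Embedding, aggregation, clustering

Fractional counts are z-scored per region across brains (sample SD;
zero-variance regions become all-zero rows with a warning, and are kept).
UMAP (via `uwot`) embeds the 57 region points once per seed — defaults: 20
embeddings, seeds 0–19, `n_neighbors = 10`, `min_dist = 0.1`, Euclidean
metric, single-threaded so each embedding is an exact function of its
seed. Because individual embeddings are stochastic, each one is reduced to
its pairwise-distance matrix normalized by that embedding's maximum
distance, and the ensemble is averaged element-wise. The aggregated matrix
is symmetric, zero-diagonal and bounded in [0, 1] by construction, and is
what gets clustered: agglomerative, average linkage (Ward is not
meaningful on these non-Euclidean aggregated distances), with k chosen
from 2–6 by mean silhouette unless fixed. Automatic selection is the
tested default precisely so the "three clusters" outcome is a finding of
the procedure, not an input to it.

The original embedding hyperparameters were "tuned manually" and are
irrecoverable; the defaults above were chosen once for stability on the
synthetic model and all are exposed in the API.

### Recovery experiments and problem sizes

Parameter-recovery tests run at sizes where Monte-Carlo error is well
below the tolerance being asserted: 50-brain cohorts for composition,
local-share, starter-mix and co-label-rate recovery; 200 brains for the
convergence-index check (tolerance ±0.25). Planted-archetype recovery
(silhouette selecting k = 3, adjusted Rand ≥ 0.9) runs on 6-brain cohorts
at `noise_scale = 0.05`. Six rather than the study's four because of an
identifiability limit of the *synthetic design*, not the method: after
z-scoring, an n-brain region profile lives on an (n−2)-sphere, and with
n = 4 two of the three Dirichlet mixture centers are occasionally
near-collinear there, merging two planted clusters no matter how little
noise is added. At n = 6 the three centers are reliably distinguishable.

### The mixing diagnostic

Whether two cohorts can be pooled is judged in the other orientation:
points are brains, features are the jointly z-scored region fractions over
a chosen subset. The formal statistic is nearest-neighbor label purity —
the mean fraction of each brain's k nearest embedded neighbors that come
from the same cohort — reported against its analytic chance level and a
permutation null (labels shuffled over brains, embeddings fixed). The
published analysis made this judgment visually; the statistic is this
package's formalization of it.

## Innervation profiles

`extract_band_profile()` reproduces the measurement convention of an
interactive line tool: a line from the midline point laterally through the
VTA, sampled at unit arc-length steps, each sample the mean of `thickness`
bilinear interpolants spaced one pixel apart along the perpendicular. The
exact interactive kernel is unrecoverable, so the implementation is pinned
instead to a brute-force pixel-enumeration oracle in the tests. Raw
profiles are resampled into exactly 100 bins — bin j takes samples i with
(j−1)n/100 < i ≤ jn/100, in exact integer arithmetic; shorter-than-100
profiles are first up-sampled by linear interpolation — then normalized to
the image maximum (image-level profiles peak at exactly 1). Averaging
moves up the hierarchy (3 images → brain, 3 brains → region, 3 regions →
cluster); averaged profiles peak at ≤ 1. Bin 1 is the midline, bin 100 the
lateral terminus; pixel coordinates are 1-based (row, column). Thickness
is interpreted in pixels.

## Degenerate inputs and numerical choices

* Brains with zero inputs (or zero inputs under a denominator) error
  explicitly rather than produce NaN fractions.
* Zero starter cells make the convergence index and starter summaries
  undefined: explicit errors.
* All-zero profiles cannot be max-normalized: error.
* Coincident embedded points (maximum pairwise distance 0) make the
  normalized distance undefined: error.
* Composition weights must be nonnegative and sum to 1 within 1e-9;
  co-label rates must be probabilities.
* Every stochastic stage takes explicit seeds; a cohort is a deterministic,
  byte-for-byte reproducible function of (config, seed), and the full
  pipeline report reproduces exactly under a fixed master seed.

## Known limitations

* The long-range region list and the unpinned composition entries are
  reconstructions; analyses that depend on exact per-region identity
  beyond the pinned anchors should treat the defaults as illustrative.
* The generator's archetype model plants exactly three clusters; it cannot
  probe how the clustering behaves under continuous topographic gradients,
  which the real circuit likely has.
* Innervation profiles collapse the VTA to its medial–lateral axis; no
  dorsal–ventral or anterior–posterior structure is profiled.
* `uwot`'s UMAP differs in minor numerical details from the reference
  Python implementation; aggregated distances are stable across the
  ensemble but individual embeddings are not comparable across libraries.
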