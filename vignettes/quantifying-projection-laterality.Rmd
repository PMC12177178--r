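---
title: "Quantifying the laterality of descending axon projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the laterality of descending axon projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axolat)
```

## The problem

Descending projections from the somatosensory cortex reach the brainstem
through the corticobulbar/corticospinal tract and innervate target nuclei —
the principal (PrV) and spinal (SpVi, SpVc) trigeminal nuclei, the pontine
nuclei (P) and the facial nucleus (VII) — through side branches
(collaterals) that leave the main tract on both sides of the midline.
Whole-brain light-sheet imaging of cleared tissue yields 3D axon-probability
volumes (from CNN segmentation tools such as TrailMap) in which the question
"how strongly does this projection favour one hemisphere?" becomes a
geometric counting problem. `axolat` implements that quantification, from
raw probability volume to group comparison.

## The measurement model

The pipeline runs six stages, each a small, separately testable operation:

1. **Binarize.** Voxels with probability at or above a threshold are
   positive. The whole-brain segmentation contract uses 0.5; the stricter
   brainstem laterality analysis uses 0.95. The comparison is closed at the
   threshold, so the positive set is non-increasing in the threshold.
2. **Extract and downsample.** Each positive voxel's world centre (voxel
   `i`, 0-based, sits at `(i + 0.5) * voxel_size`) is mapped to the cell
   `floor(coord / 25 µm)` of an isotropic grid. Occupied cells are counted
   once (set semantics).
3. **Mask.** Cells outside the hindbrain mask are dropped.
4. **Partition.** A midline plane `ax + by + cz + d = 0` is fitted through
   three operator-chosen points on the midline; its unit normal is
   canonicalized toward the positive mediolateral axis so the
   signed-distance convention never depends on point order. Two planes
   parallel to the midline at signed distances `±w` bound a sagittal
   exclusion band that removes the corticospinal tract itself, which runs
   adjacent to the ventral midline; exclusion is applied before hemisphere
   assignment. Each remaining cell centre is `ipsi`, `contra`, or
   `on_plane` (exactly zero distance; counted toward neither hemisphere,
   since any assignment would bias a perfectly symmetric cloud).
5. **Summarise.** The lateralization index is
   `LI = (n_ipsi − n_contra) / (n_ipsi + n_contra)`: −1 for a maximal
   contralateral bias, +1 for a maximal ipsilateral bias, 0 for symmetry.
   Per-nucleus contralateral fractions `n_contra / (n_ipsi + n_contra)` are
   computed against a co-registered label atlas; hemisphere assignment is
   always the cell's own geometric side, because CCFv3-style atlases label
   nuclei symmetrically. Mediolateral profiles histogram signed distances
   divided by a reference length (so brains of different ages/sizes are
   comparable), with the midline mapped to normalized coordinate 0.5.
6. **Compare.** Per-brain metrics are summarised as mean ± SEM and compared
   across groups with a two-tailed unpaired Mann-Whitney test. For tie-free
   pooled samples of at most 20 the p-value is exact by full enumeration of
   all `choose(n1 + n2, n1)` group assignments, doubling the smaller tail
   (capped at 1); with ties or larger samples a normal approximation with
   tie and continuity corrections is used and flagged.

Single-cell companions: SWC reconstructions are classified
ipsi/contra/bilateral by the atlas regions their *leaf* nodes fall in, each
leaf taking its geometric side of the plane; retrograde soma tables are
counted per hemisphere, with cross-channel pairs closer than a pairing
radius treated as double-labelled (bilaterally projecting) cells, matched
greedily nearest-first.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| segmentation threshold | 0.5 | probability | whole-brain segmentation-mask contract |
| analysis threshold | 0.95 | probability | strict brainstem laterality analysis |
| analysis resolution | 25 | µm | isotropic downsampling pitch of the quantification |
| exclusion half-width `w` | 150 | µm | see below; covers the tract hugging the midline |
| profile bins | 100 | — | spans both hemispheres with the midline centred |
| density-map smoothing σ | 1 | cell | rendering kernel for averaged maps |
| neuron terminal threshold | 1 | terminals | one in-region terminal defines "projects to a side" |
| double-label pairing radius | 10 | µm | co-location tolerance of a two-channel soma |

Two of these deserve explanation, because the construction they make
explicit is genuinely under-determined in the field's written methods:

* **Exclusion half-width.** "Two sagittal planes parallel to the midline"
  defines a band but not its width. `axolat` exposes a single half-width
  `w` (default 150 µm at full resolution, strict inequality `|d| < w`), so
  the choice is visible, testable, and adjustable per brain.
* **Downsampling multiplicity.** Downsampling "coordinates of positive
  pixels" does not say whether a 25 µm cell hit by many raw voxels counts
  once or many times. The default is set semantics (once), which is stable
  across native scan resolutions; the same choice then defines "axon
  pixels" for the per-nucleus fractions, keeping them consistent with the
  LI computed on the same cloud.

## The synthetic world

No public imaging data accompanies this analysis, so the package ships a
phantom generator that is itself first-class, tested code. A phantom is a
120 × 80 × 120 grid of 25 µm voxels (3 × 2 × 3 mm, brainstem-sized) holding:

* a contiguous descending tract at 100 µm from the midline on the injection
  side (inside the default exclusion band, as the pyramidal tract is), with
  an optional caudal decussation loop;
* five pairs of region ellipsoids (250 µm semi-axes) mirrored exactly
  across a midline that lies on a voxel boundary — so mirror reflection of
  cells is exact integer arithmetic and a symmetric phantom yields LI = 0
  exactly, not approximately;
* `n` collateral voxels, each assigned to the contralateral side with
  probability `f` (default 0.87, the adult contralateral fraction in PrV
  reported for this system) and placed *without replacement* inside its
  region ellipsoid, so set-semantics downsampling at native resolution
  recovers the generator's per-region counts exactly;
* speckle noise (default 20 voxels per 10⁶) drawn uniformly outside all
  ellipsoids, keeping region-level ground truth exact;
* probability levels 0.99/0.01 for foreground/background, straddling the
  0.95 analysis threshold.

Everything is a pure function of `(config, seed)`. The generator emulates
the *statistical and geometric* structure the analysis assumes — it does
not emulate optics (point-spread functions, autofluorescence texture),
axon continuity within collaterals, registration error, or segmentation
artefacts other than uniform speckle. A green test therefore establishes
that the measurement pipeline is correct on its own terms (counts, geometry,
indices, statistics), not that any particular segmentation network is
accurate.

Cohort defaults in `run_demo()` follow the same stated-world logic: a
control-like group of 7 brains at `f = 0.87` versus a mutant-like group of
5 at `f = 0.565` (the reduced-bias magnitude reported for mutants with a
partially uncrossed ascending pathway), each brain quantified end-to-end
and the per-brain LIs compared with the exact test.

## Numerical choices

* **Voxel centres, not corners.** World position of voxel `i` is
  `(i + 0.5) · voxel_size`. With the midline on a voxel boundary, reflection
  `i ↦ 2b − 1 − i` is exact, which the mirror-antisymmetry tests exploit.
* **Closed threshold** (`value ≥ t`), so thresholding at 0 keeps everything
  and at 1 keeps only exact ones.
* **Strict exclusion** (`|d| < w`), so `w = 0` excludes nothing and a point
  exactly on a band edge is kept.
* **Exact zero for on-plane.** Only `d == 0` is `on_plane`; no epsilon. At
  25 µm with a boundary-aligned midline, cell centres are never on the
  plane, so the label only appears for continuous coordinates (e.g. SWC
  nodes) that truly lie on it.
* **Plane fitting** uses the cross product of two edge vectors; collinearity
  is rejected on the triangle area relative to the points' scale. Degenerate
  (`NA`-producing) inputs fail loudly, never silently.
* **Undefined ratios are flagged**, not zeroed: LI with no classified
  cells, region fractions with empty regions, SEM of a single value.
* **Greedy double-label pairing** is nearest-first over cross-channel pairs;
  it never pairs within a channel and `n_double ≤ min(channel counts)` by
  construction. Ties in distance resolve by array order, which is
  deterministic for a fixed table.
* **Exact Mann-Whitney** enumerates assignments only for tie-free pooled
  `n ≤ 20` (at most 184 756 assignments); beyond that the corrected normal
  approximation takes over and the output is flagged accordingly. Two-sided
  p-values double the smaller tail rather than summing point
  probabilities — the convention of the ranked-test software this field
  commonly uses, and of `wilcox.test`, which the test suite uses as an
  independent cross-check.

## Design choices where the ground truth is silent

* The field's written methods report a *visual* classification of
  single-neuron laterality; `axolat` operationalizes it as "≥ 1 terminal
  inside a listed target region on that side" with the threshold
  configurable.
* Group outputs always carry explicit direction (ipsi/contra counts), not
  just a signed index, because published sign conventions for "bias toward
  the contralateral side" are inconsistent across figures of the source
  literature.
* An exact equal-n 4-vs-4 two-sided Mann-Whitney cannot produce p < 0.0286;
  reported values below that for such designs must come from approximations
  or unequal n. `axolat` makes no attempt to match any specific published
  p-value; it reports its method flag instead.
* Profile normalization offers sum-to-one (default) and unit-maximum modes,
  since "normalized densities" is ambiguous; the reference length (e.g. a
  P10 mediolateral extent) is an explicit parameter rather than a hidden
  rescaling.

## Known limitations

* The midline is a plane; curved or kinked midlines (common in damaged or
  very young tissue) are out of scope.
* TIFF support is baseline (uncompressed grayscale, 8/16-bit unsigned or
  32-bit float); compressed or tiled TIFFs are rejected with a format
  error. NRRD is the preferred container because it carries spacing.
* Region assignment is voxel-label lookup at the cell's own position; no
  partial-volume handling at nucleus borders.
* The phantom's collateral clusters are filled ellipsoids, not branching
  tubes; morphology-sensitive methods should not be validated against them.

## A minimal session

```{r demo, eval = FALSE}
library(axolat)

# Ground-truthed phantom, quantified end-to-end.
cfg <- phantom_config(contralateral_fraction = 0.87, seed = 1)
ph  <- generate_axon_phantom(cfg)
fr  <- phantom_frame(cfg, exclusion_halfwidth_um = 150)
cloud <- apply_mask(extract_and_downsample(binarize(ph$volume, 0.95), 25),
                    ph$mask)
laterality(cloud, fr)
region_laterality(cloud, fr, ph$atlas)

# Two synthetic cohorts compared with the exact Mann-Whitney test.
run_demo(seed = 1)
```
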