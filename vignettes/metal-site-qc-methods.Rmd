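---
title: "Regional quality control of metal binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional quality control of metal binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsiteqc)
```

## The method

A deposited crystal structure is a model; the experimental evidence behind
it is the electron density. `metalsiteqc` evaluates the 3.5 Å region
around each metal ion of an entry against that evidence and against three
model-level red flags, producing a per-site verdict on four criteria:

1. **Resolution** (`resolution_max`, default 2.5 Å). Entries refined
   against lower-resolution data cannot resolve waters and small ligands,
   so the whole entry is treated as below the quality floor for regional
   analysis. Entries with no declared resolution (non-diffraction methods)
   fail this criterion rather than erroring: they are parsed and carried
   through with `resolution = NA`.
2. **Occupancy** (`occupancy_min`, default 0.9). An occupancy below 1
   means only a fraction of unit cells contains the modeled ion — either
   an alternate conformation or genuinely partial binding. Either way the
   experimental support is fractional.
3. **Symmetry exclusion** (`symmetry_radius`, default 3.5 Å). An ion
   coordinated partly by a symmetry copy of the protein is, at best,
   ambiguous between a real site and a crystallization artifact. Images
   are generated from the entry's own `REMARK 290 SMTRY` operators
   (Cartesian rotation + translation) combined with lattice translations;
   space-group symbols are never interpreted.
4. **Regional discrepancy** (`region_radius` 3.5 Å, `z_cut` 3,
   `electron_scale` 1). Significant Fo−Fc density near the ion — positive
   or negative — indicates local disagreement between model and
   experiment. The score is the sum of `|value| × voxel volume ×
   electron_scale` over voxels whose center lies within the sphere and
   whose value deviates from the map mean by at least `z_cut` map
   standard deviations. The criterion compares this sum against a cutoff
   derived from the cohort being screened, not a fixed constant, so the
   screen adapts to the overall discrepancy level of the input set.

A site passes overall only if it passes all four criteria *and* its
density is usable (its sphere fully covered by the map).

### The data-driven cutoff

Scoring is two-phase because the cutoff cannot be known until every site
is scored. Phase one (`run_evaluate()`) records values and the first
three flags. Phase two (`run_finalize()`) collects the discrepancy sums
of sites passing criteria 1–2 with usable density, removes outliers in a
single pass at `mean ± trim_sd·SD` (defaults: 2) of the untrimmed
distribution, and sets the cutoff to `cutoff_sd` (default 1) times the
standard deviation of the surviving values. The criterion itself is
strict: a site passes when its sum is strictly below the cutoff.

Two related quantities are reported alongside: the whole-map background
discrepancy (mean absolute significant discrepancy per Å³ times the
volume of the region sphere), the natural baseline for judging how much
noisier metal regions are than the map at large; and a cluster flag
marking ions with another metal strictly within `cluster_distance`
(default 3 Å) in the same asymmetric unit, since multi-metal centers such
as Fe–S clusters show systematically elevated discrepancies.

## Statistical and numerical choices

**Population standard deviations throughout.** Map sigma is the
population SD over all stored voxels, and the cutoff derivation uses
population SDs for both the trim bound and the trimmed spread. For the
cohort sizes the method targets the sample/population distinction is
negligible; using one convention everywhere keeps the trim bound and the
reported SD consistent.

**Computed, not declared, map statistics.** The 3σ significance threshold
uses the mean and SD computed from the voxels, never the header
`AMEAN`/`ARMS` fields, which are occasionally stale in distributed maps.
The parser warns (in tests, compares) when the two disagree, but analysis
always uses the computed values.

**Significance vs. contribution.** A voxel is significant when
`|value − mean| ≥ z_cut·σ` (two-sided on the mean-centered value), but
contributes `|value|`, not `|value − mean|`: difference maps are
essentially zero-mean, and the quantity of interest is discrepant
electrons, i.e. the density itself converted to electrons. For real Fo−Fc
maps the two conventions differ by far less than the grid discretization
error.

**Boundary conventions.** All inclusive/exclusive decisions are fixed and
tested: a symmetry contact at exactly 3.5 Å *fails* the exclusion
criterion; sphere membership is voxel center at distance ≤ radius
(partial-voxel weighting would be unwarranted precision at typical grid
spacings); the discrepancy comparison is strictly `<` the cutoff; the
outlier trim removes values at or beyond the bound (`|x − mean| <
trim·SD` survives, with a zero-spread input kept whole); cluster
membership is strictly `< 3 Å`. The trim-boundary choice is what makes a
five-value worked example `[1, 1, 1, 1, 1000]` trim its outlier exactly
at the bound; see `derive_cutoff()`.

**Single-pass trim.** The outlier trim is applied once, on bounds from
the untrimmed distribution, and never iterated to convergence — iteration
would quietly shrink the cutoff.

**Periodicity and partial maps.** When a map's stored extents equal the
full-cell sampling counts on every axis, distances use the per-axis
minimum-image convention in fractional space. Maps covering less than a
cell are never wrapped: a site whose sphere needs voxels outside the
stored slab is flagged `density_usable = FALSE`, its (partial) sum is
excluded from cutoff derivation, and it cannot pass overall. Silently
wrapping or truncating such spheres would corrupt sums in exactly the
cases PDBe-style model-neighborhood maps produce.

**Symmetry search extent.** Lattice translations default to the 27
neighboring cells (`shells = 1`), escalated automatically whenever any
cell edge is smaller than the search radius plus 2 Å slack; an explicitly
requested but insufficient shell count is an error rather than a silent
near-miss. SMTRY rotations act in Cartesian space (the REMARK 290
convention); lattice shifts are applied fractionally through the cell
transform.

**Degenerate inputs.** A constant map has σ = 0 and no defined
significance level; regional and background scoring raise a
degenerate-map error rather than returning 0. Cells whose angles give a
non-positive metric determinant are rejected at construction.

**File formats.** The PDB parser reads fixed columns only (element from
columns 77–78, title-cased, falling back to the digit-stripped atom name
when blank), drops hydrogens (invisible at the method's resolutions and
irrelevant to every criterion), reads only the first MODEL, and ignores
records after END. Alternate-location metal records are counted as
separate sites — occupancy then reflects each conformer's support, which
is the quantity criterion 2 is about. The CCP4/MRC reader handles mode 2
(32-bit float) with endianness auto-detected from the machine stamp and
arbitrary MAPC/MAPR/MAPS axis orders; the writer recomputes the header
statistics and emits either byte order. Symmetry images are generated
from *all* non-hydrogen atoms, waters included: a packing contact
mediated by an ordered water is still a packing contact.

## What the synthetic fixtures emulate — and what they do not

The generator (`fixture_spec()`, `build_entry_fixture()`,
`build_map_fixture()`, `fixture_suite()`) produces paired toy entries and
maps whose every relevant property is known by construction:

* entries with configurable cells, SMTRY operators, metal placements,
  occupancies and resolutions, written at authentic fixed columns;
* maps of seeded Gaussian background noise plus isotropic Gaussian blobs,
  each normalized analytically so that its full-space integral equals a
  specified electron count at `electron_scale = 1`, planted with
  crystallographic periodicity;
* ground truth — minimum symmetry-image distances, cluster flags,
  voxel-loop discrepancy sums, the trimmed-SD cutoff and all criterion
  flags — computed exclusively by independent brute-force oracles
  (exhaustive operator × shift enumeration, plain triple loops over
  voxels, a separately coded trim-then-SD), never by the functions under
  test.

The default suite (`fixture_suite()`) spans a clean pass-all site, a 7 Å
resolution failure, a 0.7 occupancy failure, a symmetry image planted at
3.2 Å, a high-discrepancy site, a 2.5 Å two-metal cluster, and a
half-cell partial map, on 16 Å cubic cells with 32³ grids (0.5 Å
spacing). The blob-recovery fixture uses a 30 Å cell at 150³ (0.2 Å
spacing) so that a 0.6 Å-wide, 25-electron blob is recoverable by
quadrature; its noise level (0.008 map units) keeps the blob core above
the 3σ threshold out to ~2.8 blob widths, bounding the significance-
clipped tail loss at roughly 5% — which is why recovery is asserted at
10%, not at quadrature precision. These sizes keep the full suite,
including its pure-R voxel-loop oracles, to about a minute of test time
while still exercising axis permutation, periodic wrapping and partial
coverage.

Passing on these fixtures demonstrates that the geometry, the format
round-trips, the sums and the cohort statistics are computed correctly.
It does *not* demonstrate robustness to what real depositions contain:
non-ideal Gaussian density (anisotropy, series-termination ripples,
bulk-solvent artifacts), misassigned elements, nonstandard REMARK
formatting, maps on shifted origins, or the companion problem of
calibrating `electron_scale` from a 2Fo−Fc map. The electron scale is
deliberately an explicit hook: the package treats map units as
electrons/Å³ unless a per-entry density-to-electron ratio is supplied.

## Choices where the design was genuinely open

* **Cutoff = 1 × trimmed SD, not mean + SD.** The reported cohort mean is
  a separate diagnostic; folding it into the threshold would double-count
  the typical discrepancy level and is inconsistent with the cutoff and
  mean being separately meaningful numbers.
* **Cutoff cohort = criteria 1–2 survivors only.** Whether
  symmetry-criterion failures should also be excluded is arguable; the
  two-criteria reading is implemented literally, and symmetry failures
  therefore do contribute their sums to the cutoff distribution.
* **Two-sided trim.** For the non-negative, right-skewed sum
  distributions the method produces, the lower trim bound is usually
  vacuous, so a one-sided trim would rarely differ; two-sided is the
  neutral default and is what the implementation and its oracle both do.
* **altLoc metals as separate sites, waters as symmetry contacts,
  first-model-only parsing** — each documented above and flagged in the
  relevant function's documentation.

## Problem sizes and runtime

Default test and demonstration sizes: 100 random symmetry fixtures of
4–20 atoms and 1–4 operators checked against exhaustive 5³-shift
enumeration; 12³–48³ oracle-checked maps; 10,000-draw cutoff
distributions checked to 10⁻¹²; the 7-fixture suite end-to-end with
byte-identical rerun checks. The complete suite runs in about a minute on
one CPU; `scripts/acceptance.R` in a few seconds.

## Known limitations

* Legacy PDB format only; mmCIF entries must be converted upstream.
* Mode-2 CCP4/MRC maps only (the mode PDBe distributes); no origin-shift
  (`ORIGIN`-word) handling beyond start indices.
* The electron conversion is a linear scale per entry; no per-blob
  modeling of the density is attempted.
* Coordination geometry, bond lengths to ligating atoms, and
  biological-vs-artifactual judgment are out of scope by design; the
  four criteria are exactly the ones that apply uniformly to every metal
  element observed in deposited structures.
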