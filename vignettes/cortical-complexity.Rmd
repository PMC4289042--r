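---
title: "Measuring cortical complexity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cortical complexity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Grey-matter volume and surface area describe how much cortex there is, not
how it is shaped: two ribbons of identical volume can differ widely in
folding. The fractal dimension (FD) condenses shape complexity into one
scaling exponent D between 2 (a smooth sheet) and 3 (a space-filling
solid). `ribbonfd` measures D of binary cortical-ribbon masks with the two
classical voxel-domain estimators — box counting (BC) and
Minkowski–Bouligand dilation (MB) — and wraps them in the region
extraction, morphometry and nonparametric group statistics that a
two-group (e.g. adolescent vs adult, per sex) study needs.

The package works downstream of segmentation: its input is an
integer-labeled volume (e.g. a FreeSurfer-style parcellation exported to
NIfTI) plus a user-supplied mapping of labels to lobes and hemispheres.
Surface reconstruction, intensity normalisation and the segmentation
itself are out of scope by design.

## Ribbon masks and regions

`load_label_volume()` reads a 3D NIfTI volume of non-negative integer
labels with the header's voxel spacing; no resampling or reorientation is
applied. `default_region_atlas()` expands a label→(lobe, hemisphere)
mapping into the standard 11 regions — frontal/parietal/temporal/occipital
× left/right, `LH`, `RH`, `WB` — where the hemisphere and whole-brain
label sets are exact unions of their lobar parts. Because segmentation
conventions differ, the mapping is a required configuration file rather
than a hard-coded table; `inst/extdata/atlas_8lobe_example.json`
documents the format. A complete atlas partitions the ribbon: the eight
lobe masks tile the whole-brain mask exactly, which the test suite asserts.

Voxels are treated as closed unit cubes, indices are voxel units, and only
morphometry converts to millimetres. FD estimation requires isotropic
voxels (checked to 1e-6 relative tolerance) because the scale variable r
is expressed in voxels; anisotropic volumes remain loadable for
volumetry but are rejected by `compute_fd()` with the offending spacing in
the message.

## Box counting

`box_count(mask, r)` counts cells of an r-voxel lattice containing at
least one foreground voxel. Two conventions matter and are fixed
deliberately:

* **Lattice anchoring.** The lattice is anchored at the minimum corner of
  the foreground bounding box — a single origin, no offset averaging. This
  makes the count deterministic and invariant under *any* integer
  translation of the mask (property-tested), at the cost of a slightly
  noisier N(r) than offset-averaged variants.
* **All integer scales.** Box edges increase by one voxel per step —
  r = 2..30 for whole brain and hemispheres, r = 2..14 for lobes — rather
  than dyadic scales. If r exceeds the bounding-box longest edge the
  series is truncated there with a warning (larger boxes would all count
  1); the pipeline logs such truncations because they silently change the
  fit support for small regions.

A consequence of anchored single-origin counting worth knowing: N(r) is
*not* guaranteed to be monotone in r. For multiples (r, kr) the nesting of
lattices gives N(kr) ≤ N(r), but for incommensurate scales the count can
rise locally — visible on the Menger sponge, whose structure aligns with
r = 3^k and misaligns elsewhere. `fit_fd()` therefore rejects only series
that *end* higher than they start; local lattice-phase rises stay in the
fit and surface in `fit_r2`.

## Minkowski–Bouligand dilation

`dilate_count(mask, r)` counts voxel centers within Euclidean distance r
of a foreground center — the Minkowski dilation by a discrete closed ball.
It is computed from an exact squared Euclidean distance transform
(separable lower-envelope algorithm, implemented in C++; squared distances
on the integer grid are integers, so the ≤ r² threshold is exact), on a
grid padded by r so nothing clips. A true sphere is used, not a
Chebyshev or city-block approximation. Radii run r = 1..7, one voxel per
step.

The dilated volume of a D-dimensional set embedded in 3-space scales as
V(r) ~ r^(3−D); `fit_fd()` reports D = 3 − slope of the ordinary
least-squares fit of log V on log r. Alternative normalisations in the
literature (fitting log(V/r³)) shift the slope by exactly 3 and leave D
unchanged.

Both estimators share the fit: unweighted OLS over the full stated scale
range, no automatic linear-regime selection. The ranges are part of the
method definition; `fit_r2` is reported so users can judge linearity
themselves.

## Estimator accuracy at finite scales

On ideal phantoms both estimators carry a finite-scale bias that users
should expect; the validation suite (`validate_phantoms()`, and the
figures recomputed by `scripts/acceptance.R`) quantifies it:

| phantom | analytic D | BC (lobe range) | MB |
|---|---|---|---|
| solid block 64³ | 3 | ≈ 2.87 | ≈ 2.76 |
| slab 64×64×1 | 2 | ≈ 1.92 | ≈ 2.04 |
| Menger sponge 81³ | 2.727 | ≈ 2.55 | ≈ 2.55 |
| line, length 64 | 1 | ≈ 0.96 | ≈ 1.21 |

The mechanisms are understood and scale as O(r/size). For BC, partial
boxes at the far faces inflate N(r) at large r (`ceil(size/r)³` vs
`(size/r)³`), flattening the slope; on a 64³ solid the lobe-range fit
gives 2.87, and the whole-brain range (r to 30) is worse, 2.71. For MB on
a solid, the dilation only adds a surface shell, V(r) ≈ V + S·r, whose
slope contribution (S·r/V ≈ 6r/size) is far from negligible at size 64;
hence 2.76. The sponge's self-similar scales (3, 9, 27) are interleaved
with misaligned integer scales, biasing both estimators low by ≈ 0.18 at
level 4. These biases shrink with object size — cortical ribbons at 1 mm
span 120–170 voxels, several times the phantom sizes used here — and they
are *shared* offsets within a study, which is why the group comparisons
the method is used for remain meaningful while absolute D values should
not be over-interpreted.

Two further accuracy facts the suite checks: BC and MB agree to within
0.15 on the sheet-like and volumetric phantoms (block 0.12, slab 0.13,
sponge 0.001, folded ribbon 0.15), mirroring the expectation that the two
estimators tell one story; and the near-1D line phantom is the exception —
the MB disk/ball counts at r = 1..2 are strongly quantised (7 and 33
voxels against the continuum πr² scaling), inflating D to ≈ 1.21
regardless of line length, so BC is the more trustworthy estimator for
filamentary structures. The dimension ordering
line < slab < sponge < block holds for both methods.

## Morphometry

Volume is voxel count × voxel volume (valid for anisotropic spacing).
Surface area counts exposed voxel faces — a face whose 6-neighbour is
background or outside the grid — times the face area. Face counting is
exact, deterministic and order-preserving between subjects, but it
measures the *staircase* boundary: it overestimates the area of a smooth
surface by up to ×1.5 for oblique orientations (a mesh-based area is
deliberately out of scope). It also measures the full ribbon boundary,
outer (pial-side) plus inner (white-side) plus any internal walls, which
should be stated alongside any comparison to mesh-derived pial areas. The
isoperimetric inequality S³ ≥ 36πV² holds for every discrete mask and is
property-tested.

## Statistical workflow

Group comparisons use the Mann–Whitney U test with the reporting
convention of the major statistical packages: U = min(U₁, U₂), where
U₁ = R₁ − n₁(n₁+1)/2 from the midrank sum of the first sample. With
n₁ + n₂ ≤ 16 and no ties the two-tailed p is exact (Wilcoxon
distribution, equal to enumerating all C(n₁+n₂, n₁) assignments, which
the test suite verifies by brute force); otherwise the tie-corrected
normal approximation is used *without* continuity correction — the
asymptotic two-tailed significance that standard packages print. The
mapping is pinned by frozen checks, e.g. at n = 11 vs 7: U = 37 → p =
0.892, U = 11 → p = 0.013, U = 4 → p = 0.002.

`compare_all_groups()` emits one row per (region, measure) with group
means and sample standard deviations (n−1 denominator), U, raw p, a
`significant` flag at α = 0.05 on the raw p, and — as a clearly labeled
extension beyond per-region raw reporting — a Holm-adjusted `p_holm`
within each measure family. FD–volume association uses the Pearson
product-moment correlation with the t-transform p (n − 2 df), paired
region-wise: GM-LH with FD-LH, GM-RH with FD-RH, GM-WB with FD-WB.

Two conventions worth noting. Whole-brain is defined as the exact union of
the hemisphere label sets, so WB volume is the sum of LH and RH volumes;
published tables sometimes report a WB measure that is not that sum
(different mask provenance), so reconcile definitions before comparing
absolute volumes. And no head-size/ICV correction is applied anywhere —
volumes are compared raw.

## Phantoms and the cohort generator

The folded ribbon is the cortical surrogate: the doubly-sinusoidal sheet
z = size/2 + A·sin(2πf·x/size + φ)·sin(2πf·y/size + ψ), thickened by t
voxels along the local surface normal, with a small seeded phase jitter so
subjects differ. Fold frequency f is the monotone complexity knob; at the
reference setting (96³, A = 8, t = 3) the BC dimension rises strictly from
2.16 (f = 0, a slab) to 2.63 (f = 8), and f = 4..8 spans BC FD ≈ 2.39–2.63,
inside the 2.2–2.8 band where regional cortical FD values at 1 mm are
reported. The MB estimate of the *same* ribbons dips by ≈ 0.03 between
f = 0 and f = 2 before rising: a gently waved slab dilates slightly more
slab-like than the flat one at small radii, so MB monotonicity in f only
holds from f ≈ 2 upward — one reason BC is the primary complexity readout
for the generator.

Thickness is the volume knob. Its FD-neutrality is scale-dependent:
at 128³ (f = 5, A = 10) thickening 3 → 3.7 voxels adds 24% volume while
moving BC FD by < 0.04, demonstrating that volume and complexity are
separately controllable; at 96³ and below the same relative thickening
leaks 0.05–0.09 into D, so the decoupling demonstration is run at the
large-grid setting.

`cohort_spec()` encodes the emulated study design: cells of 11/6
adolescents (female/male) versus 7/7 adults, one whole-brain surrogate
phantom per subject at 64³. Group structure enters only through fold
frequency — adolescent f ~ N(6, 0.5) vs adult N(5.5, 0.5), calibrated once
against the generator's measured frequency→FD response so the group FD gap
lands near 0.03 with within-group FD sd ≈ 0.01–0.04 (the scale of
reported cortical FD group effects), and, as a side effect of folding,
≈ 10% more grey-matter volume in adolescents, in the reported direction.
Thickness is N(3, 0.2) for both groups by default. All per-subject draws
are truncated at ±2.5 sd so extreme subjects cannot push a ribbon outside
its grid, and every random quantity derives from the single spec seed
(the global RNG stream is left untouched, which the suite asserts).

**Statistical calibration.** Type-I error and power of the full
phantom-measurement-plus-Mann-Whitney chain are estimated on reduced 48³
cohorts in the 11-vs-7 design. Two design notes: the fold-frequency
operating point at 48³ is means 5.25 vs 4.5 (sd 0.5), chosen on a measured
locally monotone stretch of the 48³ frequency→FD response — at this grid
size the response aliases (non-monotone wiggles) once the fold wavelength
approaches the box-count scale range, and an aliased operating point would
measure the artefact, not the statistics; and thickness is held fixed in
these cohorts, because the manipulated variable is fold frequency and
nuisance variance would dilute the nominal 1.5-pooled-sd shift. Measured
on 500/200 replicates (see `scripts/acceptance.R` output): type-I ≈ 0.04–
0.06, matching the nominal 0.05 up to the discreteness of the U statistic;
power ≈ 0.77. The power ceiling is a property of the design, not the
phantoms: the Mann–Whitney rejection region at n = 11 vs 7, α = 0.05 is
U ≤ 16, whose power against a 1.5-sd location shift is just below 0.8, and
since the test is invariant under monotone transforms, mapping f through
the ribbon geometry cannot systematically beat it.

**What the generator does not emulate.** Phantoms are anatomically
unstructured (no gyral/sulcal anatomy, no regional parcellation — regional
tables on simulated data carry a single `WB` surrogate region), masks are
noise-free (no partial-volume effect, no segmentation error), and a single
latent parameter drives both FD and volume, which makes simulated
FD–volume Pearson correlations run close to 1 — substantially tighter than
the 0.5–0.86 range reported for real cohorts, where the two measures have
independent sources of variance. Passing calibration on phantoms therefore
validates the estimator/statistics chain, not the biological effect
itself.

## Numerical choices and degenerate inputs

* Empty masks: volume 0 and surface 0 are returned; FD estimation refuses
  with an error, and region extraction warns with the region name. In the
  pipeline a failing subject is excluded, counted and named in the run
  metadata rather than aborting the cohort.
* The slab/ribbon voxelisation uses a half-open band
  [center − t/2, center + t/2), so a thickness-1 slab is exactly one voxel
  layer and the f = 0, jitter = 0 ribbon equals `make_slab()` bit for bit.
* Complete ties across both groups give U = n₁n₂/2 and p = 1; zero
  variance in a correlation input is an error naming the degenerate
  variable.
* Scale-series and FD computations are fully deterministic; two pipeline
  runs from the same config and seed produce byte-identical CSVs (tested).
* The Menger sponge generator is capped at level 4 (81³, 160 000 voxels);
  phantom grids used routinely are 32–128 voxels per edge. These sizes
  keep the full suite at desk scale while leaving the finite-size biases
  described above visible — both numbers are stated in the accuracy table
  rather than hidden.

## Known limitations

* Absolute D values at 64–96³ carry the documented finite-scale bias;
  compare groups, not absolute dimensions, and report the scale range with
  any D.
* Surface area is staircase area, not mesh area.
* One anchored lattice (no offset averaging) trades a little variance for
  strict translation invariance; offset averaging is a possible extension.
* The MB estimator is unreliable for near-1D structures (ball
  quantisation at r ≤ 2) and only monotone in fold frequency away from the
  flat regime.
* The cohort simulator validates the measurement/statistics chain; it is
  not a brain model, and its FD–volume coupling is tighter than real
  data's.
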