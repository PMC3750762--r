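---
title: "Co-registering microCT, LM serial sections and TEM images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-registering microCT, LM serial sections and TEM images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricoreg)
```

## The problem

A single small specimen — think of a juvenile mollusc less than a
millimetre long, osmium-fixed and resin-embedded — can be imaged three
ways in sequence: microCT of the intact block, brightfield microscopy of
a complete series of semithin (~1.5 µm) sections, and TEM of ultrathin
re-sections cut from individual LM sections. Each modality answers
different questions, but only in a common coordinate frame can an
ultrastructural observation be pointed at *in the whole animal*. This
package computes that common frame.

The microCT volume is the reference: tomographic reconstruction
introduces neither sectioning compression nor slice-to-slice alignment
error, so all other data are moved into its space. Three transforms are
estimated: one affine 3D map for the LM stack (shared by its label
volumes), and for each TEM image one 2D similarity map into a template
cropped from its parent LM slice, whose 3D placement is already known.

## Coordinate conventions

Everything physical is in micrometres. Axes are ordered (z, y, x) =
(slice, row, column), matching slice-major multi-page TIFF storage.
Voxel indices are 0-based; a voxel's world coordinate is the coordinate
of its **center**; intervals in voxel space are half-open. A stated
convention matters more than which convention: it is what prevents
half-voxel drift when a 2D crop is resampled 16-fold and placed back
into 3D. Transforms map **moving-world to fixed-world**; resampling uses
the inverse map, pulling values from the moving volume onto the target
grid.

Rotations are parameterized as intrinsic Euler angles (z, then y, then
x) about the moving volume's physical center. Pivoting at the center
keeps rotation and translation parameters comparably scaled, which a
coordinate-descent optimizer needs; pivoting at the corner would couple
a 1° step to a ~7 µm apparent shift at the far end of a 0.8 mm specimen.

## Similarity-enhancing preprocessing

Correlation is only a sensible objective if the two volumes look alike.
LM sections are dark tissue on a bright background; CT is the opposite.
`invertIntensities()` applies `v -> 255 - v`, and `gaussianSmooth()`
(3×3×3 support) removes LM detail that has no CT counterpart. The
support size is fixed by the workflow this mirrors; the Gaussian's sigma
is not published anywhere, so the package defaults to 0.8 voxels — the
common choice for a radius-1 sampled Gaussian — and exposes it as a
parameter. Borders are edge-replicated: zero padding would darken the
volume rim and bias the metric toward background alignment. Each
operator re-quantizes to 8 bits (round-half-up), mirroring a pipeline of
8-bit image modules; a `quantize = FALSE` flag exists for numerical
tests.

## The registration objective and optimizer

`correlationMetric()` is the Pearson correlation between fixed voxel
values and linearly interpolated moving values, computed over exactly
those fixed voxels whose mapped position lands inside the moving
volume's physical extent. Overlap below `minOverlapFraction` (default
0.25) is an error rather than a number: a tiny overlap can correlate
perfectly and means nothing. Constant masked signals are likewise
errors. Pearson (mean-centered) rather than zero-anchored normalized
cross-correlation was chosen and is documented here because the two
differ on 8-bit data with nonzero background; Pearson is invariant to
the linear intensity remaps this pipeline applies.

`affineRegister()` searches the transform parameters (3 translations, 3
rotations, plus 0/1/3 scales depending on `mode`) with a derivative-free
coordinate search per pyramid level: parameters are swept in a
seed-determined order, each tried at ± the current step, improvements
accepted, and all steps halved after a sweep without acceptance, until
the steps fall below tolerance (0.01 µm / 0.01° / 10⁻⁴ by default).
Initial steps are 2 voxels, 2° and 2% at the coarsest level. The pyramid
mean-pools by factor 2 per axis (default 3 levels), never pooling an
axis below 16 voxels; anisotropic stacks therefore stop pooling their
thin axis early. All overlapping voxels enter the metric at every level
— no stochastic subsampling — so the whole procedure is deterministic
given the configuration; the seed only orders the sweeps. A simple
scheme with provable monotonicity was deliberately preferred over a
black-box optimizer: every accepted step increases the metric, the trace
records it, and a run that cannot improve on its initialization at the
finest level is flagged `converged = FALSE` instead of silently
returning.

The initial alignment is the caller's job, mirroring the manual coarse
alignment such workflows start from; `centroidAxesInit()` offers a
centroid-plus-principal-axes guess but is never applied silently, since
principal axes are sign-ambiguous on near-symmetric specimens.
Whether rotation/translation should be optimized jointly or in
alternating stages is ambiguous in interactive tools; the joint
parameter-vector sweep was chosen because it cannot get trapped by a
stage ordering.

The three modes mirror the three physically meaningful degrees of
freedom ladders: `rigid` for the standard case, `rigid_iso_scale` for
calibration mismatches, and `rigid_aniso_scale` whose z-scale can absorb
a systematic microtome thickness error (sections cut at 0.95 µm but
declared 1.0 µm stretch the stack by 5% along z; no rigid map can fix
that).

`propagateTransform()` applies the estimated transform — the identical
object, not a copy that might drift — to companions on the moving grid:
the original unfiltered LM stack and the segmentation labels. Labels are
resampled nearest-neighbour only; interpolating label ids would invent
tissue.

## Embedding TEM images

`extractTemplate()` crops one slice of the registered stack and keeps
the entire placement chain (grid, slice index, crop offset, stack
transform). The crop is anchored at the outer edge of its first voxel,
so `resampleTemplate()` — which raises the template to the TEM pixel
size (e.g. 0.413 µm → 0.025 µm, a 16.52× supersampling) — preserves the
world coordinate of every material point exactly; upsampling beyond 64×
is refused with advice to crop a smaller region first, which also keeps
memory bounded. `register2D()` then runs the same pyramid/coordinate
search, specialized to a 2D similarity transform. The model is
deliberately *not* affine or elastic: distortion of TEM re-sections
relative to their parent LM section is mostly negligible, and the
smallest sufficient model is the most testable one. Scale, when enabled,
is bounded (default 0.9–1.1) because only slight rescales are physically
plausible and unbounded scale can degenerate on low-contrast crops.

Display needs exact background separation: `levelsRemap()` compresses
the TEM histogram into 10–255, `compositeOnBlack()` writes the
transformed TEM onto a template-sized black canvas (covered pixels are
clamped up to the floor, uncovered pixels are exactly 0), and the
display colormap sets opacity 0 for gray 0–9 and 255 for 10–255. The
clamp is what makes "covered ⇒ visible" a guarantee rather than a
probability. The canvas size must equal the template size: that identity
is what lets `placeIn3D()` reuse the template's analytic pixel-to-world
map for the composited image, storing the mapping symbolically instead
of burning the TEM into a 3D raster (which would destroy the resolution
the whole exercise exists to preserve). A TEM section is placed at its
parent LM slice's center plane; sub-slice z position within the ~1.5 µm
section is not recoverable from the data and is not modelled.

## The phantom generator

`PhantomSpec()` defines the synthetic study conditions: a 64³ canvas of
12.5 µm voxels (≈0.8 mm extent, the scale of the motivating specimens)
holding four smooth-edged bodies — a large "mantle" ellipsoid and three
denser organ-like bodies (0.35/0.55/0.75/0.95 density, pairwise
separated by ≥0.1) — plus band-limited texture; an anisotropic LM grid
(46×120×120 at 15.625×6.25×6.25 µm — finer in-plane, coarser across
slices, like semithin sections); and ground-truth transforms (default: a
5° in-plane rotation with a (6, −4, 3) µm shift for the LM stack; 2°,
(12.5, −7.25) px for the TEM image at a 16× finer pixel). MicroCT
renders bright-on-dark with light blur and gray-level noise (σ = 3); LM
renders dark-on-bright by sampling the continuous phantom through the
inverse ground truth; TEM upsamples an LM crop and adds sub-LM-scale
texture. All generators are pure functions of the spec and seed.

Two imperfections of real serial-section data are modelled explicitly.
A *slice-thickness error* samples slices at the true thickness while the
stack declares another, so the effective ground truth gains an exact z
scale. *Per-slice jitter* is a mean-removed random walk of in-plane
shifts (default step σ = 1.5 µm when enabled): sequential alignment of
sections accumulates drift, and global pre-alignment removes only its
mean, which concentrates the residual at the stack ends. This is the
mechanism by which a stack-to-stack affine registration — which cannot
fix internal misalignments by construction — leaves residuals that grow
toward the specimen periphery; `sliceJitterResiduals()` quantifies it as
the mean residual in the outer versus inner quintile of distance from
the stack center.

What the phantom does *not* emulate: CT reconstruction physics (beam
hardening, ring artefacts), optical PSFs, section folds/tears, stain
variation between sections, or realistic EM texture. Passing tests
therefore demonstrate the correctness of the geometry, the metric, the
optimizer and the transform plumbing under controlled contrast — they do
not certify performance on pathological real-world data, where the
coarse manual initialization and preprocessing choices matter more.

## Numerical choices and degenerate inputs

* Linear interpolation defines "inside" as the continuous index range
  [0, n−1] per axis (with 10⁻⁹ slack against floating-point edges);
  nearest-neighbour uses the half-open voxel boxes [k−0.5, k+0.5), which
  preserves label voxel counts under integer-voxel shifts exactly.
* Metric ties (improvement below `metricTol` = 10⁻⁷) count as
  rejections, so step halving always terminates.
* 8-bit quantization is round-half-up everywhere, chosen over banker's
  rounding for its monotonicity (`levelsRemap` must be order-preserving).
* Singular transforms, insufficient overlap, constant masked regions,
  16-bit input without an explicit rescale flag, label volumes with
  linear interpolation, and out-of-bounds crops are all loud errors, not
  warnings.
* TIFF resolution tags are not trusted (nor written by the binding used
  here): grid spacing travels in a JSON sidecar, the caller's spacing
  always wins on read, and a >0.1% disagreement warns.

## Problem sizes used in the tests

The shipped tests and the acceptance script run entirely on phantoms:
64³ reference volumes, 46×120×120 LM stacks, 640² TEM images, 20
phantoms for the rigid-recovery study, 100 random 8³ pairs for the
metric-oracle comparison. These sizes were chosen so the whole
validation suite runs on a desktop in minutes while leaving every
algorithmic path identical to full-scale use; the printed full-scale
grids (650×638×838 CT, 1200×1600×585 LM) are reachable through the same
configuration objects.

## Known limitations

Elastic registration is out of scope by design: the workflow's own
validation logic treats residual peripheral deviation as a *finding*
about stack quality, not something to warp away. Mutual-information and
other metrics are not implemented (the correlation metric plus polarity
inversion covers the CT/LM pairing this package addresses); the
config's `metric` field is a fixed tag so a future extension is a
declared, not silent, change. Stitching of multiple TEM exposures and
automatic pixel-size detection from scale bars are likewise out of
scope — the TEM pixel size is caller input.
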