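---
title: "Quantifying navigated posterior-margin delineation on synthetic maxillary phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying navigated posterior-margin delineation on synthetic maxillary phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NaviMargin)
```

## The problem

In transnasal surgery for locally advanced maxillary tumors, the posterior
margin (PM) of the resection must be delineated in a narrow corridor where the
tumor can lie within millimeters of the internal carotid artery (ICA). Whether
real-time surgical navigation -- tracked pointers rendered against 3-D tumor
and vessel models, optionally with a proximity alarm around the carotid --
actually improves the geometric quality of that delineation is a quantitative
question: for a recorded pointer pose, how far is every point of the implied
cutting plane from the tumor surface and from the carotid wall?

NaviMargin implements the full measurement chain on procedurally generated
phantoms: phantom geometry with controlled tumor-carotid clearances, CBCT-like
volume synthesis, threshold segmentation, signed Euclidean distance fields,
the 2-mm carotid alert cloud, paired-point rigid registration with a fiducial
registration error (FRE) gate, a stochastic model of surgeon pointer placement
under three guidance settings, the nine-zone classification of the isolated
30 x 11 mm cutting-plane area, and the group statistics (Kruskal-Wallis,
Steel-Dwass-Critchlow-Fligner post-hoc, Fisher exact, intraindividual gain)
that compare the settings.

## Phantom geometry

Each phantom combines three analytic structures, realized both as triangle
meshes and as voxel occupancy masks on the acquisition grid (256 x 256 x 192
voxels at isotropic 0.8 mm by default):

* **Tumor**: an ellipsoid body in the maxillary region (semi-axes
  25 x 20 x 18 mm) joined to a posterior spherical lobe (radius 9 mm) that
  models the posterior extension toward the carotid.
* **ICA**: a tube of radius 2.5 mm swept along a piecewise-cubic centerline.
  The stock presets use a straight vertical segment -- the paraclival/vertical
  petrous portion that actually borders the posterior maxillectomy margin --
  because a straight segment makes the clearance analytically exact; the
  generator itself supports curved centerlines.
* **Bone**: a hollow ellipsoid shell standing in for the skull, which also
  carries the six registration divots.

The four stock presets S1-S4 differ only in how far posteriorly the lobe
reaches: the lobe center is placed on the line from the tumor body toward the
carotid axis at a standoff of `clearance + lobeRadius + tubeRadius`, so the
closest tumor-to-carotid surface distance *is* the configured clearance
(14.9, 10.2, 6.2 and 3.5 mm). Because the body ellipsoid stays at least a few
millimeters farther from the vessel than the lobe in every preset, the
minimum over the union is attained at the lobe and the construction is exact
up to mesh chord error (< 0.01 mm at the stock tessellation):

```{r clearances}
sapply(c("S1", "S2", "S3", "S4"), function(id)
  measureClearance(buildPhantom(id, voxelize = FALSE)))
```

A clearance below half a voxel is rejected as unrepresentable, and geometry
that would leave the imaged field of view is a configuration error rather
than a silent truncation.

## Imaging surrogates

The CBCT acquisition is replaced by direct intensity painting: background 0,
bone 400, tumor 1200, carotid 1500 (arbitrary units), with overlap priority
carotid > tumor > bone so the vessel is never erased, plus optional additive
Gaussian noise. The two-step semi-automatic contouring workflow of clinical navigation
suites (global threshold, then interactive smoothing) becomes a reproducible
pair:
threshold at the midpoint between material intensities, then morphological
closing and opening with a Euclidean ball. On noiseless volumes the midpoint
threshold recovers the generator's masks exactly; with noise at 10% of the
bone-tumor contrast and a 1.6-mm refinement ball the Dice overlap against the
ground-truth masks stays above 0.95 in the test suite.

Distance fields use the exact Euclidean distance transform
(lower-envelope-of-parabolas algorithm, implemented in C++), signed as
`distance to nearest structure voxel - distance to nearest background voxel`:
negative inside, positive outside, with the surface at the voxel-center
crossing. No half-voxel shift correction is applied; all tolerances downstream
budget for the resulting sub-voxel bias, and the voxel-center values match an
O(n^2) brute-force search to 1e-6 mm. Note that the signed value jumps by a
full voxel step across the surface between adjacent centers (both transforms
read the opposite class's *centers*), so the 1-Lipschitz property holds within
each side of the surface and the trilinear interpolation localizes the zero
crossing at the midpoint between boundary centers.

Surface extraction uses marching tetrahedra on the voxel-center lattice (six
tetrahedra per cell sharing the main diagonal, consistent across cells), which
guarantees watertight, consistently oriented meshes, including for masks that
touch the array border. Mesh volumes agree with analytic and voxel-count
volumes within 5% for blobs larger than about 10 voxels.

**Alert cloud.** The 2-mm carotid proximity shell is the Euclidean-ball
dilation of the vessel mask minus the vessel (dilation is realized by
thresholding the distance transform, so the structuring element is isotropic
in millimeters). For the rendered wireframe we extract the offset surface as
the continuous 2-mm level set of the distance-to-vessel-surface field rather
than re-binarizing the dilated mask: marching a binary dilation quantizes the
offset to the voxel grid and biases the mean vessel-to-wireframe distance a
half voxel low, while the continuous level set reproduces the margin to a few
hundredths of a millimeter on a cylinder test body.

## Registration gate

Image-to-tracker registration is the closed-form SVD solution of the
paired-point least-squares problem, with the standard reflection guard. The
FRE is the RMS residual (the conventional fiducial-registration-error
definition) and a registration is accepted when FRE <= 1 mm.
Six divots on the bone shell, perturbed with isotropic Gaussian localization
noise of SD 0.25 mm per axis, keep the maximum FRE over 100 Monte-Carlo
repetitions near 0.55 mm -- comfortably inside the gate. The divot count is
configurable; six is the default because four to eight well-spread,
non-coplanar divots is typical practice.

## Cutting-plane analysis

A pointer pose defines the cutting plane: the plane contains the tip and the
shaft axis, and the roll angle about the shaft fixes the normal (mirroring
planar virtual tool clipping for an osteotome or saw). The analyzed area is a
lattice starting at the tip: 30 mm along the shaft, 5.5 mm to each side, at a
0.5-mm step by default (61 x 23 points). There is no canonical sampling
density for the analyzed plane; 0.5 mm was chosen as comfortably finer
than both the voxel grid and every zone boundary, and it is exposed in
`planeSamplingSpec()`. Each point gets both signed distances by trilinear
interpolation; a point outside the field grid is an error naming the point;
planes are never silently truncated at the volume edge.

The nine-way zone rule partitions the (d_ICA, d_tumor) plane:

| carotid distance | into tumor | < 5 mm | 5-10 mm | > 10 mm |
|---|---|---|---|---|
| <= 0 mm | R | R | R | R |
| 0-2 mm (danger) | O1 | O2 | O3 | O4 |
| > 2 mm (adequate) | Y1 | Y2 | G | B |

Boundary conventions are fixed once and logged with every run: d_ICA = 2 mm
falls in the danger zone (an *adequate* carotid distance is strictly greater
than 2 mm), and tumor distances of exactly 5 and 10 mm are "clear" (the
5-10 mm band is closed). The partition's totality and exclusivity are
property-tested on 10^6 random pairs plus exact boundary values.

Plane-level flags summarize each map: intratumoral (any point at or inside
the tumor) versus adequate margin, and exactly one of carotid damaged (any
point at or inside the wall), danger zone, or carotid adequate. The tip-level
proximity alert (`evaluateAlert`) reproduces the alarm logic -- breach at or
inside the wall, proximity within the margin -- and is tip-only, matching the
navigation system's real-time trigger; whole-plane breach is available from
the flags. The color map renderer writes one pixel per lattice point with a
fixed zone-to-color table and is byte-stable, so rendered outputs participate
in checksum-based reproducibility checks.

## Simulated surgeon behavior

Human pointer placement is modeled around the *ideal* plane: the vertical
plane tangent to the tumor's posterior offset surface at half the local
tumor-carotid gap. Because both tumor components are convex and the carotid
lies beyond the tangent plane in every preset, the ideal plane is provably
clear of both structures, and the zero-noise sampler reproduces it exactly --
a fixed point the test suite checks on all presets. The superior and inferior
PM portions are two sampling bands (window running up or down from a split
plane); the anatomical split at the nasopharyngeal vault has no synthetic
counterpart, so a horizontal plane through the lobe equator stands in.

Noise perturbs the ideal frame by rotations about the two in-plane axes
(N(0, rotSd^2) degrees each) and a translation along the normal
(N(0, transSd^2) mm). The default calibration -- unguided 8 degrees / 3 mm,
navigation-guided 4 degrees / 1.5 mm -- is a stated default chosen to give
realistic breach rates on the hardest phantom, not a fitted model of human
performance; every acceptance claim about simulated behavior is therefore
ordinal (direction of differences), never numeric. The carotid-guided setting
adds the alarm: poses whose sampled area would enter the vessel (checked
against the analytic tube surface, the stand-in for the real-time system) are
resampled up to 5 times, and an exhausted budget returns the last pose
flagged `breachUnresolved`. Pointer angulations are drawn from the observed
usage frequencies of the 30/45/60/90-degree tips; they are metadata in this
model, since the plane is fully determined by tip, shaft and roll.

Surgeon heterogeneity (3-13 years of experience in the simulated cohort) is a
per-surgeon multiplicative noise factor drawn once from LogNormal(0, 0.25^2).
The study runner crosses surgeons x presets x settings x portions
(x replicates), seeding every pose from a stream keyed by the cell, so
changing the surgeon count does not perturb other cells, and a fixed seed
reproduces every output file byte for byte. How physical simulation sessions
apportion delineations per setting varies with protocol; the runner exposes
the factorial design and leaves the per-setting count a free parameter.

## Statistics

Distance distributions are compared as *plane-level zone percentages* (one
value per delineation), not pooled raw distances: a zone-by-zone summary
table with one p-value per row only makes sense for plane-level aggregation. The alternative (pooled per-point distances) remains
available by operating on the exported map CSVs, but carries no acceptance
claims.

* **Kruskal-Wallis**: tie-corrected H with the chi-square reference by
  default; a Monte-Carlo permutation p-value is available and is checked
  against an independent permutation oracle. The H statistic is computed from
  the rank formula (validated against `kruskal.test` to machine precision)
  because the permutation option must recompute it ~10^5 times.
* **Steel-Dwass-Critchlow-Fligner**: all-pairs two-sample rank statistics with
  tie-corrected variance, referred to the studentized-range distribution with
  k groups. The choice of small-sample reference distribution is genuinely open;
  the default is the standard asymptotic procedure, and
  an exact per-pair enumeration mode exists and is verified against exhaustive
  permutation at n = (4,4,4).
* **Fisher exact on 2 x k flag tables**: Freeman-Halton by direct enumeration
  of all tables with the observed margins (feasible for 2 x k at study sizes),
  cross-checked against both `fisher.test` and an independent enumeration
  oracle.
* **Gain**: per surgeon, the pooled guided minus unguided difference in the
  rates of clear-margin and carotid-spared planes, reported as mean and range.
  "Guided" pools the tumor- and carotid-guided settings, since both offer
  real-time tracking.

The significance level 0.05 is recorded in the report metadata; no
multiplicity correction is applied beyond the Steel-Dwass procedure itself.

## Problem sizes and numerical choices

The package defaults reproduce the full acquisition grid (256 x 256 x 192 at
0.8 mm). The test suite and the simulated-study checks run the same code on a
128 x 128 x 96 grid at 1.6 mm (and a 104 x 104 x 80 grid at 2 mm for the file
pipeline), sizes at which every property under test -- exactness of the
distance transform, watertightness, zero-noise invariants, ordinal guidance
effects with 8 surgeons x 20 replicates -- is already decisive. Degenerate
inputs fail loudly: empty or full masks have no distance field, empty
segmentations name the threshold, sub-voxel clearances and out-of-view
structures are configuration errors, and fewer than three or collinear
fiducials cannot be registered.

## What passing tests do and do not show

The phantoms emulate the *geometry* of physical maxillary tumor models --
stated clearances, voxel grid, material contrast, divot registration -- not CBCT
physics (no projection/reconstruction, beam hardening or scatter), not skull
anatomy or the nasal corridor's reachability constraints, and not human
decision-making (approach choice and inadequate-exposure cases are out of
scope). Consequently, passing the ordinal behavior checks shows that the
measurement chain orders guidance settings correctly *given* the stated noise
calibration; it does not validate that calibration against human performance,
and human-performance group percentages from physical simulation sessions
are deliberately not targets of the test suite. The geometric and statistical components
-- clearances, distance fields, alert cloud, registration, zone partition,
exact tests -- are checked against analytic values and independent oracles
and carry over to real volumes with the usual caveat of segmentation quality.
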