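---
title: "Methods: image quantification for neurosphere cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quantification for neurosphere cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherequant)
```

# The measurement problem

Enteric neural stem cells cultured in non-adherent conditions form mixed
spheroids whose surface carries neurospheres: aggregates of neural
crest-derived progenitors, neurons and glia. Two read-outs drive the
biology: (i) per-neurosphere composition — how many nuclei there are and
what fraction is positive for each marker (HU for neurons, PHOX2B/green
and SOX10/red for lineage state, EdU/far-red for S-phase labeling), and
(ii) migration capacity — how far cells and neurites travel from a
spheroid plated on fibronectin.

`spherequant` implements both read-outs as a deterministic pipeline over
2-D multichannel fluorescence planes, and validates every stage against a
synthetic image generator with exact ground truth.

# Pipeline stages and their parameters

## Neurosphere detection (HU channel)

8-bit conversion → inversion → inclusive intensity window → morphological
clean → distance-transform watershed → particle gate.

* **Intensity window.** Thresholds follow the closed-window convention of
  common threshold dialogs: a pixel is foreground iff
  `lo <= p <= hi`, both ends inclusive. Windows are quoted for the
  *inverted* image, which keeps the printed low windows (e.g. 0–13 a.u.)
  meaningful for bright signal. The neurosphere-stage default window is
  0–100 a.u. after inversion (i.e. original intensity ≥ 155 a.u.); no
  printed value exists for this stage, so the default was chosen once to
  sit well below the rendered neurosphere intensity (200 a.u.) and well
  above background.
* **Morphological clean** is binary closing-then-opening with one disk
  radius (default 25 px, the midpoint of the 20–30 px range used for this
  kind of consolidation). Closing first merges a speckled stain into one
  blob; opening then removes sub-element debris. The direction
  (close-then-open) is this package's choice.
* **Particle gate**: area 1,000–50,000 px², circularity 0.5–1.0, both
  intervals closed.

## Nucleus isolation (DAPI channel, per ROI)

8-bit conversion → rolling-ball background subtraction (30 px) →
inversion → window 0–13 a.u. → median filter (disk, 1 px) → watershed →
gate 10–1,000 px² at circularity 0.3–1.0. A nucleus belongs to a
neurosphere iff its centroid lies inside the ROI mask — the centroid rule
makes boundary-straddling nuclei unambiguous.

* **Rolling-ball subtraction** is implemented as grayscale opening with a
  disk of the stated radius: structures smaller than the element never
  enter the background estimate, so they survive subtraction unchanged,
  and the output is pixelwise ≤ the input. This is a morphological
  stand-in for the sliding-paraboloid estimator; the difference is a
  smooth-background detail that the synthetic validation is insensitive
  to, because acceptance is parameter and count recovery, not bit parity
  with any particular program.
* **Median filter** uses a Euclidean-disk neighborhood
  (`dr² + dc² ≤ r²`; radius 1 gives the 5-pixel cross) with
  edge-replicated borders. All morphology likewise replicates edges via
  explicit padding, so a constant image is a fixed point of background
  estimation up to the border.
* **Whether the window applies to the inverted image** is configurable
  per stage (`invert`); the printed 0–13 window is only consistent with
  near-saturating nuclear signal measured after inversion, which is how
  the default is wired and how the generator renders DAPI.

## Watershed splitting

Touching objects are split by watershed on the Euclidean distance
transform. Seeds are the distance-transform local maxima; maxima are
merged into one seed when closer than `min_distance` (each maximum is
grown by half the spacing, so grown regions touch exactly when maxima are
nearer than `min_distance`); every foreground pixel is then assigned to
one seed by deterministic region growing (`EBImage::propagate`). A
component with a single seed is returned whole, so the operation degrades
to 4-connected component labeling on well-separated objects.
`min_distance` defaults to 5 px for nuclei (radius ≥ 4 px separates) and
25 px for neurospheres. Ties at region boundaries follow the growing
order of the underlying implementation; the result is deterministic for
fixed input, which is the property the pipeline relies on.

## Geometry

* **Perimeter** is measured on the traced object contour with the
  Vossepoel–Smeulders corrected chain length
  (0.980·straight + 1.406·diagonal − 0.091·corners). The naive (1, √2)
  chain length overestimates digital-disk perimeters by ≈ 5 %, which
  would push ideal disks to circularity ≈ 0.91 and distort the gate;
  the corrected estimator is accurate to ≈ 1 %.
* **Circularity** is `min(1, 4πA/P²)`; single-pixel objects (zero
  contour) are assigned circularity 1.
* Particles touching the image border are retained; connectivity is
  4-connected throughout.

## Marker classification

Marker channels are 8-bit converted and background-subtracted (30 px)
before measurement — stated for the multichannel design, and applied to
the single-marker design too for uniform intensity semantics
(`subtract_marker_background = TRUE` to disable per run). Per-nucleus
intensity is the arithmetic mean over the nucleus mask, and positivity is
*strictly* greater than the marker threshold (mean 10.0 against threshold
10 is negative). Defaults: 10 a.u. for HU, green and far-red; 30 a.u. for
red.

## Migration distances

Emigrated cells / neurite tips are segmented outside the spheroid mask
with the nucleus-stage primitives and the permissive gate
(0.001–1,000 px², circularity 0.1–1.0). Each particle contributes the
pixel of its mask *farthest* from the spheroid border, so tips rather
than centroids set the length; where a measurement terminates along a
neurite is not otherwise defined, and the farthest-pixel rule is this
package's convention. Distances are minimum Euclidean distances to the
border pixel set (a point on the border itself measures 0), in pixel
units — no micron calibration is applied unless the caller converts.
Exactly the five largest distances per spheroid are reported, sorted
descending.

## Statistics

Omnibus comparisons use Kruskal–Wallis (mid-rank tie correction) or
one-way ANOVA; which metric gets which test is explicit configuration,
not automatic normality testing — reproducibility over convenience. Post
hoc tests are Dunn's pooled-rank z tests, Tukey's HSD, or Mann–Whitney
(exact enumeration for untied samples of size ≤ 8, tie-corrected normal
approximation otherwise). Holm step-down adjustment is applied within
each metric's pairwise family; Tukey p-values are already
family-adjusted and pass through unchanged. Whether the post hoc family
or only the omnibus family is adjusted is exposed (`adjust = "holm"` /
`"none"`). All tests are two-sided; significance is α = 0.05 with stars
at 0.05/0.01/0.001/0.0001.

# The synthetic benchmark

`generate_stack()` renders what the pipeline assumes: hard-disk nuclei
(radius 3–7 px) packed inside disk spheroids with a minimum centroid
separation, a near-saturating DAPI channel (250 a.u. over background 5,
σ = 2 Gaussian noise, clipped and quantized), an HU channel with
200 a.u. spheroid disks, and marker channels that are dark outside nuclei
and carry `mu_pos` = 60 / `mu_neg` = 2 a.u. per planted sign — so at
σ = 0 the mean over a non-overlapping nucleus disk equals its µ exactly.
Marker signs come either from independent per-marker fractions or from a
joint co-expression table (the `e8`/`e12`/`d0` presets encode an
illustrative decline of the green+/red+ bipotent fraction; they are
defaults, not data). One integer seed drives all draws via a local RNG
scope, making every fixture bit-reproducible.

Chosen operating points, fixed once:

* **Nucleus separation** defaults to 11 px between centroids — touching
  but watershed-separable for radii up to 7 px. Count-recovery
  validation runs at this setting (seeds 1–10, two spheroids of 50–200
  nuclei) and recovers per-ROI counts within ±5 %; the residual error is
  dominated by strongly overlapping pairs merging.
* **Classification validation** uses 15 px separation
  (non-overlapping). Where disks overlap, the rendered image genuinely
  mixes the neighbours' marker signal inside a nucleus, so per-nucleus
  intensity ground truth is ill-defined; the ≥ 99 % accuracy condition
  is therefore evaluated on geometry where the truth is exact. The
  analysis scripts additionally report accuracy on touching-nuclei
  stacks (≈ 98 %), quantifying that leakage.
* **Spheroid radii** 90–115 px keep areas inside the 1,000–50,000 px²
  gate; when a requested nucleus count cannot pack at the drawn radius,
  the radius is raised to the feasibility minimum
  (πr² ≥ 1.5 n d²) so rejection sampling stays bounded, and generation
  fails cleanly rather than looping if packing is infeasible.

What the generator does **not** emulate: optics (PSF blur, vignetting),
Poisson shot noise, nuclear shape variation, tissue-section geometry, or
spectral bleed-through. Passing the synthetic validation therefore shows
that the algorithmic chain is correct and calibrated under its own
assumptions — it does not certify performance on real micrographs with
out-of-focus light or irregular chromatin texture, where thresholds would
need re-tuning against manual counts.

# Numerical conventions

* Coordinates are 0-based `(row, col)`; polygons rasterize by the
  pixel-center-inside (even-odd, half-open) rule.
* 16-bit input maps linearly onto 0–255 with round-half-up; 8-bit input
  passes through unchanged.
* ROI polygon files, result tables and overlays are plain CSV/PNG;
  integer TIFF stacks round-trip bit-exactly.
* Manual review of automatic ROIs is represented by include/exclude
  flags in the ROI file, keeping an interactive step reproducible.
* Validation problem sizes (640×640 to 1000×1000 px images, 10 seeds,
  10,000-replicate null simulations) were chosen to exercise every code
  path at realistic densities while keeping a full run in minutes.

# Known limitations

* The rolling-ball estimator is a grayscale opening, not a sliding
  paraboloid; very large smooth gradients are flattened slightly
  differently.
* Watershed over-splits elongated or dumbbell-shaped single objects if
  `min_distance` is small relative to object size; the per-stage
  defaults encode the intended object scales.
* Mixed 8-/16-bit stacks are written at 16 bit; per-plane bit depth is
  not preserved on write.
* Dunn's test uses the normal approximation; for very small groups its
  p-values are approximate (the Mann–Whitney path enumerates exactly).
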