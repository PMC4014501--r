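---
title: "Morphometric profiling of 3D spheroid cultures: models and methods"
author: "spheromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of 3D spheroid cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromorph)
```

# The measurement problem

Epithelial cells embedded in laminin-rich extracellular matrix differentiate
into multicellular spheroids whose shapes report their biology: round,
polarized acini with hollow lumens at one end of the spectrum; irregular
filled masses in between; stellate structures with invasive protrusions at
the malignant end. A drug screen built on such 3D cultures produces hundreds
of structures per low-magnification (5x) confocal field and hundreds of
fields per plate, far beyond what visual scoring can handle. `spheromorph`
turns each field into a per-structure table of morphometric parameters and
provides the statistics layer that turns those tables into treatment-level
conclusions.

The pipeline has four phases per image — projection and pre-processing,
preliminary structure segmentation, substructural (cell-level) segmentation,
and parameterisation — followed by a screen-level statistics phase.

# Image model and pre-processing

Input is a multi-channel confocal stack (typically ~672 x 512 px per plane,
8-30 planes, 8- or 16-bit), a pre-projected 2D image, or a phase-contrast
frame. Because the sandwich-culture geometry confines spheroids to a narrow
focal band, analysis is deliberately two-dimensional: each channel is
collapsed by average intensity projection (AIP) — the per-pixel mean over
z-planes — and a maximum projection is available as an alternative. AIP is
the default; it is the projection the rest of the pipeline is calibrated
against, and on depth-1 input both are the identity.

Grayscale conversion is a weighted per-pixel channel sum. No channel
weighting is canonical for these stains, so the default weights all present
channels equally; weights are user-configurable and normalized internally.

Background normalization excludes the tails of the intensity distribution:
values at or below the 5th percentile map to 0, at or above the 95th to full
scale, linear in between. On sparsely populated fields the foreground can
occupy under 5% of pixels, which makes the upper clip land inside the
background; the thresholding step below is designed to survive that (see the
histogram-valley notes). Optional denoising (Gaussian, median, or 3x3
Laplacian edge enhancement) follows. Phase-contrast frames get large-kernel
median background flattening instead, which converts them to the same
dark-background regime the thresholding expects.

16-bit input is processed natively; only the threshold histograms are binned
to 256 bins after linear rescale.

# Preliminary segmentation

**Histogram-valley threshold.** The 256-bin histogram of the grayscale image
is smoothed with a Gaussian kernel (sigma 3 bins) and, if more than two
modes survive, smoothed repeatedly until it is bimodal (the classic mode
method). Three robustness rules matter in practice, all visible in the
degenerate-input tests:

* a mode must carry real mass (at least 10% of the mean bin count within a
  3-sigma window of the lightly smoothed histogram) — otherwise isolated
  outlier bins in a distribution tail masquerade as modes with perfectly
  empty valleys;
* the cut is placed at the *deepest* valley between adjacent surviving
  peaks, taking the middle of the minimal run when the valley is flat —
  this keeps the clip spikes that percentile normalization piles up at 0
  and full scale from displacing the background/foreground gap, which is
  always the deepest (usually exactly empty) valley;
* if the deepest valley is not a real dip (its floor above half the lower
  adjacent peak on the lightly smoothed histogram), the image is treated as
  unimodal and the function falls back to Otsu's method with a warning. A
  constant image yields an empty mask with a warning.

The user-facing `thresholdLevel` stringency maps level L to
valley + (L-1) x 2% of the dynamic range. The mapping is this package's
choice (only the direction — higher level, more stringent cut, smaller
foreground — is externally fixed); 2% per level makes level 5 visibly but
not destructively stricter than level 1, and the monotone-foreground
property is asserted over seeded fields in the test suite.

**Gap filling.** Thresholding marks dim interiors (hollow lumens) as
background holes. Background connected components fully enclosed by
foreground and *strictly* smaller than 1000 px are filled; a hole of
exactly 1000 px is retained. Foreground is 8-connected and background
4-connected (the standard duality). The bound is located to the pixel by a
bisection test in the acceptance suite.

**Watershed labeling.** A single morphological opening (disc, radius 3 px)
separates weakly touching structures, then the Euclidean distance transform
(EDT) of each 8-connected component is computed and its regional maxima
become watershed seeds. Two rules govern the seeds:

* maxima closer than `sensitivity` px (default 20) are merged by single
  linkage, and the merged cluster's centroid becomes the seed — this is the
  single knob controlling over- versus under-splitting of touching
  structures;
* a maxima cluster whose EDT peak is below `openingRadius + 1` is ridge
  residue (e.g. a thin invasive protrusion that survived the opening), not
  a structure center, and is dropped unless it is the only cluster.

Every foreground pixel of the *unopened* mask is then assigned to the
nearest seed of its component (Euclidean distance, ties to the lower seed
label). Assigning the unopened mask keeps thin appendages inside the
structure's pixel set — essential for the invasion features — while seeding
from the opened mask prevents those appendages from nucleating spurious
splits. On small masks this labeling provably equals a brute-force
nearest-seed assignment, which the test suite checks against an independent
double-loop oracle. Objects below `minStructureSize` (100 px) are discarded
and labels renumbered 1..N. The whole segmentation is deterministic: the
same input and configuration reproduce the label map bit for bit.

**Focus adjustment (3D input).** For stacks, each structure's focus plane is
the z-plane maximizing the intensity variance over the structure's pixels;
the threshold is then recomputed on that plane's histogram restricted to
the structure's bounding box and the structure's pixels re-evaluated
against the local cut. Structures are only ever shrunk, never split or
removed, so the label count is preserved; an empty re-evaluation keeps the
original pixels. Whether focus refinement may change topology was an open
design point; forbidding it makes the 2D and 3D paths agree on structure
counts by construction.

# Substructural segmentation

Within each structure, and separately for the green (viability) and red
(dead/apoptotic) channels, cells are extracted by Otsu's threshold computed
on the 256-bin histogram of the in-structure pixels only. Because Otsu
partitions *any* histogram, a noise guard requires the between-class
contrast to exceed `cellContrastMin` (default 0.35) of the in-structure
intensity range; channels that are noise-like inside a structure yield zero
cells instead of a spurious partition. The cell mask is cleaned by an
adaptive opening whose disc radius scales with the structure equivalent
diameter (`cellKernelScale`, default 0.02) but is capped at `cellKernelMax`
(default 1 px): substructures such as nuclei and apoptotic bodies have a
fixed physical size at fixed magnification, so the cleaning kernel must not
grow with the host structure — an uncapped kernel erases small dead-cell
dots inside large spheroids. Touching cells are split by the same
EDT/nearest-seed watershed with a cell-scale merge distance
(max(4, 2 x opening radius) px).

Body/appendage decomposition uses a second, larger adaptive opening
(`bodyKernelScale`, default 0.1 x equivalent diameter): the opened mask is
the body, and 8-connected components of the remainder that touch the body
and hold at least `minAppendageSize` (5 px, chosen to exclude single-pixel
contour ripple) are the invasive appendages. "Outline variance" — contour
ripple below the kernel scale — is thereby absorbed into the body rather
than counted. If opening empties the mask (thin, all-appendage structures),
the body falls back to the whole structure and the record is flagged.

# The parameter catalogue

Nineteen named parameters are written per structure; the five functional
ones are computed for the red and green channels separately (24 feature
columns). Two internal quantities — the center of mass and the radius — are
used by the formulas but not written to the result file. The verbal
definitions below are this package's explicit, configurable reading of each
parameter; each is pinned by fixtures with known geometry in the tests.

Let D be the set of Euclidean distances from the structure's center of mass
to its edge pixels (foreground pixels with a background 4-neighbor), and
the *radius* the m-quantile of D (m = 0.25 by default).

* **Area** — pixel count.
* **Roundness** — 100 x max(0, 1 − sd(D)/mean(D)): the edge-distance
  coefficient-of-variation form. A rasterized disk scores near 100, a
  10:1 rectangle tens of points lower. An isoperimetric alternative
  (4 pi A / P^2) is available behind `roundnessMethod = "isoperimetric"`.
* **FiltRound** — Roundness of the opened body mask; **RoundDiff** =
  FiltRound − Roundness, positive when the body is rounder than the whole
  (i.e. the outline, not the bulk, is irregular).
* **Roughness** — 100 x mean(|D − Ds|)/mean(D), where Ds is D ordered by
  polar angle and smoothed with a circular moving average (window 15):
  small-scale contour texture, distinct from appendages by scale.
* **AppIndex** — appendage area / body area, the severity-of-invasion
  index; **AppNumber**, **MaxApp**, **MedApp** — count and per-appendage
  length statistics, length being the maximum Euclidean distance from an
  appendage pixel to the body.
* **Closest** — center-to-center distance to the nearest other structure
  (−1 sentinel for a lone structure; the row wording fixes center-to-center
  rather than edge-to-edge); **Neighbors** — number of distinct 8-adjacent
  labels; **SharedBound** — structure pixels 8-adjacent to another label;
  **CellRatio** — 100 x total structure area / field area, a global value
  repeated per row.
* **Density**, **Deviation** — mean and standard deviation of channel
  intensity over the structure (Deviation reported unitless per the
  catalogue convention; it is computed on the structural channel).
* **AreaRatio** — 100 x (cell area)/(structure area); for the red channel
  this is the cytotoxicity readout (AreaRatioR).
* **CellNumber**, **AveArea** — cell count and mean cell area per channel.
* **Hollowness** — 100 x max(0, 1 − mean(core)/mean(rim)) with the core
  the pixels within half the radius of the center of mass. The 50% split is
  this package's choice, made so that bright annuli (polarized, lumen
  forming) score high while filled disks score near 0; both ends are
  asserted in the tests.

# Screen statistics

Records are annotated against a plate map (image → well, position,
treatment, ...; ambiguous or missing mappings are hard errors), then QC
filtered: minimum object size, optional per-feature range limits, and a
manually curated excluded-structures list, with every rejected row carrying
a reason code.

The heatmap statistic is the difference in medians between each treatment
and the control, standardized per feature *across treatments* to unit
variance — the only reading of column standardization that makes features
of different units comparable on one color scale. Zero-variance feature
columns are set to 0 and flagged. Significance per cell is the two-sided
Mann-Whitney U test against the control — exact when both groups have at
most 8 tie-free observations, normal approximation with continuity and tie
correction otherwise — Bonferroni-corrected by multiplying by the number of
treatments T (capped at 1), masked at corrected p < 0.05. Standardization
happens before the p-mask is applied; whether to standardize before or
after filtering was open, and standardizing first keeps the displayed
magnitudes independent of the mask. Under a global null with T = 19 the
family-wise false-positive rate stays below 5% (asserted by simulation).

Feature similarity uses Spearman rank correlation (average ranks on ties;
constant features recorded as 0 and flagged), and heatmap axes are ordered
by complete-linkage clustering of Euclidean distances (`stats::hclust`,
deterministic tie handling).

Robustness QC fits the linear mixed model

    value = grand mean + well effect + position-within-well effect + residual

by REML (`lme4`), with wells and positions-within-wells as random effects —
positions are fields of a well, so nesting is the physically sensible
structure. The three standard deviations and their ratios to the residual
are reported; a robust screen has well and position components consistently
smaller than the residual. REML was chosen over method-of-moments for
non-negative estimates. Parameter recovery (planted sd 2/1/1 on a
20-well x 4-position x 25-observation design, within 25% on the 10-seed
median) is part of the acceptance suite.

# The synthetic-field generator

Because no public image set accompanies this problem, the generator is the
package's test surface, and every test traces back to quantities it plants:

* structures are radially deformed disks, r(theta) = R(1 + low-order
  cosine deformation + high-frequency ripple), with radius R ~ N(25, 5^2)
  px truncated at 2.5 sd — the size regime of spheroids under a 5x
  objective at 672 x 512 px;
* appendages are rays of configurable length (default 15-35 px) and width
  (6 px) planted at known angles; hollow structures dim their inner 50%
  radius core; red "apoptotic dots" (radius 2.5 px) are placed
  non-overlapping inside the body so the planted count equals the rendered
  component count;
* intensities: background 20, rim 200, dots 220, additive Gaussian noise
  sd 5 on an 8-bit scale, plus ~10% multiplicative intra-structure texture
  (real spheroids are not flat; texture also makes defocus measurable);
* centers are rejection-sampled with a minimum spacing that keeps *bodies*
  disjoint by construction (appendages may touch a neighbor, which
  exercises the watershed split without changing counts); infeasible
  packings fail loudly after bounded retries;
* 3D stacks render each structure sharp at a per-structure focus plane and
  defocused elsewhere (Gaussian blur plus pinhole dimming 1/(1 + 0.8
  sigma)), so in-structure variance peaks at the focus plane;
* the same seed renders bit-identical output, and rendering does not
  disturb the caller's RNG stream.

`makeScreen()` arranges fields in a wells x positions design per treatment,
applies treatment effects as multiplicative modifiers of the phenotype
specification (e.g. cytotoxic: dot rate x3; anti-invasive: appendage count
down; growth inhibition: radius down), optionally adds log-normal well and
position offsets for variance-component testing, and writes TIFFs plus a
plate map so the command-line front end runs end to end on files.

What the generator does *not* emulate: optics (no PSF model), shot noise,
staining gradients, debris, and densely overlapping cultures. Passing tests
therefore demonstrate correctness of the measurement definitions and the
pipeline's wiring under controlled conditions, not segmentation performance
on adverse real-world material — on real screens the sensitivity/threshold
knobs and the QC layer exist precisely because fields are messier than
these.

# Problem sizes and numerical choices

The test and acceptance suites run on 384 x 512 px fields with 5-6
structures (50 seeded fields for recovery rates, 10 for monotonicity), 500
null replicates for the family-wise error rate, and 10 seeds for
variance-component recovery; these sizes give stable rates while keeping a
full run in the low minutes on one core. Other numerical choices collected
in one place: histograms use 256 bins over the full dynamic range; valley
ties resolve to the middle of the minimal run; quantiles are R's default
type 7; watershed ties go to the lower seed label; seed-cluster order (and
hence labeling) follows first-pixel raster order; the hollowness core/rim
split is at 50% of the quantile radius; appendage components need 5 px and
body contact.

# Known limitations

* The appendage/deformation boundary is a scale decision: a genuine
  low-order lobe of a deformed body can be counted as an appendage when it
  survives the body opening (about 1-2% of structures at the generator's
  deformation settings). Both features measure real shape irregularity;
  only their attribution differs.
* Counting merged, heavily overlapping dead cells as one object is
  inherent to connected-component counting; AreaRatioR is the robust
  cytotoxicity readout, CellNumberR the approximate one.
* The CSV writer is the canonical result path; spreadsheet output is not
  built in.
* No time-lapse tracking and no volumetric segmentation: the pipeline is
  2D by design, resting on the narrow focal band of the culture geometry.
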