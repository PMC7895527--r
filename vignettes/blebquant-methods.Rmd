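---
title: "Quantifying bleb-based amoeboid motility: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bleb-based amoeboid motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebquant)
```

## The problem

Confined flagellates (the motivating system is the choanoflagellate
*Salpingoeca rosetta* compressed below ~3 µm) retract their flagellum and
switch to an amoeboid phenotype: they stochastically nucleate blebs —
cortex-free membrane protrusions that expand over minutes and retract
once actomyosin reinvades — crawl slowly (~0.1–0.3 µm/min), and can
escape a confinement zone by elongating across its border. blebquant
turns time-lapse movies of such cells into quantitative readouts:
a blebbing-activity score, protrusion counts and classes, phenotype
calls, escape geometry and morphodynamics, cortical enrichment ratios,
and replicate-aware statistics.

## The blebbing-activity statistic

Movies are resampled to one frame per 20 s, truncated to the first
240 s, and registered to the first frame (integer-pixel FFT
cross-correlation) so that global stage drift does not masquerade as
shape change. For a tracked cell with masks $M_t$ on this grid, each
step scores

$$ d_t \;=\; \frac{\lvert M_t \setminus M_{t-1}\rvert +
\lvert M_{t-1}\setminus M_t\rvert}{\lvert M_t\rvert}, $$

and the cell's activity is the mean of $d_t$ over all steps. It is
unitless (fraction of the footprint turned over per 20 s) and equals
zero for a static cell. Two normalizations are available: the default
divides each step by the current-frame area (each step is then a local
rate); `normalization = "mean"` divides by the track-mean area. The
difference is computed on globally registered frames without per-cell
re-centring; cells moving more than 5 px per step are excluded upstream,
which bounds translation leakage.

An irreducible *activity floor* exists even without blebs: a cell
crawling at 0.3 µm/min shifts its rasterized outline by a fraction of a
pixel per 20 s, turning over roughly 4–5% of its footprint per step at
the default geometry. This floor is a property of the measurement
itself, identical in kind to what any pixel-based implementation would
see; the phenotype threshold (below) is calibrated to sit above it.

## Track quality control

A track is excluded when its duration is under 200 s, or when any
considered time point has area < 500 px (at 0.1625 µm/px), centroid
displacement > 5 px between consecutive 20 s points, absolute relative
area change > 10%, or circularity < 0.7. "Change" is read as absolute
change in either direction. The exclusion report counts every rule a
track violates, so the per-reason counts can exceed the number of
excluded tracks in general.

## Morphometrics

Descriptors come from the pixel set of a single 8-connected component:
centroid as the pixel-centre mean; area as pixel count × spacing²; axes
from the second central moments (axis length $4\sqrt{\lambda}$ of the
covariance eigenvalues, which reproduces the semi-axes of an ideal
ellipse); aspect ratio $a/b \ge 1$; circularity $4\pi A/P^2$. The
perimeter estimator matters because the 0.7 circularity threshold is
read against it: we use the Kulpa-corrected Freeman chain length
(straight steps weighted 0.948, diagonal 1.340), which is asymptotically
unbiased for smooth outlines and gives a digital disc circularity within
a few percent of 1. The raw 1/√2 chain (which overestimates smooth
perimeters by ~5% and pushes a disc's circularity to ~0.91) remains
available via `perimeter_correction = "none"`.

## Protrusion classification and nucleation counting

Connected components of the gained region between consecutive frames are
*expanding* protrusions; components of the lost region are *retracting*
ones. Components under `min_protrusion_px` (default 10 px at 0.1625
µm/px) are treated as boundary flicker.

Counting *distinct* blebs is harder than classifying steps, because a
growing bleb produces a gained ring every step and neighbouring blebs'
rings can merge into one component. `count_bleb_onsets()` therefore
works in boundary-angle space: gained pixels are binned by angle around
the current centroid (2° bins), the previous step's coverage (dilated by
6° to absorb ring widening) blocks re-detection, and each novel angular
run of 6–90° containing at least 5 gained pixels counts as one
nucleation. Runs wider than 90° are translation crescents from cell
motion, not blebs, and block without counting; runs still below the size
minimum do not enter the blocking coverage, so a slowly growing bleb
stays novel until it first qualifies and is then counted exactly once.
At high nucleation rates the cell boundary crowds with concurrently
expanding blebs and angular novelty saturates; with the default
kinetics, recovery is within ~±10% of the true count at 0.5–1 events/min
and within ~20% at 2 events/min — a physical identifiability limit of
crowded boundaries rather than a detector artefact.

## Phenotype threshold

The amoeboid phenotype is defined by the presence of dynamic
protrusions; no numeric activity cutoff exists because the original
scoring was visual. `calibrate_activity_threshold()` makes the choice
reproducible: simulate non-blebbing cells, render them with noise, run
the full segmentation/tracking/activity pipeline, and take the 99th
percentile of the resulting activities. By construction this bounds the
false-amoeboid rate near 1% under the calibration conditions;
classification accuracy is then limited mainly by genuinely ambiguous
cells (a "blebbing" cell that happens to nucleate nothing inside the
240 s window is indistinguishable from a flagellate). The threshold is
inclusive: activity exactly at the threshold is called amoeboid.

## Escape-assay geometry

The confinement border is a circle; distances use the unsigned gap to
the circle, $\bigl|\,\lVert p - c\rVert - R\,\bigr|$, evaluated at every
cell pixel (front = minimum, rear = maximum) and at the centroid, while
escape *state* uses the signed side ($\lVert p - c\rVert > R$ =
outside). Published escape criteria do not say whether "escape" meant
the first protrusion across the border or the whole cell, so both times
are reported: `t_front_s` (any pixel outside) and `t_complete_s` (all
pixels outside); `escaped` keys on the sharper whole-cell crossing.
Escape angles compare each centroid step with the outward radial
direction — the shortest possible escape path — and skip sub-half-pixel
steps. Speed over a sliding 2-min window is total path / duration;
directional persistence is reported in the published form, total path
over Euclidean displacement (≥ 1, larger = more tortuous). Because that
form *increases* when straightness decreases while the accompanying
text described persistence as decreasing, the conventional reciprocal
(∈ [0, 1], larger = straighter) is exposed as
`definition = "conventional"`; no intent is guessed and the default
stays paper-literal.

## Fluorescence quantification

Linescans sample the image along a segment at ≤ 1 px spacing with
bilinear interpolation, averaging `width_px` parallel lines. Peaks are
local maxima filtered by topographic prominence relative to the profile
range. The cortical/cytoplasmic ratio was not given a published formula;
we use region means — cortex = mask pixels within a band (default
0.5 µm, matching the visible cortex width) of the boundary, cytoplasm =
the eroded interior — which is scale-invariant and robust to noise; a
peak-height alternative can be assembled from `linescan()` +
`detect_peaks()`. This is flagged as an approximation of an unspecified
procedure.

## Replicate statistics

SuperPlot tables separate technical replicates (cells) from biological
replicates (batches); all inference consumes replicate means — the
anti-pseudoreplication convention — unless the user explicitly opts into
per-cell mode, which warns. Dunnett's many-to-one comparisons use the
exact product-correlation structure
$\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}$ and evaluate the
two-sided multivariate-*t* box probability by a deterministic 2-D
Gauss–Legendre quadrature over the shared latent factor and the pooled-SD
scale (64 nodes each; agreement with `multcomp::glht` is ~10⁻¹² and the
null family-wise error calibrates to 0.05 within Monte-Carlo error).
With one treatment it reduces exactly to the pooled two-sample
*t*-test. The Mann–Whitney *U* test enumerates all
$\binom{n_x+n_y}{n_x}$ labelings when $n_x+n_y \le 12$ without ties and
otherwise uses the tie-corrected normal approximation with continuity
correction.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture:
cells are discs (radius 2.5 µm) rasterized by pixel-centre membership at
0.1625 µm/px, crawling as persistent random walks (default 0.3 µm/min,
directional correlation 120 s) with reflecting walls, never overlapping
(initial placement enforces a separation margin covering the maximal
programmed drift). Blebs nucleate as a per-cell Poisson process at a
fixed boundary angle, growing linearly to 1.5 µm over 170 s and
shrinking over 340 s — the expansion and retraction timescales of the
one fully documented bleb in the source imagery; nucleation rates are
not reported there, so the default (1/min) is simply a regime in which
blebs are frequent but countable. Per-cell substream seeds
(`(seed mod 1e5)·10007 + 7919·cell_id`) make each cell's trajectory
independent of `n_cells`. The escape simulator places one cell inside a
circular border, blebs in place (events scheduled to finish before
crawling starts, so the crossing geometry is clean), then crawls
radially outward while the body deforms area-preservingly into an
ellipse whose aspect ratio ramps to 1.8 during crossing and relaxes
afterwards; ground-truth crossing times come from the analytic radial
extents of the ellipse and any active bleb discs. The fluorescence
render paints cytoplasm at a baseline, a cortical band (default 0.5 µm)
at a chosen enrichment ratio — omitted on currently expanding blebs,
which are cortex-free — and adds seeded Gaussian noise.

What the generator does *not* emulate: membrane mechanics, DIC optics,
photobleaching, cell–cell contact, flagella and microvilli, 3-D shape.
Passing tests therefore demonstrate that the pipeline recovers known
geometry and kinetics under realistic sampling, noise and crowding — not
that it segments arbitrary real microscopy.

## Numerical choices and degenerate inputs

Pixel indices are 0-based (row, col) in documentation terms; physical
coordinates are `(index − 1) × spacing` µm with y pointing down. Masks
use 8-connectivity throughout (thin bleb necks must not split
components). Resampling picks nearest frames (ties to the earlier
frame) and never interpolates masks. Registration returns zero shift
with a message on flat correlation; empty frames segment to zero
labels; empty masks, multi-component masks, bands swallowing a cell,
zero net displacement windows, and centroids at the circle centre are
each either an error or a logged skip, as documented on the function.
Problem sizes in the test-suite and acceptance runs (cohorts of 20
cells per condition, 640-px frames, 10-min movies, 10⁴ null replicates
for test calibration) were chosen as the smallest sizes at which the
statistical assertions are stable.

## Known limitations

Activity conflates motion flicker with blebbing below the ~5% floor;
nucleation counting degrades on crowded boundaries; the greedy linker
assumes cells do not touch (guaranteed in simulation, approximate on
real data); the cortical ratio depends on the chosen band width; and
segmentation is a classical pipeline tuned for bright-cell renders —
real DIC data would need the learned segmenters it stands in for.
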