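---
title: "Stereology of the endomysium: models, estimators, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereology of the endomysium: models, estimators, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomorph)
```

## The measurement problem

In a transverse section of skeletal muscle, fibers form a polygonal mosaic
separated by a thin (1–5 μm) sheath of connective tissue, the endomysium.
Two immunofluorescence strategies make this geometry measurable. Boundary
stains (laminin-γ-1 / collagen IV) label the basement membrane: a bright
line surrounds every fiber, the fiber interiors are dark, and the
endomysium must be *derived*. Fill stains (collagen I / III) label the
endomysial band itself, so a black/white pixel count gives the areas
*directly* but the fiber geometry must be approximated. `myomorph`
implements both routes over a common set of stereological formulas, and a
synthetic-data generator that makes every estimator testable against known
truth.

## Estimators

For a rectangular ROI (area $A_{ROI}$, perimeter $P_{ROI}$) containing
$N_f$ fibers, $N_t$ of them cut by the ROI border:

$$N_c = N_f - N_t/2, \qquad \bar A = A_f / N_c, \qquad A_e = A_{ROI} - A_f,$$
$$\bar t = \frac{A_e}{P_f/2 - P_{ROI}}, \qquad \hat P_f = 4\sqrt{\bar A}\,N_c .$$

The half-count of trimmed fibers makes $N_c$ an unbiased fiber count under
random ROI placement (a border fiber is, on average, half inside). The
thickness estimator divides the endomysium area by an estimate of the
band's total mid-line length: every interior band segment is bordered by
two fibers, so half the total fiber perimeter counts each segment once;
the $P_{ROI}$ subtraction removes the contribution of the ROI border,
where fiber edges face the ROI boundary instead of another fiber. The
square-approximation $\hat P_f$ serves the fill-stain route, where no
per-fiber perimeters exist.

### Known bias of the thickness estimator

Write $P_f = 2 L_{band} + L_{border}$, where $L_{band}$ is the total
band mid-line length and $L_{border} \approx P_{ROI}$ the fiber edge
length lying on the ROI border. Then

$$P_f/2 - P_{ROI} \;=\; L_{band} - \tfrac{1}{2}P_{ROI} - \tfrac{1}{2}(P_{ROI}-L_{border}) \;\approx\; L_{band} - \tfrac{1}{2}P_{ROI},$$

i.e. the denominator *undershoots* the true band length by about half the
ROI perimeter, so $\bar t$ *overestimates* the thickness by roughly
$P_{ROI} / (2 L_{band})$ — about 10–13% at 100–120 fibers per ROI, shrinking
as $1/\sqrt{N}$. A second, smaller upward term comes from the band's
triple junctions, whose area exceeds the band-width times mid-line-length
model (larger for thicker bands). The formula is kept exactly as stated
because it is the field's published convention; the alternative
$(P_f - P_{ROI})/2$, which our derivation above would suggest, is nearly
unbiased, but it is *not* what the convention computes, so we document the
bias rather than silently change the estimator. The acceptance script
measures the recovery error directly (`thickness_recovery_median_relerr_pct`).

A related convention: trimmed fibers contribute their clipped area to
$A_f$ and their clipped perimeter — *including* the cut edge — to $P_f$.
This matches what segmentation software reports for a clipped region, and
the $P_{ROI}$ term in the denominator is precisely the correction for
those cut edges. Excluding the cut edge instead would double-correct and
roughly triple the thickness bias.

## The mosaic generator

`generate_mosaic()` builds the tissue model the estimators assume:

1. lattice sites (hexagonal by default; square lattice available as a
   closed-form "grid mode") at spacing chosen so the inset cell hits the
   target mean fiber area, jittered by a Gaussian whose scale maps
   `fiber_area_cv` onto the realized area spread;
2. the Voronoi tessellation of the sites (computed by iterative half-plane
   clipping; cells are convex polygons);
3. each cell inset inward by $t/2$, so adjacent fibers are separated by a
   band of width exactly $t$ — the generative thickness is a direct
   parameter, not an emergent property;
4. clipping to the ROI; a fiber that loses area to the ROI border is
   flagged trimmed. Sub-resolution border slivers (below
   `min_fiber_area_um2`, default 10 μm²) are excluded from the fiber
   ground truth but their basement membrane is still rendered;
5. rendering: the boundary modality draws a bright membrane line of width
   `boundary_width_um` *outward* from each fiber polygon into the band
   (so fiber interiors stay unbiased); the fill modality renders the band
   bright and interiors dark. Both get additive Gaussian noise and 16-bit
   quantization. The default line width is $0.75\,t$, clamped to
   $[t/2, t]$: at least half the band per side so that opposing membranes
   tile the band without an unstained mid-corridor, and at most the band
   width so the line never invades a neighboring fiber.

Default conditions emulate a soleus-muscle ROI: 750 × 750 μm at
0.5 μm/px, target mean fiber area 5500 μm² with CV 0.25 (matching
reported soleus means near 5000–7000 μm² with SD/mean ≈ 0.22), band
thickness 3 μm, 30% type II fibers — approximately 120 fibers per ROI.
Fiber types are assigned independently or spatially grouped through a
fixed number (20) of composition-preserving swap sweeps with interaction
strength `type_clustering`.

What the generator deliberately does **not** emulate: perimysium,
staining gradients and autofluorescence, out-of-plane sectioning obliquity,
nuclei, and the irregular (non-convex) outlines of pathological fibers.
Passing recovery tests on these mosaics therefore validates the
*estimators and their implementation*, not robustness to every real-world
staining artifact.

## Segmentation

The boundary modality is thresholded (inter-class-variance/Otsu by
default, with a fixed-value override for reproducibility), optionally
closed morphologically, and the complement is decomposed into 4-connected
components; 4-connectivity prevents fibers from leaking diagonally through
thin membrane lines. Components below the minimum fiber area are
discarded, and a border-touching component far larger than its peers
(over 25× the median, or most of the ROI) is treated as background — this
is what turns an all-dark image into "no fibers" rather than one giant
fiber. Per-fiber area is pixel count × pixel area; perimeter and Feret
diameters are computed on the convex hull of the pixel centres, expanded
outward by half a pixel because the region physically extends half a
sample step beyond its sampled centres (on pixel-aligned rectangles this
expansion makes the perimeter exact). Fiber cross-sections are convex to
good approximation, so the hull is the natural contour model; a Crofton
correction is deliberately not applied. Feret diameters use a
720-direction caliper sweep (0.25° resolution).

Degenerate inputs are defined, not exceptional: an empty image yields an
empty fiber list; a flat image has no threshold and no boundary network; a
non-positive thickness denominator yields an `NA` flagged undefined, with
a warning — never a silent negative thickness. A section with zero
endomysium has thickness 0 by definition.

## Diagnostic rules

`classify_biopsy()` applies a fixed precedence cascade: (1) chronic
neurogenic atrophy when at least one contiguous type I *and* one type II
group of ≥ 15 fibers exist (components of the same-type subgraph of the
shared-boundary adjacency graph); (2) type II fiber atrophy when more
than half of type II fibers have a minimal Feret diameter more than 12%
below the *population mean* of type I (per-fiber counting against a
population-mean reference — the standard myopathometric reading; a
shifted-mean criterion is the documented alternative); (3) unspecific
myositic changes on any inflammatory-infiltrate flag; (4) unspecific
myopathological changes on any minor finding; (5) normal. Single labels
per biopsy force a precedence; the rarest and most specific patterns are
checked first. Under purely random typing (30% type II, ~100 fibers on a
triangular adjacency), chance same-type grouping triggers rule 1 in
just under 10% of populations — a useful reminder that the grouping
criterion is a screening rule, not proof of reinnervation.

## Statistics

Two-group comparisons gate on Shapiro–Wilk at α = 0.05 per sample (the
test and level are our documented choice; conventions differ), then
Welch's *t* (unequal variances) or Mann–Whitney *U*, both two-sided, with
no multiple-testing correction across group pairs — the individual
significances are reported as such. Bland–Altman agreement uses the 1.96
multiplier for the limits of agreement (not a *t* quantile) and ordinary
least squares of difference on pairwise mean for the proportional bias.

The proteomics chain operates on log-abundance matrices with explicit
missingness: the valid-value filter keeps proteins quantified in ≥ 70% of
samples of at least one group (exact fractions: 7/10 passes, 7/11 fails);
imputation draws from a Gaussian centred 1.8 sample-SDs below the sample
mean with width 0.3 SDs (the standard detection-limit model); ANOVA and
pairwise Welch statistics get their FDR from group-label permutations
(labels permuted identically across proteins; default 1000 rounds, seeded;
the SAM-style fudge `s0` defaults to 0). The presence/absence screen runs
*before* imputation — imputation erases exactly the pattern it looks
for — and flags a protein when its detection fraction is ≤ 0.25 in one
group and ≥ 0.8 in all others; the bounds are calibrated so that a
2-of-10 detection against 9/10, 9/11, 12/12 elsewhere is a positive, and
both are configurable.

## Problem sizes and reproducibility

The default test-suite mosaics are 300 × 300 μm at 1 μm/px (~30 fibers),
which exercises every code path in seconds; recovery studies use
full-size 750 × 750 μm ROIs at 0.5 μm/px over 20 seeds, and statistical
calibration uses 10⁴ null draws — sizes at which the Monte-Carlo error is
comfortably below the asserted tolerances. All randomness is drawn from
one seeded generator per call (`withr::with_seed`); no global state is
left behind, and identical seeds reproduce images bit-for-bit.

## Limitations

* The thickness estimator inherits the convention's $O(1/\sqrt{N})$
  upward bias described above; comparisons *between* groups measured with
  the same ROI protocol are unaffected, absolute values should be read
  with the bias in mind.
* The membrane-line placement of real boundary stains (inner edge versus
  centre of the basement membrane) is not standardized across software;
  we fix "line belongs to the endomysium", which can introduce a constant
  offset relative to other tools.
* Infiltrates, ragged-red fibers, COX-negative fibers and centralized
  nuclei enter the classifier as counts/flags, not from pixels.
* Peptide-to-protein rollup, database search, and enrichment analysis are
  out of scope for the proteomics chain; protein-level wide tables are
  assumed.
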