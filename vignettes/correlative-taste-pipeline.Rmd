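---
title: "Methods: correlative taste-cell imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative taste-cell imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `corrtaste`. The package analyzes correlative taste-bud
experiments: in vivo two-channel calcium imaging (green GCaMP6f activity
over red tdTomato structure) of the same taste bud that is subsequently
fixed, sectioned and probed over several smFISH/HCR and immunofluorescence
rounds, with nuclear staining as the round-to-round landmark.

## Functional model and trace statistics

Taste responses are modeled ratiometrically. For an ROI (a cell footprint on
the apical plane, or an afferent-nerve region on the basolateral plane) the
per-frame ratio is `mean(G)/mean(R)` — ROI means are taken *before* the
division, because pixelwise ratios blow up at dim red pixels and the ROI
mean suppresses that division noise. From the ratio trace R(t) and the
baseline (artificial-saliva) window:

- ΔF/F(t) = R(t)/μ₀ − 1,
- Z(t) = (R(t) − μ₀)/σ₀,

with μ₀, σ₀ the baseline mean and sample SD. These are exact identities in
the code (the Z-trace has mean 0, SD 1 over the baseline by construction); a
constant baseline raises an error rather than silently producing zeros.

**Responsiveness.** Two printed criteria exist for calling an epoch
responsive: a peak-Z rule (Z during stimulation exceeding 2 baseline SDs)
and a mean-Z rule (mean epoch Z above 1). Which one applies where is
ambiguous for nerve ROIs, so the package conjoins them — an epoch is
responsive only if the peak exceeds `sdMult` (default 2) *and* the mean
exceeds `meanZCutoff` (default 1). The conjunction is the conservative union
of the two rules; both thresholds are exposed as parameters. Non-responsive
epochs have their mean Z clamped to 0.

**Response index and tuning.** The sweet–umami response index is
(S − U)/(S + U) on the *clamped* mean Z-scores. Clamped values are used
(rather than raw means) because the clamp is defined immediately before the
index and guarantees a positive denominator and an index in [−1, 1]. S = U =
0 is excluded (an `NA` sentinel, not an error). Because response amplitudes
vary across tastants and the analysis targets responsiveness rather than
magnitude, every intermediate index value classifies as dual-tuned; exactly
±1 are the single-tuned classes.

**Motion correction.** Per-frame translations are estimated on the red
channel (stable anatomy), summed over planes, against the temporal-mean
reference, via FFT cross-correlation with parabolic subpixel refinement, and
applied identically to both channels. Rigid translation only: the movies are
short and the jitter is respiratory/pulsatile, not deforming.

## Registration

**In vivo → fixed (non-rigid).** Fixation deforms the tongue epithelium
slightly. The package registers the in vivo reporter image to the round-1
fixed reporter with a cubic B-spline free-form deformation: displacement
u(p) is a tensor-product B-spline over a control lattice (default spacing 32
px — wide enough to forbid unphysical high-frequency warps, fine enough for
the smooth fixation distortion), optimized by L-BFGS-B on the mean squared
intensity difference with an analytic gradient, over a 3-level
multiresolution pyramid (factors 4, 2, 1). MSD is appropriate because both
images are the same modality (reporter) after intensity normalization. The
result is the dense deformation vector field, in the pull-back convention
`warped(p) = moving(p + u(p))`.

**Distortion QC.** For matched centroids the QC compares true vs recovered
*relative* displacement between every pair of points, expressed as a
percentage of the pair distance, aggregated as RMS per distance bin.
Pairwise centroid distance is used as the "measured distance" axis (the
natural reading for cell-to-cell measurements; a field-center reference
would be arbitrary for this geometry). On the default synthetic bud the
recovered field's error is well below 0.5% of distance over 20–200 px.

**Round-to-round (rigid).** Later rounds are each registered directly to
round 1 (not chained, so errors do not accumulate) on the nuclear channel:
a coarse rotation sweep (±8° in 1° steps) with FFT cross-correlation for
translation, then Nelder–Mead refinement of normalized cross-correlation
under bilinear warping. Rigid is sufficient because fixed sections do not
deform between probing rounds. QC reports the Pearson correlation over the
reference's Otsu foreground (background pixels would inflate the
correlation; the foreground restriction is the stricter choice and is
stated here deliberately) and line-profile peak offsets: profiles are
smoothed with a Gaussian of σ = 1 px, the reference peak is the (leftmost)
argmax, and the registered peak is searched within 15 px of it so the
offset measures the displacement of the *corresponding* structure. Default
lines run horizontally, vertically and diagonally through the brightest
landmark of the reference.

**Transform application.** Intensity images are resampled bilinearly; label
masks with nearest-neighbor lookup so labels are never blended and the label
set is preserved (up to border clipping); points are mapped analytically.
This triple consistency is property-tested.

## Spot calling and digital counting

Detection follows the established smFISH recipe: difference-of-Gaussians
(defaults σ = 1 and 2 px for ~1.5 px PSF spots), subtraction of the global
background (the image median — the simplest location-free global estimate),
local maxima above threshold with minimum-separation suppression (default 5
px; among maxima within the radius the brightest is kept — the criterion is
implemented as a suppression radius, one of the two readings of a
"local maxima within a radius" rule), then a subpixel 2-D Gaussian fit in a
7×7 window with a local planar background term; amplitude and background are
profiled out linearly so only (x, y, σ) are optimized, which converges
reliably; a diverging fit falls back to the integer maximum and is flagged.
The automatic threshold is median + 5 robust SDs (1.4826·MAD) of the DoG
image, with a small absolute floor (10⁻³ of the dynamic range) so noise-free
images do not degenerate to a zero threshold.

Counting is digital (dHCR): integer spot tallies per cell per gene against
the round-1 mask, after mapping later-round detections through that round's
rigid transform. Background spots within 2 px (default) of exactly one label
join it; of several labels, the nearest boundary wins — a deterministic,
reproducible stand-in for manual dense-region assignment — and exact ties
stay unassigned. Conservation (assigned + unassigned = detected) is tested.
A cross-plane merge (same gene, ≤2 px lateral, adjacent planes) prevents
double counting in pseudo-volumetric stacks.

## Segmentation

The round-1 cytosolic reporter uniformly fills taste-cell bodies, so
segmentation is Otsu foreground → Euclidean distance transform → watershed
(EBImage, peak-merge tolerance 2) → area filter (defaults 50–2000 px², the
taste-cell footprint scale at 0.5 µm/px). It is deterministic, replacing
interactive curation so the pipeline is fully automatable; hand-curated
masks load through `loadMask()` with invariant validation and are treated
identically. Nerve ROIs are user-supplied polygons (they are drawn manually
in practice; no automatic nerve segmentation is attempted).

## Correlative statistics

**IF positivity** defaults to a two-component Otsu split of per-cell mean
intensities (scale-invariant); a fixed threshold is supported.

**ROC.** The univariate classifier "feature > threshold" is traced over all
observed values; AUC by trapezoid equals the Mann–Whitney U statistic over
n₁n₂ (asserted to 10⁻⁹ in tests, with pROC as an independent cross-check);
the operating point maximizes Youden's J with ties resolved to the lower
threshold. Functional features default to per-tastant mean Z (pooling across
same-quality tastants is available as an option).

**Receptor classes.** Because type II cells cannot be typed from IF alone,
per-gene positivity cuts for the Tas1R subunits come from their counts in
CA4⁺ cells — sour cells do not express sweet/umami receptors, so they are an
in-tissue negative control. The cut is the control distribution's 95th
percentile (the criterion is printed, the percentile is not; 95% is the
conventional specificity choice and is configurable). Classes follow the
heterodimer logic: R2⁺/R3⁺ sweet, R1⁺/R3⁺ umami, R1⁺/R2⁺/R3⁺ dual, CA4⁺
sour, else negative. CA4 positivity itself uses the digital count threshold
(default 13 spots).

**Adjacency and dual-tuning attribution.** A cell is adjacent to a nerve ROI
if its label comes within `radiusUm` (default 2 µm — "adjacent" is never
quantified in print; 2 µm is roughly the scale of a wavy junction contact,
is declared in outputs, and is configurable). A dual-tuned nerve is
attributed as *intrinsic* when any adjacent cell co-expresses all three
Tas1R subunits — intrinsic co-expression takes precedence as the primary
driver when both patterns coexist — else *spillover* when separate sweet and
umami neighbors coexist (shared-cleft ATP diffusion), else unexplained. The
categories are exclusive and exhaustive; fractions sum to 1 whenever any
dual-tuned nerve exists.

## Synthetic data: what it emulates, what it does not

The generator produces scenes with known truth: elongated, radially oriented,
non-overlapping cell footprints packed in a circular bud (default diameter
60 µm, within the 40–80 µm fungiform range) at 0.5 µm/px (a declared
default — consistent with 40× imaging — not an inferred value; frame rate
1 Hz likewise). Classes are drawn i.i.d. from requested fractions. Counts:
high expressers ~ NegBin(mean 25, size 5), negatives ~ Poisson(1), truncated
to a floor of 10 / ceiling of 5 so class invariants hold for every draw; the
two distributions straddle the ~13-spot digital threshold that separates
marker-positive cells. Movies: red static per cell, green = red × (1 + ΔF/F)
with 1 s rise / 4 s decay kinetics (so the epoch plateau matches the nominal
amplitude to within ~2%, which the closed-form rendering test exploits);
apical cell responses and basolateral nerve responses on distinct planes;
optional uniform rigid jitter recorded as truth; the schedule defaults to
20 s saliva, then 20 s stimulus + 50 s washout per tastant. Histology: scene
content is defined in the in-vivo frame; round 1 samples it through a smooth
random B-spline warp (so non-rigid ground-truth recovery is well-posed
without inverting the warp), later rounds add their rigid truth; the
reporter exists only in round 1 (formamide quenching), nuclei attenuate by
20%/round (a progressive loss is expected; the rate is the package's
choice), fiducial landmark blobs persist unattenuated; spots render as
isotropic Gaussians (σ 1.5 px) with per-spot amplitude jitter.

Not emulated: realistic optical PSFs (Gaussian spots only), photobleaching
kinetics, tissue autofluorescence texture, probe aggregation, 3-D PSF
overlap between planes, and the wavy 3-D geometry of nerve–cell contacts.
Passing tests therefore demonstrate correctness of the *computation* under
the stated statistical structure, not robustness to every real-tissue
artifact.

**Desk-scale choices.** Image-level count-recovery experiments use smaller
per-cell counts (mean ≈ 5–6) with a 6–7 px minimum spot separation, because
~25 spots at >5 px separation cannot physically pack into a ~200 px² cell
footprint — the statistics-level experiments (ROC, stability) keep the full
NegBin(25,5)/Poisson(1) model on true counts. Property suites run at
documented sizes: 200 tuning-recovery buds of 6 cells at 48×48 px, a
12-seed rigid-recovery sweep at 128×128 px, and 256×256 px registration QC
scenes (~30 cells), the scale at which a single bud is acquired.

## Numerical notes and limitations

- Coordinates are 0-based, pixel-center, x = column, y = row; transforms act
  about the image center. Images on disk are 32-bit float TIFF, rescaled to
  [0, 1] with an exact affine range sidecar (the TIFF writer stores
  normalized samples); label masks are 16-bit TIFF.
- Registration determinism: both registrations are deterministic functions
  of their inputs (no stochastic optimization). The B-spline optimizer can
  in principle stop at a local optimum for warps much larger than the
  control spacing; the multiresolution pyramid handles the ≤3 px fixation
  scale with large margin.
- The rigid coarse search covers ±8°; larger round-to-round rotations would
  need a wider sweep (parameter `rotRangeDeg`).
- Dense spot clusters closer than the separation radius merge into single
  detections, deflating digital counts in very high expressers; counts
  remain monotone in expression, which is what the downstream thresholding
  uses. Spot decomposition is out of scope.
- Watershed may split strongly elongated cells at high tolerance or merge
  tightly touching ones; imported curated masks bypass this entirely.
- The per-purpose seed derivation keeps stages decorrelated under one user
  seed; all derived seeds stay below 2³¹.
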