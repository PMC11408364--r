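---
title: "Quantifying channel colocalization in confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying channel colocalization in confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcoloc)
```

## The problem

Confocal fluorescence microscopes record a specimen as a z-stack: a 3D grid
of voxels, one grayscale volume per fluorescent channel, where each voxel
value is the detected signal of one stained structure at that location.
Colocalization analysis asks whether two (or three) labelled molecules
occupy the same space. Two complementary views answer it:

* **Correlation** — do the intensities of two channels rise and fall
  together, voxel by voxel? Quantified here by Pearson's correlation
  coefficient (PCC).
* **Co-occurrence** — ignoring how bright a voxel is, do the channels'
  signal-bearing regions overlap? Quantified by intersection coefficients
  computed from binary masks.

voxcoloc computes both on thresholded, optionally ROI-restricted volumes,
and emits the diagrams and tables an analyst needs to document a run.

## Thresholds: one pair of bounds, two semantics

Every selected channel gets a `(lower, upper)` intensity pair. The upper
bound exists to discard oversaturated voxels; the lower bound separates
signal from background. The same pair is interpreted two different ways,
deliberately:

**Binary weight mask** (for all intersection coefficients). A voxel carries
valid signal iff `lower < v <= upper` — strict at the lower bound, inclusive
at the upper. Everything about co-occurrence depends on channels only
through these 0/1 masks. A direct consequence of the strict/inclusive
boundary pair: when `lower == upper` no value can satisfy the condition and
the mask is empty. This edge case is kept, documented, and tested rather
than "fixed", because it falls straight out of the defining inequality.

**Clip-and-subtract preprocessing** (for PCC only). Before correlating,
each channel is transformed: intensities above `upper` are set to 0, then
`lower` is subtracted and negative results are clamped to 0
(`v' = 0` if `v > upper`, else `max(v - lower, 0)`). The correlation is
then computed over *every* voxel of the (cropped) grid — zeroed voxels are
set to 0, not excluded from the sums. The alternative (restricting the sums
to voxels with signal in at least one channel) changes the coefficient; it
is not what the preprocessing rule describes, so full-grid summation is the
behaviour implemented and tested.

With the default full-range thresholds (`lower` = channel minimum,
`upper` = channel maximum) the preprocessing subtracts a constant, and PCC
reduces to the plain Pearson correlation of the raw intensities.

```{r thresholds}
v <- array(c(1, 3, 6), c(1, 1, 3))
t <- threshold_range(2, 5)
as.vector(weight_mask(v, t)$weights)   # 0 1 0: strict lower, inclusive upper
as.vector(preprocess_for_pcc(v, t))    # 0 1 0: clip, subtract, clamp
```

### The automatic threshold

`auto_threshold()` excludes the darkest and brightest 0.1% of the voxel
value distribution: `lower` is the 0.1st percentile and `upper` the 99.9th.
Percentiles are taken by the **nearest-rank** rule (`s[ceiling(p * n)]` on
the sorted values) rather than any interpolated quantile definition:
nearest-rank is dialect-free and reproduces exactly across platforms. The
choice of percentile convention is documented rather than claimed to match
any particular GUI widget bit-for-bit; for realistically sized channels the
difference is at most one intensity level.

## The coefficients

With mask sums `Sa`, `Sb` (and `Sc`), product sums `Sab`, `Sac`, `Sbc`,
`Sabc`:

* Two channels: the **global intersection coefficient** is
  `I = Sab / (Sa + Sb - Sab)` — intersection volume over union volume.
  Per-channel coefficients `i1 = Sab / Sa`, `i2 = Sab / Sb` express how
  much of each channel's own volume is shared.
* Three channels: `I = Sabc / (Sa + Sb + Sc - Sab - Sac - Sbc + Sabc)`,
  the denominator being the union volume by the inclusion–exclusion
  principle, and `i_k = Sabc / Sk`.

All sums are voxel counts accumulated in double precision (a 32-bit stack
with hundreds of millions of voxels would overflow single-precision
accumulation). Voxel spacing is carried as metadata only — the coefficients
count voxels, they do not weight by physical volume, so anisotropic spacing
scales numerator and denominator identically.

**Undefined outcomes are first-class.** A zero-variance preprocessed
channel makes PCC undefined; an empty union makes `I` undefined; an empty
channel makes its `i_k` undefined. These are reported as `"n/a"`, never
silently coerced to 0 — a 0 claims "no colocalization was measured", which
is a different statement from "nothing was measurable".

## ROI restriction

An ROI box is an axis-aligned sub-volume in `(z, y, x)` voxel coordinates,
0-based with half-open `[min, max)` bounds — ordinary array-slicing
semantics, chosen to remove the off-by-one ambiguity that inclusive bounds
invite. Boxes partly outside the stack are clamped (as when a box handle is
dragged beyond the rendered volume); a box that misses the stack entirely
is an error. Boxes may be given in microns and are converted through the
stack's voxel spacing. Every metric commutes with cropping: analysing a
cropped stack equals cropping first and analysing — a property the test
suite checks on random instances.

## Venn diagrams and the fluorogram

`venn_regions()` partitions the union of the masks into exclusive regions
(3 for two channels, 7 for three) and normalises each region's voxel count
by the **union** volume, so the displayed percentages sum to 100% and the
all-channels region equals `I` exactly. Union normalisation (rather than
whole-grid normalisation) is the internally consistent choice: it keeps the
central Venn field identical to the global coefficient the table reports.
Percentages are displayed with four decimal places; the underlying
fractions are kept at full precision and only rounded at render time.

`build_histogram2d()` is the fluorogram: raw intensity pairs binned on a
2D grid, x-axis first channel, y-axis second. Background voxels — outside
the valid band in **both** channels — are not plotted; a voxel is counted
iff at least one channel is in range (the OR rule). Because the valid bands
are the same ones behind the weight masks, the plotted voxels partition
exactly into valid-in-both / only-first / only-second, and those three
counts divided by the union volume reproduce the three regions of the
two-channel Venn diagram. Highly correlated channels gather along a line
whose slope is the fluorescence ratio. Default binning is 256 bins per axis
for 8-bit stacks and 512 otherwise: a full 16-bit axis would allocate a
65536² grid for no visual gain, and the bin edges are recorded in the
result and the HTML output. Counting always uses raw intensities — the
clip-and-subtract transform is a PCC-internal device, not a display
transform.

## File formats

**TIFF.** Stacks are multi-page grayscale TIFFs, channel-fastest interleave
(slice 1 channel 1, slice 1 channel 2, ...), the page order of ImageJ-style
hyperstacks. The TIFF container does not reliably announce a channel count
for arbitrary acquisition software, so `read_zstack()` takes `channels = N`
(`--channels-in-file` on the command line) and de-interleaves pages into
repeating channel blocks. Intensities are never rescaled on load. All three
depths (8/16/32-bit) are treated as unsigned integer count scales
`[0, 2^depth - 1]`; 32-bit samples are stored as unsigned 32-bit integers,
and integer counts round-trip exactly at every depth (verified voxel-exact
in the suite). Up to 15 channels may be loaded, but an analysis selects 2
or 3 — with each added channel the pairwise structure grows combinatorially
and the coefficients lose interpretability.

**Reports.** Every run writes a workbook (Summary sheet: stack, timestamp,
annotation, thresholds, ROI, artifact paths; Results sheet: all
coefficients) in SpreadsheetML XML — a plain-text format that Excel and
LibreOffice open natively — plus a CSV twin of the results sheet.
Coefficients are displayed with four decimals (round-half-even), undefined
values as `"n/a"`. The timestamp is injected by the caller, not sampled
inside the writer, so identical runs produce byte-identical files.

## The synthetic-stack generator

`generate_stack()` realises a `fixture_spec()`: solid spheres and boxes of
plateau intensity on a flat background, plus optional additive Gaussian
noise, rounded and clipped to the bit-depth range. Shape membership is
decided at voxel centers (integer coordinates), so every channel's true
mask is an exact, pre-computable voxel set — overlap volumes and therefore
all intersection coefficients have closed-form values. The constraint
`plateau > background + 5 * noise_sd` keeps the midpoint threshold at least
2.5 standard deviations from both levels, so mask recovery failures are
rare at moderate noise and vanish as the signal-to-noise ratio grows; the
suite checks that the recovered `I` converges to its geometric value across
three noise levels at a fixed seed.

What the generator deliberately does **not** emulate: the microscope's
point-spread function, Poisson shot noise, spectral crosstalk and
bleed-through between channels, depth-dependent attenuation. Those are
acquisition-side effects; passing tests on synthetic stacks therefore
demonstrates that the *computation* is correct, not that any particular
acquisition is well calibrated. Crosstalk in particular inflates PCC on
real data regardless of how faithfully the coefficient is computed —
sequential scanning and single-labelled controls remain the acquisition-side
remedies.

A worked example with exact integer geometry, on a 10×20×40 grid
(8000 voxels): channel 1 a box of 4000 voxels, channel 2 a box of 3000,
overlapping in 2000:

```{r engineered}
spec <- fixture_spec(
  dims = c(10, 20, 40), bit_depth = 8,
  shapes = list(
    list(list(type = "box", min = c(0, 0, 0),  max = c(10, 20, 20))),
    list(list(type = "box", min = c(0, 0, 10), max = c(10, 20, 25)))),
  plateau = 200, noise_sd = 0, seed = 7)
gen <- generate_stack(spec)
res <- analyze_coloc(gen$stack, c(1, 2), thresholds = gen$midpoint_thresholds)
res$global_intersection        # 2000 / (4000 + 3000 - 2000) = 0.4
res$per_channel_intersection   # 0.5 and 2/3
```

## Numerical and design notes

* **Problem sizes.** Validation sweeps use many small random stacks
  (hundreds of 4×6×6 grids with random thresholds) rather than few large
  ones: the coefficient definitions are scale-free ratios of integer
  counts, so a small grid exercises every code path — including empty
  masks, empty unions and zero-variance channels — while keeping each
  oracle comparison exactly checkable.
* **Oracle independence.** The suite checks the vectorised implementation
  against literal transliterations (per-voxel loops, explicit index-set
  arithmetic) kept separate from the library code.
* **Tie-breaks and edges.** `lower == upper` gives an empty mask (see
  above); `auto_threshold` of a constant channel returns that constant for
  both bounds; a duplicated third mask reduces the three-channel formulas
  exactly to the two-channel ones.
* **Determinism.** Generation is reproducible from the seed; reports are
  byte-stable given a pinned timestamp.

## Limitations

* No Manders', Spearman or overlap coefficients, and no significance
  testing of PCC.
* No Costes automatic threshold (regression on the fluorogram); the
  percentile rule is distribution-based, not model-based.
* Only axis-aligned box ROIs — no ellipsoids, cylinders or freehand
  regions.
* No deconvolution or denoising; noisy inputs should be filtered upstream,
  since noise systematically attenuates correlation.
* The TIFF reader expects uniform grayscale pages; RGB-interleaved or
  mixed-depth files are rejected rather than guessed at.
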