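---
title: "Quantifying NMJ puncta and co-localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NMJ puncta and co-localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

## The problem

Zebrafish neuromuscular junctions (NMJs) are imaged as two-channel confocal
z-stacks: a presynaptic marker (SV2, channel 1) and a postsynaptic marker
(α-bungarotoxin, channel 2). Each hemisomite contains dozens of bright
puncta per slice, each punctum one synaptic terminus. Two quantities matter
for NMJ morphology: how many puncta each channel contains, and how many of
them co-localize with a punctum of the other channel. Manual counting is slow
and biased, and confocal resolution fuses neighbouring termini into single
blobs, inflating per-punctum sizes and deflating counts.

`nmjquant` implements the full analysis as a deterministic pipeline: per-slice
preprocessing and thresholding, shape-based detection of fused ("clustered")
puncta, a recursive declustering algorithm driven by local intensity maxima,
and object-based co-localization by fractional area overlap, tallied at
eleven thresholds.

## Pipeline stages

### Preprocessing

Each slice of each channel is processed independently within the
user-supplied polygonal ROI (one per hemisomite, applied to all slices):

1. **Gaussian blur**, `sigma = 1` px by default. Separable convolution with a
   normalized kernel of radius `ceiling(4*sigma)` and reflect padding, so a
   constant image is preserved exactly and edges do not darken.
2. **Histogram expansion** ("LUT compression"): with observed extremes
   `min`, `max` and `range = max − min`, the window
   `[min + f·range, max − f·range]` (trim fraction `f = 0.10`) is stretched
   linearly onto the full bit range, saturating outside the window. For an
   8-bit slice spanning 0–255 the window is `[25.5, 229.5]`. This boosts
   contrast without letting a handful of hot pixels compress the histogram.
3. **Otsu thresholding** on the integer histogram of ROI pixels: the
   threshold `t` maximizes the between-class variance; foreground is strictly
   `> t`. Ties resolve to the smallest `t`. The implementation uses the exact
   integer-level histogram rather than a binned approximation, so it agrees
   with an exhaustive scan of all candidate thresholds level for level.
4. **Despeckle**: every 8-connected component with physical area
   ≤ 0.043 µm² is removed. At the default calibration (0.21 µm/px, one pixel
   = 0.0441 µm²) this floor is intended to catch single-pixel noise; note
   that it sits just *below* one pixel at exactly 0.21 µm/px, so the floor
   only bites when the calibration is at or below ~0.2073 µm/px or when the
   user raises `despeckle_area_um2`.

A slice that is constant within the ROI has no separable intensity classes;
it contributes an empty mask and a logged warning rather than an error.

### Punctum detection and classification

Foreground components (8-connectivity, the ImageJ particle convention) become
puncta. Three descriptors decide whether a punctum is a single terminus or a
fused cluster:

* **area** `A` = pixel count × pixel area (µm²);
* **circularity** `4πA/P²`, capped at 1, with the perimeter `P` measured by a
  Moore boundary walk (orthogonal steps 1 px, diagonal steps √2 px). A single
  pixel has no boundary walk and is assigned circularity 1 by convention.
* **aspect ratio**: major/minor axis ratio of the best-fit ellipse from
  second-order central moments. Each pixel contributes an additional 1/12
  variance per axis (a pixel treated as a unit square), which keeps the minor
  axis positive for degenerate (collinear) shapes and makes a single pixel
  exactly isotropic (ratio 1).

A punctum is **clustered** when *any* of: `A > 4 µm²`, circularity `< 0.65`,
aspect ratio `> 2.5` (all comparisons strict; a punctum exactly on all three
thresholds is single). The three defaults are the values tuned for zebrafish
NMJ puncta and are overridable per channel — the same machinery applies to
other punctate structures with different size regimes.

Puncta clipped by the ROI boundary are kept and flagged (`roi_clipped`)
rather than discarded; discarding them would bias counts low near the
hemisomite edge.

### Declustering (recursive seeded expansion)

Clustered puncta are split where the underlying intensity shows several
peaks. The slice is blurred (`sigma = 1` px); local maxima within the
punctum are found with a prominence criterion: a candidate peak is suppressed
if a higher pixel can be reached from it without descending more than the
prominence. Plateaus contribute one seed at the plateau pixel nearest its
centroid. The prominence defaults to **10% of the blurred slice's dynamic
range**. The original interactive workflow this package automates does not
record its noise tolerance, so this relative default is a package choice —
it is robust across bit depths, but absolute counts on real data can shift
with this parameter, and it is deliberately exposed (`--prominence`).

With `k ≥ 2` seeds, the punctum's pixels are partitioned by a deterministic
multi-source growth. Each seed keeps an ordered list of claimed pixels (the
seed is pixel 0). Growth proceeds over the claimed-pixel index; at each index
the eight neighbours are tried in the fixed order *top-left, left,
bottom-left, below, bottom-right, right, top-right, above*, and within each
direction seeds act in ascending label order; a neighbour is claimed iff it
lies in the punctum and is unclaimed, first claim wins. This makes the
partition a pure function of the mask and seed set: no randomness, no
dependence on iteration order of a hash map, identical output on every
platform. Each resulting region is 8-connected and contains exactly one
seed, and the regions partition the parent exactly (pixel conservation).

Children are re-measured and re-classified; clustered children re-enter the
worklist. A punctum with ≤ 1 maximum is **unsegmentable** and kept as is. A
lineage still failing the criteria after `max_rounds = 10` generations is cut
off as unsegmentable with a warning; every split strictly shrinks the largest
region, so the loop terminates even without the cap — the cap only guards
pathological parameterizations.

Unsegmentable clusters are *included* in totals and co-localization by
default: they are real signal, and dropping them would undercount termini.
`exclude_unsegmentable = TRUE` switches to the stricter reading in which only
puncta meeting the single-punctum criteria are tallied; both behaviours are
tested.

### Co-localization

Per slice, the two channels' post-segmentation foregrounds are intersected
pixel-wise (Boolean AND). For every punctum the overlap fraction is the
number of its pixels covered by the other channel divided by its pixel count
— computed in integer pixel counts, so calibration cancels and threshold
comparisons are exact. At thresholds `t ∈ {0, 10, …, 90}` a punctum is
co-localized iff `100·overlap_pixels > t·total_pixels` (strict), and at
`t = 100` iff it is fully covered. Counts are accumulated over all slices of
the ROI; a terminus spanning several z-slices is therefore counted once per
slice, matching the per-slice tally convention of the original workflow
(3-D linking across slices is possible future work). Both directions
(channel 1 against channel 2's foreground and vice versa) are tallied
independently.

The result table has, per ROI and channel, `total` and `single_t`/`coloc_t`
for the eleven thresholds; `single_t + coloc_t = total` always holds and
`coloc_t` is non-increasing in `t`.

## The synthetic-stack generator

`make_stack()` renders calibrated two-channel stacks with known ground
truth. It emulates the geometry that matters to the pipeline — spot density,
spot fusion, cross-channel overlap — and deliberately nothing else:

* **Isolated Gaussian spots** (default): spots on a shuffled grid of cells
  sized so neighbours never merge; with zero noise, detected counts equal
  planted counts exactly.
* **Fused groups**: listed spots share a cell, spaced `3·sigma` apart, so
  they merge into one component at threshold while keeping distinct peaks
  with a deep saddle — the declustering test bed.
* **Exact-overlap rectangles**: uniform-intensity rectangles 10 px wide, the
  channel-2 copy shifted so the channel-1 overlap fraction is an exact tenth
  by pixel counting. These fixtures are analysed with blur and trim disabled
  (`gaussian_sigma = 0`, `trim_fraction = 0`): blurring followed by Otsu
  grows a rectangle's mask by its edge ramp, which would perturb the
  by-construction exact fractions that the threshold-boundary tests rely on.

Defaults are 256 × 256 px frames, 2 slices, 50 spots per channel per slice at
0.21 µm/px, 8-bit, background 8, peak 200, `sigma = 3.2` px. The per-slice
spot density matches a typical hemisomite slice (tens of puncta); the frame
and slice count are scaled down from a real acquisition (1024 × 1024,
80–100 slices) so the whole validation suite runs in seconds — the pipeline
itself is size-agnostic. Noise is additive Gaussian, clipped to the bit
range; this exercises thresholding and prominence but does not model a
confocal PSF, axial blur, photobleaching, or autofluorescence gradients.
Passing tests therefore demonstrate algorithmic correctness on controlled
geometry, not parameter optimality on real microscopy data; the
shape-criteria and prominence defaults remain the quantities a user should
review on their own acquisitions.

`make_disease_contrast()` builds two matched stack sets, the depleted group
with ~28% fewer spots per channel and a lower cross-channel pairing rate,
to demonstrate that group means order correctly under the pipeline. It is a
qualitative construction only; it makes no claim about effect sizes in any
real disease model.

## Numerical and design choices

* **Coordinates**: `(row, col)`, 0-based in all file formats (ROI JSON,
  ground-truth sidecars), pixel centers at integer coordinates; boundary
  pixels count as inside an ROI polygon. One 2-D ROI applies to every slice.
* **Calibration priority**: explicit argument/config > JSON sidecar > TIFF
  resolution tags (cm or inch units) > hard default 0.21 µm/px with a
  warning.
* **Blur at two stages**: the detection blur and the declustering blur are
  applied independently to the raw slice, each with its own sigma; the
  declustering stage does not inherit the detection-stage blur.
* **Otsu within the ROI**: the histogram is computed over ROI pixels only,
  so a bright structure outside the hemisomite cannot shift the threshold.
* **Tie-breaks**: Otsu ties resolve to the lowest threshold; maxima with
  equal height are processed in row-major order; expansion conflicts resolve
  by direction-then-label order as described above. All tie-breaks are fixed,
  making the pipeline bit-deterministic end to end (two runs produce
  byte-identical CSVs).
* **Degenerate inputs**: constant slices warn and yield empty masks;
  degenerate (collinear or self-intersecting) ROI polygons are rejected at
  construction; empty puncta are errors at the overlap computation.
* **Connectivity** is 8-connected everywhere (labeling, despeckle, expansion
  regions), the ImageJ particle-analysis convention.

## Known limitations

* Counts are per-slice tallies; a terminus spanning `n` slices contributes
  `n` counts. Comparisons between groups imaged with the same z-step are
  unaffected; absolute counts are not "number of synapses".
* The maxima prominence default is a package choice (see above); absolute
  declustering behaviour on real data should be calibrated against a small
  manually-annotated set.
* The perimeter estimator (chain code with √2 diagonals) overestimates
  smooth contours by a few percent; circularity values are consistent within
  the package but not interchangeable with other software's estimators.
* Only TIFF input is supported; proprietary formats (CZI/LSM) must be
  converted first. ROIs are supplied as files, not drawn interactively.
* No intensity-based co-localization (Pearson/Manders): the method is
  strictly object- and area-based.

## Worked example

```{r example, eval = FALSE}
# two fused presynaptic termini, noise-free
fx <- make_stack(n_spots_per_channel = 2, fusion_groups = list(1:2),
                 n_slices = 1, noise_sd = 0, seed = 11)
res <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]))
res$counts[res$counts$channel == 1, ]
#>          roi channel detected single clustered parents_split children unsegmentable
#> 1 full_frame       1        1      2         1             1        2             0
res$table[res$table$channel == 1, c("total", "coloc_0")]
#>   total coloc_0
#> 1     2       0
```

The two planted termini fuse into one clustered component (`detected = 1`),
which the expansion splits into two single puncta (`children = 2`,
`total = 2`).
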