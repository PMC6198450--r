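---
title: "Methods: quantifying replication timing and repair kinetics of repetitive DNA"
author: "repkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying replication timing and repair kinetics of repetitive DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repkin)
```

# Scope and model

Repetitive DNA elements — SINEs such as Alu, LINE-1 retrotransposons,
pericentromeric satellites, LTR elements — make up roughly half of the human
genome, yet they are systematically under-represented in sequencing-based
analyses because most reads originating from them cannot be mapped uniquely.
`repkin` implements the computational side of a combined
genomics-plus-imaging strategy for asking when these elements are
replicated and how fast they are repaired after DNA double-strand breaks:

1. **Interval statistics.** Repeat abundance, GC content, RPKM coverage of
   chromatin marks, Repli-Seq stage signal and gammaH2AX ChIP signal are all
   projected onto a common grid of non-overlapping 10 kb genomic intervals
   and compared by Spearman's rank correlation, optionally stratified into
   repeat-rich versus repeat-poor intervals.
2. **Metarepetitive elements.** Multi-mapped reads are rescued by a
   class-signature rule: a read placed only within copies of one repeat
   class is counted for that class; a read touching two classes is
   discarded. Per-class fractions of the single-class-signature total give
   an aggregate ("metarepetitive") coverage per class; ratios against an
   unirradiated baseline give time-resolved enrichment.
3. **3D image quantification.** Nuclei are segmented from the DNA
   counterstain; colocalization between a repeat FISH probe and a
   replication (EdU) or damage (gammaH2AX) channel is quantified per
   z-plane by Pearson's r and by the H coefficient; S-phase substages are
   called from the spatial EdU pattern; gammaH2AX foci are segmented and
   the fraction of probe intensity inside them tracked over post-irradiation
   timepoints.
4. **Synthetic data.** Every input above can be generated with known ground
   truth, so each estimator in the pipeline is testable against planted
   values.

# Interval statistics

`bin_genome()` tiles each chromosome into half-open `[start, end)` intervals
of at most `width` bp (default 10 kb); the terminal interval keeps its true,
shorter length and RPKM uses that true length. Applied to the hg19
chromosome lengths this yields more than 290,000 intervals.

Two rules needed a decision that standard practice leaves open:

* **Boundary-spanning elements** are assigned to the single interval
  containing their midpoint (`floor((start + end) / 2)`, half-open lookup).
  This conserves copy number — the track sums to the number of annotations —
  which matches "number of copies" semantics; fractional assignment would
  not.
* **Reads** are counted at their 5' placement position, so a placement
  falls in exactly one interval. Multi-mapped reads contribute each
  placement here; the metarepeat rule below is a separate accounting.

Missing values are explicit (`NA`, never silently zero: an interval of all-N
sequence has no GC value, not a GC of 0) and are removed pairwise per
correlation cell, with the retained pair count reported as `n_used`.
Spearman's rho is the Pearson correlation of tie-averaged fractional ranks;
p-values use the asymptotic approximation (with genome-scale n the relevant
statement is only `P < 2.2e-16`), and no multiple-testing correction is
applied. Degenerate cells (constant input, fewer than 3 pairs) carry a
reason code instead of raising.

Stratification follows the repeat-rich/poor contrast: *rich* intervals have
strictly more than `threshold_rich` (default 10) elements per interval,
*poor* intervals exactly `threshold_poor` (default 0). Where the source
material gives two inconsistent wordings for "poor" (no elements
vs. more than one), the zero-count definition is used, because only it
makes the two strata disjoint and matches the accompanying text.

```{r correlation-example}
st <- simulate_tracks(2000, matrix(c(1, .6, .6, 1), 2),
                      labels = c("alu_count", "h3k9ac"), seed = 1)
correlation_matrix(st$tracks)
```

# The metarepeat rule

For a read with placements $P$ and $C(P)$ the set of repeat classes its
placements overlap (any overlap of at least 1 bp counts, as no minimum
overlap is prescribed):

* $|C| = 1$ and every placement inside that class: count for that class;
* $|C| \ge 2$: discard;
* $|C| = 0$: non-repeat;
* $|C| = 1$ but some placement outside any repeat: discarded by default,
  because counted reads must carry *only* the signature of a single class;
  `mixed_policy = "class"` switches to counting them, as the alternative
  reading is defensible.

Fractions are normalised to the total of single-class-signature reads
(non-repeat and discarded reads never enter the denominator), and
time-course enrichment is the ratio of fractions at a timepoint over the
baseline. Fraction ratios rather than raw-count ratios make the statistic
invariant to library size. No de-duplication is applied. The class
vocabulary is configurable via a grouping map from annotation family names
(e.g. RepeatMasker families) to reported classes, since the exact grouping
used by any given annotation release varies.

# Image analysis

All image operations work on named 3D channel arrays with physical voxel
sizes. The reference acquisition geometry is 0.0866 um laterally and
0.125 um axially; the synthetic defaults are coarser (0.25 x 0.25 x 0.4 um)
to keep simulated stacks small while leaving every structure several voxels
wide.

**Nuclear segmentation** follows a fixed step order: per-plane
Gaussian smoothing (sigma 1 px), a global automatic threshold (implemented
as Otsu on the pooled histogram, as only "automatic" is specified), hole
filling, removal of regions below the 400 um^3 minimum nuclear volume, then
a 2-iteration dilation plus second hole fill. Volumes and integrated DNA
are measured on the segmented nucleus *before* dilation — the dilated mask
exists to decide which foci touch the nucleus — so the reported volume
estimates true nuclear geometry rather than a padded one.

**Background.** Two subtraction modes serve two different measurements. For
colocalization, a per-plane local-mean filter (default radius 10 px,
about 0.87 um) removes smooth background while preserving focal structure;
the window mean is computed over in-mask pixels only, because averaging
dark out-of-mask pixels into the estimate near the nuclear rim leaves a
spurious rim-shaped residual that biases H downward. For intensity
*fractions*, local-mean filtering would be wrong: it also removes genuine
diffuse nuclear probe signal, which must stay in the denominator. There the
flat camera offset is estimated from voxels outside the dilated nucleus and
subtracted (`subtract_offset()`).

**Colocalization.** Pearson's r and the H coefficient are computed per
z-plane over in-mask voxels; a mid-nuclear reporting plane is chosen as the
plane with the highest total in-mask DNA intensity (a deterministic proxy
for "best signal quality", ties to the lower index). The H coefficient is
defined here as the normalised intensity cross-product

$$H = \frac{\langle I_1 I_2 \rangle}{\langle I_1 \rangle \langle I_2 \rangle},$$

chosen because it has every property the measure is used for: expectation 1
for voxel-wise independent signals, above 1 for co-enriched signals,
below 1 (0 for disjoint supports) for mutually exclusive ones, and
invariance to positive rescaling of either channel. Note that a truly
random pairing gives H near 1, not below 1; values below 1 indicate
exclusion.

**S-phase substages** are called by a rule that mirrors the visual
criteria: EdU-negative nuclei (background-subtracted in-mask mean below
`edu_min_mean`, default 5 counts) are non-S; *late* S requires few foci
(`late_max_foci`, default 25) of large mean volume (`late_min_volume`,
default 0.8 um^3, midway between the ~0.13 um^3 foci of interior patterns
and the >1.5 um^3 spots of late patterns); *mid* S requires at least
`mid_min_peripheral` (default 0.5) of the EdU intensity within a 1-um
peripheral shell of the nucleus; everything else is *early*. The shell uses
a depth map computed as the minimum of the per-plane 2D Euclidean distance
(scaled by the lateral voxel size) and the along-z run distance (scaled by
the axial size) — a conservative approximation of the anisotropic 3D
distance that is exact where shells matter, near smooth boundaries.

**DNA-content staging** assigns EdU-positive cells to S and splits
EdU-negative cells into G1/G2 by 2-class k-means on standardised nuclear
volume and integrated DAPI, deterministically initialised at the extreme
cells; the cluster with lower mean DAPI is G1.

**Focus segmentation** implements the "SD" recipe: threshold at the
in-nucleus mean plus `k_sd` (default 3, intended to be calibrated once per
staining condition) standard deviations, noise removal with a fine filter,
separation of touching objects with a 1-um size guide, a 0.3 um^3 minimum
object volume, and exclusion of objects not touching the dilated nucleus.
Because the source software's fine filter is unspecified, it is implemented
as a per-plane 3x3 binary median; a cubic 3x3x3 median was rejected because
with anisotropic voxels it erodes legitimate two-to-three-plane foci below
the minimum volume. Touching objects are separated by a seeded partition of
each connected component: seeds are local maxima of the component's depth
map kept at least `size_guide` apart (strongest first, deterministic
tie-breaks), and voxels join the nearest seed in physical coordinates. For
the compact, convex blobs that repair foci are, this partition coincides
with the distance-transform watershed while remaining fully deterministic.

**Repair kinetics.** Per cell, the fraction of (offset-subtracted) probe
intensity inside the segmented gammaH2AX foci is recorded; the same
operation with target and focus channels swapped gives the reciprocal
satellite analysis. Unirradiated cells are excluded — their gammaH2AX
signal is too low to segment reliably. Fractions are normalised to the
median of the 0.5 h timepoint, so the baseline median fold change is 1 by
construction; summaries report the median, quartiles (linear-interpolation
quantiles, R type 7) and whisker fences at three interquartile distances.

# The synthetic-data generators

The generators define the conditions under which the pipeline is validated;
their defaults are fixed once and shared by the tests and the acceptance
script.

* **Tracks** use a Gaussian copula: latent correlation
  $\rho_{lat} = 2\sin(\pi\rho_S/6)$, the inverse of the copula Spearman
  map, so continuous margins realise the target Spearman exactly in
  expectation at any sample size. Count (Poisson) margins introduce ties
  and a small attenuation, visible but well inside the +-0.05 recovery band
  at n = 10,000. The stratified generator draws interval counts from a
  zero-inflated Poisson (30% zeros, Poisson mean 15 otherwise) so both the
  rich (>10) and poor (=0) strata exceed 2,000 of 10,000 intervals, and
  plants a different pair-correlation per stratum.
* **Reads** live on a 1 Mb toy genome of interleaved class blocks
  (Alu 300 bp, LINE 1 kb, SAT 800 bp, LTR 500 bp, 400 bp gaps; 36 bp
  reads). Gaps exceed the read length, so each placement overlaps exactly
  the intended annotation and every read's truth label is provably the
  unique correct assignment — the classifier can be required to match it
  *exactly*, and a brute-force overlap oracle confirms the indexed
  implementation.
* **Images** render an ellipsoidal nucleus (semi-axes 6 x 6 x 3.5 um,
  about 530 um^3, comfortably above the 400 um^3 segmentation minimum) with
  textured DNA, an EdU pattern per substage (early: 120 small interior
  foci; mid: 100 foci in the 0.8-um rim shell; late: 8 large spots),
  gammaH2AX foci as Gaussian blobs (sigma 0.4 x 0.4 x 0.45 um, matching
  the ~1 um repair foci that the 0.3 um^3 volume filter presumes, placed at
  least 2 um apart so planted foci are individually resolvable and the
  planted count is a meaningful truth), and Poisson noise over a constant
  offset — the simplest noise model that exercises both background
  subtraction modes. When an overlap fraction is planted, the in-focus
  share of FISH intensity is confined to the 1-sigma focus cores so that
  any reasonable segmentation captures it in full, making the planted
  fraction recoverable rather than an upper bound. The alpha-mixed FISH
  channel for colocalization mixes the EdU reference with an independent
  fine-grained focal pattern whose centers are uniform over the nucleus:
  uniform placement makes alpha = 0 voxel-level independent (E[H] = 1),
  and fine granularity lets the independent component survive local-mean
  subtraction so H and r increase smoothly with alpha.
* **Time courses** draw per-cell overlaps as baseline x decay x a
  lognormal cell factor (sigma 0.12), 30 cells per timepoint at 0.5, 3 and
  24 h with default relative decay (1, 0.5, 0.2).

One global seed is threaded everywhere; per-cell sub-seeds are derived
deterministically from (seed, index), so identical specs are bit-identical
and cohorts can be realised lazily (`make_cell()`) without holding 90
stacks in memory.

What the generators deliberately do *not* emulate: optics (no PSF,
deconvolution artifacts or chromatic shift — deconvolved stacks are the
assumed input), nucleoli (peri-nucleolar mid-S foci are folded into the
peripheral-shell feature), genome sequence evolution, and read-mapper
behaviour (alignments are consumed, not produced). Passing tests therefore
demonstrate estimator correctness under controlled conditions, not
robustness to acquisition pathologies.

# Problem sizes and numerical choices

The validation cohorts are sized so the full suite runs comfortably on one
CPU: 10,000 intervals for correlation recovery, 20,000 reads for the
classification oracle, 300 nuclei (100 per substage) for the S-phase
classifier, 50 images for focus-count exactness and 30 cells per timepoint
for kinetics. Tolerances follow the corresponding sampling error: +-0.05 on
Spearman recovery at n = 10,000, 3-sigma multinomial bands for class
fractions, +-0.1 on fold-change medians over 30 cells, and exactness where
the construction guarantees a unique answer (read classification, focus
counts). Deterministic tie-breaks are fixed throughout (lower plane index,
first-by-position labels, strongest-first seed suppression) so repeated
runs are identical.

# Known limitations

* The H coefficient has no single canonical formula in the literature; the
  cross-product definition above satisfies all stated properties but may
  differ from the original in scale for strongly structured signals.
* The depth map underestimates true 3D distance away from axis-aligned
  boundaries; shells and seeds are unaffected in practice, but it is not a
  general EDT.
* The S-phase rule is tuned to the canonical three patterns; intermediate
  or mixed patterns are forced into the nearest class.
* Stratified correlations inherit whatever confounding the stratifying
  track carries; no partial correlation is attempted.
* Pooled per-element statistics across probes (e.g. combining Alu and L1
  ranges) are left to the user.
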