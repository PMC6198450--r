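# repkin

Replication timing and DNA-repair kinetics of repetitive DNA elements.

About half of the human genome consists of repetitive DNA — Alu and other
SINEs, LINE-1 retrotransposons, pericentromeric satellites, LTR elements.
Because reads from these elements rarely map uniquely, they are largely
invisible to standard sequencing analyses, and how they are replicated and
repaired is correspondingly under-studied. `repkin` provides the
computational toolkit for a combined genomics + 3D-imaging approach to this
question, aimed at researchers in epigenomics and genome stability:

* **Interval statistics** — tile a genome into non-overlapping 10 kb
  intervals; project repeat-copy counts, GC content and RPKM read coverage
  (chromatin marks, Repli-Seq stages, gammaH2AX) onto the grid; compare
  tracks by Spearman's rank correlation matrices
  (rho = Pearson correlation of tie-averaged ranks), optionally stratified
  into repeat-rich (> 10 copies/interval) versus repeat-poor (0 copies)
  intervals.
* **Metarepetitive elements** — rescue multi-mapped reads with a
  class-signature rule: a read whose placements all fall in copies of one
  repeat class counts for that class; placements in two classes discard the
  read. Per-class fractions of the single-class-signature total, and their
  ratios against an unirradiated baseline, quantify per-class gammaH2AX
  coverage over the repair time course.
* **3D image quantification** — nucleus segmentation from the DNA
  counterstain (smooth, Otsu, fill, 400 µm³ minimum); per-plane Pearson r
  and H coefficient, `H = ⟨I₁I₂⟩ / (⟨I₁⟩⟨I₂⟩)` (≈1 independent, >1
  co-enriched); S-phase substage calls from the EdU pattern (early /
  mid / late / non-S) and G1/S/G2 staging from DNA content; gammaH2AX focus
  segmentation (mean + k·SD threshold, 0.3 µm³ minimum, 1 µm size-guide
  separation) and fraction-in-foci repair kinetics normalised to the 0.5 h
  median.
* **Synthetic data with ground truth** — Gaussian-copula tracks with a
  planted Spearman matrix, an annotated toy genome with multi-mapped reads
  whose true class is provable, and 3D multichannel nuclei with planted
  EdU patterns, colocalization levels, foci and overlap decay. Every
  estimator is validated against these planted truths.

## Worked example

Correlate a simulated repeat-count track with a covarying chromatin-mark
track, then run a simulated repair time course:

```r
library(repkin)

# tracks with a planted Spearman correlation of 0.6 on 2,000 intervals
st <- simulate_tracks(2000, matrix(c(1, .6, .6, 1), 2),
                      labels = c("alu_count", "h3k9ac"), seed = 1)
correlation_matrix(st$tracks)
#> Spearman correlation matrix (rho):
#>           alu_count h3k9ac
#> alu_count     1.000  0.628
#> h3k9ac        0.628  1.000

# repair time course: 10 cells per timepoint, planted decay (1, 0.5, 0.2)
tc <- simulate_repair_timecourse(n_cells = 10, seed = 31)
rk <- run_kinetics(tc)
rk$summary[, c("timepoint", "n", "median", "q1", "q3")]
#>   timepoint  n    median        q1        q3
#> 1       0.5 10 1.0000000 0.9307010 1.0926861
#> 2       3.0 10 0.4527747 0.4324652 0.4871686
#> 3      24.0 10 0.1951076 0.1909226 0.2070337
```

The recovered rho (0.628) sits within sampling error of the planted 0.6.
The fold-change medians track the planted relative decay: by construction
the 0.5 h median is 1; the 3 h and 24 h cohorts recover the planted 0.5 and
0.2 — the cells' repeat signal leaves the damage foci at the planted repair
rate.

## Layout

```
R/                  implementation (binning, correlation, metarepeat,
                    imaging, S-phase, foci/kinetics, simulators)
tests/testthat/     unit + property tests with independent oracles
scripts/acceptance.R  end-to-end validation run
vignettes/          methods vignette (models, parameters, design choices)
```
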