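# qibcr

Quantitative image-based cytometry (QIBC) and degenerate DNA-motif
scanning in R.

QIBC turns fluorescence-microscopy fields into flow-cytometry-like
single-cell distributions: nuclei are segmented in the DAPI channel, the
nuclear masks are applied to every other channel, and each nucleus becomes
one row of a feature table (integrated DAPI as a proxy for DNA content,
per-channel mean intensities in arbitrary units). Downstream, populations
are gated to interphase cells with 2C–4C DNA content, subsampled to equal
depth across conditions, optionally split by replication state
(EdU- or chromatin-bound-PCNA-positive S-phase cells), and drawn as
DNA-content scatter plots or jittered dot-bar plots. This is the standard
readout for DNA-damage and replication-stress experiments (EdU
incorporation, γH2AX, chromatin-bound RPA2, PCNA, ADP-ribose signal per
nucleus).

The package also counts non-overlapping occurrences of degenerate DNA
motifs (alphabet A/C/G/T plus N = any base) in sequences and FASTA
genomes — the computation behind asking how often a toxin target site such
as TNTC occurs per base of a genome.

Because real acquisitions are large and instrument-specific, a synthetic
data module generates ground-truth scenes (nucleus positions, radii,
cell-cycle phases, true channel means under named genotoxin presets),
renders them to multi-channel images with background and Gaussian noise,
and generates DNA sequences with controlled base composition and planted
motifs — so segmentation, quantification, gating, plotting and motif
counting are all testable offline against known truth.

## The core operations

- **Segmentation** — two-class Otsu thresholding of the (smoothed) DAPI
  channel on a 256-bin histogram, hole filling, then seeded watershed on
  the Euclidean distance transform (seeds = distance maxima separated by a
  minimum distance), and size/border filtering. Touching nuclei whose
  centres are far enough apart are split into separate labels.
- **Quantification** — per nucleus: area, centroid, `total_dapi`
  (integrated DAPI, proportional to DNA content) and the arithmetic mean
  of every channel under the nuclear mask; raw A.U., no background
  subtraction.
- **Gating** — the G1 (2C) peak is the leftmost dominant mode of the
  log-total-DAPI histogram; cells are kept inside
  `[0.75, 2.5] ×` peak (a widened 2C–4C window); equal-depth random
  subsampling across conditions; S-phase called by marker threshold
  (fixed, or a quantile of a negative-control population).
- **Motif counting** — greedy leftmost scan: at each position, if the
  motif matches, count and advance by the motif length, else advance by
  one. For fixed-length motifs this greedy count equals the maximum
  number of mutually non-overlapping occurrences. Density is
  `100 × count / length` (per strand; reverse-complement scans are
  reported separately, never merged).

## Worked example

```r
library(qibcr)

cfg   <- scene_config(n_nuclei = 120, condition = "dart_wt", seed = 7)
scene <- make_scene(cfg)                    # ground truth
fov   <- render_scene(scene)                # multi-channel field
mask  <- segment_nuclei(fov)
mask
#> <label_mask> 800 x 800, 120 object(s)

cells <- measure_nuclei(mask, fov, condition = "dart_wt")
gated <- gate_interphase(cells)
gated$result$g1_peak
#> [1] 982681
gated$result$window
#> [1]  737011 2456702

flags <- call_sphase(gated$table,
                     gating_params(sphase_marker = "PCNA",
                                   sphase_threshold = 200))
mean(flags)
#> [1] 0.3
mean(gated$table$mean_EdU[flags]); mean(gated$table$mean_EdU[!flags])
#> [1] 187.2
#> [1] 109.9
```

All 120 simulated nuclei are recovered and pass the 2C–4C gate; the G1
peak (~9.8e5 A.U.) sits at 2 × `dapi_per_c` plus the integrated
background, and the window spans 0.75–2.5 × that peak. 30% of cells are
flagged S-phase via chromatin-bound PCNA, matching the configured
`fraction_s = 0.3`. Under the `dart_wt` preset the S-phase EdU mean
(187 A.U.) is strongly suppressed toward the non-S level (110 A.U., mostly
the 100 A.U. background) — the "DarT limits EdU incorporation" direction.

Motif density on a 1 Mb i.i.d. sequence with human-autosome base
composition (A=T=29.5%, C=G=20.5%):

```r
s <- random_sequence(1e6, c(A = .295, T = .295, C = .205, G = .205), seed = 1)
motif_density(count_nonoverlapping(s, "TNTC"), 1e6)
#> [1] 1.6814
```

i.e. a TNTC site roughly every 60 bases of single-stranded DNA.

## Command-line interface

Thin wrappers live in `inst/scripts/` (after installation:
`system.file("scripts", ..., package = "qibcr")`):
`qibc_simulate.R`, `qibc_segment.R`, `qibc_quantify.R`, `qibc_gate.R`,
`qibc_plot.R` (scatter | dotbar), `qibc_motif.R`. Every figure writes a
machine-readable data sidecar CSV next to it.

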