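# h1scape

Genome-wide occupancy analysis of linker histone H1 variants from
ChIP-seq read positions.

Somatic cells express several H1 subtypes (H1.0, H1.2–H1.5, H1X) whose
genomic distributions differ: some track GC-rich, gene-dense territory
while others accumulate in GC-poor, lamina-associated chromatin, and all
of them are depleted in a "valley" around active transcription start
sites. `h1scape` implements the computational pipeline needed to map and
compare such occupancy landscapes, and ships a synthetic-genome read
simulator with known generative parameters so every stage can be
validated by parameter recovery.

## What the package computes

Given aligned read 5′ positions for each ChIP library and its input
control, a chromosome-sizes table, gene annotation with expression, and
region sets of interest (LADs, CpG islands, mark peaks):

* **Signal tracks** — reads are extended to a nominal fragment size
  (150 bp), counted in fixed bins (50 bp), and combined as
  input-subtracted, library-normalised occupancy,
  `(chip_i/N_chip − input_i/N_input) × 10⁶` (RPM), or as a log2
  fold-change track. Tracks read/write dense bedGraph.
* **Anchored profiles** — per-gene signal matrices over
  [−3.2 kb, +0.8 kb) around the TSS (strand-aware), column means,
  LOESS smoothing (tricube, degree 1), stratification into equal-size
  expression groups EG1 (highest) … EG10 (lowest), and length-normalised
  metagene profiles (gene body rescaled to 60 bins, 1 kb flanks).
* **Islands** — SICER-style enriched/depleted domain calling: Poisson
  background rate `λ₀ = N·w / (G·f)` with effective genome fraction
  `f = 0.75`, per-window eligibility at p < 0.2, gap-bounded merging
  (gap = 200 bp), Poisson island scores, Benjamini–Hochberg q-values
  (FDR 0.01) and a minimum chip/input fold change of 2. Islands are
  annotated to the nearest TSS, classified into genomic feature classes
  (promoter / UTR / exon / intron / downstream / distal intergenic), and
  mapped to target genes via the extended span [TSS − 5 kb, TTS + 3 kb].
* **Domain statistics** — per-chromosome gene-richness coefficient
  `GRC_c = (genes_c/genes_tot) / (bp_c/bp_tot)`; chromosome occupancy
  matrices and their hierarchical clustering (distance
  `1 − Pearson r`, average linkage); region-class enrichment tested
  against a width-matched random-window null with a two-sample
  Kolmogorov–Smirnov test; Pearson correlation of occupancy with GC
  content in 1 kb windows; per-gene distal-promoter scores
  ([−3200, −2000) bp of the TSS) with top/bottom-10% overlap analysis
  between variants and KS comparison of intersection expression against
  the transcriptome.
* **Simulator** — an autocorrelated GC landscape, LADs in its low-GC
  troughs, GC-attracted gene placement with log-normal expression
  (suppressed 4× inside LADs), and a per-bin ChIP intensity field
  `exp(β·GC + γ·1[LAD]) · Π_g (1 − d_g K(x − tss_g)) · (1 + a K₊)`
  with expression-rank-scaled valley depths `d_g` and an optional
  +125 bp (+1 nucleosome) peak; reads are multinomial draws from the
  normalised field.

## Worked example

Simulate an H1.2-like variant (GC-averse, LAD-enriched, deep TSS valley)
on the default toy genome (2 × 5 Mb, 400 genes, 20 LADs, 2 × 10⁶ reads
per library) and recover its generative structure:

```r
library(h1scape)
truth <- generate_genome(seed = 1)
model <- h12_like_model(seed = 1)
sim   <- simulate_reads(truth, model)
occ   <- normalize_subtract(bin_coverage(sim$chip, truth$genome),
                            bin_coverage(sim$input, truth$genome))

gc_correlation(occ, truth$gc)$r
#> r = -0.725
region_enrichment_test(occ, truth$lads, seed = 1)
#> <h1_enrichment> 20 regions, D = 0.861, p = 4.74e-13, enriched

prof   <- anchored_profile(occ, truth$genes)   # TSS -3.2 kb .. +0.8 kb
groups <- expression_deciles(truth$genes)
# smoothed valley minima of the top and bottom expression groups:
#> EG1 valley minimum:  -17.49 RPM
#> EG10 valley minimum:  -1.92 RPM
```

The negative GC correlation, significant LAD enrichment and
expression-dependent valley depth are exactly the knobs the generative
model was given (`gc_coupling = -0.8`, `lad_log_enrichment = +0.7`,
`tss_valley_depth = 0.9`).

The whole pipeline can also be driven from a YAML config with
`run_all()`, which writes signal tracks, profile tables, annotated
island calls, domain statistics and a machine-readable `summary.json`
into an output directory, deterministically for a fixed config.

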