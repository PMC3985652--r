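---
title: "Methods: mapping linker histone H1 variant occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping linker histone H1 variant occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`h1scape`, the assumptions behind them, the parameters a user may want
to change, and the design decisions taken where several reasonable
choices existed. Linker histone H1 variants bind chromatin broadly
rather than in sharp peaks, so the pipeline is built around binned,
input-subtracted signal and domain-scale statistics rather than
narrow-peak detection.

## Coordinates and containers

All coordinates are 0-based, half-open, on a single `genome()` frame per
run; BED input therefore needs no shifting. Genes are stored in genomic
orientation with strand-aware anchors: the TSS of a `+` gene is its
`start`, of a `-` gene its `end - 1`, and the TTS symmetrically. Overlap
everywhere means at least one shared base between half-open intervals.
Unknown chromosomes in any input are skipped and counted rather than
fatal (ordinary data hygiene for mixed-provenance genomics files);
records with impossible coordinates are rejected and reported, while
syntactically malformed lines are hard errors naming the line.

## From reads to occupancy

Reads are reduced to their 5′ position and strand. Coverage extends
each read to `fragment_size` (default 150 bp, a typical sonicated
ChIP fragment) in the read direction and counts, per `bin_size` bin
(default 50 bp), the fragments overlapping it by at least one bp;
fragments running past a chromosome end are clipped. At most one read
per (position, strand) is kept by default (redundancy threshold 1),
suppressing PCR duplicates. Occupancy is the difference of
reads-per-million coverages, `(chip/N_c - input/N_i) * 1e6`; it is
deliberately signed, since H1 depletion is as informative as
enrichment. A log2 fold-change track is available for promoter-ratio
style analyses; sequencing ratios need a pseudocount (default 0.5 RPM,
configurable) where hybridisation ratios did not, which is why the
subtracted track, not the ratio, is the package's common currency.

Island calling instead assigns extended-fragment *midpoints* to
non-overlapping windows, the convention of the SICER family of broad
peak callers; both counting rules are implemented and tested
separately because they answer different questions (coverage semantics
vs window scoring).

## Profiles

`anchored_profile()` extracts `[-upstream, +downstream)` of bp-level
signal around each anchor, mirrored for `-` strand genes so that
upstream is always transcriptionally upstream. Offset 0 is the anchor
base itself and columns are labelled by their left bp edge, which
makes the bin bookkeeping unambiguous. Cells are length-weighted bp
averages of the binned track, so profile bins need not coincide with
track bins; cells extending beyond a chromosome are masked, and column
means are taken over unmasked cells only (a fully masked column is
reported missing, never zero). Defaults (-3200..+800 bp, 50 bp bins)
give the 80-column promoter window used throughout.

Expression groups EG1..EG10 are equal-size deciles of the genes with
non-missing expression, EG1 highest; with `N` genes the first
`N mod 10` groups take one extra member, and ties are broken by gene
id so the partition is deterministic. Metagene profiles rescale each
gene body [TSS, TTS) to `body_bins` (default 60) by exact
step-function integration, with 1 kb flanks at native resolution;
genes shorter than `body_bins * 10` bp are excluded by default because
rescaling bodies much shorter than the target grid manufactures
autocorrelation.

LOESS smoothing is local degree-1 regression with tricube weights over
the `floor(span * n)` nearest neighbours. Degree 1 reproduces linear
trends exactly, which the tests exploit as a closed-form oracle. The
default span of 0.1 on the 80-column window is cosmetic — it controls
plot smoothness, not any statistic — and is exposed as a parameter. A
span covering fewer than 3 points is refused with the minimal usable
span in the message.

## Island detection

Windows (200 bp) are eligible when their chip count exceeds the
Poisson threshold at upper-tail p < 0.2 under the background rate
`lambda0 = N * w / (G * f)`, with effective genome fraction
`f = 0.75` accounting for unmappable sequence. Eligible windows merge
into islands bridging at most `gap` (200 bp) of ineligible windows.
Each island is scored by the sum of `-ln P_Poisson(count)` over its
eligible windows and assigned an upper-tail Poisson p-value on its
span's total chip count; q-values are Benjamini-Hochberg across
islands, filtered at FDR 0.01 and chip/input fold change >= 2 (input
pseudocount of one read avoids infinite fold changes over empty
input). This Poisson-score + BH construction is a deliberate,
documented simplification of SICER's full random-background score
distribution: it preserves the two-stage design and the FDR/fold
change contract, and its null behaviour is checked by simulation (a
matched-rate null at 2e6 reads over 5 Mb yields on average well under
one called island; a planted 1 kb region at 5x background is
recovered essentially always). Depleted islands are the same
computation with the chip and input channels swapped — the natural
reading of a caller that reports both directions — and the swap
identity is asserted exactly in the tests.

Annotation assigns each island to the gene with the nearest TSS from
the island midpoint (ties to the smaller genomic coordinate), with
distances signed by transcript orientation. Feature classification is
by island midpoint with priority promoter > 5'UTR > exon > intron >
3'UTR > downstream > distal intergenic; promoter and downstream extend
3 kb from TSS/TTS. UTR discrimination requires a CDS interval and
exon structure; without exons a gene body is the undivided class
"genic". Target genes are those whose extended span
[TSS - 5 kb, TTS + 3 kb] is touched by at least one island.

## Domain statistics

The gene-richness coefficient
`GRC_c = (genes_c / genes_tot) / (bp_c / bp_tot)` satisfies the
algebraic identity `sum_c GRC_c * bpfrac_c = 1`, which the tests
assert to 1e-12 as a guard on the implementation. Chromosome occupancy
is the plain mean of a variant's subtracted signal per chromosome;
variants (or chromosomes) are clustered with distance
`1 - Pearson r` and average linkage. Zero-variance items, for which
correlation is undefined, are flagged and fall back to Euclidean
distance with a warning rather than silently dropping out.

Region-class enrichment (`region_enrichment_test()`) compares
per-region mean signal against `n_null` random windows whose widths
are resampled from the observed width multiset and placed uniformly
genome-wide (never crossing a chromosome end), using a two-sided
two-sample KS test. Width resampling (rather than per-region pairing)
preserves the width distribution while allowing `n_null` to exceed the
number of regions; genome-wide placement is the literal reading of a
"random sample of genomic windows", and chromosome-matched sampling
would be a one-line variant. The KS statistic is unsigned, so the
reported direction comes from the sign of the observed-minus-null
median difference, called only when p < alpha. Region means include
the bins whose midpoints fall inside the region (a region narrower
than a bin falls back to its containing bin); bp-weighted border
handling would change LAD-scale means negligibly and is not offered.
The null sampler is seeded explicitly and restores the caller's RNG
state, so results are reproducible and side-effect free. Calibration:
on iid-noise signal with regions drawn by the null's own sampler, the
test rejects at the 5% level in 3-7% of repetitions (the slight
conservatism is the usual discreteness of the two-sample KS at these
sample sizes).

GC correlation averages signal and GC into common 1 kb windows
(dropping a trailing partial window) and reports Pearson's r; it
refuses degenerate zero-variance inputs by name. Distal-promoter
scores are bp means over the strand-aware window [-3200, -2000) from
the TSS, averaging over whatever part of the window lies inside the
chromosome. The top/bottom overlap analysis ranks a common gene
universe by two variants' distal scores, takes the top and bottom
`ceiling(0.10 * N)` (ties by gene id), counts the four intersections
and KS-tests each intersection's expression against the full universe
— the transcriptome is the reference, matching how target-gene
expression is usually benchmarked.

## The synthetic genome

The simulator exists so that every downstream statistic can be checked
against known generative parameters; its defaults define the package's
standard test conditions and were chosen once, for statistical power at
desk scale, not tuned to any observed test outcome.

* Scale: 2 chromosomes x 5 Mb, 400 genes (2 kb bodies, >= 1 kb
  spacing), 20 LADs of 100 kb, 2e6 reads per library. This gives
  minutes-scale analyses with stable statistics (about 40 fragments
  per 50 bp bin).
* GC landscape: a smoothed Gaussian random walk squashed logistically
  into [0.3, 0.7] at 50 bp resolution — autocorrelated with
  long-range drifts, like real isochore structure in miniature.
* LADs are centred on the lowest-GC stretches; genes are placed with
  weight `exp(5 * GC)` and land outside LADs with probability 0.8;
  expression is LogNormal(0, 1), scaled down 4x inside LADs. These
  couplings reproduce, generatively, the empirical associations the
  pipeline is meant to detect: LADs are GC-poor and transcriptionally
  quiet, genes prefer GC-rich ground.
* ChIP intensity per 50 bp bin:
  `exp(beta_GC * GC + gamma * 1[LAD]) * prod_g (1 - d_g * K(x - tss_g))
  * (1 + a * K1(x - tss_g - 125))`, where `K` is a Gaussian bump of
  scale `valley_halfwidth`, `d_g` is the valley depth scaled by the
  gene's expression *rank* (the natural generative link when analyses
  stratify by decile), and `K1` (100 bp scale, strand-aware +125 bp)
  is an optional +1-nucleosome peak. Reads are multinomial draws of
  5' positions from the normalised field, uniform within a bin,
  strand uniform; input is a uniform field at the same depth.

Two presets bracket the biology: `h12_like_model()` (GC coupling
-0.8, LAD log-enrichment +0.7, valley depth 0.9 with 900 bp
halfwidth, no +1 peak) and `h1x_like_model()` (signs flipped, valley
0.45/400 bp, +1 peak amplitude 0.6). The coupling magnitudes are the
package's own choice — made once for recovery power, since no
quantitative effect sizes were available to copy — and the
deeper/wider valley versus present +1 peak asymmetry encodes the
qualitative contrast between replication-dependent and
replication-independent variant classes.

What the simulator does **not** model: mappability and GC bias of the
input (input is uniform), PCR duplicate structure, replicate
variability, diploid copy number, and sequence-level effects. Passing
recovery tests therefore demonstrate that the statistics detect the
encoded structure at realistic depth and noise; they do not certify
behaviour under real-data artefacts such as blacklisted regions or
copy-number variation, which a user should handle upstream.

## Test and validation design

Deterministic operations are validated against independent brute-force
oracles (per-bp counting and averaging, O(n*m) nearest-TSS search,
O(n^2) overlap enumeration, per-point weighted least squares) at
tolerances 1e-9 to 1e-12; stochastic properties use fixed seeds and
rate thresholds with comfortable margins. The recovery experiments run
at the simulator's default scale over 20 seeds; the variant-clustering
check uses 8 x 1.25 Mb chromosomes (the same total genome) because
correlation across only two chromosomes is degenerate — with two
points every correlation is ±1, so chromosome-profile clustering only
becomes meaningful at several chromosomes. The acceptance script
reports the same quantities at 5 seeds per recovery experiment, 20
seeds for island calibration and 300 repetitions for KS calibration,
sizes at which each rate estimate is already stable.

## Known limitations

* The island significance model is Poisson with a global background
  rate; local biases (GC, mappability) are not modelled, so on real
  data the FDR is nominal rather than exact.
* The KS direction call uses medians; a class whose distribution
  differs in shape but not location is reported significant with a
  direction that may be uninformative.
* `run_all()` processes variants sequentially on one core; the
  pipeline is CPU-light at toy scale but memory-bound for mammalian
  genomes at 50 bp resolution (about 60M bins for hg-scale input),
  where per-chromosome streaming would be the first optimisation.
* Expression enters only as a per-gene scalar; isoform structure and
  alternative TSSs are out of scope (one TSS per gene record).
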