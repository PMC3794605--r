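---
title: "Methods: linking tissue-specific methylation to alternative splicing"
author: "methylsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking tissue-specific methylation to alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

Two tissues are profiled twice: genome-wide DNA methylation on a dense
tiling array (a methylation-enriched channel hybridized alongside untreated
input DNA, three replicates per tissue) and exon-level expression on an
exon array. The package calls tissue-specific differentially methylated
regions (T-DMRs) from the probe-level relative methylation, calls
alternatively spliced (AS) exons from the exon-level splicing index, joins
the two coordinate-wise, labels each T-DMR/AS-exon pair as positive or
negative regulation depending on whether hypermethylation travels with
inclusion or exclusion, and then asks which 6-bp sequence words are
overrepresented in the T-DMR sequence flanking AS exons, stratified by
position and regulation sign.

## Relative methylation and T-DMR calling

Per probe and sample the relative methylation is the log2 ratio of the
enriched to the input channel, `M = enriched − input` on the log2 scale.
Before that ratio is formed, two normalization steps run:

* **Control-probe lowess.** Non-genomic control probes see no real
  enrichment, so a lowess fit of `M` versus input intensity on controls
  estimates the intensity-dependent enrichment bias; the fitted curve is
  subtracted from every probe's enriched channel, extrapolated flat beyond
  the control intensity range. With fewer than 10 controls the step is
  skipped with a warning. If control intensities are degenerate (as in
  noise-free simulations) only the flat mean bias is removed.
* **Quantile normalization** across samples, per channel, so sorted
  per-sample distributions coincide exactly.

Probes whose mean input falls below the 2.5th percentile of control input
intensities are treated as background and removed; controls never enter
differential testing.

Each retained probe is tested for a tissue difference in `M`. Two tests
are available. The default is a moderated t-statistic (limma's
empirical-Bayes variance shrinkage): with three replicates per tissue a
raw Welch test has about four degrees of freedom, and its heavy critical
values at `p < 0.005` leave per-probe power near 0.13 for an effect of
three noise standard deviations — far too little for a run-based region
caller. Genome-wide variance pooling restores per-probe power to ~0.8
under the same conditions, which is why moderation is the standard
practice for small-replicate array designs; the plain Welch test remains
available as `call_tdmrs(method = "welch")` and is exact in noise-free
limits (conventions: zero variance in both groups gives p = 1 for equal
means, p = 0 otherwise).

A T-DMR is a maximal run of at least 3 neighbouring probes that all pass
`p < 0.005` with the same sign of the tissue difference. "Neighbouring"
means adjacent in array order on the same chromosome with a genomic gap of
at most 300 bp — tiling is dense (40 bp spacing by default), and the gap
cap prevents spurious mergers across untiled territory. The reported
region spans the first probe's start to the last probe's end; its
direction is the hypermethylated tissue of the probe-mean difference.

## Genomic context

Intervals are assigned to exactly one category with the precedence
5'UTR > 3'UTR > exon > intron > upstream > intergenic, across genes — a
total order is required because category percentages must sum to 100%.
Upstream windows extend 4 kb 5' of every annotated TSS, strand-aware.
Category enrichment of T-DMR probes against the array design uses the
upper-tail hypergeometric test: under the null, T-DMR probes fall into a
category in proportion to the probes designed there. CpG context follows
the island/shore/shelf convention: overlapping an island, within 3 kb, or
within 4 kb; anything farther is open sea. Conservation statistics are
pooled per base — the fraction of scored bases strictly above a cutoff —
so they are invariant to how intervals are fragmented; unscored bases are
excluded from denominators rather than counted as zero.

## Exon inclusion and AS calls

The normalized intensity of an exon is its log2 intensity minus its gene's
level, with the gene level summarized as the mean of its exons' log2
intensities per sample. The mean summarizer keeps the per-gene NIs summing
to zero and makes planted effects exactly computable; single-exon genes
have NI ≡ 0 and are flagged out of AS testing. The splicing index is the
difference of mean NIs between tissues; an exon is AS when the Welch test
across replicates gives `p < 0.01` and `|SI| > log2(1.25)` (both
inequalities strict). A robustness sweep re-runs the caller over a grid of
cutoff pairs and reports AS counts and T-DMR overlap enrichment per pair.
A gene has differential alternative-start usage when it carries at least
two annotated TSSs and at least one AS exon lies entirely within the
genomic interval between its most distal start sites.

## Integration and regulation labels

Gene-level association uses the hypergeometric overlap of T-DMR genes and
AS genes within the expressed-gene universe (the genes represented on the
expression platform). Exon-level links join a T-DMR to an exon when the
T-DMR intersects the exon's window — either the exon plus its two directly
flanking introns, or the exon ± 1 kb; a T-DMR touching the exon itself
(including either junction) is `within_exon`, otherwise the side is
upstream/downstream in gene-sense orientation. One T-DMR linking several
AS exons contributes one assignment per exon. The regulation label is a
two-by-two truth table: positive when the hypermethylated tissue equals
the tissue of greater inclusion, negative otherwise; it is invariant under
renaming the tissues.

## 6mer motif discovery

Foreground sequences are T-DMR subsequences clipped to the 1 kb gene-sense
flank window of their linked AS exon, grouped by position × regulation
(four groups); sequences from minus-strand genes are reverse-complemented
so all counting happens in gene sense, and no reverse-complement pooling is
applied — upstream versus downstream is strand-meaningful. The background
is the pooled 6mer composition of the matching 1 kb flank (upstream or
downstream) of 10,000 randomly chosen exons, counted with overlapping
windows exactly like the foreground (a sequence of length L contributes
L − 5 windows). Each kmer's count M among the group's N windows is tested
with the upper-tail binomial probability `P(X ≥ M)` for
`X ~ Binomial(N, f)`, where f is the kmer's background frequency, computed
through the survival function so it is stable for N in the millions.
Benjamini–Hochberg correction runs within each group's 4096 tests;
significance means `q < 0.01`. A kmer observed in the foreground but absent
from the background gets p = 0 and a flag; an optional pseudocount
(0.5/total) is available for tiny synthetic backgrounds.

A kmer's role at a position is *dual* if it is significant in both the
positive and negative group there, otherwise the single significant label.
Comparing positions partitions the union of ever-significant kmers into
same-role, one-position-only, and opposing; dual-versus-single mismatches
count as opposing so that the three classes partition the union.

CpG content is reported four ways: the fraction of unique significant
kmers containing CG, the analytic fraction of all 4096 kmers containing CG
(1185/4096 = 28.93%, by enumeration or the recurrence
`f(n) = 4f(n−1) − f(n−2)` for CG-avoiding strings), and the corresponding
instance-weighted fractions over T-DMR windows, with two-proportion
comparisons.

Similar kmers cluster hierarchically (average linkage) on the best
ungapped-alignment match count over shifts of up to ±2, cut at
dissimilarity 2.5 (members agree in ≥ 4 aligned positions); consensus
strings use IUPAC degeneracy for letters reaching at least half of the
column maximum, with deterministic tie-breaks (members align to the
alphabetically first kmer; shift ties resolve toward the smaller absolute
shift). PWM similarity is the maximum over offsets of the mean
per-position log2-odds against a uniform background, with the score
distribution over all 4096 kmers as reference and a one-sided rank-sum
comparison.

The motif-pair distance test collects genomic start positions of
significant-motif instances within the T-DMR pieces flanking the same AS
exon side and compares all pairwise distances to a null in which each
instance is repositioned uniformly within its own piece, 100 seeded
shuffles; the one-sided p-value is the fraction of shuffles whose mean
distance is at most the observed mean. For two instances on a piece of
length L the null mean is L/3, which the implementation reproduces within
a few percent — this analytic identity is one of the package's calibration
checks.

## The synthetic-data generator

`simulate_bundle()` draws i.i.d. uniform ACGT chromosomes; lays out
non-overlapping genes on both strands with 4–8 exons (100–250 bp) and
introns of 0.5–1.5 kb, UTRs on coding genes, and a second TSS on 20% of
eligible genes; places CpG islands so island, shore, shelf and open-sea
context all occur; and simulates a piecewise-constant conservation track
with Beta(2, 5) segment scores. Truth planting couples most T-DMRs
(400–700 bp, placed in the flanking intron within the 1 kb window, or
inside the exon) to one internal exon per gene under a positive or
negative label; the planted AS effect is scaled by K/(K−1) so the expected
SI equals `as_effect` exactly under the mean-NI definition. Motif planting
overwrites 6 bp at Poisson-drawn positions inside the target group's
T-DMRs, in gene-sense orientation, at a rate of `(fold − 1)` times the
uniform background. Intensities are Gaussian on the log2 scale with the
replicate noise applied to the relative methylation directly, so the
planted delta is exact in the noise-free limit. All stages derive their
streams from one root seed; identical configurations are bit-identical.

What the generator does *not* emulate: CpG-biased probe design and probe
sequence effects, spatially correlated array noise, expression-dependent
exon-array detection limits, and realistic genome composition (repeats,
isochores, codon structure). Passing the planted-truth benchmarks
therefore demonstrates the correctness and calibration of the algorithms,
not their field performance on real arrays.

## Problem sizes and benchmark conditions

The validation experiments use sizes chosen to keep a full run on one CPU
in minutes: the T-DMR recovery benchmark tiles ~50,000 probes over 2 Mb
with 100 planted regions (delta 0.3, noise sd 0.1, 3v3) and requires
interval sensitivity ≥ 0.9 at empirical FDR ≤ 0.1; the motif benchmark
plants one 6mer at 5x background in a downstream-negative group of more
than 200 kb and checks recovery at q < 0.01, with 20 unplanted
pseudo-group replicates as calibration (≤ 5% of kmers significant in at
least 95% of them); regulation classification is checked noise-free, where
recovery must be exact. The demo analysis under `analysis/` uses a
smaller genome (two 1.5 Mb chromosomes, 120 T-DMRs) so each stage's output
remains human-readable.

## Known limitations

* Probe-level significance imposes no minimum effect size; with very large
  replicate numbers trivial deltas could reach `p < 0.005`.
* The moderated test assumes exchangeable probe variances; strongly
  heteroscedastic arrays would weaken the shrinkage target.
* Within-exon T-DMRs clipped to short exons can carry fewer than three
  fully contained probes and are then uncallable by construction — a
  resolution limit of the run rule, visible in the noise-free benchmark as
  couplings that classify perfectly from planted geometry but are absent
  from probe-level calls.
* The positional comparison treats the four group tests as independent BH
  families; a joint FDR across groups would be stricter.
* Background frequencies use overlapping windows; kmer counts are
  therefore weakly autocorrelated, which the binomial model ignores. At
  6-mer scale and the group sizes used this has no practical effect on the
  FDR calibration (the null replicates confirm this), but it is a model
  approximation, not an exact likelihood.
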