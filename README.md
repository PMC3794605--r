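# methylsplice

An R package for the integrative analysis of tissue-specific DNA
methylation and alternative splicing. It reimplements, as a tested and
fully synthetic-data-validated pipeline, the chain of analyses that links
two-tissue tiling-array methylation profiles to exon-level expression:

1. **T-DMR calling** — two-channel (methylation-enriched vs input) probe
   intensities are lowess-corrected on control probes, quantile-normalized
   across samples and background-filtered; per-probe relative methylation
   `M = log2(enriched) - log2(input)` is tested between tissues and runs of
   ≥ 3 neighbouring concordant probes with `p < 0.005` become
   tissue-specific differentially methylated regions (T-DMRs).
2. **Genomic context** — probes and T-DMRs are assigned to upstream
   (≤ 4 kb of a TSS), 5'UTR, exon, intron, 3'UTR or intergenic categories
   with hypergeometric enrichment against the array design, plus CpG
   island/shore (≤ 3 kb)/shelf (≤ 4 kb) context and conservation-score
   profiles (fraction of bases with score > cutoff).
3. **AS-exon calling** — the normalized intensity of an exon,
   `NI = log2 exon intensity - log2 gene level`, gives the splicing index
   `SI = mean NI(tissue1) - mean NI(tissue2)`; exons with `p < 0.01` and
   `|SI| > log2(1.25)` are alternatively spliced (AS).
4. **Integration** — gene-level overlap enrichment of T-DMR genes with AS
   genes, exon-level T-DMR links within 1 kb (or flanking-intron) windows,
   coverage statistics, and classification of each link as **positive**
   (hypermethylation in the tissue with greater exon inclusion) or
   **negative** (hypermethylation with greater exclusion) regulation.
5. **Motif discovery** — all 4096 6mers are counted in T-DMR sequence
   stratified by position (upstream/downstream of the AS exon, gene-sense)
   and regulation, and tested against a 10,000-exon flank background with
   the upper-tail binomial model `P(X >= M), X ~ Binomial(N, f)` at
   Benjamini–Hochberg FDR 1%, followed by positional-role comparison,
   CpG-content statistics, consensus clustering, PWM similarity scoring and
   a motif-pair distance test against a positional shuffle null.

A first-class synthetic-data module (`sim_config()`, `simulate_bundle()`)
generates genomes, annotations, probe arrays, conservation tracks and
expression matrices with *planted* T-DMRs, AS exons, regulation couplings
and motifs, so every stage is benchmarked against a machine-readable truth
set.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
bundle (seed 1; two 1.5 Mb chromosomes, ~75k probes, 120 planted T-DMRs,
two planted motifs) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_tdmrs.R
# ... through analysis/07_benchmarks.R
```

Representative output (exact values for seed 1):

```
planted-interval sensitivity: 1.00, call FDR: 0.00          # stage 2
T-DMR genes: 79; AS genes: 78; overlap: 69 (87.3% of T-DMR genes), p = 6.3e-12
T-DMR coverage of exon neighbourhoods: AS 0.142 vs non-AS 0.040 (p = 0)
downstream_negative :  1 significant 6mers; planted ranks ACCGCT = 1 ...
CpG content: 100.0% of significant 6mers vs 28.9% of all 6mers
```

Stage 2's sensitivity/FDR line says every planted differentially
methylated interval was recovered with no false region. Stage 5 shows the
T-DMR/AS gene overlap enrichment (87.3% of T-DMR genes are AS here because
most planted T-DMRs are coupled to an exon) and that AS exon
neighbourhoods carry ~3.5x more T-DMR sequence than non-AS ones. Stage 6
recovers the planted downstream-negative motif ACCGCT as the group's top
and only FDR-significant 6mer; 28.9% is the exact fraction of all 4096
6mers that contain a CpG (1185/4096). The second planted motif (GCGCAA,
upstream-positive) ranks 7th in its group but does not pass FDR at this
group size — detection power scales with group sequence, as the full-scale
benchmark in stage 7 shows.

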