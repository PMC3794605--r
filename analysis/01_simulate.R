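#!/usr/bin/env Rscript
# Stage 1: simulate the study bundle.
#
# Two tissues (retina, brain), three replicates each; two 1.5 Mb
# chromosomes tiled with 50-bp probes every 40 bp; 120 planted T-DMRs
# (delta = 0.3, replicate noise sd = 0.1), most coupled to an internal exon
# under positive or negative regulation; ACCGCT planted at 8x background in
# the downstream-negative group and GCGCAA in the upstream-positive group.
# Everything downstream reads the files this stage writes.

suppressPackageStartupMessages(library(methylsplice))

cfg <- sim_config(seed = 1, n_chromosomes = 2, chrom_length = 1.5e6,
                  n_genes = 110, n_ncrna = 8, planted_tdmr_count = 120,
                  planted_motifs = list(
                    list(kmer = "ACCGCT", position = "downstream",
                         regulation = "negative", fold = 8),
                    list(kmer = "GCGCAA", position = "upstream",
                         regulation = "positive", fold = 8)))
bundle <- simulate_bundle(cfg)
write_bundle(bundle, "results/sim")

tr <- bundle$truth
cat("simulated", length(bundle$genome$seqs), "chromosomes,",
    nrow(bundle$genome$annotation$genes), "genes,",
    sum(!bundle$probe_set$probes$is_control), "genomic probes\n")
cat("planted:", nrow(tr$tdmrs), "T-DMRs (",
    sum(tr$tdmrs$regulation == "positive"), "positive,",
    sum(tr$tdmrs$regulation == "negative"), "negative couplings ),",
    nrow(tr$motif_sites), "motif copies\n")
cat("bundle written to results/sim\n")
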