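#!/usr/bin/env Rscript
# Stage 3: genomic context of the T-DMRs.
#
# Region assignment (4 kb upstream windows, UTRs, exons, introns),
# hypergeometric enrichment of T-DMR probes against the array design,
# CpG island/shore/shelf context, and conservation profiles of T-DMRs
# versus all probes.

suppressPackageStartupMessages(library(methylsplice))

bundle <- read_bundle("results/sim")
tdmrs <- read_tdmrs_bed("results/tdmr/tdmrs.bed")
stats <- utils::read.table("results/tdmr/probe_stats.tsv", header = TRUE,
                           sep = "\t")
ps <- filter_background(normalize_probes(bundle$probe_set))
ann <- bundle$genome$annotation
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

sig_probes <- stats$probe_id[stats$p_value < 0.005]
enr <- region_enrichment(intersect(sig_probes, ps$probes$probe_id),
                         ps$probes, ann)
utils::write.table(enr, "results/annotation/region_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("probe-category enrichment (observed vs expected %):\n")
print(enr, digits = 3)

ctx <- cbind(tdmrs["tdmr_id"], cpg_context(tdmrs, bundle$genome$islands))
utils::write.table(ctx, "results/annotation/tdmr_cpg_context.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nCpG context of T-DMRs:\n")
print(table(ctx$class))

prof <- conservation_profile(
  list(tdmrs = tdmrs[, c("chrom", "start", "end")],
       all_probes = ps$probes[, c("chrom", "start", "end")]),
  bundle$genome$conservation)
utils::write.table(prof$profile, "results/annotation/conservation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nconserved-nucleotide fractions written",
    "(uniform simulated track: sets should match)\n")
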