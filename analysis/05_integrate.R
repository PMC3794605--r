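#!/usr/bin/env Rscript
# Stage 5: join methylation and splicing.
#
# Gene-level overlap enrichment between T-DMR genes and AS genes in the
# expressed universe, exon-level T-DMR links (1 kb windows), coverage of
# AS versus non-AS exon neighbourhoods, and positive/negative regulation
# classification.

suppressPackageStartupMessages(library(methylsplice))

bundle <- read_bundle("results/sim")
tdmrs <- read_tdmrs_bed("results/tdmr/tdmrs.bed")
calls <- utils::read.table("results/splicing/as_calls.tsv", header = TRUE,
                           sep = "\t")
ann <- bundle$genome$annotation
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

expressed <- unique(bundle$exon_expr$exons$gene_id)
tdmr_regions <- assign_region(tdmrs, ann)
tdmr_genes <- intersect(unique(stats::na.omit(tdmr_regions$gene_id)),
                        expressed)
as_genes <- unique(calls$gene_id[calls$is_as])
ov <- gene_overlap_enrichment(tdmr_genes, as_genes, expressed)
cat(sprintf("T-DMR genes: %d; AS genes: %d; overlap: %d (%.1f%% of T-DMR genes), p = %.2g\n",
            ov$n_tdmr_genes, ov$n_as_genes, ov$overlap,
            ov$pct_tdmr_genes_as, ov$p_value))

links <- exon_level_association(calls$exon_id, tdmrs, ann, window = "1kb")
reg <- classify_regulation(links, tdmrs, calls)
utils::write.table(links, "results/integration/links.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(reg, "results/integration/regulation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("exon-level links:", nrow(links), "; classified (AS-linked):",
    nrow(reg), "\n")
print(table(reg$position, reg$regulation))

cov <- coverage_fraction(calls$exon_id[calls$is_as],
                         calls$exon_id[!calls$is_as], tdmrs, ann)
cat(sprintf("T-DMR coverage of exon neighbourhoods: AS %.3f vs non-AS %.3f (p = %.2g)\n",
            cov$as_fraction, cov$non_as_fraction, cov$p_value))

jsonlite::write_json(
  list(overlap = ov, coverage = cov),
  "results/integration/summary.json", auto_unbox = TRUE, digits = NA)
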