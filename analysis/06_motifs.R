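#!/usr/bin/env Rscript
# Stage 6: position-dependent 6mer motif discovery.
#
# T-DMR sequences are grouped by regulation (positive/negative) and
# position (upstream/downstream of the AS exon, 1 kb windows, gene-sense
# strand); every 6mer is tested against a random-exon-flank background
# with the upper-tail binomial model at BH FDR 1%. Downstream analyses:
# positional-role comparison, CpG content, consensus clustering, CTCF-like
# PWM similarity, and the motif-pair distance test.

suppressPackageStartupMessages(library(methylsplice))

bundle <- read_bundle("results/sim")
tdmrs <- read_tdmrs_bed("results/tdmr/tdmrs.bed")
calls <- utils::read.table("results/splicing/as_calls.tsv", header = TRUE,
                           sep = "\t")
reg <- utils::read.table("results/integration/regulation.tsv", header = TRUE,
                         sep = "\t")
ann <- bundle$genome$annotation
seqs <- bundle$genome$seqs
dir.create("results/motifs", showWarnings = FALSE, recursive = TRUE)

groups <- motif_groups(reg, tdmrs, ann, seqs)
for (key in names(groups))
  cat(sprintf("%-20s %6d bp in %d pieces\n", key,
              sum(Biostrings::width(groups[[key]]$seqs)),
              length(groups[[key]]$seqs)))

bg <- list(
  upstream = build_background(ann, seqs, 2000, "upstream", seed = 1),
  downstream = build_background(ann, seqs, 2000, "downstream", seed = 2))
stats <- list()
for (key in names(groups)) {
  side <- sub("_.*", "", key)
  if (length(groups[[key]]$seqs) == 0) next
  st <- count_and_test(groups[[key]]$seqs, bg[[side]])
  stats[[key]] <- st
  utils::write.table(st[order(st$q_value), ][1:50, ],
                     sprintf("results/motifs/top50_%s.tsv", key),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ranks <- vapply(c("ACCGCT", "GCGCAA"), function(km)
    which(st$kmer[order(st$p_value)] == km), integer(1))
  cat(key, ": ", sum(st$significant),
      "significant 6mers; planted ranks ACCGCT =", ranks[1],
      ", GCGCAA =", ranks[2], "\n")
}

null_stats <- local({
  k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
  data.frame(kmer = k, M = 0L, N = 0L, f = 0, p_value = 1, q_value = 1,
             significant = FALSE, zero_background = FALSE)
})
pick <- function(key) if (is.null(stats[[key]])) null_stats else stats[[key]]
pc <- positional_comparison(
  up = list(positive = pick("upstream_positive"),
            negative = pick("upstream_negative")),
  down = list(positive = pick("downstream_positive"),
              negative = pick("downstream_negative")))
utils::write.table(pc$table, "results/motifs/positional_comparison.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("positional roles:", pc$counts$n_union, "kmers in the union;",
    pc$counts$n_one_position, "one-position-only;",
    pc$counts$n_same, "same-role;", pc$counts$n_opposing, "opposing\n")

sig <- unique(unlist(lapply(stats, function(s) s$kmer[s$significant])))
all_seqs <- do.call(c, unname(lapply(groups, `[[`, "seqs")))
cpg <- cpg_content(sig, all_seqs)
cat(sprintf("CpG content: %.1f%% of significant 6mers vs %.1f%% of all 6mers\n",
            cpg$pct_sig_kmers_cpg, cpg$pct_all_kmers_cpg))

if (length(sig) > 1) {
  cl <- cluster_consensus(sig)
  utils::write.table(cl, "results/motifs/clusters.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat("clustered", length(sig), "significant 6mers into", nrow(cl),
      "consensus groups\n")
}

# similarity of the significant set to a CTCF-like core PWM
ctcf_core <- local({
  cons <- c("C", "C", "G", "C", "G", "A", "G", "G")  # core CCGCGAGG-like
  m <- matrix(0.06, 4, length(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 0.82
  m
})
if (length(sig) > 0) {
  ps <- pwm_similarity(sig, ctcf_core)
  cat(sprintf("PWM similarity (significant vs all 6mers): rank-sum p = %.3g\n",
              ps$p_value))
}

inst <- do.call(rbind, lapply(c("downstream_negative", "downstream_positive"),
                              function(k) find_motif_instances(groups[[k]], sig)))
dt <- pair_distance_test(inst, n_shuffles = 100, seed = 3)
if (!dt$empty) {
  cat(sprintf("motif-pair distances: observed mean %.0f vs shuffled %.0f (p = %.3g, %d pairs)\n",
              dt$observed_mean, dt$expected_mean, dt$p_value, dt$n_pairs))
  jsonlite::write_json(dt[c("observed_mean", "expected_mean", "p_value",
                            "n_pairs")],
                       "results/motifs/distance_test.json",
                       auto_unbox = TRUE, digits = NA)
}
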