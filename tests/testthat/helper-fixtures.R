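# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# A small but complete study bundle with planted couplings and a motif.
small_bundle <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(seed = 11, n_chromosomes = 2, chrom_length = 4e5,
                      n_genes = 30, n_ncrna = 4, planted_tdmr_count = 30,
                      planted_motifs = list(
                        list(kmer = "ACCGCT", position = "downstream",
                             regulation = "negative", fold = 5)))
    .fixtures$small <- simulate_bundle(cfg)
  }
  .fixtures$small
}

small_pipeline <- function() {
  if (is.null(.fixtures$small_res))
    .fixtures$small_res <- run_pipeline(
      small_bundle(), pipeline_params(n_background = 2000, seed = 5))
  .fixtures$small_res
}

# Noise-free bundle: exact planted effects, used for recovery tests.
noisefree_bundle <- function() {
  if (is.null(.fixtures$nf)) {
    cfg <- sim_config(seed = 7, n_chromosomes = 2, chrom_length = 4e5,
                      n_genes = 30, n_ncrna = 4, planted_tdmr_count = 24,
                      methyl_noise_sd = 0, expr_noise_sd = 0,
                      coupling_table = c(positive = 0.5, negative = 0.5,
                                         none = 0))
    .fixtures$nf <- simulate_bundle(cfg)
  }
  .fixtures$nf
}

# Hand-built four-gene annotation exercising strands, UTRs and multi-TSS.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(10000, 30000, 19000, 5000),
    end = c(15000, 36000, 22000, 9000),
    strand = c("+", "-", "+", "-"),
    coding = c(TRUE, TRUE, FALSE, TRUE),
    n_exons = c(3L, 3L, 2L, 2L))
  exons <- data.frame(
    exon_id = c("gA_e01", "gA_e02", "gA_e03",
                "gB_e03", "gB_e02", "gB_e01",
                "gC_e01", "gC_e02", "gD_e02", "gD_e01"),
    gene_id = c(rep("gA", 3), rep("gB", 3), rep("gC", 2), rep("gD", 2)),
    chrom = c(rep("chr1", 8), "chr2", "chr2"),
    start = c(10000, 12000, 14000, 30000, 32500, 35000,
              19000, 21000, 5000, 8000),
    end = c(10500, 12400, 15000, 30800, 33000, 36000,
            19400, 22000, 5600, 9000),
    strand = c(rep("+", 3), rep("-", 3), "+", "+", "-", "-"),
    exon_index = c(1L, 2L, 3L, 3L, 2L, 1L, 1L, 2L, 2L, 1L))
  tss <- data.frame(
    gene_id = c("gA", "gB", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(10000, 36000, 33000, 19000, 9000),
    strand = c("+", "-", "-", "+", "-"))
  utr5 <- data.frame(gene_id = c("gA", "gB", "gD"),
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(10000, 35900, 8900),
                     end = c(10060, 36000, 9000))
  utr3 <- data.frame(gene_id = c("gA", "gB", "gD"),
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(14920, 30000, 5000),
                     end = c(15000, 30080, 5080))
  gene_annotation(genes, exons, tss, utr5, utr3)
}

# A stats table over all 4096 kmers with a chosen significant subset.
mkstats <- function(sig_kmers) {
  k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
  data.frame(kmer = k, M = 0L, N = 0L, f = 0, p_value = 1,
             q_value = ifelse(k %in% sig_kmers, 0.001, 1),
             significant = k %in% sig_kmers, zero_background = FALSE)
}
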