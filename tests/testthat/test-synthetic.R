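test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, chrom_length = 1e5, n_genes = 4, n_ncrna = 1,
                    planted_tdmr_count = 4, n_control_probes = 50,
                    planted_motifs = list(
                      list(kmer = "ACGTAC", position = "upstream",
                           regulation = "positive", fold = 3)))
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(as.character(b1$genome$seqs), as.character(b2$genome$seqs))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$probe_set$input, b2$probe_set$input)
  expect_identical(b1$probe_set$enriched, b2$probe_set$enriched)
  expect_identical(b1$exon_expr$expr, b2$exon_expr$expr)
})

test_that("zero genes still yields sequences and an empty annotation", {
  cfg <- sim_config(seed = 2, chrom_length = 5e4, n_genes = 0, n_ncrna = 0,
                    planted_tdmr_count = 0)
  g <- generate_genome(cfg)
  expect_equal(length(g$seqs), cfg$n_chromosomes)
  expect_equal(nrow(g$annotation$genes), 0)
})

test_that("gene structure is internally consistent", {
  b <- small_bundle()
  ann <- b$genome$annotation
  # every exon inside its gene span, correct count per gene
  m <- match(ann$exons$gene_id, ann$genes$gene_id)
  expect_true(all(ann$exons$start >= ann$genes$start[m]))
  expect_true(all(ann$exons$end <= ann$genes$end[m]))
  expect_equal(as.vector(table(ann$exons$gene_id)[ann$genes$gene_id]),
               ann$genes$n_exons)
  # genes non-overlapping per chromosome
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # conservation scores within [0, 1]
  for (r in b$genome$conservation)
    expect_true(all(S4Vectors::runValue(r) >= 0 & S4Vectors::runValue(r) <= 1))
  # some genes carry two start sites
  expect_gt(max(table(ann$tss$gene_id)), 1)
})

test_that("exact exon counts are produced for a fixed exon range", {
  cfg <- sim_config(seed = 8, chrom_length = 4e5, n_genes = 20, n_ncrna = 0,
                    exons_per_gene = c(5L, 5L), planted_tdmr_count = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation$exons), 100)
  expect_equal(unname(table(g$annotation$exons$gene_id)), rep(5L, 20),
               ignore_attr = TRUE)
})

test_that("truth set keeps referential integrity", {
  b <- small_bundle()
  tr <- b$truth
  ann <- b$genome$annotation
  expect_true(all(tr$couplings$tdmr_id %in% tr$tdmrs$tdmr_id))
  expect_true(all(tr$couplings$exon_id %in% ann$exons$exon_id))
  expect_true(all(tr$as_exons$exon_id %in% ann$exons$exon_id))
  lens <- stats::setNames(Biostrings::width(b$genome$seqs),
                          names(b$genome$seqs))
  expect_true(all(tr$tdmrs$start >= 0))
  expect_true(all(tr$tdmrs$end <= lens[tr$tdmrs$chrom]))
  if (nrow(tr$motif_sites) > 0)
    expect_true(all(tr$motif_sites$pos + 6 <= lens[tr$motif_sites$chrom]))
})

test_that("noise-free methylation reproduces the planted delta exactly", {
  b <- noisefree_bundle()
  ps <- b$probe_set
  m <- ps$enriched - ps$input
  tiss <- ps$samples$tissue
  d <- rowMeans(m[, tiss == "retina"]) - rowMeans(m[, tiss == "brain"])
  pg <- GenomicRanges::GRanges(ps$probes$chrom[!ps$probes$is_control],
                               IRanges::IRanges(
                                 ps$probes$start[!ps$probes$is_control] + 1,
                                 ps$probes$end[!ps$probes$is_control]))
  tg <- GenomicRanges::GRanges(b$truth$tdmrs$chrom,
                               IRanges::IRanges(b$truth$tdmrs$start + 1,
                                                b$truth$tdmrs$end))
  inside <- GenomicRanges::countOverlaps(pg, tg, type = "within") > 0
  dg <- d[!ps$probes$is_control]
  expect_true(all(abs(abs(dg[inside]) - b$config$planted_delta) < 1e-12))
  outside_far <- GenomicRanges::countOverlaps(pg, tg) == 0
  expect_true(all(abs(dg[outside_far]) < 1e-12))
})

test_that("noise-free expression plants the splicing index exactly with the right sign", {
  b <- noisefree_bundle()
  ee <- b$exon_expr
  ni <- compute_ni(ee$expr, ee$exons$gene_id)
  tiss <- ee$samples$tissue
  si <- rowMeans(ni$ni[, tiss == "retina"]) - rowMeans(ni$ni[, tiss == "brain"])
  tr <- b$truth$as_exons
  planted <- si[match(tr$exon_id, rownames(ni$ni))]
  expect_equal(unname(abs(planted)), rep(b$config$as_effect, nrow(tr)),
               tolerance = 1e-9)
  expect_equal(unname(sign(planted)), tr$si_sign)
  # positive coupling: hypermethylated tissue has the higher inclusion
  cp <- merge(b$truth$couplings, b$truth$tdmrs[, c("tdmr_id", "direction")])
  cp <- merge(cp, tr[, c("exon_id", "included_in")])
  pos <- cp$regulation == "positive"
  expect_true(all(cp$direction[pos] == cp$included_in[pos]))
  expect_true(all(cp$direction[!pos] != cp$included_in[!pos]))
  # non-planted exons have SI exactly 0 except gene-mean leakage in AS genes
  untouched <- !(ee$exons$gene_id %in% tr$gene_id)
  expect_true(all(abs(si[untouched]) < 1e-12))
})

test_that("zero AS effect plants nothing above threshold", {
  cfg <- sim_config(seed = 13, chrom_length = 2e5, n_genes = 10, n_ncrna = 0,
                    planted_tdmr_count = 6, as_effect = 0,
                    methyl_noise_sd = 0, expr_noise_sd = 0)
  b <- simulate_bundle(cfg)
  ni <- compute_ni(b$exon_expr$expr, b$exon_expr$exons$gene_id)
  tiss <- b$exon_expr$samples$tissue
  si <- rowMeans(ni$ni[, tiss == "retina"]) -
    rowMeans(ni$ni[, tiss == "brain"])
  expect_true(all(abs(si) < 1e-12))
  calls <- call_as_exons(ni, b$exon_expr$samples)
  expect_equal(sum(calls$is_as), 0)
})

test_that("motif planting validates its input and is a no-op at fold 1", {
  expect_error(sim_config(planted_motifs = list(
    list(kmer = "ACGTN", position = "upstream", regulation = "positive",
         fold = 2))), "ACGT")
  expect_error(sim_config(planted_motifs = list(
    list(kmer = "ACGTACG", position = "upstream", regulation = "positive",
         fold = 2))), "6-letter")
  cfg <- sim_config(seed = 4, chrom_length = 2e5, n_genes = 12, n_ncrna = 0,
                    planted_tdmr_count = 8,
                    planted_motifs = list(
                      list(kmer = "TTTAAA", position = "downstream",
                           regulation = "negative", fold = 1)))
  g <- generate_genome(cfg)
  tr <- plan_truth(g, cfg)
  expect_equal(nrow(tr$motif_sites), 0)
  expect_identical(as.character(plant_motifs(g$seqs, tr, cfg)),
                   as.character(g$seqs))
})

test_that("planted motif sites carry the motif in gene-sense orientation", {
  b <- small_bundle()
  ms <- b$truth$motif_sites
  if (nrow(ms) > 0) {
    for (j in seq_len(nrow(ms))) {
      s <- as.character(Biostrings::subseq(b$genome$seqs[[ms$chrom[j]]],
                                           ms$pos[j] + 1, ms$pos[j] + 6))
      expected <- if (ms$strand[j] == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ms$kmer[j]))) else ms$kmer[j]
      expect_identical(s, expected)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(planted_delta = 0), "planted_delta")
  expect_error(sim_config(probe_length = 0), "probe_length")
  expect_error(sim_config(coupling_table = c(positive = 0.7, negative = 0.7)),
               "sum")
  expect_error(generate_genome(sim_config(chrom_length = 2e4, n_genes = 50)),
               "too short")
})
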