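test_that("gene overlap enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:100)
  tdmr_genes <- universe[1:20]
  as_genes <- universe[6:35]
  res <- gene_overlap_enrichment(tdmr_genes, as_genes, universe)
  expect_equal(res$overlap, 15)
  expect_equal(res$pct_tdmr_genes_as, 75)
  expect_equal(res$pct_as_genes_tdmr, 50)
  oracle <- sum(vapply(15:20, function(k)
    choose(30, k) * choose(70, 20 - k) / choose(100, 20), numeric(1)))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  # disjoint small sets in a big universe are unremarkable
  expect_gt(gene_overlap_enrichment(universe[1:3], universe[50:52],
                                    universe)$p_value, 0.5)
  # full nesting is maximally surprising for the margins
  nest <- gene_overlap_enrichment(universe[1:5], universe[1:10], universe)
  expect_equal(nest$overlap, 5)
  expect_lt(nest$p_value, 1e-4)
  expect_error(gene_overlap_enrichment("x", "y", character(0)), "empty")
})

test_that("exon-level association is strand-aware and window-bounded", {
  ann <- toy_annotation()
  # gA_e02 spans 12000-12400 on the plus strand
  tdmrs <- data.frame(
    tdmr_id = c("t_in", "t_left", "t_right", "t_far"),
    chrom = "chr1",
    start = c(12100, 11300, 12600, 14500),
    end = c(12250, 11500, 12800, 14700))
  links <- exon_level_association("gA_e02", tdmrs, ann, window = "1kb")
  expect_equal(links$position[links$tdmr_id == "t_in"], "within_exon")
  expect_equal(links$position[links$tdmr_id == "t_left"], "upstream")
  expect_equal(links$position[links$tdmr_id == "t_right"], "downstream")
  expect_false("t_far" %in% links$tdmr_id)

  # same geometry on the minus-strand gene gB: genomic left of the exon is
  # downstream in gene sense. gB_e02 spans 32500-33000.
  tdmrs_b <- data.frame(tdmr_id = c("b_left", "b_right"), chrom = "chr1",
                        start = c(32000, 33200), end = c(32300, 33400))
  links_b <- exon_level_association("gB_e02", tdmrs_b, ann, window = "1kb")
  expect_equal(links_b$position[links_b$tdmr_id == "b_left"], "downstream")
  expect_equal(links_b$position[links_b$tdmr_id == "b_right"], "upstream")

  # a T-DMR 2 kb away links in no mode
  far <- data.frame(tdmr_id = "f", chrom = "chr1", start = 14500, end = 14600)
  expect_equal(nrow(exon_level_association("gA_e02", far, ann, "1kb")), 0)

  # flanking-intron mode reaches through the whole intron
  intronic <- data.frame(tdmr_id = "i", chrom = "chr1", start = 10550,
                         end = 10650)
  expect_equal(nrow(exon_level_association("gA_e02", intronic, ann, "1kb")),
               0)
  li <- exon_level_association("gA_e02", intronic, ann, "flanking_introns")
  expect_equal(li$position, "upstream")
})

test_that("T-DMRs overlapping the exon boundary count as within_exon", {
  ann <- toy_annotation()
  junction <- data.frame(tdmr_id = "j", chrom = "chr1", start = 11900,
                         end = 12080)  # spans the 5' junction of gA_e02
  links <- exon_level_association("gA_e02", junction, ann, "1kb")
  expect_equal(links$position, "within_exon")
})

test_that("link output is invariant to T-DMR input order", {
  ann <- toy_annotation()
  tdmrs <- data.frame(tdmr_id = c("t1", "t2", "t3"), chrom = "chr1",
                      start = c(12100, 11300, 12600),
                      end = c(12250, 11500, 12800))
  a <- exon_level_association("gA_e02", tdmrs, ann, "1kb")
  b <- exon_level_association("gA_e02", tdmrs[c(3, 1, 2), ], ann, "1kb")
  expect_equal(a, b)
})

test_that("coverage fractions follow pooled-base arithmetic and merging", {
  ann <- toy_annotation()
  # gA_e02 window in flanking-intron mode: 10500..14000 (3500 bases)
  tdmrs <- data.frame(tdmr_id = "t", chrom = "chr1", start = 12000,
                      end = 12350)
  cov <- coverage_fraction("gA_e02", "gA_e01", tdmrs, ann)
  expect_equal(cov$as_total, 3500)
  expect_equal(cov$as_covered, 350)
  expect_equal(cov$as_fraction, 0.1)
  # duplicated overlapping T-DMRs change nothing
  dup <- rbind(tdmrs, data.frame(tdmr_id = "t2", chrom = "chr1",
                                 start = 12100, end = 12350))
  cov2 <- coverage_fraction("gA_e02", "gA_e01", dup, ann)
  expect_equal(cov2$as_covered, cov$as_covered)
  # no T-DMRs at all
  cov0 <- coverage_fraction("gA_e02", "gA_e01", tdmrs[0, ], ann)
  expect_equal(cov0$as_fraction, 0)
  expect_true(cov$as_fraction >= 0 && cov$as_fraction <= 1)
})

test_that("regulation classification reproduces the canonical patterns", {
  links <- data.frame(tdmr_id = c("t1", "t2"), exon_id = c("e1", "e2"),
                      gene_id = c("g1", "g2"),
                      position = c("within_exon", "within_exon"))
  tdmrs <- data.frame(tdmr_id = c("t1", "t2"),
                      direction = c("retina-hyper", "brain-hyper"))
  # exon e1: more methylated in retina, excluded in retina -> negative
  # exon e2: more methylated in brain, included in brain -> positive
  as_calls <- data.frame(exon_id = c("e1", "e2"), si = c(-1, -1),
                         p_value = 1e-6, is_as = TRUE,
                         included_in = c("brain", "brain"))
  res <- classify_regulation(links, tdmrs, as_calls)
  expect_equal(res$regulation, c("negative", "positive"))
  # relabeling tissues leaves the labels unchanged
  tdmrs_sw <- data.frame(tdmr_id = c("t1", "t2"),
                         direction = c("brain-hyper", "retina-hyper"))
  as_sw <- as_calls
  as_sw$included_in <- c("retina", "retina")
  res_sw <- classify_regulation(links, tdmrs_sw, as_sw)
  expect_equal(res_sw$regulation, res$regulation)
  # non-AS exons produce no assignment
  as_none <- as_calls
  as_none$is_as <- FALSE
  expect_equal(nrow(classify_regulation(links, tdmrs, as_none)), 0)
})

test_that("planted regulation labels are recovered on noise-free data", {
  b <- noisefree_bundle()
  res <- run_pipeline(b, pipeline_params(tdmr_method = "welch",
                                         n_background = 500, seed = 3))
  truth <- b$truth$couplings
  # every classified link agrees with the planted label
  agree <- merge(res$regulation, truth, by = "exon_id")
  expect_gt(nrow(agree), 0)
  expect_true(all(agree$regulation.x == agree$regulation.y))
  # classification applied to the planted T-DMR geometry itself recovers
  # every planted coupling (independent of probe-level callability)
  tt <- b$truth$tdmrs
  tt$direction <- paste0(tt$direction, "-hyper")
  links <- exon_level_association(truth$exon_id, tt,
                                  b$genome$annotation, "1kb")
  cls <- classify_regulation(links, tt, res$as_calls)
  full <- merge(cls, truth, by = c("tdmr_id", "exon_id"))
  expect_equal(nrow(full), nrow(truth))
  expect_true(all(full$regulation.x == full$regulation.y))
})
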