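dss <- function(...) Biostrings::DNAStringSet(c(...))

test_that("background frequencies behave on degenerate and uniform genomes", {
  # homopolymer genome: only AAAAAA has mass
  ann <- toy_annotation()
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 40000),
                                     chr2 = strrep("A", 10000)))
  bg <- build_background(ann, seqs, n_exons = 50, side = "downstream",
                         flank = 200, seed = 1)
  # minus-strand flanks are reverse-complemented, so the mass splits
  # between the homopolymer and its complement
  expect_equal(unname(bg$f["AAAAAA"] + bg$f["TTTTTT"]), 1)
  expect_gt(bg$f["AAAAAA"], 0)
  expect_equal(sum(bg$f), 1)
  # a sequence of length L contributes L-5 windows
  expect_equal(sum(methylsplice:::count_6mers(dss(strrep("A", 100)))), 95)
  # i.i.d. uniform genome: every kmer close to 1/4096
  b <- small_bundle()
  bg2 <- build_background(b$genome$annotation, b$genome$seqs,
                          n_exons = 3000, side = "upstream", seed = 2)
  expect_equal(sum(bg2$f), 1)
  # tolerance ~ 6 sd of a binomial proportion at ~3e6 windows
  tol <- 6 * sqrt((1 / 4096) / bg2$total)
  expect_lt(max(abs(bg2$f - 1 / 4096)), 12 * tol)
  expect_gt(min(bg2$f), 0)
})

test_that("count_and_test covers edge cases and partitions windows", {
  bg <- list(f = stats::setNames(rep(1 / 4096, 4096),
                                 Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)),
             total = 4096)
  st <- count_and_test(dss("ACGTACGTACGT", "TTTTTTTT"), bg)
  expect_equal(sum(st$M), sum(st$N[1] * 0) + (12 - 5) + (8 - 5))
  expect_true(all(st$N == sum(st$M)))
  expect_true(all(st$p_value[st$M == 0] == 1))
  expect_false(any(st$significant[st$M == 0]))
  # zero background frequency with observations flags p = 0
  bg0 <- bg
  bg0$f["TTTTTT"] <- 0
  st0 <- count_and_test(dss("TTTTTTTT"), bg0)
  row <- st0[st0$kmer == "TTTTTT", ]
  expect_equal(row$p_value, 0)
  expect_true(row$zero_background)
  expect_error(count_and_test(Biostrings::DNAStringSet(), bg), "no 6mer")
})

test_that("lowering the FDR threshold never adds motifs", {
  b <- small_bundle()
  res <- small_pipeline()
  st <- res$motifs$stats$downstream$negative
  for (thr in c(0.05, 0.01, 0.001)) {
    s_lo <- sum(st$q_value < thr / 10)
    s_hi <- sum(st$q_value < thr)
    expect_lte(s_lo, s_hi)
  }
})

test_that("positional comparison classifies roles by set algebra", {
  A <- "AAAAAA"; B <- "CCCCCC"; C <- "GGGGGG"
  # downstream: A negative, B positive; upstream: B negative, C positive
  down <- list(positive = mkstats(B), negative = mkstats(A))
  up <- list(positive = mkstats(C), negative = mkstats(B))
  pc <- positional_comparison(up, down)
  expect_equal(pc$counts$n_union, 3)
  expect_equal(pc$counts$n_one_position, 2)   # A and C
  expect_equal(pc$counts$n_opposing, 1)       # B flips sign
  expect_equal(pc$counts$pct_one_position, 200 / 3)
  tab <- pc$table
  expect_equal(tab$class[tab$kmer == B], "opposing")
  # same role at both positions
  same <- positional_comparison(list(positive = mkstats(character(0)),
                                     negative = mkstats(A)),
                                list(positive = mkstats(character(0)),
                                     negative = mkstats(A)))
  expect_equal(same$counts$n_same, 1)
  expect_equal(same$counts$pct_same, 100)
  # dual at one position vs single at the other counts as opposing
  dual_down <- list(positive = mkstats(A), negative = mkstats(A))
  single_up <- list(positive = mkstats(A), negative = mkstats(character(0)))
  pc2 <- positional_comparison(single_up, dual_down)
  expect_equal(pc2$counts$n_opposing, 1)
  # bookkeeping identities
  cnt <- pc$counts
  expect_equal(cnt$n_same + cnt$n_opposing + cnt$n_one_position, cnt$n_union)
  expect_equal(cnt$n_same + cnt$n_opposing,
               cnt$n_up + cnt$n_down - cnt$n_union)
})

test_that("CpG content analytics match enumeration", {
  res <- cpg_content(c("CGAAAA", "CGCGCG", "ACGTAC"), dss("ACGTACGTAAAA"))
  expect_equal(res$n_all_kmers_cpg, 1185)
  expect_equal(res$pct_all_kmers_cpg, 100 * 1185 / 4096)
  expect_equal(round(res$pct_all_kmers_cpg, 1), 28.9)
  expect_equal(res$pct_sig_kmers_cpg, 100)
  # dimer analogue by the same recurrence: strings over 4 letters of length
  # 2 avoiding CG = 16 - 1
  f <- function(n) if (n == 0) 1 else if (n == 1) 4 else
    4 * f(n - 1) - f(n - 2)
  expect_equal(4^2 - f(2), 1)
  expect_equal(4^6 - f(6), 1185)
})

test_that("kmer clustering yields deterministic IUPAC consensus", {
  one <- cluster_consensus("ACGTAC")
  expect_equal(nrow(one), 1)
  expect_equal(one$consensus, "ACGTAC")
  dup <- cluster_consensus(c("ACGTAC", "ACGTAC"))
  expect_equal(nrow(dup), 1)
  pair <- cluster_consensus(c("CCGGAA", "CCGGCA"))
  expect_equal(nrow(pair), 1)
  # one degenerate column: A/C -> M
  expect_equal(pair$consensus, "CCGGMA")
  pfm <- attr(pair, "pfm")[[1]]
  expect_equal(colSums(pfm), rep(1, 6), ignore_attr = TRUE)
  expect_equal(unname(pfm["A", 5]), 0.5)
  expect_equal(unname(pfm["C", 5]), 0.5)
  # unrelated kmers split into separate clusters
  many <- cluster_consensus(c("AAAAAA", "AAAAAT", "GCGCGC", "CGCGCG"))
  expect_gt(max(many$cluster), 1)
  # determinism
  expect_identical(cluster_consensus(c("CCGGAA", "CCGGCA", "TTTTTT")),
                   cluster_consensus(c("TTTTTT", "CCGGCA", "CCGGAA")))
})

test_that("PWM similarity scoring is maximal at the consensus and flat for uniform", {
  # near-deterministic PWM for CCGGAA
  cons <- "CCGGAA"
  pwm <- matrix(0.02, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  bases <- strsplit(cons, "")[[1]]
  for (j in 1:6) pwm[bases[j], j] <- 0.94
  res <- pwm_similarity(c(cons, "TTTTTT"), pwm)
  expect_equal(res$background$kmer[which.max(res$background$score)], cons)
  expect_gt(res$scores$score[1], res$scores$score[2])
  # uniform PWM scores every kmer identically
  uni <- matrix(0.25, 4, 6)
  resu <- pwm_similarity(c("AAAAAA", "CGCGCG"), uni)
  expect_equal(resu$scores$score[1], resu$scores$score[2])
  # hand-computed two-offset case
  pwm8 <- cbind(pwm, matrix(0.25, 4, 2))
  k <- "CGGAAT"
  brute <- max(vapply(0:2, function(o)
    mean(log2(pmax(pwm8, 1e-3)[cbind(match(strsplit(k, "")[[1]],
                                           rownames(pwm8)), o + 1:6)] / 0.25)),
    numeric(1)))
  expect_equal(pwm_similarity(k, pwm8)$scores$score, brute)
  expect_error(pwm_similarity("AAAAAA", pwm[, 1:4]), "6 columns")
})

test_that("motif instances are located with genomic coordinates on both strands", {
  group <- list(
    seqs = dss("AATTTGGGACCGCTAA", "ACCGCTAAAA"),
    meta = data.frame(tdmr_id = c("t1", "t2"), exon_id = c("e1", "e2"),
                      chrom = "chr1", start = c(100, 500),
                      end = c(116, 510), strand = c("+", "-")))
  inst <- find_motif_instances(group, "ACCGCT")
  expect_equal(nrow(inst), 2)
  plus <- inst[inst$piece == 1, ]
  expect_equal(plus$gpos, 100 + 8)   # eight bases precede the motif
  minus <- inst[inst$piece == 2, ]
  # local 0 on a minus-strand piece maps to the right edge
  expect_equal(minus$gpos, 510 - 0 - 6)
})

test_that("pair distances and the shuffle null behave analytically", {
  group <- list(
    seqs = dss(paste0(strrep("T", 10), "ACCGCT", "AAAAAA", "GGCGCT")),
    meta = data.frame(tdmr_id = "t1", exon_id = "e1", chrom = "chr1",
                      start = 1000, end = 1028, strand = "+"))
  inst <- find_motif_instances(group, c("ACCGCT", "GGCGCT"))
  expect_equal(sort(inst$local), c(10, 22))
  res <- pair_distance_test(inst, n_shuffles = 50, seed = 2)
  expect_equal(res$observed, 12)
  expect_false(res$empty)
  # two instances repositioned uniformly on length L have mean distance L/3
  L <- 3000
  big <- list(
    seqs = dss(paste0(strrep("T", 100), "ACCGCT",
                      strrep("A", L - 212), "GGCGCT", strrep("T", 100))),
    meta = data.frame(tdmr_id = "t", exon_id = "e", chrom = "chr1",
                      start = 0, end = L, strand = "+"))
  binst <- find_motif_instances(big, c("ACCGCT", "GGCGCT"))
  null <- pair_distance_test(binst, n_shuffles = 3000, seed = 3)
  expect_equal(null$expected_mean, L / 3, tolerance = 0.05)
  # a single instance yields an empty, flagged result
  single <- pair_distance_test(binst[1, ], n_shuffles = 10, seed = 1)
  expect_true(single$empty)
})

test_that("a planted motif is recovered through the full stack", {
  res <- small_pipeline()
  st <- res$motifs$stats$downstream$negative
  row <- st[st$kmer == "ACCGCT", ]
  # the planted kmer is enriched relative to background at this small scale
  expect_gt(row$M / (row$N * row$f), 1.5)
})
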