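#' Planted-truth benchmark: T-DMR recovery
#'
#' Simulates a two-chromosome genome tiled with ~50k probes, plants
#' \code{n_tdmrs} free-standing T-DMRs (default delta 0.3, replicate noise
#' sd 0.1, 3 vs 3), runs normalization, background filtering and T-DMR
#' calling at p < 0.005 with the >= 3-probe rule, and scores interval-level
#' sensitivity (planted regions overlapped by a call) and empirical FDR
#' (calls overlapping no planted region).
#'
#' @param seed Integer seed driving the whole simulation.
#' @param n_tdmrs Number of planted regions.
#' @param chrom_length,n_chromosomes Genome dimensions.
#' @param delta Planted methylation difference.
#' @param noise_sd Replicate noise sd.
#' @param method Probe-level test passed to \code{\link{call_tdmrs}}.
#' @return A list with \code{sensitivity}, \code{fdr}, \code{n_called},
#'   \code{n_planted} and \code{n_probes}.
#' @export
benchmark_tdmr_recovery <- function(seed, n_tdmrs = 100,
                                    chrom_length = 1e6, n_chromosomes = 2,
                                    delta = 0.3, noise_sd = 0.1,
                                    method = "moderated") {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chromosomes,
                    chrom_length = chrom_length, n_genes = 40, n_ncrna = 0,
                    planted_tdmr_count = n_tdmrs,
                    coupling_table = c(positive = 0, negative = 0, none = 1),
                    planted_delta = delta, methyl_noise_sd = noise_sd)
  g <- generate_genome(cfg)
  tr <- plan_truth(g, cfg)
  ps <- simulate_methylation(g, tr, cfg)
  ps <- filter_background(normalize_probes(ps))
  calls <- call_tdmrs(relative_methylation(ps), ps$probes, ps$samples,
                      method = method)
  tg <- df_to_granges(tr$tdmrs)
  cg <- df_to_granges(calls$tdmrs)
  list(sensitivity = mean(GenomicRanges::countOverlaps(tg, cg) > 0),
       fdr = if (length(cg)) mean(GenomicRanges::countOverlaps(cg, tg) == 0)
             else 0,
       n_called = nrow(calls$tdmrs), n_planted = n_tdmrs,
       n_probes = nrow(ps$probes))
}

#' Planted-truth benchmark: regulation-label recovery
#'
#' Builds a noise-free bundle in which every planted T-DMR is coupled to an
#' exon under a positive or negative regulation label, runs the pipeline
#' (plain Welch probe test; noise-free variances make moderation
#' unnecessary), and checks that classification recovers the planted
#' labels, both on the called T-DMRs and on the planted T-DMR geometry
#' directly.
#'
#' @param seed Integer seed.
#' @param n_tdmrs Number of planted couplings.
#' @return A list with \code{n_links}, \code{accuracy} (on classified
#'   links), \code{n_truth}, \code{truth_accuracy} (classification run on
#'   the planted intervals themselves).
#' @export
benchmark_regulation_recovery <- function(seed, n_tdmrs = 24) {
  cfg <- sim_config(seed = seed, n_chromosomes = 2, chrom_length = 4e5,
                    n_genes = 30, n_ncrna = 4,
                    planted_tdmr_count = n_tdmrs,
                    methyl_noise_sd = 0, expr_noise_sd = 0,
                    coupling_table = c(positive = 0.5, negative = 0.5,
                                       none = 0))
  b <- simulate_bundle(cfg)
  res <- run_pipeline(b, pipeline_params(tdmr_method = "welch",
                                         n_background = 500, seed = seed))
  truth <- b$truth$couplings
  linked <- merge(res$regulation, truth, by = "exon_id")
  tt <- b$truth$tdmrs
  tt$direction <- paste0(tt$direction, "-hyper")
  links <- exon_level_association(truth$exon_id, tt, b$genome$annotation,
                                  "1kb")
  cls <- classify_regulation(links, tt, res$as_calls)
  full <- merge(cls, truth, by = c("tdmr_id", "exon_id"))
  list(n_links = nrow(linked),
       accuracy = mean(linked$regulation.x == linked$regulation.y),
       n_truth = nrow(full),
       truth_accuracy = mean(full$regulation.x == full$regulation.y))
}

#' Planted-truth benchmark: 6mer motif recovery and null calibration
#'
#' Plants one 6mer at \code{fold}-times its background frequency inside the
#' downstream-negative T-DMR group of a genome large enough to give the
#' group well over 200 kb of sequence, tests all 4096 6mers against a
#' 10000-exon flank background, and reports the planted kmer's q-value. As
#' a calibration control it also tests \code{n_null_reps} seeded replicates
#' of unplanted pseudo-groups and reports the fraction of kmers called
#' significant in each.
#'
#' @param seed Integer seed.
#' @param kmer Planted 6mer.
#' @param fold Planted enrichment fold.
#' @param n_null_reps Number of null pseudo-group replicates.
#' @return A list with \code{group_bp}, \code{q_value}, \code{significant},
#'   \code{n_significant}, \code{null_fractions} and
#'   \code{frac_null_calibrated} (share of null replicates with <= 5\% of
#'   kmers significant).
#' @export
benchmark_motif_recovery <- function(seed, kmer = "ACCGCT", fold = 5,
                                     n_null_reps = 20) {
  cfg <- sim_config(seed = seed, n_chromosomes = 3, chrom_length = 2e6,
                    n_genes = 320, n_ncrna = 0, planted_tdmr_count = 300,
                    coupling_table = c(positive = 0, negative = 1, none = 0),
                    position_probs = c(upstream = 0, downstream = 1,
                                       within_exon = 0),
                    tdmr_width = c(600L, 900L),
                    planted_motifs = list(
                      list(kmer = kmer, position = "downstream",
                           regulation = "negative", fold = fold)))
  g <- generate_genome(cfg)
  tr <- plan_truth(g, cfg)
  g$seqs <- plant_motifs(g$seqs, tr, cfg)
  grp <- motif_groups(tr$couplings, tr$tdmrs, g$annotation, g$seqs)
  dn <- grp$downstream_negative
  bg <- suppressMessages(
    build_background(g$annotation, g$seqs, 10000, "downstream",
                     seed = seed))
  st <- count_and_test(dn$seqs, bg)
  row <- st[st$kmer == kmer, ]

  null_fractions <- vapply(seq_len(n_null_reps), function(i) {
    set.seed(seed * 1000L + i)
    n <- 60
    ch <- sample(names(g$seqs), n, replace = TRUE)
    starts <- sample.int(cfg$chrom_length - 2000, n)
    iv <- Biostrings::DNAStringSet(lapply(seq_len(n), function(j)
      Biostrings::subseq(g$seqs[[ch[j]]], starts[j], starts[j] + 699)))
    mean(count_and_test(iv, bg)$significant)
  }, numeric(1))
  list(group_bp = sum(Biostrings::width(dn$seqs)),
       q_value = row$q_value, significant = row$significant,
       n_significant = sum(st$significant),
       null_fractions = null_fractions,
       frac_null_calibrated = mean(null_fractions <= 0.05))
}

#' Analytic benchmark: motif-pair distance null
#'
#' Two motif instances repositioned uniformly on a sequence of length L
#' have expected distance L/3; the shuffle null of
#' \code{\link{pair_distance_test}} must reproduce that expectation.
#'
#' @param seed Integer seed.
#' @param L Sequence length.
#' @param n_shuffles Number of shuffles per estimate (the estimate pools
#'   \code{n_pairs} independent sequences, each shuffled
#'   \code{n_shuffles} times).
#' @param n_pairs Number of two-instance sequences pooled.
#' @return A list with \code{expected_mean}, \code{analytic} (= L/3) and
#'   \code{rel_error}.
#' @export
benchmark_distance_null <- function(seed, L = 3000, n_shuffles = 100,
                                    n_pairs = 40) {
  seqs <- Biostrings::DNAStringSet(rep(paste0(
    strrep("T", 100), "ACCGCT", strrep("A", L - 212), "GGCGCT",
    strrep("T", 100)), n_pairs))
  meta <- data.frame(tdmr_id = sprintf("t%02d", seq_len(n_pairs)),
                     exon_id = sprintf("e%02d", seq_len(n_pairs)),
                     chrom = "chr1",
                     start = seq(0, by = L + 100, length.out = n_pairs),
                     end = seq(0, by = L + 100, length.out = n_pairs) + L,
                     strand = "+")
  inst <- find_motif_instances(list(seqs = seqs, meta = meta),
                               c("ACCGCT", "GGCGCT"))
  res <- pair_distance_test(inst, n_shuffles = n_shuffles, seed = seed)
  list(expected_mean = res$expected_mean, analytic = L / 3,
       rel_error = abs(res$expected_mean - L / 3) / (L / 3))
}
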