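#' Configuration for the synthetic methylation/splicing simulator
#'
#' Collects every tunable of the synthetic-data generator with defaults that
#' emulate a scaled-down two-tissue tiling-array methylation study paired with
#' exon-level expression: 50-bp probes tiled densely along small chromosomes,
#' three replicates per tissue, planted differentially methylated regions
#' (T-DMRs), planted alternatively spliced (AS) exons coupled to T-DMRs under
#' positive or negative regulation, and optional 6mer motifs planted inside
#' T-DMR sequence.
#'
#' @param seed Integer root seed; every stage derives its stream from it.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Number of protein-coding genes.
#' @param n_ncrna Number of non-coding RNA genes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length,intron_length Ranges (bp) for exon and intron sizes.
#' @param probe_length Tiling probe length in bp.
#' @param probe_spacing Distance between consecutive probe starts in bp.
#' @param n_control_probes Number of non-genomic control probes.
#' @param n_replicates_per_tissue Replicates per tissue (arrays per channel).
#' @param tissues Character vector of the two tissue labels.
#' @param methyl_noise_sd Replicate noise sd of per-probe relative
#'   methylation, log2 units.
#' @param expr_noise_sd Replicate noise sd of exon log2 intensities.
#' @param planted_tdmr_count Number of planted T-DMRs.
#' @param planted_delta Planted between-tissue difference in relative
#'   methylation (log2 enriched/input units); must be > 0.
#' @param tdmr_width Range (bp) of planted T-DMR widths.
#' @param coupling_table Named fractions of planted T-DMRs assigned
#'   \code{positive}, \code{negative} regulation or \code{none}; must sum to
#'   at most 1 (the remainder is treated as \code{none}).
#' @param position_probs Named probabilities over coupled T-DMR positions
#'   (\code{upstream}, \code{downstream}, \code{within_exon}).
#' @param as_effect Planted |splicing index| of coupled AS exons, log2 units.
#' @param planted_motifs List of motif plans, each a list with \code{kmer}
#'   (6-letter ACGT string), \code{position} ("upstream"/"downstream"),
#'   \code{regulation} ("positive"/"negative") and \code{fold} (>= 1).
#' @param multi_tss_fraction Fraction of eligible genes given a second
#'   transcription start site.
#' @param background_input Log2 input intensity of non-genomic controls.
#' @param genomic_input Log2 input intensity of genomic probes.
#' @param islands_per_chrom CpG islands placed per chromosome.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length = 1e6,
                       n_genes = 50,
                       n_ncrna = 8,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(100L, 250L),
                       intron_length = c(500L, 1500L),
                       probe_length = 50L,
                       probe_spacing = 40L,
                       n_control_probes = 2000L,
                       n_replicates_per_tissue = 3L,
                       tissues = c("retina", "brain"),
                       methyl_noise_sd = 0.1,
                       expr_noise_sd = 0.1,
                       planted_tdmr_count = 60L,
                       planted_delta = 0.3,
                       tdmr_width = c(400L, 700L),
                       coupling_table = c(positive = 0.35, negative = 0.35,
                                          none = 0.30),
                       position_probs = c(upstream = 0.4, downstream = 0.4,
                                          within_exon = 0.2),
                       as_effect = 0.8,
                       planted_motifs = list(),
                       multi_tss_fraction = 0.2,
                       background_input = 6,
                       genomic_input = 10,
                       islands_per_chrom = 6L) {
  if (probe_length <= 0) stop("probe_length must be positive")
  if (planted_delta <= 0) stop("planted_delta must be positive")
  if (length(tissues) != 2) stop("exactly two tissue labels are required")
  ct <- coupling_table[setdiff(names(coupling_table), "none")]
  if (sum(ct) > 1 + 1e-9) stop("coupling_table fractions must sum to <= 1")
  if (abs(sum(position_probs) - 1) > 1e-9)
    stop("position_probs must sum to 1")
  for (pm in planted_motifs) {
    validate_kmer(pm$kmer)
    if (is.null(pm$fold) || pm$fold < 1) stop("motif fold must be >= 1")
    if (!pm$position %in% c("upstream", "downstream"))
      stop("motif position must be 'upstream' or 'downstream'")
    if (!pm$regulation %in% c("positive", "negative"))
      stop("motif regulation must be 'positive' or 'negative'")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

validate_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) != 1 || nchar(kmer) != 6 ||
      grepl("[^ACGT]", kmer))
    stop("motif must be a 6-letter string over ACGT, got: ", kmer)
  invisible(kmer)
}

# Stage-specific substream seeds derived from the root seed (kept < 2^31).
stage_seed <- function(config, stage) {
  offsets <- c(genome = 11L, truth = 29L, motifs = 47L, methylation = 83L,
               expression = 131L)
  (abs(as.integer(config$seed)) %% 2000000000L) + offsets[[stage]]
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic genome bundle
#'
#' Builds random chromosome sequences, a non-overlapping gene annotation with
#' exons, introns, UTRs and (for a subset of genes) multiple transcription
#' start sites, CpG-island intervals spaced so that island, shore, shelf and
#' open-sea context all occur, and a piecewise-constant per-base conservation
#' track with scores in [0, 1].
#'
#' All coordinates are 0-based, half-open.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{sim_genome}: a list with \code{seqs}
#'   (\code{DNAStringSet}), \code{annotation} (see
#'   \code{\link{gene_annotation}}), \code{islands} (data.frame),
#'   \code{conservation} (named list of \code{Rle}) and \code{config}.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length

  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- chroms

  ann <- place_genes(config, chroms, L)
  islands <- place_islands(config, chroms, L)
  cons <- lapply(chroms, function(ch) simulate_conservation(L))
  names(cons) <- chroms

  structure(list(seqs = seqs, annotation = ann, islands = islands,
                 conservation = cons, config = config),
            class = "sim_genome")
}

# Lay out genes sequentially per chromosome with wide intergenic gaps so
# upstream windows never collide and open-sea territory exists.
place_genes <- function(config, chroms, L) {
  n_total <- config$n_genes + config$n_ncrna
  if (n_total == 0) return(empty_annotation())
  coding <- sample(rep(c(TRUE, FALSE), c(config$n_genes, config$n_ncrna)))
  chrom_of <- rep(chroms, length.out = n_total)

  genes <- exons <- tss <- utr5 <- utr3 <- list()
  gid <- 0
  for (ch in chroms) {
    cursor <- 6000 + sample.int(4000, 1)
    for (i in which(chrom_of == ch)) {
      gid <- gid + 1
      k <- runif_int(1, config$exons_per_gene)
      elens <- runif_int(k, config$exon_length)
      ilens <- if (k > 1) runif_int(k - 1, config$intron_length) else integer(0)
      span <- sum(elens) + sum(ilens)
      if (cursor + span + 6000 > L)
        stop("chromosome ", ch, " too short for the requested gene count")
      strand <- sample(c("+", "-"), 1)
      gene_id <- sprintf("gene%03d", gid)
      estarts <- cursor + cumsum(c(0, head(elens, -1) + ilens))
      eends <- estarts + elens
      gstart <- estarts[1]; gend <- eends[k]
      # exon index runs 5' to 3' in gene sense
      idx <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      exons[[gid]] <- data.frame(
        exon_id = sprintf("%s_e%02d", gene_id, idx),
        gene_id = gene_id, chrom = ch, start = estarts, end = eends,
        strand = strand, exon_index = idx)
      main_tss <- if (strand == "+") gstart else gend
      tss[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                               pos = main_tss, strand = strand)
      if (coding[i]) {
        u5 <- min(60L, elens[if (strand == "+") 1 else k])
        u3 <- min(80L, elens[if (strand == "+") k else 1])
        if (strand == "+") {
          utr5[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                                    start = gstart, end = gstart + u5)
          utr3[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                                    start = gend - u3, end = gend)
        } else {
          utr5[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                                    start = gend - u5, end = gend)
          utr3[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                                    start = gstart, end = gstart + u3)
        }
      }
      genes[[gid]] <- data.frame(gene_id = gene_id, chrom = ch,
                                 start = gstart, end = gend, strand = strand,
                                 coding = coding[i], n_exons = k)
      cursor <- gend + 9000 + sample.int(5000, 1)
    }
  }
  ann <- gene_annotation(do.call(rbind, genes), do.call(rbind, exons),
                         do.call(rbind, tss),
                         if (length(utr5)) do.call(rbind, utr5) else NULL,
                         if (length(utr3)) do.call(rbind, utr3) else NULL)
  add_alternative_tss(ann, config)
}

# A configurable subset of multi-exon genes receives a second TSS at the
# gene-sense start of its second exon, defining an alternative start region.
add_alternative_tss <- function(ann, config) {
  elig <- ann$genes$gene_id[ann$genes$n_exons >= 3]
  n_alt <- round(config$multi_tss_fraction * length(elig))
  if (n_alt == 0) return(ann)
  alt <- sort(sample(elig, n_alt))
  extra <- lapply(alt, function(g) {
    ex <- ann$exons[ann$exons$gene_id == g & ann$exons$exon_index == 2, ]
    pos <- if (ex$strand == "+") ex$start else ex$end
    data.frame(gene_id = g, chrom = ex$chrom, pos = pos, strand = ex$strand)
  })
  ann$tss <- rbind(ann$tss, do.call(rbind, extra))
  ann$tss <- ann$tss[order(ann$tss$gene_id, ann$tss$pos), ]
  rownames(ann$tss) <- NULL
  ann
}

place_islands <- function(config, chroms, L) {
  n <- config$islands_per_chrom
  out <- lapply(chroms, function(ch) {
    centers <- round(seq(L * 0.08, L * 0.92, length.out = n) +
                       stats::runif(n, -8000, 8000))
    lens <- runif_int(n, c(500L, 1500L))
    start <- pmax(0, centers - lens %/% 2)
    data.frame(chrom = ch, start = start, end = pmin(L, start + lens),
               name = sprintf("%s_cgi%02d", ch, seq_len(n)))
  })
  do.call(rbind, out)
}

# Piecewise-constant conservation scores; segment lengths ~ 50 + Geom(1/150).
simulate_conservation <- function(L) {
  n_seg <- ceiling(L / 120)
  lens <- 50 + stats::rgeom(n_seg, 1 / 150)
  while (sum(lens) < L) lens <- c(lens, 50 + stats::rgeom(n_seg, 1 / 150))
  cum <- cumsum(lens)
  keep <- seq_len(which(cum >= L)[1])
  lens <- lens[keep]
  lens[length(lens)] <- lens[length(lens)] - (cum[keep[length(keep)]] - L)
  S4Vectors::Rle(stats::rbeta(length(lens), 2, 5), lens)
}

#' Plan the planted truth set for a genome bundle
#'
#' Chooses T-DMR intervals, their hypermethylated tissue, their couplings to
#' internal exons (positive/negative regulation at an upstream, downstream or
#' within-exon position), the resulting AS exons, and the genomic sites where
#' configured motifs will be planted.
#'
#' Coupled T-DMRs are placed inside the flanking intron within 1 kb of the
#' exon edge (or inside the exon for within-exon couplings) so that the 1-kb
#' association window recovers every planted link. At most one exon per gene
#' is coupled, keeping the planted splicing index exact under the
#' gene-mean normalized-intensity definition.
#'
#' @param genome A \code{sim_genome}.
#' @param config The \code{sim_config} used to build it.
#' @return An object of class \code{sim_truth} with elements \code{tdmrs},
#'   \code{as_exons}, \code{couplings} and \code{motif_sites} (data.frames).
#' @export
plan_truth <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(stage_seed(config, "truth"))
  n <- config$planted_tdmr_count
  ct <- config$coupling_table
  n_pos <- round(n * ct[["positive"]])
  n_neg <- round(n * ct[["negative"]])
  regulation <- c(rep("positive", n_pos), rep("negative", n_neg),
                  rep("none", n - n_pos - n_neg))

  ex <- genome$annotation$exons
  genes <- genome$annotation$genes
  internal <- ex[ex$exon_index > 1 &
                   ex$exon_index < genes$n_exons[match(ex$gene_id, genes$gene_id)], ]
  # one coupled exon per gene
  pool <- internal[!duplicated(internal$gene_id), ]
  pool <- pool[sample.int(nrow(pool)), ]
  n_coupled <- n_pos + n_neg
  if (n_coupled > nrow(pool))
    stop("not enough internal exons to host ", n_coupled, " couplings")

  tdmrs <- vector("list", n)
  couplings <- vector("list", n)
  tiss <- config$tissues
  ci <- 0
  for (i in seq_len(n)) {
    reg <- regulation[i]
    width <- runif_int(1, config$tdmr_width)
    dir_tissue <- sample(tiss, 1)
    if (reg %in% c("positive", "negative")) {
      ci <- ci + 1
      e <- pool[ci, ]
      position <- sample(names(config$position_probs), 1,
                         prob = config$position_probs)
      span <- place_coupled_tdmr(e, position, width)
      tdmrs[[i]] <- data.frame(
        tdmr_id = sprintf("tdmr%03d", i), chrom = e$chrom,
        start = span[1], end = span[2], direction = dir_tissue,
        regulation = reg, position = position, exon_id = e$exon_id,
        stringsAsFactors = FALSE)
      couplings[[i]] <- data.frame(
        tdmr_id = sprintf("tdmr%03d", i), exon_id = e$exon_id,
        gene_id = e$gene_id, regulation = reg, position = position,
        stringsAsFactors = FALSE)
    } else {
      span <- place_free_tdmr(genome, width)
      tdmrs[[i]] <- data.frame(
        tdmr_id = sprintf("tdmr%03d", i), chrom = span$chrom,
        start = span$start, end = span$end, direction = dir_tissue,
        regulation = "none", position = NA_character_,
        exon_id = NA_character_, stringsAsFactors = FALSE)
      couplings[[i]] <- NULL
    }
  }
  tdmrs <- do.call(rbind, tdmrs)
  couplings <- if (ci > 0) do.call(rbind, couplings) else
    data.frame(tdmr_id = character(0), exon_id = character(0),
               gene_id = character(0), regulation = character(0),
               position = character(0))

  as_exons <- build_as_truth(couplings, tdmrs, ex, genes, tiss)
  motif_sites <- plan_motif_sites(genome, tdmrs, config)
  structure(list(tdmrs = tdmrs, as_exons = as_exons, couplings = couplings,
                 motif_sites = motif_sites),
            class = "sim_truth")
}

# Coupled T-DMR span relative to its exon, in genomic coordinates.
# "upstream"/"downstream" are gene-sense; the region sits in the flanking
# intron, starting 50 bp from the exon edge so it stays within the 1-kb
# association window.
place_coupled_tdmr <- function(exon, position, width) {
  if (position == "within_exon") {
    w <- min(width, exon$end - exon$start)
    return(c(exon$start, exon$start + w))
  }
  genomic_left <- (position == "upstream") == (exon$strand == "+")
  if (genomic_left) c(exon$start - 50 - width, exon$start - 50)
  else c(exon$end + 50, exon$end + 50 + width)
}

place_free_tdmr <- function(genome, width) {
  ch <- sample(names(genome$seqs), 1)
  L <- length(genome$seqs[[ch]])
  start <- sample.int(L - width - 2000, 1) + 1000
  list(chrom = ch, start = start, end = start + width)
}

# An AS exon's inclusion tissue follows the coupling: positive regulation
# means the hypermethylated tissue shows greater inclusion; negative means
# the other tissue does.
build_as_truth <- function(couplings, tdmrs, exons, genes, tissues) {
  if (nrow(couplings) == 0)
    return(data.frame(exon_id = character(0), gene_id = character(0),
                      included_in = character(0), si_sign = numeric(0)))
  hyper <- tdmrs$direction[match(couplings$tdmr_id, tdmrs$tdmr_id)]
  included <- ifelse(couplings$regulation == "positive", hyper,
                     ifelse(hyper == tissues[1], tissues[2], tissues[1]))
  data.frame(exon_id = couplings$exon_id, gene_id = couplings$gene_id,
             included_in = included,
             si_sign = ifelse(included == tissues[1], 1, -1))
}

# Number and placement of extra motif copies written into each group's
# T-DMRs: expected extra count = (fold - 1) * background rate * windows.
plan_motif_sites <- function(genome, tdmrs, config) {
  set.seed(stage_seed(config, "motifs"))
  empty <- data.frame(kmer = character(0), chrom = character(0),
                      pos = numeric(0), strand = character(0),
                      tdmr_id = character(0))
  if (length(config$planted_motifs) == 0) return(empty)
  strand_of <- genome$annotation$exons$strand[
    match(tdmrs$exon_id, genome$annotation$exons$exon_id)]
  sites <- list()
  for (pm in config$planted_motifs) {
    grp <- which(tdmrs$regulation == pm$regulation &
                   tdmrs$position == pm$position)
    base_rate <- 0.25^6
    for (i in grp) {
      n_win <- max(0, tdmrs$end[i] - tdmrs$start[i] - 5)
      n_extra <- stats::rpois(1, (pm$fold - 1) * base_rate * n_win)
      if (n_extra == 0) next
      pos <- tdmrs$start[i] + sample.int(n_win, min(n_extra, n_win))
      sites[[length(sites) + 1]] <- data.frame(
        kmer = pm$kmer, chrom = tdmrs$chrom[i], pos = pos,
        strand = strand_of[i], tdmr_id = tdmrs$tdmr_id[i])
    }
  }
  if (length(sites) == 0) empty else do.call(rbind, sites)
}

#' Write planted motif sites into genome sequence
#'
#' Overwrites the 6 bases at each planned site with the motif, in gene-sense
#' orientation (the reverse complement is written for minus-strand genes).
#' With \code{fold = 1} no sites are planned and the sequences are returned
#' unchanged.
#'
#' @param seqs A \code{DNAStringSet}.
#' @param truth A \code{sim_truth} with \code{motif_sites}.
#' @param config The \code{sim_config} (motif validity is re-checked).
#' @return The modified \code{DNAStringSet}.
#' @export
plant_motifs <- function(seqs, truth, config) {
  for (pm in config$planted_motifs) validate_kmer(pm$kmer)
  ms <- truth$motif_sites
  if (nrow(ms) == 0) return(seqs)
  for (ch in unique(ms$chrom)) {
    rows <- ms[ms$chrom == ch, ]
    s <- as.character(seqs[[ch]])
    for (j in seq_len(nrow(rows))) {
      kmer <- rows$kmer[j]
      if (identical(rows$strand[j], "-"))
        kmer <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(kmer)))
      substr(s, rows$pos[j] + 1, rows$pos[j] + 6) <- kmer
    }
    seqs[[ch]] <- Biostrings::DNAString(s)
  }
  seqs
}

#' Tile probes over a genome and append non-genomic controls
#'
#' @param genome A \code{sim_genome}.
#' @param config The \code{sim_config}.
#' @return A data.frame with \code{probe_id}, \code{chrom}, \code{start},
#'   \code{end} and \code{is_control}; control probes carry no coordinates.
#' @export
tile_probes <- function(genome, config) {
  per_chrom <- lapply(names(genome$seqs), function(ch) {
    L <- length(genome$seqs[[ch]])
    starts <- seq.int(0, L - config$probe_length, by = config$probe_spacing)
    data.frame(chrom = ch, start = starts,
               end = starts + config$probe_length, is_control = FALSE)
  })
  probes <- do.call(rbind, per_chrom)
  ctrl <- data.frame(chrom = NA_character_, start = NA_real_, end = NA_real_,
                     is_control = rep(TRUE, config$n_control_probes))
  probes <- rbind(probes, ctrl)
  probes$probe_id <- sprintf("p%06d", seq_len(nrow(probes)))
  probes[, c("probe_id", "chrom", "start", "end", "is_control")]
}

#' Simulate two-channel methylation intensities over a probe table
#'
#' Each genomic probe receives a log2 input intensity around the genomic
#' level and an enriched intensity equal to input + baseline methylation +
#' the planted tissue effect + Gaussian replicate noise, so the per-probe
#' relative methylation (enriched - input) has noise sd exactly
#' \code{methyl_noise_sd}. Probes lying fully inside a planted T-DMR carry an
#' expected between-tissue difference of \code{planted_delta} (positive in
#' the hypermethylated tissue); all other probes have expected difference 0.
#' Control probes fluctuate around the background input level in both
#' channels.
#'
#' @param genome A \code{sim_genome}.
#' @param truth A \code{sim_truth}.
#' @param config The \code{sim_config}.
#' @return An object of class \code{probe_set}: list with \code{probes}
#'   (data.frame), \code{input} and \code{enriched} (probe x sample
#'   matrices) and \code{samples} (data.frame with \code{sample},
#'   \code{tissue}).
#' @export
simulate_methylation <- function(genome, truth, config) {
  if (config$planted_delta <= 0) stop("planted_delta must be positive")
  set.seed(stage_seed(config, "methylation"))
  probes <- tile_probes(genome, config)
  reps <- config$n_replicates_per_tissue
  samples <- data.frame(
    sample = paste(rep(config$tissues, each = reps), seq_len(reps), sep = "_"),
    tissue = rep(config$tissues, each = reps))
  np <- nrow(probes); ns <- nrow(samples)
  genomic <- !probes$is_control

  delta_mat <- matrix(0, np, ns)
  if (nrow(truth$tdmrs) > 0 && any(genomic)) {
    pg <- GenomicRanges::GRanges(probes$chrom[genomic],
                                 IRanges::IRanges(probes$start[genomic] + 1,
                                                  probes$end[genomic]))
    tg <- GenomicRanges::GRanges(truth$tdmrs$chrom,
                                 IRanges::IRanges(truth$tdmrs$start + 1,
                                                  truth$tdmrs$end))
    hits <- GenomicRanges::findOverlaps(pg, tg, type = "within")
    hyper <- truth$tdmrs$direction[S4Vectors::subjectHits(hits)]
    rows <- which(genomic)[S4Vectors::queryHits(hits)]
    for (t in config$tissues) {
      cols <- which(samples$tissue == t)
      sel <- rows[hyper == t]
      delta_mat[sel, cols] <- config$planted_delta
    }
  }

  baseline <- stats::rnorm(np, 1, 0.3)          # probe-specific methylation
  input <- matrix(NA_real_, np, ns,
                  dimnames = list(probes$probe_id, samples$sample))
  input[genomic, ] <- config$genomic_input +
    matrix(stats::rnorm(sum(genomic) * ns, 0, 0.2), sum(genomic), ns)
  input[!genomic, ] <- config$background_input +
    matrix(stats::rnorm(sum(!genomic) * ns, 0, config$methyl_noise_sd),
           sum(!genomic), ns)
  enriched <- input + baseline + delta_mat +
    matrix(stats::rnorm(np * ns, 0, config$methyl_noise_sd), np, ns)
  # controls: no enrichment signal, both channels hover at background
  enriched[!genomic, ] <- config$background_input +
    matrix(stats::rnorm(sum(!genomic) * ns, 0, config$methyl_noise_sd),
           sum(!genomic), ns)

  structure(list(probes = probes, input = input, enriched = enriched,
                 samples = samples),
            class = "probe_set")
}

#' Simulate exon-level expression with planted AS exons
#'
#' Exon log2 intensities are gene baseline + exon offset + noise; each
#' planted AS exon additionally receives, in its inclusion tissue, an effect
#' scaled by K/(K-1) (K = exons in the gene) so that its expected splicing
#' index under the gene-mean NI definition is exactly \code{as_effect}.
#'
#' @param genome A \code{sim_genome}.
#' @param truth A \code{sim_truth}.
#' @param config The \code{sim_config}.
#' @return An object of class \code{exon_expr}: list with \code{expr}
#'   (exon x sample matrix), \code{exons} (data.frame with \code{exon_id},
#'   \code{gene_id}) and \code{samples}.
#' @export
simulate_exon_expression <- function(genome, truth, config) {
  if (nrow(truth$couplings) &&
      !all(truth$couplings$regulation %in% c("positive", "negative")))
    stop("unknown coupling regulation label")
  set.seed(stage_seed(config, "expression"))
  ex <- genome$annotation$exons
  if (nrow(ex) == 0) stop("annotation has no exons to express")
  genes <- genome$annotation$genes
  reps <- config$n_replicates_per_tissue
  samples <- data.frame(
    sample = paste(rep(config$tissues, each = reps), seq_len(reps), sep = "_"),
    tissue = rep(config$tissues, each = reps))
  ns <- nrow(samples)

  gene_base <- stats::rnorm(nrow(genes), 8, 1)
  names(gene_base) <- genes$gene_id
  exon_offset <- stats::rnorm(nrow(ex), 0, 0.3)
  expr <- matrix(gene_base[ex$gene_id] + exon_offset, nrow(ex), ns) +
    matrix(stats::rnorm(nrow(ex) * ns, 0, config$expr_noise_sd), nrow(ex), ns)
  dimnames(expr) <- list(ex$exon_id, samples$sample)

  if (nrow(truth$as_exons) > 0) {
    k <- genes$n_exons[match(truth$as_exons$gene_id, genes$gene_id)]
    eff <- config$as_effect * k / (k - 1)
    rows <- match(truth$as_exons$exon_id, ex$exon_id)
    for (j in seq_len(nrow(truth$as_exons))) {
      cols <- samples$tissue == truth$as_exons$included_in[j]
      expr[rows[j], cols] <- expr[rows[j], cols] + eff[j]
    }
  }
  structure(list(expr = expr,
                 exons = data.frame(exon_id = ex$exon_id,
                                    gene_id = ex$gene_id),
                 samples = samples),
            class = "exon_expr")
}

#' Simulate a complete study bundle
#'
#' Runs genome generation, truth planning, motif planting, methylation and
#' exon-expression simulation in order, all driven by the root seed of the
#' configuration. Repeated calls with the same configuration are
#' bit-identical.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{sim_bundle}: list with \code{genome}
#'   (sequences already carry planted motifs), \code{truth},
#'   \code{probe_set}, \code{exon_expr} and \code{config}.
#' @export
simulate_bundle <- function(config) {
  genome <- generate_genome(config)
  truth <- plan_truth(genome, config)
  genome$seqs <- plant_motifs(genome$seqs, truth, config)
  ps <- simulate_methylation(genome, truth, config)
  ee <- simulate_exon_expression(genome, truth, config)
  structure(list(genome = genome, truth = truth, probe_set = ps,
                 exon_expr = ee, config = config),
            class = "sim_bundle")
}
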