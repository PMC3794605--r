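tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_read <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated bundle to disk in standard formats
#'
#' FASTA for sequences, BED12 (+ a TSS sidecar TSV) for genes, BED4 for CpG
#' islands, bedGraph for conservation, TSV for the probe table, intensity
#' matrices and exon expression, and JSON for the truth set.
#'
#' @param bundle A \code{sim_bundle}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome$seqs, file.path(dir, "genome.fa"))
  write_genes_bed12(bundle$genome$annotation, file.path(dir, "genes.bed"))
  tsv_write(bundle$genome$annotation$tss, file.path(dir, "tss.tsv"))
  isl <- bundle$genome$islands
  utils::write.table(isl[, c("chrom", "start", "end", "name")],
                     file.path(dir, "cpg_islands.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_conservation(bundle$genome$conservation,
                     file.path(dir, "conservation.bedGraph"))
  ps <- bundle$probe_set
  tsv_write(ps$probes, file.path(dir, "probes.tsv"))
  tsv_write(data.frame(probe_id = ps$probes$probe_id, ps$input,
                       check.names = FALSE),
            file.path(dir, "input_intensity.tsv"))
  tsv_write(data.frame(probe_id = ps$probes$probe_id, ps$enriched,
                       check.names = FALSE),
            file.path(dir, "enriched_intensity.tsv"))
  tsv_write(ps$samples, file.path(dir, "samples.tsv"))
  ee <- bundle$exon_expr
  tsv_write(data.frame(exon_id = ee$exons$exon_id,
                       gene_id = ee$exons$gene_id, ee$expr,
                       check.names = FALSE),
            file.path(dir, "exon_expression.tsv"))
  jsonlite::write_json(unclass(bundle$truth),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

write_genes_bed12 <- function(ann, path) {
  g <- ann$genes
  if (nrow(g) == 0) { file.create(path); return(invisible(path)) }
  rows <- lapply(seq_len(nrow(g)), function(i) {
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    u5 <- ann$utr5[ann$utr5$gene_id == g$gene_id[i], ]
    u3 <- ann$utr3[ann$utr3$gene_id == g$gene_id[i], ]
    if (g$coding[i] && nrow(u5) == 1 && nrow(u3) == 1) {
      thick_start <- if (g$strand[i] == "+") u5$end else u3$end
      thick_end <- if (g$strand[i] == "+") u3$start else u5$start
    } else {
      thick_start <- thick_end <- g$start[i]
    }
    data.frame(chrom = g$chrom[i], start = g$start[i], end = g$end[i],
               name = g$gene_id[i], score = 0, strand = g$strand[i],
               thickStart = thick_start, thickEnd = thick_end,
               rgb = "0", blockCount = nrow(ex),
               blockSizes = paste0(paste(ex$end - ex$start, collapse = ","), ","),
               blockStarts = paste0(paste(ex$start - g$start[i], collapse = ","), ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED12 gene model (+ TSS sidecar) into a gene_annotation
#'
#' @param bed_path BED12 file.
#' @param tss_path TSV with columns gene_id, chrom, pos, strand.
#' @return A \code{\link{gene_annotation}}.
#' @export
read_genes_bed12 <- function(bed_path, tss_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  tss <- tsv_read(tss_path)
  n <- length(gr)
  genes <- exons <- utr5 <- utr3 <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- gr$name[i]
    ch <- as.character(GenomicRanges::seqnames(gr[i]))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    gstart <- GenomicRanges::start(gr[i]) - 1
    gend <- GenomicRanges::end(gr[i])
    bl <- gr$blocks[[i]]
    estarts <- gstart + IRanges::start(bl) - 1
    eends <- gstart + IRanges::end(bl)
    k <- length(bl)
    idx <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    exons[[i]] <- data.frame(
      exon_id = sprintf("%s_e%02d", gid, idx), gene_id = gid, chrom = ch,
      start = estarts, end = eends, strand = strand, exon_index = idx)
    ts <- GenomicRanges::start(gr$thick[i]) - 1
    te <- GenomicRanges::end(gr$thick[i])
    coding <- te > ts
    if (coding) {
      if (strand == "+") {
        utr5[[i]] <- data.frame(gene_id = gid, chrom = ch, start = gstart,
                                end = ts)
        utr3[[i]] <- data.frame(gene_id = gid, chrom = ch, start = te,
                                end = gend)
      } else {
        utr5[[i]] <- data.frame(gene_id = gid, chrom = ch, start = te,
                                end = gend)
        utr3[[i]] <- data.frame(gene_id = gid, chrom = ch, start = gstart,
                                end = ts)
      }
    }
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, start = gstart,
                             end = gend, strand = strand, coding = coding,
                             n_exons = k)
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons), tss,
                  do.call(rbind, utr5), do.call(rbind, utr3))
}

write_conservation <- function(cons, path) {
  grl <- lapply(names(cons), function(ch) {
    r <- cons[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1, utils::head(ends, -1) + 1)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends),
                           score = S4Vectors::runValue(r))
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph conservation track
#'
#' Positions not covered by any record are NA (unscored).
#'
#' @param path bedGraph file.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the largest end seen per chromosome.
#' @return A \code{\link{cons_track}}.
#' @export
read_conservation <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  out <- lapply(chroms, function(ch) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
         else max(GenomicRanges::end(g))
    g <- g[order(GenomicRanges::start(g))]
    starts <- GenomicRanges::start(g); ends <- GenomicRanges::end(g)
    # runs of scored intervals interleaved with NA gaps
    gap_before <- starts - c(0, utils::head(ends, -1)) - 1
    vals <- as.vector(rbind(NA_real_, g$score))
    lens <- as.vector(rbind(gap_before, ends - starts + 1))
    if (ends[length(ends)] < L) {
      vals <- c(vals, NA_real_)
      lens <- c(lens, L - ends[length(ends)])
    }
    keep <- lens > 0
    S4Vectors::Rle(vals[keep], lens[keep])
  })
  names(out) <- chroms
  cons_track(out)
}

#' Read a bundle written by \code{write_bundle}
#'
#' @param dir Directory containing the bundle files.
#' @return A list shaped like a \code{sim_bundle} (without the config).
#' @export
read_bundle <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  ann <- read_genes_bed12(file.path(dir, "genes.bed"),
                          file.path(dir, "tss.tsv"))
  isl <- utils::read.table(file.path(dir, "cpg_islands.bed"), sep = "\t",
                           col.names = c("chrom", "start", "end", "name"),
                           stringsAsFactors = FALSE)
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  cons <- read_conservation(file.path(dir, "conservation.bedGraph"), lens)
  probes <- tsv_read(file.path(dir, "probes.tsv"))
  inp <- tsv_read(file.path(dir, "input_intensity.tsv"))
  enr <- tsv_read(file.path(dir, "enriched_intensity.tsv"))
  samples <- tsv_read(file.path(dir, "samples.tsv"))
  ps <- probe_set(probes,
                  as.matrix(inp[, -1, drop = FALSE]),
                  as.matrix(enr[, -1, drop = FALSE]), samples)
  rownames(ps$input) <- rownames(ps$enriched) <- probes$probe_id
  ex <- tsv_read(file.path(dir, "exon_expression.tsv"))
  expr <- as.matrix(ex[, -(1:2), drop = FALSE])
  rownames(expr) <- ex$exon_id
  ee <- structure(list(expr = expr,
                       exons = ex[, 1:2],
                       samples = samples), class = "exon_expr")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth <- structure(truth, class = "sim_truth")
  list(genome = structure(list(seqs = seqs, annotation = ann, islands = isl,
                               conservation = cons), class = "sim_genome"),
       truth = truth, probe_set = ps, exon_expr = ee)
}

#' Write called T-DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (-log10 min probe p, capped at
#' 999), strand "."; extra columns mean_delta, n_probes, direction.
#'
#' @param tdmrs T-DMR data.frame from \code{\link{call_tdmrs}}.
#' @param path Output path.
#' @export
write_tdmrs_bed <- function(tdmrs, path) {
  df <- data.frame(chrom = tdmrs$chrom, start = tdmrs$start,
                   end = tdmrs$end, name = tdmrs$tdmr_id,
                   score = round(pmin(999, -log10(pmax(tdmrs$min_p, 1e-300)))),
                   strand = ".", mean_delta = tdmrs$mean_delta,
                   n_probes = tdmrs$n_probes, direction = tdmrs$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ T-DMR file written by \code{write_tdmrs_bed}
#'
#' @param path Input path.
#' @return T-DMR data.frame.
#' @export
read_tdmrs_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "mean_delta",
                                        "n_probes", "direction"))
  data.frame(tdmr_id = df$name, chrom = df$chrom, start = df$start,
             end = df$end, n_probes = df$n_probes, direction = df$direction,
             mean_delta = df$mean_delta, min_p = 10^(-df$score))
}
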