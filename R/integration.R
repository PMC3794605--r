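#' Overlap enrichment between T-DMR genes and AS genes
#'
#' Upper-tail hypergeometric test of the overlap between the set of genes
#' carrying a T-DMR and the set of AS genes, within the expressed-gene
#' universe (genes represented on the expression platform).
#'
#' @param tdmr_genes,as_genes Character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe Character vector of eligible gene ids.
#' @return A list with \code{overlap}, \code{n_tdmr_genes},
#'   \code{n_as_genes}, \code{pct_tdmr_genes_as} (share of T-DMR genes that
#'   are AS), \code{pct_as_genes_tdmr} and \code{p_value}.
#' @export
gene_overlap_enrichment <- function(tdmr_genes, as_genes, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  tdmr_genes <- unique(tdmr_genes); as_genes <- unique(as_genes)
  if (!all(tdmr_genes %in% universe) || !all(as_genes %in% universe))
    stop("gene sets must be subsets of the universe")
  ov <- length(intersect(tdmr_genes, as_genes))
  ht <- hypergeom_enrichment(ov, length(as_genes), length(universe),
                             length(tdmr_genes))
  list(overlap = ov,
       n_tdmr_genes = length(tdmr_genes),
       n_as_genes = length(as_genes),
       pct_tdmr_genes_as = 100 * ov / max(1, length(tdmr_genes)),
       pct_as_genes_tdmr = 100 * ov / max(1, length(as_genes)),
       p_value = ht$p_value)
}

# Association window of an exon, 0-based half-open genomic coordinates.
# "flanking_introns": the exon plus its adjacent introns; "1kb": the exon
# plus 1 kb (or `flank` bp) on each side.
exon_window <- function(exon, ann, window, flank = 1000) {
  if (window == "1kb")
    return(c(max(0, exon$start - flank), exon$end + flank))
  gene_ex <- ann$exons[ann$exons$gene_id == exon$gene_id, ]
  gene_ex <- gene_ex[order(gene_ex$start), ]
  i <- which(gene_ex$exon_id == exon$exon_id)
  lo <- if (i > 1) gene_ex$end[i - 1] else exon$start
  hi <- if (i < nrow(gene_ex)) gene_ex$start[i + 1] else exon$end
  c(lo, hi)
}

#' Link T-DMRs to exons by positional overlap
#'
#' Creates a link whenever a T-DMR intersects an exon's association window:
#' either the exon with its two directly flanking introns
#' (\code{window = "flanking_introns"}) or the exon plus \code{flank} bp on
#' each side (\code{window = "1kb"}). The link position is
#' \code{within_exon} when the T-DMR touches the exon itself (including its
#' junctions), otherwise \code{upstream} or \code{downstream} in gene-sense
#' orientation.
#'
#' @param exon_ids Exon ids to consider (e.g. all testable or all AS exons).
#' @param tdmrs T-DMR data.frame (tdmr_id, chrom, start, end, ...).
#' @param ann A \code{gene_annotation}.
#' @param window "flanking_introns" or "1kb".
#' @param flank Flank width for the 1kb mode.
#' @return data.frame of links: tdmr_id, exon_id, gene_id, position.
#' @export
exon_level_association <- function(exon_ids, tdmrs, ann,
                                   window = c("1kb", "flanking_introns"),
                                   flank = 1000) {
  window <- match.arg(window)
  empty <- data.frame(tdmr_id = character(0), exon_id = character(0),
                      gene_id = character(0), position = character(0))
  missing <- setdiff(exon_ids, ann$exons$exon_id)
  if (length(missing) > 0)
    message("skipping ", length(missing), " exon(s) absent from annotation")
  ex <- ann$exons[ann$exons$exon_id %in% exon_ids, ]
  if (nrow(ex) == 0 || nrow(tdmrs) == 0) return(empty)

  win <- t(vapply(seq_len(nrow(ex)), function(i)
    exon_window(ex[i, ], ann, window, flank), numeric(2)))
  wg <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(win[, 1] + 1, win[, 2]))
  tg <- df_to_granges(tdmrs)
  hits <- GenomicRanges::findOverlaps(wg, tg)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  in_exon <- tdmrs$end[si] > ex$start[qi] & tdmrs$start[si] < ex$end[qi]
  genomic_left <- tdmrs$end[si] <= ex$start[qi]
  position <- ifelse(in_exon, "within_exon",
                     ifelse(genomic_left == (ex$strand[qi] == "+"),
                            "upstream", "downstream"))
  out <- data.frame(tdmr_id = tdmrs$tdmr_id[si], exon_id = ex$exon_id[qi],
                    gene_id = ex$gene_id[qi], position = position)
  out <- out[order(out$exon_id, out$tdmr_id), ]
  rownames(out) <- NULL
  out
}

#' T-DMR coverage of exon neighbourhoods, AS versus non-AS
#'
#' For each exon group, merges the exon-plus-flanking-intron windows,
#' measures the pooled fraction of their bases covered by (merged) T-DMRs,
#' and compares the two groups with a two-proportion z-test.
#'
#' @param as_exon_ids,non_as_exon_ids Exon id vectors for the two groups.
#' @param tdmrs T-DMR data.frame.
#' @param ann A \code{gene_annotation}.
#' @return A list with per-group \code{fraction}, \code{covered},
#'   \code{total} and the comparison \code{p_value}.
#' @export
coverage_fraction <- function(as_exon_ids, non_as_exon_ids, tdmrs, ann) {
  tg <- GenomicRanges::reduce(df_to_granges(tdmrs))
  group_cov <- function(ids) {
    ex <- ann$exons[ann$exons$exon_id %in% ids, ]
    if (nrow(ex) == 0) return(c(covered = 0, total = 0))
    win <- t(vapply(seq_len(nrow(ex)), function(i)
      exon_window(ex[i, ], ann, "flanking_introns"), numeric(2)))
    wg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(win[, 1] + 1, win[, 2])))
    total <- sum(GenomicRanges::width(wg))
    covered <- sum(GenomicRanges::width(GenomicRanges::intersect(wg, tg)))
    c(covered = covered, total = total)
  }
  a <- group_cov(as_exon_ids); b <- group_cov(non_as_exon_ids)
  p <- if (a[["total"]] > 0 && b[["total"]] > 0)
    two_proportion_test(a[["covered"]], a[["total"]],
                        b[["covered"]], b[["total"]])$p_value else NA_real_
  list(as_fraction = if (a[["total"]] > 0) a[["covered"]] / a[["total"]] else 0,
       non_as_fraction = if (b[["total"]] > 0) b[["covered"]] / b[["total"]] else 0,
       as_covered = a[["covered"]], as_total = a[["total"]],
       non_as_covered = b[["covered"]], non_as_total = b[["total"]],
       p_value = p)
}

#' Classify methylation-to-splicing regulation for T-DMR/exon links
#'
#' Regulation is \code{positive} when the tissue with relative
#' hypermethylation at the T-DMR is the tissue with greater inclusion of the
#' linked AS exon, and \code{negative} when hypermethylation accompanies
#' greater exclusion (inclusion in the other tissue). The label is invariant
#' under swapping the tissue names. Links to exons that are not AS yield no
#' assignment.
#'
#' @param links data.frame from \code{\link{exon_level_association}}.
#' @param tdmrs T-DMR data.frame with \code{direction}
#'   (\code{"<tissue>-hyper"} or a bare tissue name).
#' @param as_calls data.frame from \code{\link{call_as_exons}}.
#' @return data.frame: tdmr_id, exon_id, position, hyper_tissue,
#'   inclusion_tissue, regulation.
#' @export
classify_regulation <- function(links, tdmrs, as_calls) {
  as_calls <- as_calls[as_calls$is_as, ]
  keep <- links$exon_id %in% as_calls$exon_id
  links <- links[keep, , drop = FALSE]
  if (nrow(links) == 0)
    return(data.frame(tdmr_id = character(0), exon_id = character(0),
                      position = character(0), hyper_tissue = character(0),
                      inclusion_tissue = character(0),
                      regulation = character(0)))
  hyper <- sub("-hyper$", "", tdmrs$direction[match(links$tdmr_id,
                                                    tdmrs$tdmr_id)])
  incl <- as_calls$included_in[match(links$exon_id, as_calls$exon_id)]
  data.frame(tdmr_id = links$tdmr_id, exon_id = links$exon_id,
             position = links$position, hyper_tissue = hyper,
             inclusion_tissue = incl,
             regulation = ifelse(hyper == incl, "positive", "negative"))
}
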