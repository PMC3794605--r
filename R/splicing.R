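#' Normalized intensity (NI) of exons
#'
#' The inclusion level of an exon is its log2 intensity relative to the
#' overall expression of its host gene; the gene level is summarized as the
#' mean of its exons' log2 intensities per sample, so a gene's NIs sum to
#' zero in every sample. Single-exon genes have NI identically zero and are
#' flagged for exclusion from AS calling.
#'
#' @param expr Exon-by-sample log2 intensity matrix.
#' @param gene_ids Character vector mapping each row to its gene.
#' @return A list with \code{ni} (exon-by-sample NI matrix),
#'   \code{gene_ids} and \code{single_exon} (logical per row).
#' @export
compute_ni <- function(expr, gene_ids) {
  stopifnot(nrow(expr) == length(gene_ids))
  gene_mean <- rowsum(expr, gene_ids) /
    as.vector(table(gene_ids)[sort(unique(gene_ids))])
  ni <- expr - gene_mean[gene_ids, , drop = FALSE]
  counts <- table(gene_ids)
  list(ni = ni, gene_ids = gene_ids,
       single_exon = as.vector(counts[gene_ids]) == 1)
}

#' Call alternatively spliced exons from NI values
#'
#' The splicing index (SI) of an exon is the difference of its mean NI
#' between the two tissues; an exon is AS when the between-tissue Welch test
#' on its NIs is significant (\code{p < p_cutoff}) and \code{|SI|} strictly
#' exceeds \code{si_cutoff}. Exons of single-exon genes are excluded.
#'
#' @param ni_obj Result of \code{\link{compute_ni}}.
#' @param samples data.frame with \code{tissue} per column of the NI matrix.
#' @param p_cutoff Significance threshold (default 0.01).
#' @param si_cutoff Minimum |SI| in log2 units (default \code{log2(1.25)}).
#' @return data.frame per testable exon: exon_id, gene_id, si, p_value,
#'   is_as, included_in (tissue with the higher mean NI).
#' @export
call_as_exons <- function(ni_obj, samples, p_cutoff = 0.01,
                          si_cutoff = log2(1.25)) {
  tissues <- unique(samples$tissue)
  if (length(tissues) != 2) stop("exactly two tissues are required")
  keep <- !ni_obj$single_exon
  ni <- ni_obj$ni[keep, , drop = FALSE]
  st <- row_welch_t(ni, samples$tissue == tissues[1])
  si <- st$delta
  is_as <- st$p_value < p_cutoff & abs(si) > si_cutoff
  data.frame(exon_id = rownames(ni),
             gene_id = ni_obj$gene_ids[keep],
             si = si, p_value = st$p_value, is_as = is_as,
             included_in = ifelse(si > 0, tissues[1],
                                  ifelse(si < 0, tissues[2], NA)),
             row.names = NULL)
}

#' Sweep AS-calling cutoffs and track T-DMR overlap enrichment
#'
#' Re-runs AS calling over a grid of (p, SI) cutoff pairs; for each pair it
#' reports the number of AS exons and genes and, when a T-DMR gene set is
#' supplied, the hypergeometric enrichment of the overlap between AS genes
#' and T-DMR genes in the expressed universe.
#'
#' @param ni_obj Result of \code{compute_ni}.
#' @param samples Sample data.frame.
#' @param grid data.frame with columns \code{p_cutoff} and \code{si_cutoff}.
#' @param tdmr_genes Optional character vector of T-DMR-associated genes.
#' @param universe Optional expressed-gene universe (defaults to all genes
#'   in \code{ni_obj}).
#' @return data.frame, one row per cutoff pair.
#' @export
as_robustness_sweep <- function(ni_obj, samples, grid, tdmr_genes = NULL,
                                universe = NULL) {
  if (nrow(grid) == 0) stop("cutoff grid is empty")
  if (is.null(universe)) universe <- unique(ni_obj$gene_ids)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    calls <- call_as_exons(ni_obj, samples, grid$p_cutoff[i],
                           grid$si_cutoff[i])
    as_genes <- unique(calls$gene_id[calls$is_as])
    row <- data.frame(p_cutoff = grid$p_cutoff[i],
                      si_cutoff = grid$si_cutoff[i],
                      n_as_exons = sum(calls$is_as),
                      n_as_genes = length(as_genes))
    if (!is.null(tdmr_genes)) {
      enr <- gene_overlap_enrichment(intersect(tdmr_genes, universe),
                                     as_genes, universe)
      row$overlap <- enr$overlap
      row$enrichment_p <- enr$p_value
    }
    row
  })
  do.call(rbind, out)
}

#' Genes with differential use of alternative start sites
#'
#' A gene is flagged when it has at least two annotated transcription start
#' sites and at least one AS exon lying entirely within its alternative
#' start region (the genomic interval between its most distal start sites).
#'
#' @param ann A \code{gene_annotation}.
#' @param as_calls Result of \code{\link{call_as_exons}}.
#' @return Character vector of flagged gene ids.
#' @export
alternative_start_genes <- function(ann, as_calls) {
  multi <- names(which(table(ann$tss$gene_id) >= 2))
  if (length(multi) == 0) return(character(0))
  as_exons <- as_calls[as_calls$is_as, ]
  hit <- vapply(multi, function(g) {
    pos <- ann$tss$pos[ann$tss$gene_id == g]
    lo <- min(pos); hi <- max(pos)
    ex <- ann$exons[ann$exons$gene_id == g &
                      ann$exons$exon_id %in% as_exons$exon_id, ]
    any(ex$start >= lo & ex$end <= hi)
  }, logical(1))
  multi[hit]
}
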