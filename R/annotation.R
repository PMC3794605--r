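#' Gene annotation container
#'
#' Bundles the gene, exon, TSS and UTR tables used throughout the pipeline.
#' All coordinates are 0-based, half-open. The TSS table may hold several
#' start sites per gene; exon indices run 5' to 3' in gene sense.
#'
#' @param genes data.frame: gene_id, chrom, start, end, strand, coding,
#'   n_exons.
#' @param exons data.frame: exon_id, gene_id, chrom, start, end, strand,
#'   exon_index.
#' @param tss data.frame: gene_id, chrom, pos, strand.
#' @param utr5,utr3 Optional data.frames: gene_id, chrom, start, end.
#' @return An object of class \code{gene_annotation}.
#' @export
gene_annotation <- function(genes, exons, tss, utr5 = NULL, utr3 = NULL) {
  empty_utr <- data.frame(gene_id = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0))
  rownames(genes) <- rownames(exons) <- rownames(tss) <- NULL
  structure(list(genes = genes, exons = exons, tss = tss,
                 utr5 = if (is.null(utr5)) empty_utr else utr5,
                 utr3 = if (is.null(utr3)) empty_utr else utr3),
            class = "gene_annotation")
}

empty_annotation <- function() {
  gene_annotation(
    genes = data.frame(gene_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       strand = character(0), coding = logical(0),
                       n_exons = integer(0)),
    exons = data.frame(exon_id = character(0), gene_id = character(0),
                       chrom = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0),
                       exon_index = integer(0)),
    tss = data.frame(gene_id = character(0), chrom = character(0),
                     pos = numeric(0), strand = character(0)))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$tss), "start sites\n")
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed).
df_to_granges <- function(df, strand = NULL) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end),
    strand = if (is.null(strand)) "*" else strand)
}

# Intron intervals (gene span minus exons), 0-based half-open.
introns_of <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  out <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Strand-aware upstream windows (one per TSS), 0-based half-open.
upstream_windows <- function(ann, upstream = 4000) {
  t <- ann$tss
  if (nrow(t) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  data.frame(gene_id = t$gene_id, chrom = t$chrom,
             start = ifelse(t$strand == "+", pmax(0, t$pos - upstream), t$pos),
             end = ifelse(t$strand == "+", t$pos, t$pos + upstream))
}

#' Assign intervals to a genomic category
#'
#' Each query interval receives exactly one category among \code{5utr},
#' \code{3utr}, \code{exon}, \code{intron}, \code{upstream} and
#' \code{intergenic}, resolved by that precedence when the interval touches
#' several features (possibly of different genes). Upstream windows extend a
#' configurable distance 5' of each annotated TSS, strand-aware.
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and optionally an id column.
#' @param ann A \code{\link{gene_annotation}}.
#' @param upstream Width of the upstream window in bp (default 4000).
#' @return data.frame with \code{category}, \code{gene_id} (NA when
#'   intergenic) and \code{gene_class} ("coding"/"ncRNA"/NA), one row per
#'   input interval, in input order.
#' @export
assign_region <- function(intervals, ann, upstream = 4000) {
  known <- unique(c(ann$genes$chrom, ann$exons$chrom))
  if (length(known) > 0 && !all(intervals$chrom %in% known))
    stop("interval on a chromosome absent from the annotation: ",
         paste(unique(setdiff(intervals$chrom, known)), collapse = ", "))
  n <- nrow(intervals)
  category <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  q <- df_to_granges(intervals)

  feats <- list(
    `5utr` = ann$utr5, `3utr` = ann$utr3, exon = ann$exons,
    intron = introns_of(ann), upstream = upstream_windows(ann, upstream))
  unassigned <- rep(TRUE, n)
  for (cat_name in names(feats)) {
    f <- feats[[cat_name]]
    if (nrow(f) == 0) next
    hits <- GenomicRanges::findOverlaps(q, df_to_granges(f))
    qh <- S4Vectors::queryHits(hits)
    keep <- !duplicated(qh) & unassigned[qh]
    qh <- qh[keep]
    category[qh] <- cat_name
    gene[qh] <- f$gene_id[S4Vectors::subjectHits(hits)[keep]]
    unassigned[qh] <- FALSE
  }
  cls <- rep(NA_character_, n)
  has_gene <- !is.na(gene)
  cls[has_gene] <- ifelse(
    ann$genes$coding[match(gene[has_gene], ann$genes$gene_id)],
    "coding", "ncRNA")
  data.frame(category = category, gene_id = gene, gene_class = cls)
}

#' Category enrichment of a probe subset against the array design
#'
#' For each genomic category, tests whether probes of interest (e.g. probes
#' inside T-DMRs) are overrepresented relative to the array's overall probe
#' distribution, using the upper-tail hypergeometric test.
#'
#' @param target_ids Probe ids of interest (subset of \code{probes$probe_id}).
#' @param probes Probe data.frame (genomic probes; controls are ignored).
#' @param ann A \code{gene_annotation}.
#' @param upstream Upstream window width in bp.
#' @return data.frame per category: \code{category}, \code{observed_n},
#'   \code{observed_pct}, \code{expected_pct}, \code{p_value}.
#' @export
region_enrichment <- function(target_ids, probes, ann, upstream = 4000) {
  probes <- probes[!probes$is_control, ]
  if (!all(target_ids %in% probes$probe_id))
    stop("target probes must be a subset of the genomic probe table")
  asn <- assign_region(probes, ann, upstream)
  cats <- c("upstream", "5utr", "exon", "intron", "3utr", "intergenic")
  in_target <- probes$probe_id %in% target_ids
  universe <- nrow(probes); draws <- sum(in_target)
  rows <- lapply(cats, function(cat) {
    size <- sum(asn$category == cat)
    if (size == 0) return(NULL)
    obs <- sum(in_target & asn$category == cat)
    ht <- hypergeom_enrichment(obs, size, universe, draws)
    data.frame(category = cat, observed_n = obs,
               observed_pct = 100 * obs / draws,
               expected_pct = 100 * size / universe,
               p_value = ht$p_value)
  })
  do.call(rbind, rows)
}

#' CpG-island context of intervals
#'
#' Classifies each interval by its distance to the nearest CpG island:
#' overlapping an island (\code{island}, distance 0), within 3 kb
#' (\code{shore}), 3-4 kb (\code{shelf}) or farther (\code{open_sea}).
#' Chromosomes without any island yield \code{open_sea} with infinite
#' distance.
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param islands data.frame of island intervals (chrom, start, end).
#' @param shore,shelf Distance thresholds in bp.
#' @return data.frame with \code{class} and \code{distance} per interval.
#' @export
cpg_context <- function(intervals, islands, shore = 3000, shelf = 4000) {
  n <- nrow(intervals)
  dist <- rep(Inf, n)
  if (nrow(islands) > 0) {
    q <- df_to_granges(intervals)
    s <- df_to_granges(islands)
    hits <- suppressWarnings(GenomicRanges::distanceToNearest(q, s))
    dist[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(hits)$distance
  }
  cls <- ifelse(dist == 0, "island",
                ifelse(dist <= shore, "shore",
                       ifelse(dist <= shelf, "shelf", "open_sea")))
  data.frame(class = cls, distance = dist)
}

#' Gene-set (term) enrichment with Bonferroni correction
#'
#' Hypergeometric upper-tail enrichment of a gene list in each annotation
#' term, Bonferroni-adjusted across terms. Terms with no gene in the
#' universe are skipped.
#'
#' @param genes_of_interest Character vector of gene ids (subset of
#'   \code{universe}).
#' @param term_map data.frame with columns \code{gene_id} and \code{term}.
#' @param universe Character vector of all eligible gene ids.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return data.frame per term: term, overlap, term_size, p_value, q_value,
#'   significant.
#' @export
geneset_enrichment <- function(genes_of_interest, term_map, universe,
                               alpha = 0.05) {
  if (!all(genes_of_interest %in% universe))
    stop("genes of interest must be a subset of the universe")
  tm <- term_map[term_map$gene_id %in% universe, ]
  if (nrow(tm) == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  terms <- split(tm$gene_id, tm$term)
  rows <- lapply(names(terms), function(tn) {
    size <- length(unique(terms[[tn]]))
    obs <- length(intersect(genes_of_interest, terms[[tn]]))
    ht <- hypergeom_enrichment(obs, size, length(universe),
                               length(genes_of_interest))
    data.frame(term = tn, overlap = obs, term_size = size,
               p_value = ht$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bonferroni(out$p_value)
  out$significant <- out$q_value < alpha
  out[order(out$p_value), ]
}
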