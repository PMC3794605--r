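#' Pipeline parameter set
#'
#' All thresholds used across the pipeline, with the study defaults: probe
#' p < 0.005, >= 3 probes per T-DMR, AS exon p < 0.01 and |SI| > log2(1.25),
#' 1 kb association flank, 4 kb upstream windows, 3/4 kb CpG shore/shelf
#' bounds, motif FDR 1\%, 10000 background exons, 100 distance shuffles.
#'
#' @param p_cutoff Probe-level p cutoff for T-DMR calling.
#' @param min_probes Minimum probes per T-DMR.
#' @param max_gap Maximum gap between neighbouring probes, bp.
#' @param tdmr_method "moderated" or "welch" probe test.
#' @param as_p_cutoff,si_cutoff AS-exon thresholds.
#' @param flank Association/motif flank width, bp.
#' @param upstream Upstream window for region assignment, bp.
#' @param shore,shelf CpG context distances, bp.
#' @param motif_fdr Motif significance threshold on BH q.
#' @param n_background Background exon sample size.
#' @param n_shuffles Motif-distance shuffles.
#' @param cons_cutoffs Conservation cutoff grid.
#' @param seed Root seed for the stochastic stages (background sampling,
#'   shuffles).
#' @return A list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(p_cutoff = 0.005, min_probes = 3, max_gap = 300,
                            tdmr_method = "moderated",
                            as_p_cutoff = 0.01, si_cutoff = log2(1.25),
                            flank = 1000, upstream = 4000,
                            shore = 3000, shelf = 4000,
                            motif_fdr = 0.01, n_background = 10000,
                            n_shuffles = 100,
                            cons_cutoffs = seq(0.1, 0.9, by = 0.2),
                            seed = 1) {
  stopifnot(p_cutoff > 0, as_p_cutoff > 0, si_cutoff > 0, flank > 0,
            upstream > 0, motif_fdr > 0)
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full methylation/splicing analysis on a bundle
#'
#' Orchestrates: intensity normalization, background filtering, relative
#' methylation, T-DMR calling; genomic-region and CpG-context annotation
#' with enrichment; conservation profiles; NI/SI computation and AS-exon
#' calling; T-DMR/AS integration (gene overlap, exon-level links, coverage,
#' regulation classification); and position/regulation-stratified 6mer
#' motif discovery with positional-role comparison, CpG content and the
#' motif-pair distance test. With the same bundle and parameters the result
#' is fully reproducible.
#'
#' @param bundle A \code{sim_bundle} (or the result of
#'   \code{\link{read_bundle}}).
#' @param params A \code{\link{pipeline_params}}.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there along with \code{summary.json} and \code{report.md}.
#' @return A list with all stage results and a \code{summary} list of the
#'   headline statistics.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(),
                         out_dir = NULL) {
  ann <- bundle$genome$annotation
  seqs <- bundle$genome$seqs

  ## --- methylation: normalize, filter, call T-DMRs -----------------------
  ps <- normalize_probes(bundle$probe_set)
  ps <- filter_background(ps)
  m <- relative_methylation(ps)
  calls <- call_tdmrs(m, ps$probes, ps$samples,
                      p_cutoff = params$p_cutoff,
                      min_probes = params$min_probes,
                      max_gap = params$max_gap,
                      method = params$tdmr_method)
  tdmrs <- calls$tdmrs

  ## --- genomic annotation ------------------------------------------------
  tdmr_probe_ids <- unlist(strsplit(tdmrs$probe_ids, ","))
  region_enr <- if (nrow(ann$genes) > 0 && length(tdmr_probe_ids) > 0)
    region_enrichment(tdmr_probe_ids, ps$probes, ann, params$upstream)
  else NULL
  tdmr_regions <- if (nrow(ann$genes) > 0 && nrow(tdmrs) > 0)
    cbind(tdmrs["tdmr_id"], assign_region(tdmrs, ann, params$upstream))
  else NULL
  tdmr_cpg <- if (nrow(tdmrs) > 0)
    cbind(tdmrs["tdmr_id"], cpg_context(tdmrs, bundle$genome$islands,
                                        params$shore, params$shelf))
  else NULL

  ## --- conservation ------------------------------------------------------
  cons <- bundle$genome$conservation
  cons_prof <- NULL
  if (!is.null(cons) && nrow(tdmrs) > 0) {
    sets <- list(tdmrs = tdmrs[, c("chrom", "start", "end")],
                 all_probes = ps$probes[, c("chrom", "start", "end")])
    cons_prof <- conservation_profile(sets, cons, params$cons_cutoffs)
  }

  ## --- splicing ----------------------------------------------------------
  ee <- bundle$exon_expr
  ni <- compute_ni(ee$expr, ee$exons$gene_id)
  as_calls <- call_as_exons(ni, ee$samples, params$as_p_cutoff,
                            params$si_cutoff)
  alt_start <- alternative_start_genes(ann, as_calls)

  ## --- integration -------------------------------------------------------
  expressed <- unique(ee$exons$gene_id)
  tdmr_genes <- if (!is.null(tdmr_regions))
    unique(stats::na.omit(tdmr_regions$gene_id)) else character(0)
  as_genes <- unique(as_calls$gene_id[as_calls$is_as])
  overlap <- if (length(expressed) > 0)
    gene_overlap_enrichment(intersect(tdmr_genes, expressed),
                            intersect(as_genes, expressed), expressed)
  else NULL
  links <- exon_level_association(as_calls$exon_id, tdmrs, ann,
                                  window = "1kb", flank = params$flank)
  coverage <- coverage_fraction(as_calls$exon_id[as_calls$is_as],
                                as_calls$exon_id[!as_calls$is_as],
                                tdmrs, ann)
  regulation <- classify_regulation(links, tdmrs, as_calls)

  ## --- motifs -------------------------------------------------------------
  motifs <- run_motif_stage(regulation, tdmrs, ann, seqs, params)

  summary <- build_summary(ps, tdmrs, as_calls, alt_start, overlap,
                           coverage, regulation, motifs)
  res <- list(probe_set = ps, methylation = m, calls = calls,
              tdmrs = tdmrs, region_enrichment = region_enr,
              tdmr_regions = tdmr_regions, tdmr_cpg = tdmr_cpg,
              conservation = cons_prof, ni = ni, as_calls = as_calls,
              alt_start_genes = alt_start, overlap = overlap,
              links = links, coverage = coverage, regulation = regulation,
              motifs = motifs, params = params, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

run_motif_stage <- function(regulation, tdmrs, ann, seqs, params) {
  if (nrow(regulation) == 0 || nrow(ann$exons) == 0) return(NULL)
  groups <- motif_groups(regulation, tdmrs, ann, seqs, params$flank)
  bg <- list(
    upstream = build_background(ann, seqs, params$n_background, "upstream",
                                params$flank, seed = params$seed),
    downstream = build_background(ann, seqs, params$n_background,
                                  "downstream", params$flank,
                                  seed = params$seed + 1))
  stats_of <- function(key, side) {
    g <- groups[[key]]
    if (length(g$seqs) == 0 || sum(Biostrings::width(g$seqs)) < 6 ||
        sum(Biostrings::width(g$seqs) - 5) == 0) return(NULL)
    count_and_test(g$seqs, bg[[side]], fdr = params$motif_fdr)
  }
  st <- list(
    upstream = list(positive = stats_of("upstream_positive", "upstream"),
                    negative = stats_of("upstream_negative", "upstream")),
    downstream = list(positive = stats_of("downstream_positive", "downstream"),
                      negative = stats_of("downstream_negative", "downstream")))
  null_stats <- data.frame(kmer = all_6mers(), M = 0L, N = 0L, f = 0,
                           p_value = 1, q_value = 1, significant = FALSE,
                           zero_background = FALSE)
  filled <- lapply(st, function(side)
    lapply(side, function(x) if (is.null(x)) null_stats else x))
  pos_cmp <- positional_comparison(filled$upstream, filled$downstream)
  sig_kmers <- unique(unlist(lapply(filled, function(side)
    lapply(side, function(x) x$kmer[x$significant]))))
  all_group_seqs <- do.call(c, unname(lapply(groups, `[[`, "seqs")))
  cpg <- cpg_content(sig_kmers, all_group_seqs)
  clusters <- if (length(sig_kmers) > 0) cluster_consensus(sig_kmers) else NULL

  dist_tests <- lapply(c("upstream", "downstream"), function(side) {
    keys <- paste0(side, c("_positive", "_negative"))
    merged <- list(
      seqs = do.call(c, unname(lapply(groups[keys], `[[`, "seqs"))),
      meta = do.call(rbind, lapply(groups[keys], `[[`, "meta")))
    inst <- find_motif_instances(merged, sig_kmers)
    pair_distance_test(inst, n_shuffles = params$n_shuffles,
                       seed = params$seed + 7)
  })
  names(dist_tests) <- c("upstream", "downstream")

  list(groups = groups, background = bg, stats = st,
       positional = pos_cmp, sig_kmers = sig_kmers, cpg = cpg,
       clusters = clusters, distance = dist_tests)
}

build_summary <- function(ps, tdmrs, as_calls, alt_start, overlap,
                          coverage, regulation, motifs) {
  s <- list(
    n_probes_retained = nrow(ps$probes),
    n_tdmrs = nrow(tdmrs),
    n_tdmr_probes = if (nrow(tdmrs)) sum(tdmrs$n_probes) else 0L,
    n_as_exons = sum(as_calls$is_as),
    n_as_genes = length(unique(as_calls$gene_id[as_calls$is_as])),
    n_alt_start_genes = length(alt_start),
    n_links = nrow(regulation),
    n_positive = sum(regulation$regulation == "positive"),
    n_negative = sum(regulation$regulation == "negative"))
  if (!is.null(overlap)) {
    s$overlap_genes <- overlap$overlap
    s$pct_tdmr_genes_as <- overlap$pct_tdmr_genes_as
    s$overlap_p <- overlap$p_value
  }
  if (!is.null(coverage)) {
    s$coverage_as <- coverage$as_fraction
    s$coverage_non_as <- coverage$non_as_fraction
  }
  if (!is.null(motifs)) {
    s$n_sig_motifs <- length(motifs$sig_kmers)
    s$n_up_motifs <- motifs$positional$counts$n_up
    s$n_down_motifs <- motifs$positional$counts$n_down
    s$n_union_motifs <- motifs$positional$counts$n_union
    s$pct_one_position <- motifs$positional$counts$pct_one_position
    s$pct_sig_kmers_cpg <- motifs$cpg$pct_sig_kmers_cpg
    s$pct_all_kmers_cpg <- motifs$cpg$pct_all_kmers_cpg
  }
  s
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tdmrs_bed(res$tdmrs, p("tdmrs.bed"))
  tsv_write(res$calls$probe_stats, p("probe_stats.tsv"))
  if (!is.null(res$region_enrichment))
    tsv_write(res$region_enrichment, p("region_enrichment.tsv"))
  if (!is.null(res$tdmr_cpg)) tsv_write(res$tdmr_cpg, p("tdmr_cpg.tsv"))
  if (!is.null(res$conservation)) {
    tsv_write(res$conservation$profile, p("conservation_profile.tsv"))
    if (!is.null(res$conservation$comparisons))
      tsv_write(res$conservation$comparisons, p("conservation_tests.tsv"))
  }
  tsv_write(res$as_calls, p("as_calls.tsv"))
  writeLines(res$alt_start_genes, p("alt_start_genes.txt"))
  tsv_write(res$links, p("links.tsv"))
  tsv_write(res$regulation, p("regulation.tsv"))
  if (!is.null(res$motifs)) {
    for (side in names(res$motifs$stats))
      for (reg in names(res$motifs$stats[[side]])) {
        st <- res$motifs$stats[[side]][[reg]]
        if (!is.null(st))
          tsv_write(st, p(sprintf("motif_stats_%s_%s.tsv", side, reg)))
      }
    tsv_write(res$motifs$positional$table, p("positional_comparison.tsv"))
    if (!is.null(res$motifs$clusters))
      tsv_write(res$motifs$clusters, p("motif_clusters.tsv"))
  }
  jsonlite::write_json(res$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report(res, p("report.md"))
  invisible(out_dir)
}

write_report <- function(res, path) {
  s <- res$summary
  lines <- c(
    "# Methylation/splicing pipeline report", "",
    sprintf("- probes retained: %d", s$n_probes_retained),
    sprintf("- T-DMRs called: %d (covering %d probes)", s$n_tdmrs,
            s$n_tdmr_probes),
    sprintf("- AS exons: %d in %d genes", s$n_as_exons, s$n_as_genes),
    sprintf("- alternative-start genes with AS support: %d",
            s$n_alt_start_genes),
    sprintf("- T-DMR/AS-exon links: %d (positive %d, negative %d)",
            s$n_links, s$n_positive, s$n_negative))
  if (!is.null(s$overlap_genes))
    lines <- c(lines, sprintf(
      "- T-DMR genes that are AS: %d (%.1f%%), enrichment p = %.3g",
      s$overlap_genes, s$pct_tdmr_genes_as, s$overlap_p))
  if (!is.null(s$n_sig_motifs))
    lines <- c(lines, sprintf(
      "- significant 6mers: %d (upstream %d, downstream %d, union %d; %.1f%% one-position)",
      s$n_sig_motifs, s$n_up_motifs, s$n_down_motifs, s$n_union_motifs,
      s$pct_one_position),
      sprintf("- CpG-containing: %.1f%% of significant 6mers vs %.1f%% of all 6mers",
              s$pct_sig_kmers_cpg, s$pct_all_kmers_cpg))
  writeLines(lines, path)
  invisible(path)
}
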