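.kmer_cache <- new.env(parent = emptyenv())

# all 4096 6-letter ACGT strings, cached after first use
all_6mers <- function() {
  if (is.null(.kmer_cache$k6))
    .kmer_cache$k6 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
  .kmer_cache$k6
}

# Overlapping 6mer window counts over a DNAStringSet, as a named vector over
# the full 4096-kmer space.
count_6mers <- function(seqs) {
  if (length(seqs) == 0) {
    z <- rep(0L, 4096); names(z) <- all_6mers(); return(z)
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = 6))
  counts[all_6mers()]
}

# Gene-sense flank interval of an exon (0-based half-open genomic coords).
flank_interval <- function(exon, side, flank, chrom_len = Inf) {
  genomic_left <- (side == "upstream") == (exon$strand == "+")
  if (genomic_left) c(max(0, exon$start - flank), exon$start)
  else c(exon$end, min(chrom_len, exon$end + flank))
}

#' Background 6mer frequencies from random exon flanks
#'
#' Randomly selects exons and pools the 6mer composition of their 1 kb
#' gene-sense upstream or downstream flanking sequence into a background
#' frequency table over all 4096 6mers. When fewer exons are annotated than
#' requested they are sampled with replacement (with a message). Flanks are
#' truncated at chromosome ends.
#'
#' @param ann A \code{gene_annotation}.
#' @param seqs \code{DNAStringSet} of chromosome sequences.
#' @param n_exons Number of exons to sample (default 10000).
#' @param side "upstream" or "downstream" of the exon, gene-sense.
#' @param flank Flank width in bp (default 1000).
#' @param seed Integer seed for the exon sample.
#' @return A list with \code{f} (named frequency vector summing to 1),
#'   \code{counts} and \code{total} (total windows).
#' @export
build_background <- function(ann, seqs, n_exons = 10000,
                             side = c("downstream", "upstream"),
                             flank = 1000, seed = 1) {
  side <- match.arg(side)
  ex <- ann$exons
  if (nrow(ex) == 0) stop("annotation has no exons")
  set.seed(seed)
  if (nrow(ex) < n_exons) {
    message("only ", nrow(ex), " exons annotated; sampling with replacement")
    idx <- sample.int(nrow(ex), n_exons, replace = TRUE)
  } else {
    idx <- sample.int(nrow(ex), n_exons)
  }
  picked <- ex[idx, ]
  counts <- extract_and_count(picked, side, flank, seqs)
  total <- sum(counts)
  list(f = counts / total, counts = counts, total = total)
}

extract_and_count <- function(exons, side, flank, seqs) {
  pieces <- list()
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, ]
    L <- length(seqs[[ch]])
    iv <- t(vapply(seq_len(nrow(e)), function(i)
      flank_interval(e[i, ], side, flank, L), numeric(2)))
    ok <- iv[, 2] - iv[, 1] >= 6
    if (!any(ok)) next
    v <- Biostrings::DNAStringSet(
      Biostrings::Views(seqs[[ch]], start = iv[ok, 1] + 1, end = iv[ok, 2]))
    minus <- e$strand[ok] == "-"
    if (any(minus)) v[minus] <- Biostrings::reverseComplement(v[minus])
    pieces[[ch]] <- v
  }
  if (length(pieces) == 0) stop("no flank sequence could be extracted")
  count_6mers(do.call(c, unname(pieces)))
}

#' Extract position/regulation-stratified T-DMR sequences
#'
#' For each classified T-DMR/exon link at an upstream or downstream
#' position, clips the T-DMR to the exon's gene-sense 1 kb flank window and
#' extracts the clipped sequence in gene-sense orientation. Links positioned
#' within the exon are not grouped (motif groups are defined for flanking
#' positions only).
#'
#' @param assignments data.frame from \code{\link{classify_regulation}}.
#' @param tdmrs T-DMR data.frame.
#' @param ann A \code{gene_annotation}.
#' @param seqs \code{DNAStringSet} of chromosomes.
#' @param flank Flank width in bp (default 1000).
#' @return Named list (\code{upstream_positive}, \code{upstream_negative},
#'   \code{downstream_positive}, \code{downstream_negative}); each element
#'   has \code{seqs} (\code{DNAStringSet}) and \code{meta} (data.frame with
#'   tdmr_id, exon_id, chrom, start, end, strand of each clipped piece).
#' @export
motif_groups <- function(assignments, tdmrs, ann, seqs, flank = 1000) {
  keys <- c("upstream_positive", "upstream_negative",
            "downstream_positive", "downstream_negative")
  out <- stats::setNames(vector("list", length(keys)), keys)
  a <- assignments[assignments$position %in% c("upstream", "downstream"), ]
  for (key in keys) {
    parts <- strsplit(key, "_")[[1]]
    rows <- a[a$position == parts[1] & a$regulation == parts[2], ]
    meta <- list(); pieces <- list()
    for (i in seq_len(nrow(rows))) {
      ex <- ann$exons[ann$exons$exon_id == rows$exon_id[i], ]
      td <- tdmrs[tdmrs$tdmr_id == rows$tdmr_id[i], ]
      L <- length(seqs[[ex$chrom]])
      win <- flank_interval(ex, parts[1], flank, L)
      s <- max(td$start, win[1]); e <- min(td$end, win[2])
      if (e - s < 6) next
      piece <- Biostrings::DNAStringSet(Biostrings::subseq(
        seqs[[ex$chrom]], s + 1, e))
      if (ex$strand == "-") piece <- Biostrings::reverseComplement(piece)
      pieces[[length(pieces) + 1]] <- piece
      meta[[length(meta) + 1]] <- data.frame(
        tdmr_id = td$tdmr_id, exon_id = ex$exon_id, chrom = ex$chrom,
        start = s, end = e, strand = ex$strand)
    }
    out[[key]] <- list(
      seqs = if (length(pieces)) do.call(c, pieces)
             else Biostrings::DNAStringSet(),
      meta = if (length(meta)) do.call(rbind, meta)
             else data.frame(tdmr_id = character(0), exon_id = character(0),
                             chrom = character(0), start = numeric(0),
                             end = numeric(0), strand = character(0)))
  }
  out
}

#' Binomial 6mer enrichment of a foreground group against a background
#'
#' Counts overlapping 6mer windows in the group sequences, tests each kmer's
#' count against its background frequency with the upper-tail binomial
#' model, and applies Benjamini-Hochberg correction across all 4096 kmers of
#' the group. Kmers absent from the background but observed in the
#' foreground receive p = 0 and are flagged; an optional pseudocount avoids
#' such infinities on tiny backgrounds.
#'
#' @param group_seqs \code{DNAStringSet} of foreground sequences.
#' @param background Result of \code{\link{build_background}} (or a list
#'   with \code{f}).
#' @param fdr Significance threshold on the q-value (default 0.01).
#' @param pseudocount If TRUE, background frequencies are smoothed by
#'   0.5/total before testing.
#' @return data.frame per kmer: kmer, M, N, f, p_value, q_value,
#'   significant, zero_background.
#' @export
count_and_test <- function(group_seqs, background, fdr = 0.01,
                           pseudocount = FALSE) {
  M <- count_6mers(group_seqs)
  N <- sum(M)
  if (N == 0) stop("foreground group contains no 6mer windows")
  f <- background$f[names(M)]
  if (pseudocount) {
    tot <- if (!is.null(background$total)) background$total else 1 / min(f[f > 0])
    f <- (f * tot + 0.5) / (tot + 0.5 * length(f))
  }
  zero_bg <- f == 0 & M > 0
  p <- binomial_uppertail(M, N, f)
  p[zero_bg] <- 0
  q <- bh_fdr(p)
  data.frame(kmer = names(M), M = as.integer(M), N = N, f = unname(f),
             p_value = unname(p), q_value = unname(q),
             significant = unname(q < fdr), zero_background = unname(zero_bg),
             row.names = NULL)
}

# Role of each kmer at one position: dual if significant in both the
# positive and negative group, else the single significant label, else none.
position_roles <- function(pos_stats, neg_stats) {
  sp <- pos_stats$significant[match(all_6mers(), pos_stats$kmer)]
  sn <- neg_stats$significant[match(all_6mers(), neg_stats$kmer)]
  ifelse(sp & sn, "dual",
         ifelse(sp, "positive", ifelse(sn, "negative", "none")))
}

#' Compare motif regulatory roles between upstream and downstream positions
#'
#' Assigns each 6mer a role at each position (positive, negative, dual or
#' none) from the per-group significance calls, then classifies every kmer
#' significant somewhere: \code{same_role} (identical non-none roles at both
#' positions), \code{one_position_only} (a role at exactly one position) or
#' \code{opposing} (non-none roles that differ, including dual-versus-single
#' mismatches).
#'
#' @param up,down Named lists with elements \code{positive} and
#'   \code{negative}, each a stats data.frame from
#'   \code{\link{count_and_test}}.
#' @return A list with \code{table} (kmer, up_role, down_role, class over
#'   the union) and \code{counts} (n_up, n_down, n_union, n_same,
#'   n_one_position, n_opposing, plus percentages of the union).
#' @export
positional_comparison <- function(up, down) {
  ur <- position_roles(up$positive, up$negative)
  dr <- position_roles(down$positive, down$negative)
  in_union <- ur != "none" | dr != "none"
  ku <- all_6mers()[in_union]
  u <- ur[in_union]; d <- dr[in_union]
  class <- ifelse(u != "none" & d != "none",
                  ifelse(u == d, "same_role", "opposing"),
                  "one_position_only")
  tab <- data.frame(kmer = ku, up_role = u, down_role = d, class = class)
  n_union <- nrow(tab)
  counts <- list(
    n_up = sum(u != "none"), n_down = sum(d != "none"), n_union = n_union,
    n_same = sum(class == "same_role"),
    n_one_position = sum(class == "one_position_only"),
    n_opposing = sum(class == "opposing"),
    pct_same = 100 * sum(class == "same_role") / max(1, n_union),
    pct_one_position = 100 * sum(class == "one_position_only") / max(1, n_union),
    pct_opposing = 100 * sum(class == "opposing") / max(1, n_union))
  list(table = tab, counts = counts)
}

#' CpG content of significant motifs and of T-DMR sequence
#'
#' Four fractions: (a) unique significant 6mers containing CG; (b) all 4096
#' 6mers containing CG; (c) significant-motif instances in the T-DMR
#' sequences containing CG; (d) all 6mer windows in the T-DMR sequences
#' containing CG. Fractions (a) vs (b) and (c) vs (d) are compared with a
#' two-proportion z-test.
#'
#' @param sig_kmers Character vector of significant 6mers.
#' @param tdmr_seqs \code{DNAStringSet} of T-DMR (group) sequences.
#' @return A list with the four fractions (as percentages), the underlying
#'   counts and the two comparison p-values.
#' @export
cpg_content <- function(sig_kmers, tdmr_seqs) {
  kmers <- all_6mers()
  has_cpg <- grepl("CG", kmers, fixed = TRUE)
  n_all_cpg <- sum(has_cpg)
  sig_cpg <- grepl("CG", sig_kmers, fixed = TRUE)
  counts <- count_6mers(tdmr_seqs)
  sig_idx <- kmers %in% sig_kmers
  inst_sig <- sum(counts[sig_idx])
  inst_sig_cpg <- sum(counts[sig_idx & has_cpg])
  inst_all <- sum(counts)
  inst_all_cpg <- sum(counts[has_cpg])
  pa <- if (length(sig_kmers) > 0)
    two_proportion_test(sum(sig_cpg), length(sig_kmers), n_all_cpg,
                        length(kmers))$p_value else NA_real_
  pc <- if (inst_sig > 0 && inst_all > 0)
    two_proportion_test(inst_sig_cpg, inst_sig, inst_all_cpg,
                        inst_all)$p_value else NA_real_
  list(pct_sig_kmers_cpg = 100 * mean(sig_cpg),
       pct_all_kmers_cpg = 100 * n_all_cpg / length(kmers),
       n_all_kmers_cpg = n_all_cpg,
       pct_sig_instances_cpg = 100 * inst_sig_cpg / max(1, inst_sig),
       pct_all_windows_cpg = 100 * inst_all_cpg / max(1, inst_all),
       p_unique = pa, p_instances = pc)
}

# Best ungapped alignment score of two 6mers over shifts -max_shift..max_shift:
# number of matching positions in the overlap.
kmer_similarity <- function(a, b, max_shift = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (s in -max_shift:max_shift) {
    ia <- seq(max(1, 1 + s), min(6, 6 + s))
    ib <- ia - s
    best <- max(best, sum(av[ia] == bv[ib]))
  }
  best
}

# Best shift of b relative to a (ties -> smallest |shift|, then negative).
best_shift <- function(a, b, max_shift = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  shifts <- (-max_shift:max_shift)[order(abs(-max_shift:max_shift),
                                         -max_shift:max_shift)]
  best <- -1; arg <- 0
  for (s in shifts) {
    ia <- seq(max(1, 1 + s), min(6, 6 + s))
    sc <- sum(av[ia] == bv[ia - s])
    if (sc > best) { best <- sc; arg <- s }
  }
  arg
}

iupac_code <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(bases)), collapse = "")
  names(map)[vapply(map, function(x)
    paste(sort(strsplit(x, "")[[1]]), collapse = ""), character(1)) == key]
}

#' Cluster similar 6mers into consensus sequences
#'
#' Hierarchically clusters kmers on their best ungapped alignment similarity
#' (shifts of up to 2 positions), cutting at a fixed dissimilarity, and
#' derives for each cluster an IUPAC consensus and a position-frequency
#' matrix from the shift-aligned members. Deterministic: members align to
#' the alphabetically first kmer of their cluster, ties in shift break
#' toward the smaller absolute shift.
#'
#' @param kmers Character vector of 6mers (duplicates collapse).
#' @param h Dissimilarity cut height (6 - matches; default 2.5 keeps kmers
#'   agreeing in at least 4 aligned positions together).
#' @return data.frame per cluster: cluster, consensus, n_members, members
#'   (comma-separated); the per-cluster PFMs are attached as the
#'   \code{"pfm"} attribute (list of 4 x width probability matrices).
#' @export
cluster_consensus <- function(kmers, h = 2.5) {
  kmers <- sort(unique(kmers))
  if (length(kmers) == 0) stop("no kmers to cluster")
  if (length(kmers) == 1) {
    cl <- 1L
  } else {
    n <- length(kmers)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- 6 - kmer_similarity(kmers[i], kmers[j])
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = h)
  }
  pfms <- list()
  rows <- lapply(sort(unique(cl)), function(k) {
    members <- kmers[cl == k]
    anchor <- members[1]
    shifts <- vapply(members, function(m) best_shift(anchor, m), numeric(1))
    lo <- min(0, shifts); hi <- max(0, shifts) + 5
    width <- hi - lo + 1
    mat <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_along(members)) {
      bases <- strsplit(members[i], "")[[1]]
      cols <- (shifts[i] - lo + 1):(shifts[i] - lo + 6)
      for (j in 1:6) mat[bases[j], cols[j]] <- mat[bases[j], cols[j]] + 1
    }
    pfm <- sweep(mat, 2, pmax(1, colSums(mat)), "/")
    consensus <- paste(vapply(seq_len(width), function(j) {
      col <- mat[, j]
      if (sum(col) == 0) return("N")
      keep <- names(col)[col >= 0.5 * max(col)]
      iupac_code(keep)
    }, character(1)), collapse = "")
    pfms[[length(pfms) + 1]] <<- pfm
    data.frame(cluster = k, consensus = consensus,
               n_members = length(members),
               members = paste(members, collapse = ","))
  })
  out <- do.call(rbind, rows)
  attr(out, "pfm") <- pfms
  out
}

#' Similarity of 6mers to a position-weight matrix
#'
#' Scores each kmer as the maximum over PWM offsets of the mean
#' per-position log2 odds of the kmer's bases against the PWM columns
#' (uniform 0.25 background). Also returns the score distribution over all
#' 4096 6mers and a one-sided rank-sum test that the supplied kmers score
#' higher than the background.
#'
#' @param kmers Character vector of 6mers.
#' @param pwm 4-row probability matrix (rows A, C, G, T), width >= 6.
#' @param pseudo Probability floor applied to PWM entries before logs.
#' @return A list with \code{scores} (kmer, score), \code{background}
#'   (score per 4096 kmers) and \code{p_value}.
#' @export
pwm_similarity <- function(kmers, pwm, pseudo = 1e-3) {
  if (nrow(pwm) != 4) stop("pwm must have 4 rows (A, C, G, T)")
  if (ncol(pwm) < 6) stop("pwm must be at least 6 columns wide")
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm[] <- pmax(pwm, pseudo)
  score_one <- function(kmer) {
    rows <- match(strsplit(kmer, "")[[1]], rownames(pwm))
    max(vapply(0:(ncol(pwm) - 6), function(o) {
      mean(log2(pwm[cbind(rows, o + 1:6)] / 0.25))
    }, numeric(1)))
  }
  bg <- vapply(all_6mers(), score_one, numeric(1))
  sc <- bg[kmers]
  p <- if (length(kmers) > 0)
    stats::wilcox.test(sc, bg, alternative = "greater", exact = FALSE)$p.value
  else NA_real_
  list(scores = data.frame(kmer = kmers, score = unname(sc)),
       background = data.frame(kmer = all_6mers(), score = unname(bg)),
       p_value = p)
}

#' Locate significant-motif instances in group sequences
#'
#' @param group One element of \code{\link{motif_groups}} (list with
#'   \code{seqs} and \code{meta}).
#' @param sig_kmers Character vector of significant 6mers.
#' @return data.frame: kmer, exon_id, tdmr_id, piece (sequence index),
#'   gpos (genomic 0-based start), local (0-based start within the piece)
#'   and piece_len.
#' @export
find_motif_instances <- function(group, sig_kmers) {
  empty <- data.frame(kmer = character(0), exon_id = character(0),
                      tdmr_id = character(0), piece = integer(0),
                      gpos = numeric(0), local = numeric(0),
                      piece_len = numeric(0), strand = character(0))
  if (length(group$seqs) == 0 || length(sig_kmers) == 0) return(empty)
  out <- list()
  chars <- as.character(group$seqs)
  for (i in seq_along(chars)) {
    meta <- group$meta[i, ]
    for (km in sig_kmers) {
      st <- gregexpr(km, chars[i], fixed = TRUE)[[1]]
      st <- st[st > 0]
      if (length(st) == 0) next
      local <- st - 1
      gpos <- if (meta$strand == "-") meta$end - local - 6
              else meta$start + local
      out[[length(out) + 1]] <- data.frame(
        kmer = km, exon_id = meta$exon_id, tdmr_id = meta$tdmr_id,
        piece = i, gpos = gpos, local = local,
        piece_len = nchar(chars[i]), strand = meta$strand)
    }
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Motif-pair distance test against a positional shuffle null
#'
#' Observed pairwise distances are computed between the genomic start
#' positions of significant-motif instances sharing the same AS exon side
#' (instances may sit in different T-DMR pieces flanking that exon). The
#' null repositions every instance uniformly within its own sequence piece
#' and recomputes the distances, \code{n_shuffles} times; the one-sided
#' p-value is the fraction of shuffles whose mean distance is at most the
#' observed mean.
#'
#' @param instances data.frame from \code{\link{find_motif_instances}}.
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed Integer seed.
#' @return A list with \code{observed} (distances), \code{observed_mean},
#'   \code{shuffled_means}, \code{expected_mean}, \code{p_value},
#'   \code{n_pairs} and \code{empty} (TRUE when no co-occurring pair
#'   exists).
#' @export
pair_distance_test <- function(instances, n_shuffles = 100, seed = 1) {
  empty_res <- list(observed = numeric(0), observed_mean = NA_real_,
                    shuffled_means = numeric(0), expected_mean = NA_real_,
                    p_value = NA_real_, n_pairs = 0L, empty = TRUE)
  if (nrow(instances) < 2) return(empty_res)
  grp <- paste(instances$exon_id)
  pair_dists <- function(pos, grp) {
    unlist(lapply(split(pos, grp), function(x) {
      if (length(x) < 2) return(numeric(0))
      as.numeric(stats::dist(x))
    }), use.names = FALSE)
  }
  obs <- pair_dists(instances$gpos, grp)
  if (length(obs) == 0) return(empty_res)
  set.seed(seed)
  # uniform repositioning within each instance's own piece, mapped back to
  # genomic coordinates through the piece's strand frame
  sgn <- if (!is.null(instances$strand))
    ifelse(instances$strand == "-", -1, 1) else rep(1, nrow(instances))
  shuf_means <- vapply(seq_len(n_shuffles), function(i) {
    new_local <- floor(stats::runif(nrow(instances)) *
                         (instances$piece_len - 5))
    new_g <- instances$gpos + (new_local - instances$local) * sgn
    mean(pair_dists(new_g, grp))
  }, numeric(1))
  list(observed = obs, observed_mean = mean(obs),
       shuffled_means = shuf_means, expected_mean = mean(shuf_means),
       p_value = (1 + sum(shuf_means <= mean(obs))) / (n_shuffles + 1),
       n_pairs = length(obs), empty = FALSE)
}
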