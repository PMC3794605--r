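#' Build a conservation track
#'
#' A per-base conservation track holding scores in [0, 1], stored
#' run-length-encoded per chromosome. Positions without a score are NA and
#' are excluded from every denominator.
#'
#' @param scores Named list of numeric \code{Rle} (or numeric vectors), one
#'   per chromosome.
#' @return An object of class \code{cons_track}.
#' @export
cons_track <- function(scores) {
  scores <- lapply(scores, function(s) {
    r <- if (methods::is(s, "Rle")) s else S4Vectors::Rle(s)
    v <- S4Vectors::runValue(r)
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("conservation scores must lie in [0, 1]")
    r
  })
  structure(scores, class = "cons_track")
}

#' @export
print.cons_track <- function(x, ...) {
  cat("cons_track:", length(x), "chromosomes,",
      sum(vapply(x, length, numeric(1))), "bases\n")
  invisible(x)
}

# Pooled per-base scores of a set of intervals (0-based half-open),
# overlapping intervals merged first so no base is double-counted.
interval_scores <- function(intervals, track) {
  out <- numeric(0)
  for (ch in unique(intervals$chrom)) {
    if (!ch %in% names(track)) next
    r <- track[[ch]]
    iv <- intervals[intervals$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end))
    ir <- IRanges::restrict(ir, start = 1, end = length(r))
    if (length(ir) == 0) next
    out <- c(out, as.numeric(unlist(IRanges::extractList(r, ir),
                                    use.names = FALSE)))
  }
  out
}

#' Fraction of conserved nucleotides in an interval set
#'
#' The fraction of bases within the intervals whose conservation score is
#' strictly greater than the cutoff, among bases that have a score. The
#' fraction is pooled over bases, so it is invariant to how the intervals
#' are fragmented.
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param track A \code{\link{cons_track}}.
#' @param cutoff Conservation threshold in [0, 1].
#' @return A list with \code{fraction} (NA when no base is scored, with
#'   \code{defined = FALSE}), \code{n_conserved}, \code{n_scored} and
#'   \code{defined}.
#' @export
fraction_conserved <- function(intervals, track, cutoff) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  sc <- interval_scores(intervals, track)
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0)
    return(list(fraction = NA_real_, n_conserved = 0L, n_scored = 0L,
                defined = FALSE))
  list(fraction = mean(sc > cutoff), n_conserved = sum(sc > cutoff),
       n_scored = length(sc), defined = TRUE)
}

#' Conservation profiles of several interval sets over a cutoff grid
#'
#' Computes the conserved-nucleotide fraction for each named interval set at
#' each cutoff, plus pairwise two-proportion comparisons between sets at
#' each cutoff. Empty sets are omitted.
#'
#' @param interval_sets Named list of interval data.frames.
#' @param track A \code{cons_track}.
#' @param cutoffs Numeric vector of thresholds.
#' @return A list with \code{profile} (set, cutoff, fraction, n_scored) and
#'   \code{comparisons} (set1, set2, cutoff, p_value).
#' @export
conservation_profile <- function(interval_sets, track,
                                 cutoffs = seq(0.1, 0.9, by = 0.2)) {
  interval_sets <- Filter(function(x) nrow(x) > 0, interval_sets)
  if (length(interval_sets) == 0) stop("need at least one non-empty set")
  scored <- lapply(interval_sets, function(iv) {
    sc <- interval_scores(iv, track)
    sc[!is.na(sc)]
  })
  profile <- do.call(rbind, lapply(names(scored), function(nm) {
    data.frame(set = nm, cutoff = cutoffs,
               fraction = vapply(cutoffs, function(cc) mean(scored[[nm]] > cc),
                                 numeric(1)),
               n_scored = length(scored[[nm]]))
  }))
  comparisons <- NULL
  nms <- names(scored)
  if (length(nms) > 1) {
    pairs <- utils::combn(nms, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- scored[[pairs[1, i]]]; b <- scored[[pairs[2, i]]]
      data.frame(set1 = pairs[1, i], set2 = pairs[2, i], cutoff = cutoffs,
                 p_value = vapply(cutoffs, function(cc) {
                   two_proportion_test(sum(a > cc), length(a),
                                       sum(b > cc), length(b))$p_value
                 }, numeric(1)))
    }))
  }
  list(profile = profile, comparisons = comparisons)
}
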